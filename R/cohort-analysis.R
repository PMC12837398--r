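#' @include molevol-stats.R
NULL

#' Fold-difference between the largest and smallest of a set of values
#'
#' Computed both over all values and after dropping named exclusions
#' (outliers are always named explicitly, never detected automatically).
#' Reported to one decimal and as the nearest integer.
#'
#' @param values named (or unnamed) numeric vector of positive values.
#' @param exclusions character vector of names to drop for the filtered
#'   fold.
#' @return list with `fold_all`, `fold_excluded` (each a list with `fold`,
#'   `one_decimal`, `integer`), `argmax`, `argmin`.
#' @export
fold_difference <- function(values, exclusions = character(0)) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(values <= 0)) stop("all values must be positive")
  fmt <- function(v) {
    f <- max(v) / min(v)
    list(fold = f, one_decimal = round(f, 1L), integer = round(f))
  }
  kept <- values[!(names(values) %||% rep("", length(values))) %in% exclusions]
  if (length(kept) < 2L) stop("fewer than 2 values left after exclusions")
  list(fold_all = fmt(values), fold_excluded = fmt(kept),
       argmax = names(values)[which.max(values)] %||% which.max(values),
       argmin = names(values)[which.min(values)] %||% which.min(values))
}

#' Mean dN/dS in diversity bins
#'
#' Populations are binned by nucleotide diversity: low (`pi < low_cut`),
#' medium (`low_cut <= pi <= high_cut`, closed on both ends so boundary
#' values fall in medium) and high (`pi > high_cut`).
#'
#' @param table cohort data.frame with columns `pi` and `dnds`.
#' @param low_cut,high_cut bin boundaries (defaults 0.001 and 0.002).
#' @return data.frame with columns `bin`, `n`, `mean_dnds`, `se` (standard
#'   error of the mean; 0 with `n = 1`, `NA` for an empty bin, with a
#'   warning).
#' @export
bin_by_diversity <- function(table, low_cut = 0.001, high_cut = 0.002) {
  stopifnot(nrow(table) > 0L)
  bin <- ifelse(table$pi < low_cut, "low",
                ifelse(table$pi > high_cut, "high", "medium"))
  out <- do.call(rbind, lapply(c("low", "medium", "high"), function(b) {
    v <- table$dnds[bin == b & !is.na(table$dnds)]
    if (!length(v)) {
      warning("empty diversity bin: ", b, call. = FALSE)
      return(data.frame(bin = b, n = 0L, mean_dnds = NA_real_, se = NA_real_))
    }
    data.frame(bin = b, n = length(v), mean_dnds = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  }))
  out
}

#' Correlation between diversity and mutation load, with a log fit
#'
#' Pearson correlation on raw values; Spearman as Pearson on mid-ranks.
#' Two-sided p-values use the t transform `t = r sqrt((n-2)/(1-r^2))` on
#' n-2 degrees of freedom. A logarithmic curve `y = a + b ln(x)` is fitted
#' by least squares; rows with `x <= 0` are excluded from the fit with a
#' warning.
#'
#' @param x diversity (pi) values.
#' @param y dN/dS values, paired with `x`.
#' @return list of class `correlation_result`: `pearson_r`, `pearson_p`,
#'   `spearman_r`, `spearman_p`, `n`, `log_fit` (list `a`, `b`,
#'   `r_squared`, `n`).
#' @export
correlate <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(pearson_r = NA_real_, pearson_p = NA_real_,
                          spearman_r = NA_real_, spearman_p = NA_real_,
                          n = n, log_fit = NULL, degenerate = TRUE),
                     class = "correlation_result"))
  p_of <- function(r) {
    if (abs(r) >= 1) return(0)
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  pr <- stats::cor(x, y)
  sr <- stats::cor(rank(x), rank(y))
  fit_ok <- x > 0
  if (!all(fit_ok))
    warning(sum(!fit_ok), " zero/negative diversity value(s) excluded ",
            "from the log fit", call. = FALSE)
  lf <- NULL
  if (sum(fit_ok) >= 3L) {
    fm <- stats::lm(y[fit_ok] ~ log(x[fit_ok]))
    lf <- list(a = unname(stats::coef(fm)[1]), b = unname(stats::coef(fm)[2]),
               r_squared = summary(fm)$r.squared, n = sum(fit_ok))
  }
  structure(list(pearson_r = pr, pearson_p = p_of(pr),
                 spearman_r = sr, spearman_p = p_of(sr),
                 n = n, log_fit = lf, degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Pearson r = %.3f (p = %.3g), ",
              x$pearson_r, x$pearson_p))
  cat(sprintf("Spearman r = %.3f (p = %.3g), n = %d\n",
              x$spearman_r, x$spearman_p, x$n))
  if (!is.null(x$log_fit))
    cat(sprintf("  log fit: y = %.4g + %.4g ln(x), R2 = %.3f\n",
                x$log_fit$a, x$log_fit$b, x$log_fit$r_squared))
  invisible(x)
}

.RISK_OF <- c(LC = "low", NT = "medium", VU = "medium",
              EN = "high", CR = "high")

#' Group populations by IUCN extinction-risk category
#'
#' LC maps to the low-risk group, NT and VU to medium, EN and CR to high;
#' DD and NE species are excluded, as are species absent from the status
#' map (with a warning). A species-level status applies to all its
#' populations, and group means weight populations equally.
#'
#' @param table cohort data.frame with columns `species`, `pi`, `dnds`.
#' @param status_map data.frame with columns `species`, `status` (IUCN
#'   codes NE, DD, LC, NT, VU, EN, CR, EW, EX).
#' @return data.frame with one row per group (`group`, `n_populations`,
#'   `n_species`, `mean_pi`, `se_pi`, `mean_dnds`, `se_dnds`).
#' @export
group_by_risk <- function(table, status_map) {
  stopifnot(all(status_map$status %in%
                  c("NE", "DD", "LC", "NT", "VU", "EN", "CR", "EW", "EX")))
  status <- status_map$status[match(table$species, status_map$species)]
  unmapped <- is.na(status)
  if (any(unmapped))
    warning("species without IUCN status excluded: ",
            paste(unique(table$species[unmapped]), collapse = ", "),
            call. = FALSE)
  risk <- .RISK_OF[status]
  out <- do.call(rbind, lapply(c("low", "medium", "high"), function(g) {
    rows <- table[!is.na(risk) & risk == g, , drop = FALSE]
    sem <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
      else if (length(v) == 1L) 0 else NA_real_
    }
    data.frame(group = g, n_populations = nrow(rows),
               n_species = length(unique(rows$species)),
               mean_pi = if (nrow(rows)) mean(rows$pi, na.rm = TRUE)
                         else NA_real_,
               se_pi = sem(rows$pi),
               mean_dnds = if (nrow(rows)) mean(rows$dnds, na.rm = TRUE)
                           else NA_real_,
               se_dnds = sem(rows$dnds))
  }))
  out
}

#' Assemble the cohort table
#'
#' Joins per-population estimates with taxonomy and IUCN status into the
#' one-row-per-population table that all cohort summaries consume.
#'
#' @param stats data.frame with columns `species`, `population`, `n`,
#'   `pi`, `pi_se`, `dnds`, `dnds_se` (one row per population; output of
#'   the stats stage).
#' @param taxonomy data.frame (`species`, `family`).
#' @param status_map optional data.frame (`species`, `status`).
#' @return cohort data.frame with an added `family` and `iucn_status`
#'   column.
#' @export
build_cohort_table <- function(stats, taxonomy = default_taxonomy(),
                               status_map = NULL) {
  stats$family <- taxonomy$family[match(stats$species, taxonomy$species)]
  stats$iucn_status <- if (is.null(status_map)) NA_character_
    else status_map$status[match(stats$species, status_map$species)]
  stats
}

#' Write cohort-level report files
#'
#' Emits machine-readable TSVs (`cohort.tsv`, `risk_groups.tsv`,
#' `correlation.tsv`, `folds.tsv`, `diversity_bins.tsv`) and, optionally,
#' a set of summary plots (diversity and dN/dS bar charts, the
#' diversity-load scatter with its log curve, and risk-group bars).
#'
#' @param table cohort data.frame (see [build_cohort_table()]).
#' @param out_dir output directory.
#' @param status_map optional IUCN status data.frame (`species`,`status`).
#' @param exclude_outliers character vector of `species:population` labels
#'   excluded from the filtered fold-differences.
#' @param plots emit PNG plots (default `FALSE`).
#' @return invisibly, a list of the computed summaries.
#' @export
render_report <- function(table, out_dir, status_map = NULL,
                          exclude_outliers = character(0), plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(table, "cohort.tsv")
  warnings_n <- 0L
  summaries <- list(cohort = table)
  if (nrow(table) == 0L) {
    warning("empty cohort table; emitting headers only", call. = FALSE)
    wtsv(data.frame(group = character(), n_populations = integer(),
                    n_species = integer(), mean_pi = numeric(),
                    se_pi = numeric(), mean_dnds = numeric(),
                    se_dnds = numeric()), "risk_groups.tsv")
    wtsv(data.frame(measure = character(), scope = character(),
                    fold = numeric(), one_decimal = numeric(),
                    integer = integer()), "folds.tsv")
    wtsv(data.frame(statistic = character(), value = numeric()),
         "correlation.tsv")
    wtsv(data.frame(bin = character(), n = integer(), mean_dnds = numeric(),
                    se = numeric()), "diversity_bins.tsv")
    return(invisible(summaries))
  }
  labels <- paste(table$species, table$population, sep = ":")
  folds <- list()
  for (measure in c("pi", "dnds")) {
    v <- stats::setNames(table[[measure]], labels)
    v <- v[!is.na(v) & v > 0]
    if (length(v) >= 2L) {
      f <- fold_difference(v, exclude_outliers)
      folds[[measure]] <- data.frame(
        measure = measure,
        scope = c("all", "outliers_excluded"),
        fold = c(f$fold_all$fold, f$fold_excluded$fold),
        one_decimal = c(f$fold_all$one_decimal, f$fold_excluded$one_decimal),
        integer = c(f$fold_all$integer, f$fold_excluded$integer))
    }
  }
  summaries$folds <- do.call(rbind, folds)
  wtsv(summaries$folds, "folds.tsv")
  ok <- !is.na(table$pi) & !is.na(table$dnds)
  if (sum(ok) >= 3L) {
    cr <- correlate(table$pi[ok], table$dnds[ok])
    summaries$correlation <- cr
    cd <- data.frame(
      statistic = c("pearson_r", "pearson_p", "spearman_r", "spearman_p",
                    "n", "logfit_a", "logfit_b", "logfit_r_squared"),
      value = c(cr$pearson_r, cr$pearson_p, cr$spearman_r, cr$spearman_p,
                cr$n, cr$log_fit$a %||% NA, cr$log_fit$b %||% NA,
                cr$log_fit$r_squared %||% NA))
    wtsv(cd, "correlation.tsv")
  }
  if (any(ok)) {
    summaries$bins <- withCallingHandlers(
      bin_by_diversity(table[ok, , drop = FALSE]),
      warning = function(w) {
        warnings_n <<- warnings_n + 1L; invokeRestart("muffleWarning")
      })
    wtsv(summaries$bins, "diversity_bins.tsv")
  } else {
    warning("no populations with both pi and dN/dS defined; ",
            "bins and correlation skipped", call. = FALSE)
    wtsv(data.frame(bin = character(), n = integer(),
                    mean_dnds = numeric(), se = numeric()),
         "diversity_bins.tsv")
  }
  if (!is.null(status_map)) {
    summaries$risk_groups <- group_by_risk(table, status_map)
    wtsv(summaries$risk_groups, "risk_groups.tsv")
  }
  if (plots) .render_plots(table, summaries, out_dir)
  invisible(summaries)
}

.render_plots <- function(table, summaries, out_dir) {
  png_of <- function(name, expr) {
    grDevices::png(file.path(out_dir, name), width = 900, height = 500)
    on.exit(grDevices::dev.off())
    expr
  }
  labels <- paste(table$species, table$population, sep = "\n")
  png_of("diversity.png", {
    ord <- order(table$pi, decreasing = TRUE)
    graphics::barplot(table$pi[ord], names.arg = labels[ord], las = 2,
                      cex.names = 0.5, ylab = "nucleotide diversity (pi)")
  })
  png_of("dnds.png", {
    ord <- order(table$dnds, decreasing = TRUE)
    graphics::barplot(table$dnds[ord], names.arg = labels[ord], las = 2,
                      cex.names = 0.5, ylab = "dN/dS")
  })
  if (!is.null(summaries$correlation) &&
      !is.null(summaries$correlation$log_fit)) {
    png_of("diversity_vs_dnds.png", {
      graphics::plot(table$pi, table$dnds, log = "x",
                     xlab = "pi (log scale)", ylab = "dN/dS")
      lf <- summaries$correlation$log_fit
      xs <- exp(seq(log(min(table$pi[table$pi > 0])),
                    log(max(table$pi)), length.out = 100))
      graphics::lines(xs, lf$a + lf$b * log(xs), col = "red")
    })
  }
  if (!is.null(summaries$risk_groups)) {
    png_of("risk_groups.png", {
      rg <- summaries$risk_groups
      graphics::barplot(rg$mean_dnds, names.arg = rg$group,
                        ylab = "mean dN/dS")
    })
  }
  invisible(NULL)
}
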