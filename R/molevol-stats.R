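#' @include codon-alignment.R
NULL

# ---- complete deletion ------------------------------------------------------

#' Complete-site deletion in whole-codon units
#'
#' Removes every codon column that contains a gap or a masked/ambiguous
#' codon in any row, so downstream statistics see only columns with clean
#' data for every sequence. The gene boundary map is updated.
#'
#' @param aln a `supergene_alignment` (or any `codon_alignment`-shaped
#'   object with `rows`).
#' @return the same class of object with offending codon columns removed.
#' @export
complete_deletion <- function(aln) {
  codons <- lapply(aln$rows, .split_codons)
  cmat <- do.call(rbind, codons)
  bad_col <- apply(cmat, 2L, function(col) any(grepl("[^ACGT]", col)))
  keep <- which(!bad_col)
  if (!length(keep)) stop("no usable sites after complete deletion")
  aln$rows <- vapply(seq_len(nrow(cmat)), function(i)
    paste(cmat[i, keep], collapse = ""), character(1))
  names(aln$rows) <- rownames(cmat)
  if (!is.null(aln$boundaries)) {
    b <- aln$boundaries
    gene_of_col <- findInterval(3L * (seq_len(ncol(cmat)) - 1L), b$start)
    kept_per_gene <- tabulate(gene_of_col[keep], nbins = nrow(b))
    ends <- cumsum(kept_per_gene * 3L)
    aln$boundaries <- data.frame(gene = b$gene, start = ends - kept_per_gene * 3L,
                                 end = ends)
  }
  aln
}

# ---- codon indexing and lookup tables ---------------------------------------

# alignment rows -> integer codon matrix (n x C), values 1..64 in the
# code's codon order; requires complete deletion (pure sense codons)
.codon_index_matrix <- function(aln, code = genetic_code(2L)) {
  rows <- if (is.list(aln)) aln$rows else aln
  codons <- names(code$map)
  m <- do.call(rbind, lapply(rows, function(r)
    match(.split_codons(r), codons)))
  rownames(m) <- names(rows)
  if (anyNA(m)) stop("alignment contains non-ACGT codons; apply ",
                     "complete_deletion() first")
  m
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# pathway-averaged transition/transversion counts per degeneracy class for
# one ordered codon pair; classification uses the degeneracy class of the
# changed site in each step's source codon
.pathway_counts <- function(a, b, code, degmat) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  dpos <- which(ca != cb)
  acc <- matrix(0, 2L, 3L, dimnames = list(c("ts", "tv"), c("0", "2", "4")))
  if (!length(dpos)) return(acc)
  paths <- .permutations(dpos)
  tally <- function(path) {
    cur <- ca
    m <- matrix(0, 2L, 3L, dimnames = dimnames(acc))
    for (p in path) {
      src <- paste(cur, collapse = "")
      if (code$map[[src]] == "*") return(NULL)  # blocked pathway
      cls <- as.character(degmat[src, p])
      kind <- if (.is_transition(cur[p], cb[p])) "ts" else "tv"
      m[kind, cls] <- m[kind, cls] + 1
      cur[p] <- cb[p]
    }
    m
  }
  counted <- Filter(Negate(is.null), lapply(paths, tally))
  if (!length(counted)) {
    # all pathways pass through a stop: reinstate them all
    counted <- lapply(paths, function(path) {
      cur <- ca
      m <- matrix(0, 2L, 3L, dimnames = dimnames(acc))
      for (p in path) {
        src <- paste(cur, collapse = "")
        # a stop-codon source has no degeneracy class; fall back to the
        # class of that position in the pathway's (sense) target codon
        cls <- if (code$map[[src]] == "*") as.character(degmat[b, p])
               else as.character(degmat[src, p])
        kind <- if (.is_transition(cur[p], cb[p])) "ts" else "tv"
        m[kind, cls] <- m[kind, cls] + 1
        cur[p] <- cb[p]
      }
      m
    })
  }
  Reduce(`+`, counted) / length(counted)
}

# 64x64 lookup tables for pairwise codon comparison, cached per code:
#  $ts0,$ts2,$ts4,$tv0,$tv2,$tv4: direction-averaged fractional counts
#  $ndiff: nucleotide differences; $deg: per-codon site counts (n0,n2,n4)
.pbl_tables <- function(code = genetic_code(2L)) {
  key <- paste0("pbl_", code$table_id)
  if (!is.null(.mitoload_cache[[key]])) return(.mitoload_cache[[key]])
  codons <- names(code$map)
  degmat <- .degeneracy_matrix(code)
  sense <- which(code$map != "*")
  nd <- matrix(0L, 64L, 64L, dimnames = list(codons, codons))
  chars <- do.call(rbind, strsplit(codons, ""))
  for (p in 1:3) nd <- nd + outer(chars[, p], chars[, p], `!=`)
  tabs <- list(ndiff = nd)
  for (nm in c("ts0", "ts2", "ts4", "tv0", "tv2", "tv4"))
    tabs[[nm]] <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  for (i in sense) for (j in sense) {
    if (j < i) next
    fwd <- .pathway_counts(codons[i], codons[j], code, degmat)
    bwd <- .pathway_counts(codons[j], codons[i], code, degmat)
    avg <- (fwd + bwd) / 2
    for (cls in c("0", "2", "4")) {
      tabs[[paste0("ts", cls)]][i, j] <- tabs[[paste0("ts", cls)]][j, i] <-
        avg["ts", cls]
      tabs[[paste0("tv", cls)]][i, j] <- tabs[[paste0("tv", cls)]][j, i] <-
        avg["tv", cls]
    }
  }
  deg <- matrix(0, 64L, 3L, dimnames = list(codons, c("0", "2", "4")))
  for (i in sense) for (p in 1:3) {
    cls <- as.character(degmat[i, p])
    deg[i, cls] <- deg[i, cls] + 1
  }
  deg[setdiff(seq_len(64L), sense), ] <- NA_real_
  tabs$deg <- deg
  .mitoload_cache[[key]] <- tabs
  tabs
}

# ---- pairwise PBL counts ----------------------------------------------------

#' Pairwise site-class counts for the Pamilo-Bianchi-Li estimator
#'
#' Classifies every codon position of a sequence pair as nondegenerate
#' (0-fold), twofold or fourfold degenerate and tallies transitional and
#' transversional differences per class. Site counts `L0`,`L2`,`L4` are
#' averaged over the two sequences. Codon pairs differing at several
#' positions are resolved by enumerating all single-step mutational
#' pathways, discarding pathways passing through stop codons (unless all
#' are blocked, in which case all are reinstated), weighting the survivors
#' equally, and classifying each step at the changed site's degeneracy
#' class in the step's source codon (averaged over the two pathway
#' directions, making the counts symmetric in sequence order).
#'
#' @param row_i,row_j codon-aligned sequences of equal length (complete
#'   deletion applied; pure sense codons).
#' @param code a [genetic_code()] object.
#' @return list with `L0`,`L2`,`L4` (site counts) and `P0`,`P2`,`P4`,
#'   `Q0`,`Q2`,`Q4` (proportions of transitional / transversional
#'   differences per class).
#' @export
pairwise_pbl_counts <- function(row_i, row_j, code = genetic_code(2L)) {
  m <- .codon_index_matrix(c(i = row_i, j = row_j), code)
  tabs <- .pbl_tables(code)
  idx <- cbind(m[1, ], m[2, ])
  L <- (tabs$deg[m[1, ], , drop = FALSE] +
        tabs$deg[m[2, ], , drop = FALSE]) / 2
  Ls <- colSums(L)
  out <- list(L0 = Ls[["0"]], L2 = Ls[["2"]], L4 = Ls[["4"]])
  for (cls in c("0", "2", "4")) {
    ts <- sum(tabs[[paste0("ts", cls)]][idx])
    tv <- sum(tabs[[paste0("tv", cls)]][idx])
    Lk <- Ls[[cls]]
    out[[paste0("P", cls)]] <- if (Lk > 0) ts / Lk else 0
    out[[paste0("Q", cls)]] <- if (Lk > 0) tv / Lk else 0
  }
  out
}

# ---- Kimura two-parameter components ----------------------------------------

#' Kimura two-parameter distance components
#'
#' `A = 1/2 ln(1/(1-2P-Q)) - 1/4 ln(1/(1-2Q))` (transitional distance) and
#' `B = 1/2 ln(1/(1-2Q))` (transversional distance). Saturation (a log
#' argument <= 0) yields `defined = FALSE` rather than an error or a
#' silent zero.
#'
#' @param P proportion of transitional differences.
#' @param Q proportion of transversional differences.
#' @return list with `A`, `B`, `defined`.
#' @export
k2p_components <- function(P, Q) {
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(A = NA_real_, B = NA_real_, defined = FALSE))
  list(A = 0.5 * log(1 / w1) - 0.25 * log(1 / w2),
       B = 0.5 * log(1 / w2), defined = TRUE)
}

#' Pamilo-Bianchi-Li pairwise dN and dS
#'
#' `dN = A0 + (L0 B0 + L2 B2) / (L0 + L2)` and
#' `dS = (L2 A2 + L4 A4) / (L2 + L4) + B4`, where `A_i`, `B_i` are the
#' K2P components of class i. Undefined (with a reason) when a needed
#' component is saturated or a class denominator is zero.
#'
#' @param counts result of [pairwise_pbl_counts()].
#' @return list with `dN`, `dS`, `defined`, `reason`.
#' @export
pbl_pair_distance <- function(counts) {
  with(counts, {
    if (L0 + L2 <= 0)
      return(list(dN = NA_real_, dS = NA_real_, defined = FALSE,
                  reason = "L0+L2 = 0"))
    if (L2 + L4 <= 0)
      return(list(dN = NA_real_, dS = NA_real_, defined = FALSE,
                  reason = "L2+L4 = 0"))
    k0 <- k2p_components(P0, Q0)
    k2 <- k2p_components(P2, Q2)
    k4 <- k2p_components(P4, Q4)
    if (!k0$defined || !k2$defined || !k4$defined)
      return(list(dN = NA_real_, dS = NA_real_, defined = FALSE,
                  reason = "saturated"))
    dN <- k0$A + (L0 * k0$B + L2 * k2$B) / (L0 + L2)
    dS <- (L2 * k2$A + L4 * k4$A) / (L2 + L4) + k4$B
    list(dN = dN, dS = dS, defined = TRUE, reason = NA_character_)
  })
}

# ---- Nei-Li nucleotide diversity --------------------------------------------

# shared resampling scheme: one column-index draw per replicate
.resample_indices <- function(C, reps, seed) {
  with_seed(seed, lapply(seq_len(reps),
                         function(r) sample.int(C, C, replace = TRUE)))
}

#' Nei-Li nucleotide diversity with bootstrap standard error
#'
#' pi is the mean pairwise uncorrected p-distance per site,
#' `pi = 2/(n(n-1)) * sum_{i<j} mismatches(i,j)/sites`. The standard error
#' is the standard deviation of pi across codon-column bootstrap
#' replicates.
#'
#' @param aln a `supergene_alignment` with complete deletion applied.
#' @param reps bootstrap pseudo-replicates (default 1000).
#' @param seed integer seed for resampling.
#' @return list of class `diversity_estimate`: `pi`, `se`, `n_sequences`,
#'   `n_sites_used`, `bootstrap_reps`, `seed`.
#' @export
nei_li_pi <- function(aln, reps = 1000L, seed = 17L) {
  code <- genetic_code(2L)
  m <- .codon_index_matrix(aln, code)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  C <- ncol(m)
  nd <- .pbl_tables(code)$ndiff
  pairs <- utils::combn(n, 2L)
  # per-codon-column nucleotide mismatch counts, one column per pair
  Mdiff <- apply(pairs, 2L, function(p) nd[cbind(m[p[1], ], m[p[2], ])])
  if (is.null(dim(Mdiff))) Mdiff <- matrix(Mdiff, nrow = C)
  pi_hat <- mean(colSums(Mdiff)) / (3 * C)
  se <- 0
  if (reps >= 2L) {
    idx <- .resample_indices(C, reps, seed)
    pis <- vapply(idx, function(ix)
      mean(colSums(Mdiff[ix, , drop = FALSE])) / (3 * C), numeric(1))
    se <- stats::sd(pis)
  }
  structure(list(pi = pi_hat, se = se, n_sequences = n,
                 n_sites_used = 3L * C, bootstrap_reps = reps, seed = seed),
            class = "diversity_estimate")
}

#' Codon-column bootstrap standard error of an alignment statistic
#'
#' Resamples codon columns with replacement (preserving codon structure)
#' and returns the standard deviation of the estimator across replicates.
#'
#' @param aln a `supergene_alignment` (complete deletion applied).
#' @param estimator function taking a resampled alignment and returning a
#'   scalar (`NA` replicates are dropped).
#' @param reps number of pseudo-replicates (>= 2).
#' @param seed integer seed.
#' @return the bootstrap SE (scalar).
#' @export
bootstrap_se <- function(aln, estimator, reps = 1000L, seed = 17L) {
  if (reps < 2L) stop("need at least 2 bootstrap replicates")
  codons <- lapply(aln$rows, .split_codons)
  C <- length(codons[[1]])
  idx <- .resample_indices(C, reps, seed)
  vals <- vapply(idx, function(ix) {
    res <- aln
    res$rows <- vapply(codons, function(cs) paste(cs[ix], collapse = ""),
                       character(1))
    res$boundaries <- NULL
    estimator(res)
  }, numeric(1))
  stats::sd(vals[!is.na(vals)])
}

# ---- population dN/dS -------------------------------------------------------

# per-pair, per-column contribution matrix: columns ordered pair-major as
# (ts0, ts2, ts4, tv0, tv2, tv4, l0, l2, l4)
.pair_contributions <- function(m, tabs) {
  n <- nrow(m)
  pairs <- utils::combn(n, 2L)
  C <- ncol(m)
  np <- ncol(pairs)
  M <- matrix(0, C, 9L * np)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ij <- cbind(m[i, ], m[j, ])
    base <- (p - 1L) * 9L
    M[, base + 1L] <- tabs$ts0[ij]
    M[, base + 2L] <- tabs$ts2[ij]
    M[, base + 3L] <- tabs$ts4[ij]
    M[, base + 4L] <- tabs$tv0[ij]
    M[, base + 5L] <- tabs$tv2[ij]
    M[, base + 6L] <- tabs$tv4[ij]
    L <- (tabs$deg[m[i, ], , drop = FALSE] +
          tabs$deg[m[j, ], , drop = FALSE]) / 2
    M[, base + 7L] <- L[, "0"]
    M[, base + 8L] <- L[, "2"]
    M[, base + 9L] <- L[, "4"]
  }
  list(M = M, n_pairs = np)
}

# vectorized PBL dN/dS from summed contributions S (9 x n_pairs [x reps])
.pbl_from_sums <- function(S) {
  P0 <- S[1, ] / S[7, ]; P2 <- S[2, ] / S[8, ]; P4 <- S[3, ] / S[9, ]
  Q0 <- S[4, ] / S[7, ]; Q2 <- S[5, ] / S[8, ]; Q4 <- S[6, ] / S[9, ]
  P0[S[7, ] == 0] <- 0; Q0[S[7, ] == 0] <- 0
  P2[S[8, ] == 0] <- 0; Q2[S[8, ] == 0] <- 0
  P4[S[9, ] == 0] <- 0; Q4[S[9, ] == 0] <- 0
  safe_log <- function(w) {
    out <- rep(NA_real_, length(w))
    pos <- !is.na(w) & w > 0
    out[pos] <- log(w[pos])
    out
  }
  A_of <- function(P, Q) 0.5 * -safe_log(1 - 2 * P - Q) -
    0.25 * -safe_log(1 - 2 * Q)
  B_of <- function(Q) 0.5 * -safe_log(1 - 2 * Q)
  A0 <- A_of(P0, Q0); B0 <- B_of(Q0)
  A2 <- A_of(P2, Q2); B2 <- B_of(Q2)
  A4 <- A_of(P4, Q4); B4 <- B_of(Q4)
  dN <- A0 + (S[7, ] * B0 + S[8, ] * B2) / (S[7, ] + S[8, ])
  dS <- (S[8, ] * A2 + S[9, ] * A4) / (S[8, ] + S[9, ]) + B4
  list(dN = dN, dS = dS)
}

#' Population dN/dS with bootstrap standard error
#'
#' Pairwise Pamilo-Bianchi-Li `dN` and `dS` are computed for every pair of
#' sequences; the population ratio is the ratio of the pairwise means
#' (ratio of means, not mean of ratios). Saturated pairs are excluded from
#' the means with a reported count. The SE of the ratio is its standard
#' deviation across codon-column bootstrap replicates; replicates with
#' zero mean dS are dropped from the SE (count reported).
#'
#' @param aln a `supergene_alignment` with complete deletion applied.
#' @param reps bootstrap pseudo-replicates (default 1000; 0 skips the SE).
#' @param seed integer seed.
#' @param code a [genetic_code()] object.
#' @return list of class `dnds_estimate`: `dN`, `dS`, `ratio` (`NA` when
#'   `dS` is 0), `se_ratio`, `n_pairs`, `undefined_pairs`,
#'   `dropped_replicates`, `bootstrap_reps`, `seed`.
#' @export
population_dnds <- function(aln, reps = 1000L, seed = 17L,
                            code = genetic_code(2L)) {
  m <- .codon_index_matrix(aln, code)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  tabs <- .pbl_tables(code)
  C <- ncol(m)
  pc <- .pair_contributions(m, tabs)
  S0 <- matrix(colSums(pc$M), nrow = 9L)  # 9 x n_pairs
  est <- .pbl_from_sums(S0)
  ok <- !is.na(est$dN) & !is.na(est$dS)
  if (!any(ok)) stop("all sequence pairs are saturated/undefined")
  dN_bar <- mean(est$dN[ok]); dS_bar <- mean(est$dS[ok])
  ratio <- if (dS_bar > 0) dN_bar / dS_bar else NA_real_
  se <- NA_real_; dropped <- 0L
  if (reps >= 2L) {
    idx <- .resample_indices(C, reps, seed)
    ratios <- numeric(reps)
    chunk <- 100L
    for (start in seq(1L, reps, chunk)) {
      rr <- start:min(start + chunk - 1L, reps)
      W <- vapply(idx[rr], function(ix) tabulate(ix, nbins = C),
                  numeric(C))
      S <- crossprod(pc$M, W)  # (9*np) x |rr|
      dim(S) <- c(9L, pc$n_pairs, length(rr))
      for (q in seq_along(rr)) {
        e <- .pbl_from_sums(matrix(S[, , q], nrow = 9L))
        okr <- !is.na(e$dN) & !is.na(e$dS)
        ratios[rr[q]] <- if (any(okr) && mean(e$dS[okr]) > 0)
          mean(e$dN[okr]) / mean(e$dS[okr]) else NA_real_
      }
    }
    dropped <- sum(is.na(ratios))
    se <- if (sum(!is.na(ratios)) >= 2L) stats::sd(ratios[!is.na(ratios)])
          else NA_real_
  }
  structure(list(dN = dN_bar, dS = dS_bar, ratio = ratio, se_ratio = se,
                 n_pairs = pc$n_pairs, undefined_pairs = sum(!ok),
                 dropped_replicates = dropped, bootstrap_reps = reps,
                 seed = seed),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf(
    "<dnds_estimate> dN = %.5g, dS = %.5g, dN/dS = %.4g (SE %.3g), %d pairs\n",
    x$dN, x$dS, x$ratio, x$se_ratio, x$n_pairs))
  invisible(x)
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate> pi = %.5g (SE %.3g), n = %d, %d sites\n",
              x$pi, x$se, x$n_sequences, x$n_sites_used))
  invisible(x)
}
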