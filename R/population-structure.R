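#' @include codon-alignment.R
NULL

.MISSING_CHARS <- "[^ACGT]"  # gaps, N and other ambiguity codes are missing

#' Extract variable sites from a supergene alignment
#'
#' Scans nucleotide columns and keeps those with at least two distinct
#' non-missing alleles. Gaps, N and other ambiguity codes are treated as
#' missing data, never as alleles. The reference allele is the majority
#' allele (tie: lexicographically smallest); alternates are the remaining
#' observed alleles in lexicographic order.
#'
#' @param supergene a `supergene_alignment` (>= 2 rows).
#' @return object of class `variant_table`: list with `positions` (0-based
#'   supergene columns, ascending), `ref`, `alt` (list of character
#'   vectors), `calls` (records x sites character matrix, `NA` = missing)
#'   and `meta` (species, boundaries).
#' @export
variable_sites <- function(supergene) {
  m <- .aln_matrix(supergene)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  m[grepl(.MISSING_CHARS, m)] <- NA_character_
  keep <- which(apply(m, 2L, function(col)
    length(unique(col[!is.na(col)])) >= 2L))
  calls <- m[, keep, drop = FALSE]
  ref <- character(length(keep)); alt <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    tab <- sort(table(calls[, j]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    ref[j] <- sort(top)[1]
    alt[[j]] <- sort(setdiff(names(tab), ref[j]))
  }
  structure(list(positions = keep - 1L, ref = ref, alt = alt, calls = calls,
                 meta = list(species = supergene$species,
                             boundaries = supergene$boundaries)),
            class = "variant_table")
}

#' Write a variant table as haploid VCF v4.2
#'
#' One record per variable site on contig `supergene`, 1-based positions,
#' haploid GT codes (`0` = ref, `1`,`2`,... = alternates, `.` = missing),
#' multi-allelic sites as comma-separated ALT. Species and gene-boundary
#' metadata are carried in `##META` header lines.
#'
#' @param vt a `variant_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(vt, path) {
  ids <- rownames(vt$calls)
  n_sites <- length(vt$positions)
  total_cols <- if (!is.null(vt$meta$boundaries))
    max(vt$meta$boundaries$end) else max(vt$positions %||% 0) + 1L
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mitoload",
           sprintf("##contig=<ID=supergene,length=%d>", total_cols),
           sprintf("##META=<key=species,value=\"%s\">",
                   vt$meta$species %||% "NA"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">")
  if (!is.null(vt$meta$boundaries)) {
    b <- vt$meta$boundaries
    hdr <- c(hdr, sprintf("##META=<key=gene,value=\"%s:%d-%d\">",
                          b$gene, b$start, b$end))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", ids), collapse = "\t"))
  body <- character(n_sites)
  for (j in seq_len(n_sites)) {
    alleles <- c(vt$ref[j], vt$alt[[j]])
    gt <- match(vt$calls[, j], alleles) - 1L
    gtc <- ifelse(is.na(gt), ".", as.character(gt))
    body[j] <- paste(c("supergene", vt$positions[j] + 1L, ".", vt$ref[j],
                       paste(vt$alt[[j]], collapse = ","), ".", "PASS", ".",
                       "GT", gtc), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a haploid VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return a `variant_table`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  chrom_line <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(chrom_line, "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  species <- sub(".*key=species,value=\"([^\"]*)\".*", "\\1",
                 grep("key=species", hdr, value = TRUE)[1] %||% NA_character_)
  gl <- grep("key=gene", hdr, value = TRUE)
  boundaries <- NULL
  if (length(gl)) {
    v <- sub(".*value=\"([^\"]*)\".*", "\\1", gl)
    gene <- sub(":.*", "", v)
    se <- strsplit(sub(".*:", "", v), "-")
    boundaries <- data.frame(gene = gene,
                             start = as.integer(vapply(se, `[`, "", 1)),
                             end = as.integer(vapply(se, `[`, "", 2)))
  }
  n <- length(body)
  positions <- integer(n); ref <- character(n); alt <- vector("list", n)
  calls <- matrix(NA_character_, length(ids), n, dimnames = list(ids, NULL))
  for (j in seq_len(n)) {
    f <- strsplit(body[j], "\t")[[1]]
    positions[j] <- as.integer(f[2]) - 1L
    ref[j] <- f[4]
    alt[[j]] <- strsplit(f[5], ",")[[1]]
    alleles <- c(ref[j], alt[[j]])
    gt <- suppressWarnings(as.integer(f[-(1:9)]))
    calls[, j] <- ifelse(is.na(gt), NA_character_, alleles[gt + 1L])
  }
  structure(list(positions = positions, ref = ref, alt = alt, calls = calls,
                 meta = list(species = species, boundaries = boundaries)),
            class = "variant_table")
}

#' Identity-by-state distance matrix
#'
#' Pairwise 1-IBS: the proportion of mismatching alleles among variable
#' sites that are non-missing in both records. Pairs with no overlapping
#' sites are set to the matrix maximum with a warning (never `NaN`).
#'
#' @param vt a `variant_table`.
#' @return symmetric distance matrix over record ids (class `matrix`).
#' @export
ibs_distance <- function(vt) {
  calls <- vt$calls
  n <- nrow(calls)
  if (n < 2L) stop("need at least 2 records")
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  overlap0 <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    if (!any(ok)) { d[i, j] <- d[j, i] <- NA_real_; overlap0 <- TRUE; next }
    d[i, j] <- d[j, i] <- mean(calls[i, ok] != calls[j, ok])
  }
  if (overlap0) {
    mx <- max(d, na.rm = TRUE)
    warning("record pair(s) with no overlapping sites; distance set to ",
            "matrix maximum (", mx, ")", call. = FALSE)
    d[is.na(d)] <- mx
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Squares the distances, double-centers (B = -1/2 J D2 J), eigendecomposes
#' and keeps the top-k non-negative eigenvalues; coordinates are
#' eigenvectors scaled by the square root of their eigenvalues. Negative
#' eigenvalues are clamped to zero with a warning; if fewer than `k`
#' positive eigenvalues exist, trailing dimensions are zero-padded and the
#' result flagged (`attr(x, "padded")`).
#'
#' @param D symmetric distance matrix.
#' @param k number of dimensions (default 2).
#' @return object of class `mds_embedding`: list with `points` (n x k,
#'   rownames = record ids) and `eigenvalues` (all n, descending).
#' @export
classical_mds <- function(D, k = 2L) {
  stopifnot(k >= 1L, nrow(D) == ncol(D))
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -1e-9 * max(abs(ev), 1)))
    warning("negative eigenvalues clamped to zero (non-Euclidean distances)",
            call. = FALSE)
  pos <- pmax(ev, 0)
  pos[pos < 1e-12 * max(pos, 1e-300)] <- 0  # numerically-zero eigenvalues
  kk <- min(k, n)
  pts <- e$vectors[, seq_len(kk), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(kk)]), kk)
  padded <- sum(pos > 1e-12) < k
  if (k > n) pts <- cbind(pts, matrix(0, n, k - n))
  rownames(pts) <- rownames(D)
  structure(list(points = pts, eigenvalues = ev),
            class = "mds_embedding", padded = padded)
}

# mean silhouette widths for a labelling over a distance matrix
.silhouette_widths <- function(D, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Assign individuals to populations from an MDS embedding
#'
#' Silhouette-gated k-means replaces the manual curation a human analyst
#' would do on the MDS scatter plot: k-means is run for k = 2..`max_k`
#' (`nstart = 20`, deterministic given `seed`) and the smallest k whose
#' mean silhouette (on Euclidean distances in the embedding) is within
#' `parsimony_margin` of the best is chosen -- the margin guards against
#' splitting tight within-population subclades, which genealogies produce
#' routinely. k = 1 (a single population) is declared when the chosen
#' silhouette falls below `structure_floor`: k-means bisections of a
#' single unstructured Gaussian blob already reach mean silhouettes of
#' about 0.35-0.58 in a 2-D embedding, so the gate for declaring
#' structure must sit above that, while genuinely separated demes score
#' well above 0.7. Under the chosen k, records whose individual
#' silhouette is below `silhouette_floor` sit between clusters and are
#' excluded as putative intermediates (e.g. introgressed genomes). An
#' overrides table wins over all automatic calls.
#'
#' @param emb an `mds_embedding`.
#' @param max_k maximum number of clusters to consider (default 6).
#' @param silhouette_floor per-record silhouette below which a record is
#'   excluded as intermediate (default 0.25).
#' @param structure_floor mean silhouette below which no population
#'   structure is declared (k = 1; default 0.6).
#' @param parsimony_margin silhouette tolerance for preferring fewer
#'   clusters (default 0.1).
#' @param merge_ratio clusters whose centroid separation is below this
#'   fraction of the largest centroid gap are merged (default 0.6); this
#'   absorbs deep within-population clades, which in non-recombining data
#'   cluster as tightly as real demes but sit much closer to their sibling
#'   cluster.
#' @param overrides optional data.frame (`record_id`, `population`);
#'   label `"EXCLUDED"` forces exclusion.
#' @param seed integer seed for k-means.
#' @return object of class `population_assignment`: data.frame with
#'   columns `record_id`, `population` (`"Pop<i>"` or `"EXCLUDED"`),
#'   `silhouette`, `excluded`; attributes `k` and `seed`.
#' @export
assign_populations <- function(emb, max_k = 6L, silhouette_floor = 0.25,
                               structure_floor = 0.6,
                               parsimony_margin = 0.1, merge_ratio = 0.6,
                               overrides = NULL, seed = 17L) {
  pts <- emb$points
  n <- nrow(pts)
  ids <- rownames(pts)
  if (!is.null(overrides)) {
    unknown <- setdiff(overrides$record_id, ids)
    if (length(unknown))
      stop("overrides reference unknown record ids: ",
           paste(unknown, collapse = ", "))
  }
  D <- as.matrix(stats::dist(pts))
  best_k <- 1L; best_sil <- -Inf; best_labels <- rep(1L, n)
  n_distinct <- nrow(unique(round(pts, 12)))
  if (n >= 3L && n_distinct >= 2L) {
    ks <- 2:min(max_k, n - 1L, n_distinct)
    fits <- lapply(ks, function(k)
      with_seed(seed, suppressWarnings(  # Quick-TRANSfer notes are benign
        stats::kmeans(pts, centers = k, nstart = 20L, iter.max = 50L))))
    sils <- vapply(fits, function(km)
      mean(.silhouette_widths(D, km$cluster)), numeric(1))
    pick <- which(sils >= max(sils) - parsimony_margin)[1]
    best_k <- ks[pick]; best_sil <- sils[pick]
    best_labels <- fits[[pick]]$cluster
  }
  if (best_sil < structure_floor) {  # no credible structure at any k
    best_k <- 1L; best_labels <- rep(1L, n); sil <- rep(NA_real_, n)
    excluded <- rep(FALSE, n)
  } else {
    # merge clusters whose centroid separation is small relative to the
    # dominant gap: a deep within-population clade of a non-recombining
    # genome clusters as tightly as a real deme, but sits much closer to
    # its sibling cluster than truly separated demes do
    while (length(unique(best_labels)) > 2L) {
      cent <- do.call(rbind, lapply(unique(best_labels), function(l)
        colMeans(pts[best_labels == l, , drop = FALSE])))
      cd <- as.matrix(stats::dist(cent))
      gaps <- cd[upper.tri(cd)]
      if (min(gaps) >= merge_ratio * max(gaps)) break
      ij <- which(cd == min(gaps) & upper.tri(cd), arr.ind = TRUE)[1, ]
      ls <- unique(best_labels)
      best_labels[best_labels == ls[ij[2]]] <- ls[ij[1]]
    }
    best_k <- length(unique(best_labels))
    sil <- .silhouette_widths(D, best_labels)
    excluded <- sil < silhouette_floor
  }
  # stable labels: clusters numbered by order of first appearance
  relabel <- match(best_labels, unique(best_labels[order(seq_len(n))]))
  pop <- ifelse(excluded, "EXCLUDED", paste0("Pop", relabel))
  if (!is.null(overrides)) {
    idx <- match(overrides$record_id, ids)
    pop[idx] <- overrides$population
    excluded[idx] <- overrides$population == "EXCLUDED"
  }
  out <- data.frame(record_id = ids, population = pop,
                    silhouette = sil, excluded = pop == "EXCLUDED",
                    stringsAsFactors = FALSE)
  structure(out, class = c("population_assignment", "data.frame"),
            k = best_k, seed = seed)
}
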