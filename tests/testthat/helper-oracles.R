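# Independent oracle implementations used to check the package's fast
# paths. These deliberately share no code with the package internals:
# the genetic code comes from Biostrings, loops are naive, and pathway
# enumeration is recursive rather than table-driven.

oracle_code <- function() Biostrings::getGeneticCode("2")

# naive all-pairs mean p-distance
naive_pi <- function(rows) {
  mats <- strsplit(unname(rows), "")
  n <- length(mats)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + mean(mats[[i]] != mats[[j]])
  tot / (n * (n - 1) / 2)
}

# naive 1-IBS over a variant-table call matrix
naive_ibs <- function(calls) {
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (s in seq_len(ncol(calls))) {
      a <- calls[i, s]; b <- calls[j, s]
      if (!is.na(a) && !is.na(b)) { den <- den + 1; num <- num + (a != b) }
    }
    d[i, j] <- if (den > 0) num / den else NA_real_
  }
  d
}

# degeneracy class of a codon position under the Biostrings table-2 code
oracle_degeneracy <- function(codon, pos) {
  gc2 <- oracle_code()
  aa <- gc2[[codon]]
  stopifnot(aa != "*")
  nts <- strsplit(codon, "")[[1]]
  syn <- 0
  for (alt in setdiff(c("A", "C", "G", "T"), nts[pos])) {
    x <- nts; x[pos] <- alt
    if (gc2[[paste(x, collapse = "")]] == aa) syn <- syn + 1
  }
  if (syn == 0) 0L else if (syn == 3) 4L else 2L
}

.oracle_is_ts <- function(a, b)
  paste0(sort(c(a, b)), collapse = "") %in% c("AG", "CT")

# exhaustive enumeration of single-step mutational pathways from codon a
# to codon b (orderings of the differing positions); pathways passing
# through stop codons are discarded unless every pathway is blocked
.oracle_paths_safe <- function(a, b) {
  gc2 <- oracle_code()
  # enumerate orderings of differing positions explicitly, tracking stops
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  dpos <- which(ca != cb)
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (r in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], r)
    out
  }
  walk <- function(order, allow_stops) {
    cur <- ca
    steps <- data.frame(class = integer(0), is_ts = logical(0))
    for (p in order) {
      src <- paste(cur, collapse = "")
      if (gc2[[src]] == "*" && !allow_stops) return(NULL)
      cls <- if (gc2[[src]] == "*") oracle_degeneracy(b, p)
             else oracle_degeneracy(src, p)
      steps <- rbind(steps,
                     data.frame(class = cls, is_ts = .oracle_is_ts(cur[p],
                                                                   cb[p])))
      cur[p] <- cb[p]
    }
    steps
  }
  pp <- perms(dpos)
  paths <- Filter(Negate(is.null), lapply(pp, walk, allow_stops = FALSE))
  if (!length(paths)) paths <- lapply(pp, walk, allow_stops = TRUE)
  paths
}

# oracle for one *directed* codon pair: average fractional ts/tv counts
# per degeneracy class over admissible pathways
oracle_directed_counts <- function(a, b) {
  acc <- matrix(0, 2, 3, dimnames = list(c("ts", "tv"), c("0", "2", "4")))
  if (a == b) return(acc)
  paths <- .oracle_paths_safe(a, b)
  for (df in paths) {
    for (r in seq_len(nrow(df))) {
      kind <- if (df$is_ts[r]) "ts" else "tv"
      cls <- as.character(df$class[r])
      acc[kind, cls] <- acc[kind, cls] + 1 / length(paths)
    }
  }
  acc
}

# oracle replica of pairwise_pbl_counts for two codon strings
oracle_pbl_counts <- function(s1, s2) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- split3(s1); c2 <- split3(s2)
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  cnt <- matrix(0, 2, 3, dimnames = list(c("ts", "tv"), c("0", "2", "4")))
  for (k in seq_along(c1)) {
    for (p in 1:3) {
      cls1 <- as.character(oracle_degeneracy(c1[k], p))
      cls2 <- as.character(oracle_degeneracy(c2[k], p))
      L[cls1] <- L[cls1] + 0.5
      L[cls2] <- L[cls2] + 0.5
    }
    cnt <- cnt + (oracle_directed_counts(c1[k], c2[k]) +
                    oracle_directed_counts(c2[k], c1[k])) / 2
  }
  list(L0 = unname(L["0"]), L2 = unname(L["2"]), L4 = unname(L["4"]),
       P0 = if (L["0"] > 0) unname(cnt["ts", "0"] / L["0"]) else 0,
       Q0 = if (L["0"] > 0) unname(cnt["tv", "0"] / L["0"]) else 0,
       P2 = if (L["2"] > 0) unname(cnt["ts", "2"] / L["2"]) else 0,
       Q2 = if (L["2"] > 0) unname(cnt["tv", "2"] / L["2"]) else 0,
       P4 = if (L["4"] > 0) unname(cnt["ts", "4"] / L["4"]) else 0,
       Q4 = if (L["4"] > 0) unname(cnt["tv", "4"] / L["4"]) else 0)
}

# random alignment rows of pure sense codons with sprinkled differences
random_sense_alignment <- function(n_rows, n_codons, p_mut = 0.02) {
  gc2 <- oracle_code()
  sense <- names(gc2)[gc2 != "*"]
  anc <- sample(sense, n_codons, replace = TRUE)
  rows <- replicate(n_rows, {
    r <- anc
    nm <- rbinom(1, n_codons, p_mut)
    if (nm > 0) {
      at <- sample(n_codons, nm)
      r[at] <- sample(sense, nm, replace = TRUE)
    }
    paste(r, collapse = "")
  })
  names(rows) <- paste0("s", seq_len(n_rows))
  rows
}

# brute-force enumeration of all global alignments of two short sequences
# under BLOSUM62 with affine gaps (open 10, extend 1); returns best score
brute_force_best_alignment <- function(a, b) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- list(score = -Inf)
  gap_cost <- function(lens) sum(vapply(lens, function(l)
    if (l > 0) 10 + (l - 1) * 1 else 0, numeric(1)))
  rec <- function(i, j, rowa, rowb) {
    if (i > length(av) && j > length(bv)) {
      # score the completed alignment
      sc <- 0
      runs_a <- rle(rowb == "-")
      runs_b <- rle(rowa == "-")
      sc <- sc - gap_cost(runs_a$lengths[runs_a$values]) -
        gap_cost(runs_b$lengths[runs_b$values])
      for (k in seq_along(rowa))
        if (rowa[k] != "-" && rowb[k] != "-")
          sc <- sc + S[rowa[k], rowb[k]]
      if (sc > best$score)
        best <<- list(score = sc, a = paste(rowa, collapse = ""),
                      b = paste(rowb, collapse = ""))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, c(rowa, av[i]), c(rowb, bv[j]))
    if (i <= length(av)) rec(i + 1, j, c(rowa, av[i]), c(rowb, "-"))
    if (j <= length(bv)) rec(i, j + 1, c(rowa, "-"), c(rowb, bv[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# small synthetic species dataset built directly from constructed genomes
toy_gene_set <- function(seqs) {
  # seqs: named character vector gene -> CDS (coding sense, no stop)
  offset <- 30L
  feats <- list()
  genome <- strrep("AT", 15L)
  for (g in names(seqs)) {
    s <- paste0(seqs[[g]], "TAA")
    start0 <- nchar(genome)
    if (g == "ND6") {
      genome <- paste0(genome, mitoload::revcomp(s))
      feats[[g]] <- gene_feature(g, c(start0, start0 + nchar(s)), "-", s)
    } else {
      genome <- paste0(genome, s)
      feats[[g]] <- gene_feature(g, c(start0, start0 + nchar(s)), "+", s)
    }
  }
  list(genome = genome, feats = feats)
}

make_toy_genome <- function(record_id, species = "Testocetus unitus",
                            gene_seqs = NULL) {
  if (is.null(gene_seqs)) {
    gene_seqs <- stats::setNames(
      rep("ATGACCATTACA", length(MITO_GENES)), MITO_GENES)
  }
  tg <- toy_gene_set(gene_seqs)
  mitogenome(record_id, species, tg$genome, tg$feats)
}
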