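#' @include mitogenome-io.R genetic-code.R
NULL

# approximate vertebrate mitochondrial gene lengths (codons), used to split
# a total supergene length over the 13 genes realistically
.BASE_GENE_CODONS <- c(ATP6 = 226, ATP8 = 67, COX1 = 516, COX2 = 227,
                       COX3 = 261, CYTB = 379, ND1 = 318, ND2 = 347,
                       ND3 = 115, ND4 = 459, ND4L = 98, ND5 = 606,
                       ND6 = 175)

#' Per-gene codon lengths for the simulator
#'
#' Splits `total_codons` (the 12-gene heavy-strand supergene length)
#' across the 13 genes in proportion to real vertebrate mitochondrial gene
#' lengths.
#'
#' @param total_codons target supergene length in codons (heavy strand
#'   only; ND6 is scaled along but not counted).
#' @return named integer vector of codon counts per gene.
#' @export
gene_lengths <- function(total_codons = 3800L) {
  heavy <- .BASE_GENE_CODONS[HEAVY_STRAND_GENES]
  scale <- total_codons / sum(heavy)
  out <- pmax(10L, as.integer(round(.BASE_GENE_CODONS * scale)))
  stats::setNames(out, names(.BASE_GENE_CODONS))
}

#' Simulation parameters
#'
#' The stated world of the generator: per-site scaled mutation rate
#' `theta` (the product of mutation rate and effective population size,
#' which sets neutral diversity), transition/transversion bias `kappa`,
#' nonsynonymous acceptance probability `omega` (the target dN/dS), and
#' optional two-subpopulation structure with a split `split_depth`
#' coalescent units in the past.
#'
#' @param n_samples individuals per deme (>= 2).
#' @param total_codons supergene length in codons (default 3800, the scale
#'   of a real 12-gene mitochondrial supergene).
#' @param theta per-site scaled mutation rate (default 0.002, the order of
#'   observed cetacean mitogenomic diversities).
#' @param omega nonsynonymous acceptance probability (default 0.1, typical
#'   mitochondrial purifying constraint).
#' @param kappa transition/transversion rate ratio (default 8, typical for
#'   mammalian mtDNA).
#' @param n_demes 1 or 2.
#' @param split_depth deme split time in coalescent units (default 5).
#' @param seed integer seed.
#' @param species synthetic binomial.
#' @param id_prefix record-id prefix.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_samples = 10L, total_codons = 3800L,
                              theta = 0.002, omega = 0.1, kappa = 8,
                              n_demes = 1L, split_depth = 5,
                              seed = 17L, species = "Simulocetus exemplaris",
                              id_prefix = "SIM") {
  stopifnot(theta > 0, omega >= 0, kappa > 0, n_samples >= 2L,
            n_demes %in% 1:2)
  structure(list(n_samples = as.integer(n_samples),
                 gene_codons = gene_lengths(total_codons),
                 theta = theta, omega = omega, kappa = kappa,
                 n_demes = as.integer(n_demes), split_depth = split_depth,
                 seed = as.integer(seed), species = species,
                 id_prefix = id_prefix),
            class = "simulation_params")
}

# coalesce a set of lineages; each lineage is list(node, time); stops at
# `limit` (NULL = run to a single lineage); returns remaining lineages,
# accumulated edges, and the updated node counter
.coalesce <- function(lineages, t, limit, next_node, edges) {
  while (length(lineages) > 1L) {
    k <- length(lineages)
    dt <- stats::rexp(1L, rate = k * (k - 1) / 2)
    if (!is.null(limit) && t + dt > limit) { t <- limit; break }
    t <- t + dt
    pick <- sample.int(k, 2L)
    a <- lineages[[pick[1]]]; b <- lineages[[pick[2]]]
    node <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges,
                   c(node, a$node, t - a$time),
                   c(node, b$node, t - b$time))
    lineages <- c(lineages[-pick], list(list(node = node, time = t)))
  }
  list(lineages = lineages, t = t, next_node = next_node, edges = edges)
}

#' Simulate a coalescent genealogy
#'
#' Standard Kingman coalescent in coalescent units (while k lineages
#' remain, waiting times are exponential with rate k(k-1)/2, so the
#' expected TMRCA of a pair is 1). With `n_demes = 2`, each deme coalesces
#' independently up to `split_depth`, after which the surviving lineages
#' join one ancestral pool.
#'
#' @param n samples per deme.
#' @param n_demes 1 or 2.
#' @param split_depth split time (coalescent units), two-deme case only.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @return an [ape::ape-package] `phylo` tree with tip labels
#'   `t1..t(n*n_demes)` and an attribute `deme` (integer per tip).
#' @export
simulate_genealogy <- function(n, n_demes = 1L, split_depth = 5,
                               seed = NULL) {
  stopifnot(n >= 2L)
  with_seed(seed, {
    ntip <- n * n_demes
    edges <- matrix(numeric(0), ncol = 3L)
    next_node <- ntip + 1L
    if (n_demes == 1L) {
      res <- .coalesce(lapply(seq_len(ntip),
                              function(i) list(node = i, time = 0)),
                       0, NULL, next_node, edges)
    } else {
      surv <- list()
      for (d in 1:2) {
        tips <- ((d - 1L) * n + 1L):(d * n)
        r <- .coalesce(lapply(tips, function(i) list(node = i, time = 0)),
                       0, split_depth, next_node, edges)
        next_node <- r$next_node; edges <- r$edges
        surv <- c(surv, r$lineages)
      }
      res <- .coalesce(surv, split_depth, NULL, next_node, edges)
    }
    edges <- res$edges
    ntotal <- res$next_node - 1L
    # renumber internal nodes so the root is ntip+1 (ape convention)
    remap <- function(x) ifelse(x <= ntip, x, ntip + 1L + (ntotal - x))
    phy <- structure(list(edge = cbind(remap(edges[, 1]), remap(edges[, 2])),
                          edge.length = edges[, 3],
                          tip.label = paste0("t", seq_len(ntip)),
                          Nnode = as.integer(ntotal - ntip)),
                     class = "phylo", order = NULL)
    storage.mode(phy$edge) <- "integer"
    attr(phy, "deme") <- rep(seq_len(n_demes), each = n)
    phy
  })
}

.TS_OF <- c(A = "G", G = "A", C = "T", T = "C")
.TV_OF <- list(A = c("C", "T"), G = c("C", "T"),
               C = c("A", "G"), T = c("A", "G"))

#' Evolve codon sequences along a genealogy
#'
#' Mutations arrive as a Poisson process at rate `theta/2` per site along
#' each branch. Each event picks a site uniformly and an alternative
#' nucleotide with transition:transversion weights `kappa:1`; events that
#' would create a stop codon are rejected and redrawn; nonsynonymous
#' events are accepted with probability `omega` (synonymous always), so
#' the realized dN/dS of the process is approximately `omega`.
#'
#' @param tree a `phylo` genealogy (from [simulate_genealogy()]).
#' @param ancestral ancestral sequence: character string whose length is a
#'   multiple of 3, sense codons only.
#' @param theta per-site scaled mutation rate.
#' @param omega nonsynonymous acceptance probability.
#' @param kappa ts/tv rate ratio.
#' @param code a [genetic_code()] object.
#' @param seed integer seed (`NULL` = current RNG state).
#' @return named character vector of tip sequences.
#' @export
mutate_codons <- function(tree, ancestral, theta, omega, kappa,
                          code = genetic_code(2L), seed = NULL) {
  anc <- strsplit(toupper(ancestral), "")[[1]]
  L <- length(anc)
  stopifnot(L %% 3L == 0L)
  p_ts <- kappa / (kappa + 2)
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- vector("character", ntip)
  with_seed(seed, {
    evolve <- function(seqv, node) {
      if (node <= ntip) { out[node] <<- paste(seqv, collapse = ""); return() }
      for (ei in children[[as.character(node)]]) {
        child <- tree$edge[ei, 2]
        s <- seqv
        n_ev <- stats::rpois(1L, tree$edge.length[ei] * (theta / 2) * L)
        for (ev in seq_len(n_ev)) {
          for (try in 1:100) {
            site <- sample.int(L, 1L)
            cur <- s[site]
            alt <- if (stats::runif(1) < p_ts) .TS_OF[[cur]]
                   else sample(.TV_OF[[cur]], 1L)
            cstart <- site - (site - 1L) %% 3L
            old_codon <- paste(s[cstart:(cstart + 2L)], collapse = "")
            new <- s[cstart:(cstart + 2L)]
            new[site - cstart + 1L] <- alt
            new_codon <- paste(new, collapse = "")
            if (code$map[[new_codon]] == "*") next  # reject stop
            nonsyn <- code$map[[new_codon]] != code$map[[old_codon]]
            if (!nonsyn || stats::runif(1) < omega) s[site] <- alt
            break
          }
        }
        evolve(s, child)
      }
    }
    root <- ntip + 1L
    evolve(anc, root)
  })
  stats::setNames(out, tree$tip.label)
}

#' Sample a random ancestral coding sequence
#'
#' Uniform over sense codons of the code.
#'
#' @param n_codons sequence length in codons.
#' @param code a [genetic_code()] object.
#' @param seed integer seed (`NULL` = current RNG state).
#' @return a single DNA string.
#' @export
random_ancestral_cds <- function(n_codons, code = genetic_code(2L),
                                 seed = NULL) {
  sense <- names(code$map)[code$map != "*"]
  with_seed(seed,
            paste(sample(sense, n_codons, replace = TRUE), collapse = ""))
}

#' Simulate a full dataset with known truth
#'
#' Draws one genealogy, evolves all 13 genes (the 12 heavy-strand genes
#' plus an ND6 decoy that downstream analyses must ignore) along it, and
#' packages the result with its truth record.
#'
#' @param params a [simulation_params()] object.
#' @return object of class `simulated_dataset`: list with `params`,
#'   `genealogy`, `sequences` (per sample: named vector of per-gene
#'   coding-sense CDS, no terminal stop), `deme` (named integer vector)
#'   and `truth` (see [truth_table()]).
#' @export
simulate_dataset <- function(params) {
  code <- genetic_code(2L)
  with_seed(params$seed, {
    tree <- simulate_genealogy(params$n_samples, params$n_demes,
                               params$split_depth, seed = NULL)
    genes <- names(params$gene_codons)
    per_gene <- lapply(genes, function(g) {
      anc <- random_ancestral_cds(params$gene_codons[[g]], code, seed = NULL)
      mutate_codons(tree, anc, params$theta, params$omega, params$kappa,
                    code, seed = NULL)
    })
    names(per_gene) <- genes
    ids <- sprintf("%s%04d", params$id_prefix, seq_len(params$n_samples *
                                                         params$n_demes))
    sequences <- lapply(seq_along(ids), function(i)
      vapply(per_gene, `[[`, character(1), i))
    names(sequences) <- ids
    deme <- stats::setNames(attr(tree, "deme"), ids)
    structure(list(params = params, genealogy = tree, sequences = sequences,
                   deme = deme, truth = truth_table(params)),
              class = "simulated_dataset")
  })
}

#' Truth record for a simulation
#'
#' @param params a [simulation_params()] object.
#' @return data.frame with one row: `theta`, `omega` (the target dN/dS),
#'   `expected_syn_diversity` (theta: the expected pairwise per-site
#'   diversity at neutral sites), `n_demes`, `n_samples`.
#' @export
truth_table <- function(params) {
  data.frame(theta = params$theta, omega = params$omega,
             expected_syn_diversity = params$theta,
             n_demes = params$n_demes, n_samples = params$n_samples)
}

#' Emit a simulated dataset as GenBank flat files
#'
#' Writes one flat file per sample with 13 CDS features: the 12
#' heavy-strand genes on the plus strand and the ND6 decoy on the minus
#' strand (stored reverse-complemented in the genome), each with a TAA
#' terminal stop and 1-based inclusive coordinates. Also writes
#' `truth.tsv` and `params.json`. Files re-read cleanly through
#' [read_flatfiles()].
#'
#' @param ds a `simulated_dataset`.
#' @param out_dir output directory.
#' @return invisibly, the written flat-file paths.
#' @export
emit_flatfiles <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spacer <- strrep("CT", 10L)
  lead <- strrep("TA", 15L)
  genomes <- lapply(names(ds$sequences), function(id) {
    cds <- ds$sequences[[id]]
    feats <- list()
    genome <- lead
    for (g in names(cds)) {
      s <- paste0(cds[[g]], "TAA")
      start0 <- nchar(genome)           # 0-based
      if (g == "ND6") {
        genome <- paste0(genome, revcomp(s))
        strand <- "-"
      } else {
        genome <- paste0(genome, s)
        strand <- "+"
      }
      feats[[g]] <- gene_feature(g, c(start0, start0 + nchar(s)), strand, s)
      genome <- paste0(genome, spacer)
    }
    mitogenome(id, ds$params$species, genome, feats, circular = TRUE)
  })
  paths <- write_flatfiles(genomes, out_dir)
  truth <- ds$truth
  truth_rows <- data.frame(record_id = names(ds$sequences),
                           species = ds$params$species,
                           deme = unname(ds$deme))
  utils::write.table(truth_rows, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(out_dir, "truth_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- ds$params
  jsonlite::write_json(
    list(n_samples = p$n_samples, theta = p$theta, omega = p$omega,
         kappa = p$kappa, n_demes = p$n_demes, split_depth = p$split_depth,
         seed = p$seed, species = p$species,
         gene_codons = as.list(p$gene_codons)),
    file.path(out_dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
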