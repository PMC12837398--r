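#' @include genetic-code.R mitogenome-io.R
NULL

# ---- FASTA helpers ----------------------------------------------------------

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings, returning/accepting plain named character
#' vectors so alignment rows stay simple R strings.
#'
#' @param path file path.
#' @param seqs named character vector.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# ---- protein alignment ------------------------------------------------------

.aa_alphabet <- c("A","R","N","D","C","Q","E","G","H","I","L","K",
                  "M","F","P","S","T","W","Y","V","X")

.blosum62 <- function() {
  if (is.null(.mitoload_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    s <- e$BLOSUM62[.aa_alphabet, .aa_alphabet]
    s["X", ] <- 0; s[, "X"] <- 0  # unknown residues score neutrally
    .mitoload_cache$blosum62 <- s
  }
  .mitoload_cache$blosum62
}

# alignment (character matrix, rows = sequences) -> residue frequency
# profile (length(.aa_alphabet) x ncol); gaps contribute nothing
.profile_of <- function(mat) {
  p <- matrix(0, length(.aa_alphabet), ncol(mat),
              dimnames = list(.aa_alphabet, NULL))
  n <- nrow(mat)
  for (j in seq_len(ncol(mat))) {
    tab <- table(factor(mat[, j], levels = .aa_alphabet))
    p[, j] <- as.numeric(tab) / n
  }
  p
}

.merge_alignments <- function(A, B, gap_open = 10, gap_ext = 1) {
  s <- crossprod(.profile_of(A), .blosum62() %*% .profile_of(B))
  moves <- .nw_path(s, gap_open, gap_ext)
  ncol_out <- length(moves)
  out <- matrix("-", nrow(A) + nrow(B), ncol_out,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  ia <- 0L; ib <- 0L
  for (k in seq_along(moves)) {
    if (moves[k] != 2L) { ia <- ia + 1L; out[seq_len(nrow(A)), k] <- A[, ia] }
    if (moves[k] != 1L) { ib <- ib + 1L;
                          out[nrow(A) + seq_len(nrow(B)), k] <- B[, ib] }
  }
  out
}

.kmer_distance <- function(seqs, k = 3L) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    kk <- min(k, n)
    unique(substring(s, seq_len(n - kk + 1L), seq_len(n - kk + 1L) + kk - 1L))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(km[[i]], km[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / min(length(km[[i]]), length(km[[j]]))
  }
  d
}

#' Align protein sequences
#'
#' Progressive global alignment: pairwise k-mer distances, a UPGMA guide
#' tree, and profile-profile Needleman-Wunsch merges scored with BLOSUM62
#' (gap open -10, gap extend -1). Within-species mitochondrial proteins are
#' near-identical, so this reproduces what a heavier aligner would produce;
#' [import_protein_alignment()] is the escape hatch for externally computed
#' alignments.
#'
#' @param seqs named character vector of amino-acid sequences (>= 2).
#' @param gene canonical gene name (metadata only).
#' @return object of class `protein_alignment`: list with `gene`, `rows`
#'   (named gapped strings) and `ncol`.
#' @export
align_proteins <- function(seqs, gene = NA_character_) {
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  mats <- lapply(seqs, function(s) {
    m <- matrix(strsplit(s, "")[[1]], nrow = 1L)
    m
  })
  for (i in seq_along(mats)) rownames(mats[[i]]) <- names(seqs)[i]
  if (length(seqs) == 2L) {
    merged <- .merge_alignments(mats[[1]], mats[[2]])
  } else {
    d <- .kmer_distance(seqs)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    pick <- function(x) if (x < 0) mats[[-x]] else nodes[[x]]
    for (r in seq_len(nrow(hc$merge)))
      nodes[[r]] <- .merge_alignments(pick(hc$merge[r, 1]),
                                      pick(hc$merge[r, 2]))
    merged <- nodes[[length(nodes)]]
  }
  merged <- merged[names(seqs), , drop = FALSE]  # stable input order
  rows <- apply(merged, 1L, paste, collapse = "")
  structure(list(gene = gene, rows = rows, ncol = ncol(merged)),
            class = "protein_alignment")
}

#' Import an externally computed protein alignment
#'
#' Reads a FASTA alignment and verifies that its record set and degapped
#' rows match the given unaligned sequences exactly.
#'
#' @param path FASTA file of aligned (gapped) protein sequences.
#' @param seqs named character vector of the unaligned input proteins.
#' @param gene canonical gene name (metadata only).
#' @return a `protein_alignment` object.
#' @export
import_protein_alignment <- function(path, seqs, gene = NA_character_) {
  rows <- read_fasta(path)
  extra <- setdiff(names(rows), names(seqs))
  missing <- setdiff(names(seqs), names(rows))
  if (length(extra) || length(missing))
    stop("imported alignment record set mismatch (extra: ",
         paste(extra, collapse = ","), "; missing: ",
         paste(missing, collapse = ","), ")")
  if (length(unique(nchar(rows))) != 1L)
    stop("imported alignment rows have unequal lengths")
  for (id in names(seqs)) {
    if (gsub("-", "", rows[[id]]) != seqs[[id]])
      stop("imported alignment row does not match input sequence for record ",
           id)
  }
  structure(list(gene = gene, rows = rows[names(seqs)],
                 ncol = nchar(rows[[1]])),
            class = "protein_alignment")
}

# ---- codon alignment --------------------------------------------------------

#' Thread nucleotide CDS back onto a protein alignment
#'
#' Each amino-acid column becomes one codon triple; protein gaps become
#' `---`, so codon structure (reading frame) is preserved exactly.
#'
#' @param cds_map named character vector of cleaned CDS (terminal stop and
#'   any trailing partial codon already removed), names matching the
#'   alignment rows.
#' @param prot_aln a `protein_alignment`.
#' @return object of class `codon_alignment`: list with `gene`, `rows`.
#' @export
backtranslate <- function(cds_map, prot_aln) {
  rows <- character(0)
  for (id in names(prot_aln$rows)) {
    if (!id %in% names(cds_map))
      stop("no CDS for record ", id, " (gene ", prot_aln$gene, ")")
    aa <- strsplit(prot_aln$rows[[id]], "")[[1]]
    cds <- cds_map[[id]]
    n_res <- sum(aa != "-")
    if (n_res * 3L != nchar(cds))
      stop("CDS length mismatch for record ", id, " (gene ", prot_aln$gene,
           "): ", nchar(cds), " nt vs ", n_res, " aligned residues")
    codons <- .split_codons(cds)
    out <- rep("---", length(aa))
    out[aa != "-"] <- codons
    rows[[id]] <- paste(out, collapse = "")
  }
  structure(list(gene = prot_aln$gene, rows = rows),
            class = "codon_alignment")
}

#' Mask ambiguous codons
#'
#' Any codon containing `N` or another non-ACGT ambiguity code is replaced
#' by `---` in that row only; column-level exclusion happens later at the
#' complete-deletion step, so rows without the ambiguity keep their data.
#'
#' @param aln a `codon_alignment`.
#' @return a `codon_alignment` with ambiguous codons masked.
#' @export
clean_codons <- function(aln) {
  aln$rows <- vapply(aln$rows, function(r) {
    codons <- .split_codons(r)
    bad <- grepl("[^ACGT-]", codons) |
      (grepl("-", codons) & codons != "---")  # partially gapped -> whole gap
    codons[bad] <- "---"
    paste(codons, collapse = "")
  }, character(1))
  aln
}

#' Concatenate per-gene codon alignments into the 12-gene supergene
#'
#' Genes are concatenated in the fixed canonical order
#' ATP6, ATP8, COX1, COX2, COX3, CYTB, ND1, ND2, ND3, ND4, ND4L, ND5.
#' ND6 (light strand) must not be supplied. All genes must cover the same
#' record set.
#'
#' @param gene_alns named list of 12 `codon_alignment` objects (names =
#'   canonical gene names).
#' @param species species label carried on the result.
#' @return object of class `supergene_alignment`: list with `species`,
#'   `rows` (named strings, sorted by record id) and `boundaries`
#'   (data.frame gene/start/end, 0-based half-open nucleotide columns).
#' @export
concatenate_supergene <- function(gene_alns, species = NA_character_) {
  if (is.null(names(gene_alns)))
    names(gene_alns) <- vapply(gene_alns, `[[`, character(1), "gene")
  if ("ND6" %in% names(gene_alns))
    stop("ND6 is excluded from the supergene (light-strand gene)")
  miss <- setdiff(HEAVY_STRAND_GENES, names(gene_alns))
  if (length(miss))
    stop("missing gene alignments: ", paste(miss, collapse = ", "))
  gene_alns <- gene_alns[HEAVY_STRAND_GENES]
  ids <- sort(names(gene_alns[[1]]$rows))
  for (g in HEAVY_STRAND_GENES) {
    if (!setequal(names(gene_alns[[g]]$rows), ids))
      stop("record set mismatch between genes (", g, ")")
  }
  widths <- vapply(gene_alns, function(a) nchar(a$rows[[1]]), integer(1))
  ends <- cumsum(widths)
  rows <- vapply(ids, function(id)
    paste(vapply(gene_alns, function(a) a$rows[[id]], character(1)),
          collapse = ""), character(1))
  structure(list(species = species, rows = rows,
                 boundaries = data.frame(gene = HEAVY_STRAND_GENES,
                                         start = ends - widths, end = ends)),
            class = "supergene_alignment")
}

#' @export
print.supergene_alignment <- function(x, ...) {
  cat(sprintf("<supergene_alignment> %s: %d sequences x %d nt (%d genes)\n",
              x$species, length(x$rows), nchar(x$rows[[1]]),
              nrow(x$boundaries)))
  invisible(x)
}

# supergene rows as a character matrix (rows = records, cols = nt columns)
.aln_matrix <- function(aln) {
  rows <- if (is.list(aln)) aln$rows else aln
  m <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(m) <- names(rows)
  m
}

#' Prepare a CDS for alignment
#'
#' Trims a trailing partial codon, translates under the code, and strips a
#' single terminal stop from both protein and CDS, keeping the two in
#' register for [backtranslate()].
#'
#' @param cds coding-sense DNA string.
#' @param code a [genetic_code()] object.
#' @return list with `cds` (cleaned) and `protein`.
#' @export
prepare_cds <- function(cds, code = genetic_code(2L)) {
  cds <- toupper(cds)
  over <- nchar(cds) %% 3L
  if (over) cds <- substr(cds, 1L, nchar(cds) - over)
  protein <- suppressWarnings(translate_cds(cds, code))
  list(cds = substr(cds, 1L, nchar(protein) * 3L), protein = protein)
}

#' Write per-gene CDS FASTA files for one species
#'
#' One FASTA per gene (`<gene>.fasta`), records named by genome
#' record id, coding-sense sequences as annotated.
#'
#' @param dataset a `species_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_gene_fastas <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (gene in MITO_GENES) {
    seqs <- vapply(dataset$genomes, function(g)
      if (gene %in% names(g$genes)) g$genes[[gene]]$sequence
      else NA_character_, character(1))
    names(seqs) <- vapply(dataset$genomes, `[[`, character(1), "record_id")
    seqs <- seqs[!is.na(seqs)]
    if (!length(seqs)) next
    paths <- c(paths, write_fasta(seqs, file.path(dir,
                                                  paste0(gene, ".fasta"))))
  }
  invisible(paths)
}

#' Build per-gene codon alignments for one species
#'
#' Runs prepare/align/backtranslate/clean for every heavy-strand gene of a
#' species dataset. Records whose CDS contains an internal stop codon are
#' excluded from the whole dataset with a warning.
#'
#' @param dataset a `species_dataset`.
#' @param code a [genetic_code()] object.
#' @param protein_aln_dir optional directory of externally computed protein
#'   alignments (`<gene>.fasta`), used instead of the internal aligner.
#' @return named list of cleaned `codon_alignment` objects (12 genes).
#' @export
align_species_genes <- function(dataset, code = genetic_code(2L),
                                protein_aln_dir = NULL) {
  ids <- vapply(dataset$genomes, `[[`, character(1), "record_id")
  prepared <- list()
  bad <- character(0)
  for (k in seq_along(dataset$genomes)) {
    g <- dataset$genomes[[k]]
    prepared[[ids[k]]] <- tryCatch(
      lapply(g$genes[HEAVY_STRAND_GENES],
             function(f) prepare_cds(f$sequence, code)),
      mitoload_internal_stop = function(e) {
        warning("record ", g$record_id, " excluded: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  prepared <- Filter(Negate(is.null), prepared)
  if (length(prepared) < 2L)
    stop("fewer than 2 usable genomes for species ", dataset$species)
  alns <- list()
  for (gene in HEAVY_STRAND_GENES) {
    prots <- vapply(prepared, function(p) p[[gene]]$protein, character(1))
    cdss <- vapply(prepared, function(p) p[[gene]]$cds, character(1))
    paln <- if (!is.null(protein_aln_dir)) {
      import_protein_alignment(file.path(protein_aln_dir,
                                         paste0(gene, ".fasta")),
                               prots, gene = gene)
    } else align_proteins(prots, gene = gene)
    alns[[gene]] <- clean_codons(backtranslate(cdss, paln))
  }
  alns
}
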