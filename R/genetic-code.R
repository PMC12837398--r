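#' Genetic code tables
#'
#' Builds a genetic-code object for translation and site-degeneracy
#' classification. The default is NCBI translation table 2 (vertebrate
#' mitochondrial), in which ATA encodes Met, TGA encodes Trp and AGA/AGG
#' are stop codons.
#'
#' @param table_id integer; NCBI translation table (1 = standard,
#'   2 = vertebrate mitochondrial).
#' @return an object of class `genetic_code`: a list with `table_id`,
#'   `map` (named character vector over all 64 codons, `*` = stop),
#'   `stops` (stop codons) and `starts` (initiation codons).
#' @examples
#' code <- genetic_code(2)
#' code$map[["ATA"]]  # "M"
#' @export
genetic_code <- function(table_id = 2L) {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- switch(as.character(table_id),
    "1" = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "2" = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
    stop("unsupported translation table: ", table_id))
  starts <- switch(as.character(table_id),
    "1" = c("TTG", "CTG", "ATG"),
    "2" = c("ATT", "ATC", "ATA", "ATG", "GTG"))
  map <- strsplit(aa, "")[[1]]
  names(map) <- codons
  structure(
    list(table_id = as.integer(table_id), map = map,
         stops = codons[map == "*"], starts = starts),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table", x$table_id,
      "| stops:", paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

.is_pure_codon <- function(codons) !grepl("[^ACGT]", codons)

.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Translates a coding-sense DNA string under the given genetic code.
#' A trailing partial codon of 1-2 nt is trimmed with a warning
#' (mitochondrial stop codons are often completed by polyadenylation, so
#' annotated CDS frequently end mid-codon). Codons containing `N` or any
#' other non-ACGT ambiguity code translate to `X`. A single terminal stop
#' codon is stripped from the result.
#'
#' @param cds DNA string (A/C/G/T plus IUPAC ambiguity codes).
#' @param code a [genetic_code()] object.
#' @return single amino-acid string, one symbol per codon, no terminal stop.
#'   An internal stop codon raises an error of class
#'   `mitoload_internal_stop` (callers exclude such records).
#' @examples
#' translate_cds("ATAACC", genetic_code(2))  # "MT"
#' @export
translate_cds <- function(cds, code = genetic_code(2L)) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  over <- nchar(cds) %% 3L
  if (over != 0L) {
    warning("trimming ", over, " nt trailing partial codon", call. = FALSE)
    cds <- substr(cds, 1L, nchar(cds) - over)
  }
  if (nchar(cds) == 0L) stop("empty sequence after trimming partial codon")
  codons <- .split_codons(cds)
  aa <- rep("X", length(codons))
  pure <- .is_pure_codon(codons)
  aa[pure] <- unname(code$map[codons[pure]])
  if (length(aa) > 1L && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  if (any(aa == "*")) {
    stop(structure(
      class = c("mitoload_internal_stop", "error", "condition"),
      list(message = sprintf("internal stop codon at codon %d",
                             which(aa == "*")[1L]),
           call = NULL)))
  }
  paste(aa, collapse = "")
}

#' Codon site degeneracy
#'
#' Classifies one codon position as 0-, 2- or 4-fold degenerate: the number
#' of the three single-nucleotide alternatives at that position that are
#' sense codons encoding the same amino acid (0 synonymous alternatives =
#' 0-fold, 3 = 4-fold, otherwise 2-fold). Alternatives creating stop codons
#' count as nonsynonymous; a 3-fold-degenerate position (possible under
#' some codes) is binned as 2-fold, following the Li convention.
#'
#' @param codon sense codon (3-mer over ACGT).
#' @param position codon position, 1, 2 or 3.
#' @param code a [genetic_code()] object.
#' @return integer: 0, 2 or 4.
#' @examples
#' site_degeneracy("GGG", 3)  # 4
#' site_degeneracy("TTA", 1)  # 2
#' @export
site_degeneracy <- function(codon, position, code = genetic_code(2L)) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L, position %in% 1:3)
  if (!.is_pure_codon(codon)) stop("ambiguous codon: ", codon)
  aa <- code$map[[codon]]
  if (aa == "*") stop("stop codon has no site degeneracy: ", codon)
  nts <- strsplit(codon, "")[[1]]
  alts <- setdiff(c("A", "C", "G", "T"), nts[position])
  nsyn <- 0L
  for (alt in alts) {
    x <- nts; x[position] <- alt
    if (code$map[[paste(x, collapse = "")]] == aa) nsyn <- nsyn + 1L
  }
  if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
}

# degeneracy class (0/2/4) of every position of every sense codon, cached;
# rows = 64 codons in the code's codon order (NA rows for stops)
.degeneracy_matrix <- function(code) {
  key <- paste0("degmat_", code$table_id)
  if (!is.null(.mitoload_cache[[key]])) return(.mitoload_cache[[key]])
  codons <- names(code$map)
  m <- matrix(NA_integer_, 64L, 3L, dimnames = list(codons, NULL))
  for (cd in codons[code$map != "*"])
    for (p in 1:3) m[cd, p] <- site_degeneracy(cd, p, code)
  .mitoload_cache[[key]] <- m
  m
}

# TRUE if the unordered nucleotide change a<->b is a transition
.is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet (including ambiguity codes).
#'
#' @param x DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
         "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                character(1)))
}
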