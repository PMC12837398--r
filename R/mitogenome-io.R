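#' @include genetic-code.R
NULL

#' Canonical mitochondrial protein-coding gene names
#'
#' The 13 protein-coding genes of the vertebrate mitogenome. All but ND6
#' are encoded on the heavy strand; ND6 is excluded from supergene analyses
#' because its base composition and mutation pattern differ from the other
#' twelve.
#' @export
MITO_GENES <- c("ATP6", "ATP8", "COX1", "COX2", "COX3", "CYTB",
                "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6")

#' The 12 heavy-strand genes, in fixed supergene concatenation order
#' @rdname MITO_GENES
#' @export
HEAVY_STRAND_GENES <- setdiff(MITO_GENES, "ND6")

.gene_synonyms <- function() {
  if (is.null(.mitoload_cache$synonyms)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitoload")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
    .mitoload_cache$synonyms <- stats::setNames(tab$canonical, tab$synonym)
  }
  .mitoload_cache$synonyms
}

#' Normalize a gene or product name to its canonical mitochondrial gene
#'
#' Case-insensitive, punctuation-insensitive lookup covering common
#' annotation synonyms (COI/CO1 for COX1, COB/CYB for CYTB, NADH
#' dehydrogenase subunit product strings, ...). Non-protein features
#' (tRNA, rRNA, D-loop) and unrecognized names map to `NA`.
#'
#' @param raw character vector of raw gene or product strings.
#' @return character vector of canonical names from [MITO_GENES], or `NA`.
#' @examples
#' normalize_gene_name(c("COI", "cytb", "tRNA-Phe"))
#' @export
normalize_gene_name <- function(raw) {
  syn <- .gene_synonyms()
  key <- toupper(gsub("[^A-Za-z0-9]", "", raw))
  out <- unname(syn[key])
  # product-style names: "NADH dehydrogenase subunit 4L", "cytochrome c
  # oxidase subunit II", "ATP synthase F0 subunit 6"
  miss <- which(is.na(out) & !is.na(key) & nzchar(key))
  for (i in miss) {
    k <- key[i]
    out[i] <- if (grepl("^NADHDEHYDROGENASE(SUBUNIT)?(\\d[L]?|[IV]+L?)$", k)) {
      n <- sub("^NADHDEHYDROGENASE(SUBUNIT)?", "", k)
      n <- c(I = "1", II = "2", III = "3", IV = "4", IVL = "4L", V = "5",
             VI = "6")[n] %||% n
      if (paste0("ND", n) %in% MITO_GENES) paste0("ND", n) else NA_character_
    } else if (grepl("^CYTOCHROME[CB]?OXIDASE(SUBUNIT)?(1|2|3|I|II|III)$", k)) {
      n <- sub("^CYTOCHROME[CB]?OXIDASE(SUBUNIT)?", "", k)
      n <- c(I = "1", II = "2", III = "3")[n] %||% n
      paste0("COX", n)
    } else if (grepl("^CYTOCHROMEB$", k)) {
      "CYTB"
    } else if (grepl("^ATP(ASE|SYNTHASE)F?O?0?(SUBUNIT)?([68])$", k)) {
      paste0("ATP", sub(".*([68])$", "\\1", k))
    } else NA_character_
  }
  out
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L) return(b)
  if (length(a) == 1L && is.na(a)) return(b)
  a
}

# ---- domain constructors ----------------------------------------------------

#' Construct a gene feature
#'
#' @param canonical_name one of [MITO_GENES].
#' @param span integer matrix with columns `start`,`end`: 0-based half-open
#'   intervals in genome coordinates, in annotation order.
#' @param strand `"+"` or `"-"`.
#' @param sequence coding-sense nucleotide sequence (5'->3').
#' @return object of class `gene_feature`.
#' @export
gene_feature <- function(canonical_name, span, strand, sequence) {
  stopifnot(canonical_name %in% MITO_GENES, strand %in% c("+", "-"))
  span <- matrix(as.integer(span), ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))
  if (sum(span[, 2] - span[, 1]) != nchar(sequence))
    stop("span length does not match sequence length for ", canonical_name)
  structure(list(canonical_name = canonical_name, span = span,
                 strand = strand, sequence = toupper(sequence)),
            class = "gene_feature")
}

#' Construct an annotated mitogenome
#'
#' @param record_id accession-like identifier.
#' @param species binomial species name.
#' @param sequence full genome sequence (may be `NA` for fixture genomes).
#' @param genes list of [gene_feature()] objects.
#' @param circular logical topology flag.
#' @return object of class `mitogenome`.
#' @export
mitogenome <- function(record_id, species, sequence, genes,
                       circular = TRUE) {
  stopifnot(nzchar(species))
  structure(list(record_id = record_id, species = species,
                 genome_length = if (is.na(sequence[1])) NA_integer_
                                 else nchar(sequence),
                 circular = isTRUE(circular),
                 sequence = sequence, genes = genes),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s (%s), %s bp, %d CDS\n", x$record_id,
              x$species, x$genome_length, length(x$genes)))
  invisible(x)
}

# ---- GenBank flat-file parsing ---------------------------------------------

.parse_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",")[[1]]
  iv <- t(vapply(parts, function(p) {
    ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    ab
  }, integer(2)))
  # 1-based inclusive -> 0-based half-open
  cbind(start = iv[, 1] - 1L, end = iv[, 2])
}

.parse_one_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("no LOCUS line")
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  record_id <- toks[2]
  circular <- any(grepl("circular", locus, ignore.case = TRUE))
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(acc[1]), "\\s+")[[1]]
    if (length(a) >= 2) record_id <- a[2]
  }
  org <- grep("^\\s{2,}ORGANISM", lines, value = TRUE)
  if (!length(org)) stop("no ORGANISM line")
  words <- strsplit(trimws(sub("^\\s*ORGANISM\\s+", "", org[1])), "\\s+")[[1]]
  if (length(words) < 2) stop("organism is not a binomial")
  species <- paste(words[1:2], collapse = " ")  # subspecies collapse

  # sequence
  oi <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(oi)) {
    body <- lines[(oi[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(paste(gsub("[^A-Za-z]", "", body), collapse = ""))
  }
  if (!nzchar(seq)) stop("no sequence in record")

  # feature table
  fi <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fi)) {
    end <- if (length(oi)) oi[1] - 1L else length(lines)
    flines <- lines[(fi[1] + 1L):end]
    keyline <- grepl("^\\s{2,8}\\S", flines) & !grepl("^\\s*/", flines)
    idx <- which(keyline)
    for (j in seq_along(idx)) {
      first <- flines[idx[j]]
      key <- sub("^\\s+(\\S+).*", "\\1", first)
      if (key != "CDS") next
      to <- if (j < length(idx)) idx[j + 1L] - 1L else length(flines)
      block <- flines[idx[j]:to]
      txt <- trimws(block)
      qstart <- grep("^/", txt)[1]
      locend <- if (is.na(qstart)) length(txt) else qstart - 1L
      loc <- paste0(sub("^\\s*CDS\\s*", "", txt[1]),
                    if (locend > 1) paste(txt[2:locend], collapse = "") else "")
      quals <- if (is.na(qstart)) character(0) else txt[qstart:length(txt)]
      getq <- function(name) {
        m <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(m)) return(NA_character_)
        gsub("\"", "", sub(paste0("^/", name, "="), "", m[1]))
      }
      feats[[length(feats) + 1L]] <-
        list(location = loc, gene = getq("gene"), product = getq("product"))
    }
  }
  genes <- list()
  dropped_features <- 0L
  for (f in feats) {
    nm <- normalize_gene_name(f$gene)
    if (is.na(nm)) nm <- normalize_gene_name(f$product)
    if (is.na(nm)) {
      warning("record ", record_id, ": CDS with unrecognizable gene name (",
              f$gene %||% f$product %||% "?", ") dropped", call. = FALSE)
      dropped_features <- dropped_features + 1L
      next
    }
    iv <- .parse_location(f$location)
    pieces <- apply(iv, 1L, function(ab) substr(seq, ab[1] + 1L, ab[2]))
    cds <- paste(pieces, collapse = "")
    strand <- if (grepl("complement", f$location)) "-" else "+"
    if (strand == "-") cds <- revcomp(cds)
    genes[[length(genes) + 1L]] <- gene_feature(nm, iv, strand, cds)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "canonical_name")
  g <- mitogenome(record_id, species, seq, genes, circular)
  attr(g, "dropped_features") <- dropped_features
  g
}

#' Read annotated mitogenomes from GenBank flat files
#'
#' Parses (possibly multi-record, possibly gzipped) GenBank flat files into
#' [mitogenome()] objects. CDS features spanning the circular origin
#' (`join` locations) are stitched in annotation order; minus-strand CDS
#' are reverse-complemented so stored sequences are coding-sense. Records
#' that fail to parse are skipped with a warning and counted in the run
#' report (`attr(x, "report")`).
#'
#' @param paths character vector of `.gb`/`.gbk`(`.gz`) file paths.
#' @return list of `mitogenome` objects, with a `report` attribute
#'   (data.frame of per-stage counts).
#' @export
read_flatfiles <- function(paths) {
  genomes <- list()
  skipped <- 0L
  for (path in paths) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    lines <- readLines(con, warn = FALSE)
    close(con)
    ends <- grep("^//", lines)
    if (!length(ends)) ends <- length(lines)
    begin <- 1L
    for (e in ends) {
      rec <- lines[begin:e]
      begin <- e + 1L
      if (!any(grepl("^LOCUS", rec))) next
      g <- tryCatch(.parse_one_record(rec), error = function(err) {
        warning("skipping unparseable record in ", basename(path), ": ",
                conditionMessage(err), call. = FALSE)
        NULL
      })
      if (is.null(g)) skipped <- skipped + 1L
      else genomes[[length(genomes) + 1L]] <- g
    }
  }
  attr(genomes, "report") <- data.frame(
    stage = c("parsed", "skipped_records"),
    n = c(length(genomes), skipped))
  genomes
}

# ---- GenBank flat-file writing ---------------------------------------------

.format_location <- function(feat) {
  iv <- feat$span
  parts <- sprintf("%d..%d", iv[, 1] + 1L, iv[, 2])
  loc <- if (nrow(iv) > 1L) paste0("join(", paste(parts, collapse = ","), ")")
         else parts
  if (feat$strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write mitogenomes as GenBank flat files
#'
#' Emits one flat file per genome (`<record_id>.gb`) containing the source
#' feature and one CDS feature per gene, with 1-based inclusive
#' coordinates. Round-trips through [read_flatfiles()].
#'
#' @param genomes list of [mitogenome()] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_flatfiles <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in genomes) {
    out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s MAM 01-JAN-2026",
                     g$record_id, g$genome_length,
                     if (g$circular) "circular" else "linear  "),
             sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     g$species),
             sprintf("ACCESSION   %s", g$record_id),
             sprintf("SOURCE      mitochondrion %s", g$species),
             sprintf("  ORGANISM  %s", g$species),
             "            Eukaryota; Metazoa; Chordata; Mammalia; Cetacea.",
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", g$genome_length),
             sprintf("                     /organism=\"%s\"", g$species),
             "                     /organelle=\"mitochondrion\"")
    for (f in g$genes) {
      out <- c(out,
               sprintf("     CDS             %s", .format_location(f)),
               sprintf("                     /gene=\"%s\"", f$canonical_name),
               "                     /transl_table=2")
    }
    out <- c(out, "ORIGIN")
    s <- tolower(g$sequence)
    starts <- seq(1L, nchar(s), 60L)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59L, nchar(s)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
    }
    out <- c(out, "//")
    path <- file.path(dir, paste0(g$record_id, ".gb"))
    writeLines(out, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# ---- filters ----------------------------------------------------------------

# resolve duplicate CDS annotations for one canonical gene: keep the longest
# feature, ties broken by annotation order
.resolve_duplicates <- function(g) {
  nms <- names(g$genes)
  if (!anyDuplicated(nms)) return(g)
  keep <- logical(length(nms))
  for (nm in unique(nms)) {
    idx <- which(nms == nm)
    if (length(idx) > 1L) {
      lens <- vapply(g$genes[idx], function(f) nchar(f$sequence), integer(1))
      warning("record ", g$record_id, ": duplicate ", nm,
              " annotations; keeping the longest", call. = FALSE)
      idx <- idx[which.max(lens)]
    }
    keep[idx] <- TRUE
  }
  g$genes <- g$genes[keep]
  g
}

#' Keep only genomes with all 13 protein-coding genes
#'
#' Duplicate annotations of one gene are first resolved to the longest
#' feature (tie: first in annotation order), with a warning.
#'
#' @param genomes list of [mitogenome()] objects.
#' @return list with elements `kept` and `dropped`.
#' @export
filter_complete_genomes <- function(genomes) {
  genomes <- lapply(genomes, .resolve_duplicates)
  ok <- vapply(genomes, function(g) all(MITO_GENES %in% names(g$genes)),
               logical(1))
  list(kept = genomes[ok], dropped = genomes[!ok])
}

#' Group genomes into species datasets
#'
#' @param genomes list of [mitogenome()] objects.
#' @param taxonomy optional data.frame with columns `species`, `family`
#'   (defaults to the packaged cetacean taxonomy table).
#' @return list of `species_dataset` objects (species, genomes, family).
#' @export
species_datasets <- function(genomes, taxonomy = default_taxonomy()) {
  sp <- vapply(genomes, `[[`, character(1), "species")
  lapply(split(genomes, sp), function(gs) {
    s <- gs[[1]]$species
    fam <- taxonomy$family[match(s, taxonomy$species)]
    structure(list(species = s, genomes = gs,
                   family = if (length(fam)) fam else NA_character_),
              class = "species_dataset")
  })
}

#' Packaged cetacean taxonomy table (species -> family)
#'
#' @return data.frame with columns `species` and `family`.
#' @export
default_taxonomy <- function() {
  utils::read.delim(system.file("extdata", "cetacean_taxonomy.tsv",
                                package = "mitoload"),
                    stringsAsFactors = FALSE)
}

#' Exclude species with fewer than `min_n` genomes
#'
#' Applied after the completeness filter, mirroring the filtering order of
#' the source dataset (min-sample exclusion, then completeness check).
#'
#' @param datasets list of `species_dataset` objects.
#' @param min_n minimum number of genomes per species (default 5, inclusive).
#' @return list with elements `kept` and `dropped`.
#' @export
filter_min_sample <- function(datasets, min_n = 5L) {
  ok <- vapply(datasets, function(d) length(d$genomes) >= min_n, logical(1))
  list(kept = datasets[ok], dropped = datasets[!ok])
}
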