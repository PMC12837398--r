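#' @include population-structure.R molevol-stats.R cohort-analysis.R
NULL

#' Run the full analysis pipeline on a directory of flat files
#'
#' extract -> align -> structure -> stats -> cohort. For each species
#' passing the inclusion filters (all 13 protein-CDS present, at least
#' `min_genomes` genomes), builds the 12-gene supergene, delineates
#' populations via MDS + silhouette-gated k-means over identity-by-state
#' distances at variable sites, and computes per-population Nei-Li
#' diversity and Pamilo-Bianchi-Li dN/dS with bootstrap SEs. All outputs
#' are plain TSV/FASTA/VCF and deterministic given `seed`.
#'
#' @param in_dir directory of `.gb`/`.gbk`(`.gz`) flat files.
#' @param out_dir output directory.
#' @param min_genomes minimum genomes per species (default 5).
#' @param reps bootstrap pseudo-replicates (default 1000).
#' @param seed integer seed driving k-means and the bootstrap.
#' @param max_k,silhouette_floor clustering controls
#'   (see [assign_populations()]).
#' @param taxonomy taxonomy data.frame (`species`, `family`).
#' @param status_map optional IUCN status data.frame (`species`,
#'   `status`).
#' @param overrides optional population override data.frame
#'   (`record_id`, `population`).
#' @param protein_aln_dir optional directory of external protein
#'   alignments, per species subdirectory.
#' @return invisibly, a list with `stats` (per-population data.frame),
#'   `assignments`, `summaries` and `report` (filter-stage counts).
#' @export
run_pipeline <- function(in_dir, out_dir, min_genomes = 5L, reps = 1000L,
                         seed = 17L, max_k = 6L, silhouette_floor = 0.25,
                         taxonomy = default_taxonomy(), status_map = NULL,
                         overrides = NULL, protein_aln_dir = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list.files(in_dir, pattern = "\\.(gb|gbk)(\\.gz)?$",
                      full.names = TRUE)
  genomes <- read_flatfiles(sort(paths))
  n_parsed <- length(genomes)
  cg <- filter_complete_genomes(genomes)
  ds <- species_datasets(cg$kept, taxonomy)
  ms <- filter_min_sample(ds, min_genomes)
  report <- data.frame(
    stage = c("parsed", "complete_13cds", "min_sample_species",
              "final_genomes"),
    n = c(n_parsed, length(cg$kept), length(ms$kept),
          sum(vapply(ms$kept, function(d) length(d$genomes), integer(1)))))
  utils::write.table(report, file.path(out_dir, "run_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stats_rows <- list()
  assignments <- list()
  for (d in ms$kept) {
    sp_dir <- file.path(out_dir, gsub(" ", "_", d$species))
    dir.create(sp_dir, showWarnings = FALSE)
    write_gene_fastas(d, file.path(sp_dir, "genes"))
    alns <- align_species_genes(d, protein_aln_dir = if (!is.null(protein_aln_dir))
      file.path(protein_aln_dir, gsub(" ", "_", d$species)) else NULL)
    sg <- concatenate_supergene(alns, species = d$species)
    write_fasta(sg$rows, file.path(sp_dir, "supergene.fasta"))
    vt <- variable_sites(sg)
    write_vcf(vt, file.path(sp_dir, "variants.vcf"))
    if (length(vt$positions) == 0L) {
      asg <- data.frame(record_id = names(sg$rows), population = "Pop1",
                        silhouette = NA_real_, excluded = FALSE)
      attr(asg, "k") <- 1L
    } else {
      D <- ibs_distance(vt)
      emb <- classical_mds(D, k = 2L)
      utils::write.table(
        data.frame(record_id = rownames(emb$points),
                   mds1 = round(emb$points[, 1], 10),
                   mds2 = round(emb$points[, 2], 10)),
        file.path(sp_dir, "embedding.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      asg <- assign_populations(emb, max_k = max_k,
                                silhouette_floor = silhouette_floor,
                                overrides = if (!is.null(overrides))
                                  overrides[overrides$record_id %in%
                                              rownames(emb$points), ,
                                            drop = FALSE] else NULL,
                                seed = seed)
    }
    asg$species <- d$species
    utils::write.table(
      data.frame(record_id = asg$record_id, species = asg$species,
                 population = asg$population,
                 silhouette = round(asg$silhouette, 10),
                 excluded = asg$excluded),
      file.path(sp_dir, "populations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    assignments[[d$species]] <- asg
    for (pop in setdiff(unique(asg$population), "EXCLUDED")) {
      ids <- asg$record_id[asg$population == pop]
      if (length(ids) < 2L) {
        warning(d$species, " ", pop, ": fewer than 2 genomes, skipped",
                call. = FALSE)
        next
      }
      sub <- sg
      sub$rows <- sg$rows[ids]
      sub <- complete_deletion(sub)
      div <- nei_li_pi(sub, reps = reps, seed = seed)
      dnds <- population_dnds(sub, reps = reps, seed = seed)
      stats_rows[[paste(d$species, pop)]] <- data.frame(
        species = d$species, population = pop, n = length(ids),
        sites_used = div$n_sites_used,
        pi = div$pi, pi_se = div$se,
        dN = dnds$dN, dS = dnds$dS,
        dnds = dnds$ratio, dnds_se = dnds$se_ratio,
        undefined_pairs = dnds$undefined_pairs,
        bootstrap_reps = reps, seed = seed)
    }
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL
  num <- vapply(stats, is.numeric, logical(1))
  stats[num] <- lapply(stats[num], function(x) round(x, 10))
  utils::write.table(stats, file.path(out_dir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cohort <- build_cohort_table(stats, taxonomy, status_map)
  summaries <- render_report(cohort, out_dir, status_map = status_map)
  invisible(list(stats = stats, assignments = assignments,
                 summaries = summaries, report = report))
}
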