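# mitoload

Population-level diversity and deleterious-mutation load from annotated
mitochondrial genomes.

## The problem

Within-population genetic diversity and the fraction of segregating
deleterious mutations are the two classic genomic read-outs of effective
population size (N<sub>e</sub>): diversity scales with the product
μ·N<sub>e</sub>, while purifying selection removes amino-acid-changing
variants less efficiently when N<sub>e</sub> is small. For non-recombining
mitochondrial genomes both quantities can be estimated from modest samples
of complete mitogenomes, which makes them attractive indicators for
conservation genetics of taxa — such as whales, dolphins and porpoises —
where thousands of assembled mitogenomes exist but nuclear data are
scarce.

`mitoload` implements the full desk pipeline from annotated GenBank-style
flat files to cohort-level summaries:

1. **Extraction & filtering** — parse flat files, normalize gene names,
   keep genomes carrying all 13 protein-CDS, keep species with ≥ 5
   genomes (`read_flatfiles()`, `filter_complete_genomes()`,
   `filter_min_sample()`).
2. **Codon alignment** — translate under the vertebrate mitochondrial
   code (table 2), align proteins (progressive profile Needleman–Wunsch,
   BLOSUM62, −10/−1; or import an external alignment), thread nucleotides
   back codon-by-codon, mask ambiguous codons, and concatenate the 12
   heavy-strand genes (ATP6 … ND5; ND6 is excluded) into a supergene
   (`align_species_genes()`, `concatenate_supergene()`).
3. **Population structure** — variable sites → haploid VCF, 1−IBS
   distances, classical (Torgerson) MDS, silhouette-gated k-means with
   exclusion of intermediate genomes, plus a plain-text override table
   (`variable_sites()`, `write_vcf()`, `classical_mds()`,
   `assign_populations()`).
4. **Statistics** — per population, after complete-site deletion in
   whole-codon units:
   - Nei–Li nucleotide diversity
     π = 2/(n(n−1)) · Σ<sub>i&lt;j</sub> d<sub>ij</sub>/L (uncorrected
     p-distance);
   - Pamilo–Bianchi–Li dN and dS from per-class (0-, 2-, 4-fold
     degenerate) transition/transversion proportions P<sub>i</sub>,
     Q<sub>i</sub> with Kimura two-parameter components
     A<sub>i</sub> = ½ln(1/(1−2P<sub>i</sub>−Q<sub>i</sub>)) −
     ¼ln(1/(1−2Q<sub>i</sub>)), B<sub>i</sub> = ½ln(1/(1−2Q<sub>i</sub>)):
     dN = A₀ + (L₀B₀ + L₂B₂)/(L₀+L₂),
     dS = (L₂A₂ + L₄A₄)/(L₂+L₄) + B₄;
   - codon-column bootstrap standard errors (1000 pseudo-replicates)
     (`nei_li_pi()`, `population_dnds()`, `bootstrap_se()`).
5. **Cohort summaries** — fold-differences, diversity bins
   (<0.001 / 0.001–0.002 / >0.002), Pearson/Spearman correlation between
   π and dN/dS with a log-curve fit, and IUCN risk groups
   (LC = low, NT+VU = medium, EN+CR = high; DD/NE excluded)
   (`fold_difference()`, `bin_by_diversity()`, `correlate()`,
   `group_by_risk()`, `render_report()`).
6. **Synthetic data** — a Kingman-coalescent codon simulator with per-site
   θ, ts/tv bias κ, nonsynonymous acceptance probability ω (the target
   dN/dS) and optional two-deme structure, emitted as GenBank-style flat
   files so the whole pipeline can be exercised with known truth and no
   downloads (`simulation_params()`, `simulate_dataset()`,
   `emit_flatfiles()`).

## Worked example

Simulate two demes of 8 genomes (1200-codon supergene, θ = 0.004,
ω = 0.1, split 5 coalescent units ago), emit flat files, and run the full
pipeline:

```r
library(mitoload)
dir <- tempfile(); dir.create(dir)
ds <- simulate_dataset(simulation_params(
  n_samples = 8, total_codons = 1200, theta = 0.004, omega = 0.1,
  n_demes = 2, split_depth = 5, seed = 1))
emit_flatfiles(ds, dir)
res <- run_pipeline(dir, file.path(dir, "out"), reps = 1000, seed = 7,
  taxonomy  = data.frame(species = "Simulocetus exemplaris",
                         family  = "Simulocetidae"),
  status_map = data.frame(species = "Simulocetus exemplaris",
                          status  = "LC"))
res$stats[, c("species", "population", "n", "pi", "pi_se",
              "dnds", "dnds_se")]
```

prints

```
                 species population n      pi    pi_se   dnds dnds_se
1 Simulocetus exemplaris       Pop1 8 0.00225 0.000525 0.0706  0.0547
2 Simulocetus exemplaris       Pop2 8 0.00151 0.000403 0.1046  0.0932
```

Both planted demes are recovered (8 + 8 genomes, no intermediates), the
per-population diversities are of order θ (0.0015–0.0023 vs θ = 0.004 —
within-deme coalescent times average well below the two expected for a
panmictic sample of this genealogy), and both dN/dS point estimates
bracket the simulated ω = 0.1; the bootstrap SEs show how noisy a
single-population ratio is at this sequence length. `out/` additionally
contains the per-species supergene FASTA, variants VCF, MDS embedding,
population assignment TSV and the cohort-level TSVs (folds, bins,
correlation, risk groups).

## Command line

```sh
Rscript inst/cli/mitoload.R simulate --out sim --n 10 --codons 3800 \
        --theta 0.002 --omega 0.1 --kappa 8 --demes 2 --split 5 --seed 17
Rscript inst/cli/mitoload.R run --in sim --out results --reps 1000 --seed 17
```
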