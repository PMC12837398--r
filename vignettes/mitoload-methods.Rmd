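---
title: "Methods and design notes for mitoload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitoload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitoload` estimates two population-genetic quantities from complete
mitochondrial genomes — Nei–Li nucleotide diversity (π) and the
Pamilo–Bianchi–Li ratio of nonsynonymous to synonymous diversity
(dN/dS) — and the machinery around them: extraction from annotated flat
files, codon-faithful alignment, population delineation, bootstrap
uncertainty, cohort summaries, and a coalescent simulator that provides
ground truth for everything upstream. This vignette records the models,
the tunable parameters and the design decisions, so a maintainer can see
*why* the code is the way it is, and what a passing test suite does and
does not establish.

## 1. The estimators

**Nucleotide diversity.** π is the mean pairwise proportion of differing
sites, `2/(n(n-1)) * sum_{i<j} d_ij / L`, computed after complete-site
deletion. We deliberately use the uncorrected p-distance: mitogenomic
within-population diversities are of order 10⁻⁴–10⁻², where any
substitution-model correction changes the value far below its bootstrap
SE. This is a documented divergence risk if results are compared against
model-corrected software output.

**dN/dS.** Each codon position of each sequence is classified as 0-, 2-
or 4-fold degenerate by counting, under the vertebrate mitochondrial code
(translation table 2), how many of the three single-nucleotide
alternatives at that position encode the same amino acid; changes to stop
codons count as nonsynonymous, and (for exotic codes) 3-fold sites are
binned as 2-fold, following the Li convention. For a sequence pair the
class site counts L₀, L₂, L₄ are averaged over the two sequences. Codon
pairs differing at m > 1 positions are resolved by enumerating all m!
single-step pathways; pathways passing through a stop codon are
discarded (all are reinstated if every pathway is blocked — a degenerate
blockage must not void the pair); survivors are weighted equally. Each
step is classified transition/transversion at the degeneracy class of the
changed site *in the step's source codon*. Because that rule is
direction-dependent, counts are averaged over the two pathway directions,
which makes the estimator exactly symmetric in sequence order (a tested
invariant). In the reinstated (all-blocked) case a step whose source
codon is a stop has no degeneracy class; we classify it at that
position's class in the pathway's sense target codon.

From the per-class proportions of transitions Pᵢ and transversions Qᵢ the
Kimura two-parameter components are
`A_i = ½ ln(1/(1-2P_i-Q_i)) - ¼ ln(1/(1-2Q_i))` and
`B_i = ½ ln(1/(1-2Q_i))`; saturation (a non-positive log argument) is a
flagged value, never a silent zero, and saturated pairs are excluded from
population means with a reported count. The pair distances are
`dN = A0 + (L0 B0 + L2 B2)/(L0+L2)` and
`dS = (L2 A2 + L4 A4)/(L2+L4) + B4`.

**Ratio of means.** The population ratio is mean(dN)/mean(dS) over
defined pairs, not the mean of pairwise ratios: pairwise dS is frequently
zero or tiny within populations, and the ratio of means matches the
within-group mean-distance semantics of the standard desktop software for
this analysis. A population of identical sequences reports the ratio as
missing (dS = 0), never as 0.

**Bootstrap.** Both estimators use one resampling scheme: codon columns
resampled with replacement, 1000 pseudo-replicates by default, SE = the
standard deviation across replicates. Resampling whole codons preserves
codon structure for dN/dS and costs nothing for π. Replicates with zero
mean dS are dropped from the ratio SE with a count. The generic
`bootstrap_se()` and the vectorised internal paths consume the same
per-replicate `sample.int()` draw, so they agree bit-for-bit under one
seed — this is tested, which pins the resampling unit down.

The pathway engine is backed by a 64×64 lookup table built once per
genetic code; an independent, naive, recursive oracle (driven by the
Biostrings copy of table 2) checks every sense-codon pair in the
acceptance suite.

## 2. Alignment

Within-species mitochondrial proteins are near-identical, so the internal
aligner is intentionally plain: 3-mer distances → UPGMA guide tree →
profile–profile Needleman–Wunsch with BLOSUM62, gap open −10 and extend
−1 (first gap residue costs 10). Any reasonable scheme reproduces what a
production aligner would output at these identities; for data where that
is not true, `import_protein_alignment()` loads an externally computed
alignment and verifies record sets and degapped rows exactly. Nucleotides
are threaded back one codon per residue (`---` for a protein gap), so
reading frames are preserved by construction; a property test translates
every degapped codon row back to its protein row.

Codons containing `N` — or any other IUPAC ambiguity code, a deliberate
extension of the published rule, which names only 'N' — are masked
per-row rather than deleted per-column: rows without the ambiguity keep
their data, and the complete-deletion step later removes any column that
still carries a masked codon in any row, so the statistics see the same
columns either way. Trailing partial codons (1–2 nt, common where the
stop is completed by polyadenylation) are trimmed with a warning; a
single terminal stop is stripped; an internal stop excludes the record
from the species dataset with a warning rather than poisoning the
alignment.

The supergene concatenates the 12 heavy-strand genes in a fixed canonical
order. ND6 — the one light-strand protein gene, with distinct base
composition and mutation spectrum — is parsed and carried by the I/O
layer but refused by `concatenate_supergene()`; the simulator emits it as
a decoy to keep that exclusion exercised.

## 3. Population delineation

The published analysis delineated populations by eye on MDS plots and
hand-removed genomes "located between two groups". That is not
reproducible, so the package automates it and keeps a plain-text override
table as the escape hatch (an override names a record and its population,
or `EXCLUDED`).

The automatic path: 1−IBS distances over variable sites (monomorphic
columns carry no grouping signal), classical Torgerson MDS (double-center
−½·J·D²·J, eigendecompose, clamp negative eigenvalues with a warning),
then k-means over the embedding for k = 2…6 with three dials:

- **structure gate** (`structure_floor = 0.6`): declare a single
  population unless the best mean silhouette clears this. The spec of
  this build suggested gating at 0.25, but a measured property of k-means
  is that bisecting a single structureless Gaussian blob in a 2-D
  embedding already yields mean silhouettes of ≈0.35–0.58, while genuine
  demes in simulation score ≥0.77 — so 0.25 would hallucinate structure
  in noise, contradicting the intended blob→k=1 behaviour. 0.25 is kept
  for its other role:
- **intermediate exclusion** (`silhouette_floor = 0.25`): under the
  chosen k, records with an individual silhouette below the floor sit
  between clusters and are excluded, the automated analogue of the manual
  removal of putative introgressants.
- **parsimony and merging** (`parsimony_margin = 0.1`,
  `merge_ratio = 0.6`): the smallest k within 0.1 silhouette of the best
  is preferred, and clusters whose centroid gap is below 0.6× the
  dominant gap are merged. Both exist for the same reason: a
  non-recombining genome is a single genealogy, and a deep within-deme
  clade clusters exactly as tightly as a real deme — silhouette alone
  will happily split it (measured subclade silhouettes of 0.93–0.98).
  The only signal separating a transient clade from a population is its
  *absolute* separation relative to the dominant gap. With these
  defaults, two-deme simulations at split depth 5 are recovered with a
  mean pairwise co-assignment accuracy of 0.95–1.00 across four disjoint
  20-seed batches; the residual failures are genealogies in which a
  within-deme lineage is older than the population split — a
  configuration that no single-locus method can resolve, because the
  deepest clade in the data genuinely is not the deme.

k-means is seeded (`nstart = 20`), so assignments are deterministic given
the inputs and the seed, and the seed is recorded in the outputs.

## 4. The simulator (and what a green test establishes)

The generator draws a Kingman coalescent (exponential waiting times at
rate k(k−1)/2; two-deme mode runs two independent coalescents to
`split_depth` and merges the survivors), then drops mutations as a
Poisson process at rate θ/2 per site per unit time: each event picks a
site uniformly, an alternative nucleotide with transition:transversion
weights κ:1, rejects and redraws stop-creating changes (sequences remain
valid sense-codon strings at every internal node), and accepts
nonsynonymous events with probability ω — synonymous always. Acceptance
thinning makes the realized nonsynonymous/synonymous substitution-rate
ratio ≈ ω by construction, which is what makes ω a usable truth value for
the estimator without a full codon substitution model.

Defaults state a mid-sized cetacean-like sample: 10 genomes, a
3800-codon supergene split over the 13 genes in proportion to real
vertebrate mitochondrial gene lengths, θ = 0.002 per site (the order of
observed cetacean mitogenomic diversities), κ = 8 (typical mammalian
mtDNA transition bias), ω = 0.1 (strong purifying constraint), split
depth 5. The ancestral sequence is uniform over sense codons; spacers and
a TAA terminal stop per CDS are added at emission, and the ND6 decoy is
written on the minus strand with correct 1-based inclusive coordinates.

What the generator does *not* emulate — and therefore what a green test
does not establish: recombination (absent in mtDNA, but also untested),
rate heterogeneity among sites and genes, base-composition and codon-usage
bias, selection regimes beyond uniform acceptance thinning (no site-class
mixture, no positive selection), sequencing error, and annotation noise
beyond what the I/O tests construct explicitly. ω-recovery holds in the
regime tested (θ·L large enough for ≳200 expected pairwise synonymous
differences); at ω = 1 the estimator reads ≈0.89 because positions whose
mutations would create stops count as nonsynonymous opportunity in the
site classification but are mutationally inaccessible in the generator —
an expected, documented bias of the stated world, inside the 20% relative
tolerance the build is held to.

## 5. Numerical and formatting choices

- Coordinates are 0-based half-open internally, converted at the
  flat-file and VCF boundaries (both 1-based inclusive).
- Ambiguity codes other than N are preserved at parse time and masked
  like N at codon cleaning.
- Duplicate CDS annotations for one gene resolve to the longest feature
  (tie: annotation order), with a warning.
- VCF: haploid GT codes, reference = majority allele (tie:
  lexicographically smallest), alternates lexicographic; species and gene
  boundaries travel in `##META` lines so the VCF round-trips the variant
  table exactly.
- MDS eigenvalues below 10⁻¹² of the maximum are treated as zero so
  padded dimensions are exactly zero.
- Pipeline TSVs round numeric columns to 10 decimals to make byte-level
  determinism meaningful across BLAS implementations.
- Diversity bins close the medium interval on both ends ([0.001, 0.002]),
  so boundary populations fall in medium; outliers for fold-differences
  are excluded by name only, never detected automatically.
- Correlation p-values are two-sided t-approximations (n−2 df) for both
  Pearson and mid-rank Spearman, with no multiple-testing correction, and
  the log fit is ordinary least squares of y on ln(x) (zero-π rows are
  excluded from the fit with a warning).
- Risk-group means weight populations equally (species status propagates
  to all its populations); per-population bootstrap SEs are carried but
  not propagated into group-mean SEs, which are plain SEs of the mean.

## 6. Known limitations

- The GenBank parser covers the feature subset this pipeline needs (CDS
  with gene/product qualifiers, join/complement locations, ORIGIN); it is
  not a general-purpose flat-file reader.
- The internal protein aligner is for near-identical sequences; divergent
  or frameshifted inputs belong to the import path.
- Population delineation from a single non-recombining locus is
  fundamentally limited (see §3); the override table is the recourse for
  cases where external information contradicts the clustering.
- dN/dS here measures segregating load within populations; it is not a
  divergence ω and makes no claim about fixed differences or positive
  selection.
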