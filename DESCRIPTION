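Package: mitoload
Title: Mitogenome Diversity and Deleterious Mutation Load in Populations
Version: 1.0.0
Authors@R: person("Alex", "Doran", email = "alex.doran@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline from annotated mitochondrial genome flat files
    to per-population molecular-evolution summaries. Extracts the 13
    mitochondrial protein-coding genes, builds protein-guided codon alignments
    and a 12-gene heavy-strand supergene, delineates populations by classical
    multidimensional scaling of identity-by-state distances over variable
    sites (with VCF export), and estimates Nei-Li nucleotide diversity and
    the Pamilo-Bianchi-Li dN/dS ratio with codon-column bootstrap standard
    errors. Includes a coalescent codon simulator with a tunable
    nonsynonymous acceptance probability for end-to-end validation without
    any external downloads, and cohort-level summaries joining diversity,
    mutation load and IUCN Red List risk groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
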