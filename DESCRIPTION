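Package: paleoload
Title: Mutational Load and Temporal Dynamics of Deleterious Variants in
    Ancient and Modern Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates phyloP-weighted mutational loads from strict
    homozygous genotype calls, reconstructs temporal allele-frequency
    trajectories of deleterious variants from ancient-DNA read counts by
    pooled-binomial maximum likelihood, builds drift-sensitive
    neighbor-joining trees from pseudo-haploid data, and co-estimates
    inbreeding coefficients and identity-by-descent tracts with a
    two-state hidden Markov model fitted by EM. A Wright-Fisher based
    synthetic-data generator emulates a horse-like time series of ancient
    and modern genomes (recessive deleterious variants, a recent
    inbreeding burst, sequencing error and post-mortem damage) and
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
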