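Package: qtsmap
Title: Full-Genetic-Model QTS Mapping for Nested Association Mapping Populations
Version: 0.1.0
Authors@R:
    person("qtsmap", "developers", email = "qtsmap@example.org", role = c("aut", "cre"))
Description: Mixed linear model association mapping of quantitative trait
    SNPs (QTS) in nested association mapping (NAM) populations under a full
    genetic model with additive, dominance, digenic epistasis (aa, ad, da,
    dd) and genotype-by-environment interaction effects.  Provides a
    GMDR-style cross-validated pre-scan for candidate loci and locus pairs,
    Henderson method III F-tests with permutation-based experiment-wise
    thresholds, Gibbs-sampler estimation of genetic effects and variance
    components, heritability partitioning into additive, dominance and
    epistasis components, and prediction of superior line and superior
    hybrid genotype combinations.  A NAM-population simulator (biparental
    families crossed to a common parent and selfed, map-based recombination,
    residual heterozygosity, missing-genotype masking) makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
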