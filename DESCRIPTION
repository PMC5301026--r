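Package: scutpop
Title: Population and Landscape Genetics of Two Insular Scutellaria Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One tested pipeline for the population-genetic and landscape-genetic
    analysis of closely related insular skullcap (Scutellaria) taxa scored at
    microsatellite loci and haploid chloroplast sequence markers. Provides
    sequence diversity and neutrality statistics (nucleotide diversity,
    Watterson's theta, Tajima's D with a coalescent null), microsatellite
    diversity indices and an Fdist-style F_ST outlier scan, hierarchical AMOVA
    with permutation tests, Nei pairwise F_ST with Rousset linearization, a
    structured-coalescent simulator of microsatellite (stepwise mutation) and
    sequence (infinite sites) data under configurable demographic scenarios,
    approximate Bayesian computation model choice with GLM marginal densities
    and Bayes factors, Mantel / partial Mantel / MMRR matrix association tests,
    and a climate layer (VIF pruning, climate PCA, partial distance-based RDA,
    per-axis GLMs). A built-in scenario generator supplies synthetic data so
    every stage runs end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
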