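Package: flockdiv
Title: Genetic Diversity Monitoring for Small Managed Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic and molecular tools to monitor genetic diversity in
    small managed populations such as local chicken breeds kept in
    conservation or breeding programs. Covers pedigree-based inbreeding,
    equivalent complete generations and realized effective population size;
    founder-based effective size from sex-specific founder counts; SNP panel
    quality control and windowed linkage-disequilibrium pruning;
    method-of-moments inbreeding coefficients (Fit/Fis), heterozygosity, MAF
    and fixed-allele summaries; Weir-Cockerham Fst and Nei's standard
    distance; sliding-window runs-of-homozygosity detection and F-ROH;
    identity-by-state distances, neighbor-joining trees, discriminant
    analysis of principal components, Mantel tests and partial correlations;
    plus a gene-dropping simulator of hierarchical mating designs that
    provides ground truth for every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    grDevices,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    vegan
Config/testthat/edition: 3
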