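Package: pedscan
Title: Mixed-Model QTL Mapping in Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative trait locus (QTL) mapping for populations with known
    pedigrees and unequal relatedness, such as advanced intercross lines.
    Computes exact condensed identity coefficients (Jacquard's nine states) from
    pedigrees by a generalized-kinship recursion with bottom-up, top-down and
    hybrid evaluation schedules; assembles the five genetic incidence matrices
    and estimates genetic and non-genetic variance components by maximum
    likelihood; performs genome scans (including Haley-Knott interval mapping,
    forward multiple-QTL selection and two-locus epistasis scans) with the
    covariance held fixed; and estimates genome-wide significance thresholds by
    genotype permutation and by gene dropping through the pedigree. A synthetic
    advanced-intercross-line simulator generates pedigrees, genotypes and
    phenotypes with known variance components and planted QTL.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
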