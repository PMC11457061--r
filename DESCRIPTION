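Package: neabc
Title: Effective Population Size from a Single SNP Sample via Approximate
    Bayesian Computation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates contemporary effective population size (Ne) from a
    single population sample of diploid biallelic SNP genotypes. Observed
    data are read from GENEPOP files and filtered for missingness and
    minor allele frequency; five summary statistics (mean expected
    heterozygosity, fixation index, the first two moments of multi-locus
    homozygosity, and the mean squared Burrows composite linkage
    disequilibrium correlation) are matched against a reference table of
    two-sex Wright-Fisher forward simulations drawn from uniform priors
    on Ne and the number of generations. Rejection sampling followed by
    weighted local linear regression on Box-Cox transformed Ne yields a
    posterior sample, summarised as a weighted median and 95 percent
    interval. A command-line front end and a deterministic synthetic
    data generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
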