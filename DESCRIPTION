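Package: methquant
Title: Bayesian Quantification of DNA Methylation from Affinity Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms per-bin read counts from affinity capture methylation
    sequencing (MBD-seq, MeDIP-seq) into regional methylation levels with
    analytic posterior means, variances and credible intervals, using an
    empirical Bayes Poisson-gamma model that optionally borrows strength from
    a fully methylated (SssI-treated) control sample. Includes CpG-density
    stratified hyperparameter estimation, library-size and copy-number-aware
    normalization offsets, highest-posterior-density, quantile and Wald
    credible intervals, collapsing of base-resolution truth sets to bins,
    performance metrics, and a generative simulator for the full model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    withr,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
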