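Package: permfdr
Title: Protein-Level False Discovery Rate Estimation via Permutation Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates protein-level false discovery rates in shotgun
    proteomics without parametric assumptions. Builds an empirical null
    distribution from decoy protein scores obtained by repeatedly shuffling a
    FASTA sequence database (the permutation method), converts protein
    probabilities to bin-based p-values and applies the Benjamini-Hochberg
    procedure to obtain q-values and an FDR-versus-identification-count
    curve. For efficient re-analysis, a feature database stores previously
    computed null distributions together with a per-sample Kullback-Leibler
    divergence feature and a per-bin logistic coefficient table; the null
    distribution of a new sample is either matched by feature similarity or
    inferred from the coefficient table, so no new permutation run is needed.
    Includes a synthetic-data generator with known ground-truth labels for
    calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
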