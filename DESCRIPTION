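Package: meiorepair
Title: Statistics for Meiotic Double-Strand-Break Repair Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for Caenorhabditis elegans meiotic
    double-strand-break repair assays: recombinant-frequency statistics
    (Wilson score intervals, Fisher exact tests, fold changes) for
    intersister/intrachromatid (ICR), interhomolog (IH) and sister
    chromatid exchange (SCE) assays; gene-conversion tract-length scoring
    and mutation-signature classification (microhomology-mediated end
    joining); a Bayesian hierarchical Beta-Binomial brood-viability model
    with a radiosensitivity posterior ratio metric; sliding-window RAD-51
    focus profiling with binned nonparametric comparisons; and seeded
    synthetic-data generators emulating the shape of each assay's source
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
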