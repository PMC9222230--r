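Package: tensorDE
Title: Integrated Multi-Tissue Differential Expression by Tensor
    Decomposition with Standard-Deviation Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a six-mode expression tensor
    (probe x time x replicate x treatment x strain x tissue) from GEO
    series-matrix style files, decomposes it by higher-order singular
    value decomposition (HOSVD), selects the singular vectors matching
    biological criteria (treatment-distinct, tissue-independent), and
    selects probes via standard-deviation-optimized chi-squared
    p-values with Benjamini-Hochberg correction.  Ships per-tissue
    baseline selectors (Welch t, a SAM-like permutation statistic, an
    empirical-Bayes moderated t) and a ComBat-style batch adjustment
    for naive cross-tissue integration, a local hypergeometric
    gene-set enrichment report for GMT libraries, and a synthetic-data
    generator emulating the full two-strain five-time-point
    three-tissue design with planted differentially expressed probes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva,
    jsonlite,
    yaml
Config/testthat/edition: 3
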