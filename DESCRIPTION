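Package: originfire
Title: Stochastic Origin Firing, Marker Frequency and ssDNA Replication
    Profiling for Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying DNA replication origin firing efficiency in
    Saccharomyces cerevisiae. Provides a stochastic per-cell origin-firing and
    fork-progression simulator (including hydroxyurea-limited synthesis and a
    tandem rDNA-array replication-completion model), marker frequency analysis
    of S/G1 read depth with region masking and fixed-bandwidth LOESS smoothing,
    processing of ssDNA replication profiles (outlier filtering, smoothing onto
    a fine grid, mode-baseline rescaling, local-maximum peak calling, peak-area
    quantification), tornado matrices and peak-area regressions with residual
    diagnostics for cross-sample comparisons, and the arithmetic for CHEF-gel
    well fractions and 2D-gel bubble-to-1N ratios.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
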