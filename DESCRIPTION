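Package: blacklistr
Title: Automated Detection of Signal-Artifact ('Blacklist') Regions from
    ChIP-seq Input Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies anomalous, assembly-driven signal regions
    ("blacklists" or exclusion lists) in a genome from a panel of control
    ("input") ChIP-seq alignments. Reads are binned into overlapping
    windows and scored per sample with reads per uniquely-mappable base
    and multimapping reads per million; scores are quantile normalized
    across samples and reduced to a per-bin median; extreme bins are
    flagged, extended through high-signal or unmappable neighbours,
    joined across short gaps, and emitted as labelled BED intervals.
    Includes an exhaustive k-mer uniqueness (mappability) computation, a
    synthetic-panel generator that plants collapsed repeats, NUMT-like
    high-copy loci and duplicated segments with ground truth for recovery
    testing, peak filtering against a blacklist, broom-style tidiers and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
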