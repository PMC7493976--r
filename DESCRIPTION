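Package: ctcfscape
Title: Cancer-Specific CTCF Binding-Site Discovery and Multi-Omic Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a union atlas of CTCF binding sites from many ChIP-seq peak
    sets, models the occupancy-score distribution with a power law to derive a
    constitutive-site cutoff, calls cancer-specific lost and gained sites from
    occupancy frequencies and a quantile-normalized binding-level matrix, and
    characterizes the calls by expected-at-distance-normalized Hi-C contact
    maps, constitutive-CTCF-bounded chromatin domains, CTCF-gene expression
    correlation, CpG methylation change, mutation-rate and motif-disruption
    profiles, and transcription-factor enrichment over a regulatory-element
    repertoire. Includes a planted-truth synthetic multi-omics generator so
    every stage can be exercised and benchmarked at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
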