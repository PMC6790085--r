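Package: footprintr
Title: Digital Genomic Footprinting from DNaseI Cleavage Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for DNaseI-seq digital genomic footprinting.
    Calls DNaseI-hypersensitive sites with a sliding-window Poisson model,
    detects transcription-factor footprints inside them from strand-polarized
    cleavage depletion, corrects sequence-specific hexamer cutting bias with a
    naked-DNA background and a multinomial mixture model, tests differential
    footprint occupancy between samples by seeded bootstrap, classifies
    footprints against gene models, tests polymorphism constraint at fourfold
    degenerate sites inside exonic footprints (duons), scans and ranks
    transcription-factor motifs, and classifies cross-species footprint
    conservation through ungapped alignment blocks. A synthetic-data generator
    produces genomes, gene models, biased cleavage profiles and ground-truth
    manifests so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    IRanges,
    Biostrings,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
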