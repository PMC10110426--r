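Package: ckcnet
Title: Corticokinematic Coherence Detection and Directed Cortical Network
    Analysis for Repetitive-Movement EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for EEG recorded during repetitive proprioceptive
    (movement) stimulation. Detects steady-state phase-locked cortical responses
    with a corticokinematic coherence (CKC) metric built on current source density
    transformed signals, Morlet-wavelet inter-trial phase coherence and parametric
    Rayleigh statistics with false discovery rate control; quantifies directed
    cortical interactions between parcel signals with phase transfer entropy
    (dPTE); estimates group-level Consistent Networks via binomial edge tests; and
    derives individual-level Spreading Index, laterality and symmetry metrics.
    Includes a synthetic-data module that generates trigger trains, scalp
    recordings with embedded phase-locked responses, band-limited artifact
    waveforms and parcel signals with known directed coupling, so the whole
    pipeline can be exercised without clinical data.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
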