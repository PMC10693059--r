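Package: somnoplaque
Title: Sleep Staging, Spectral, Imaging and Cytometry Quantification for
    Mouse Amyloidosis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested implementation of the quantification
    pipeline used in sleep-and-amyloid studies of APP/PS1-type mouse
    models: rule-based EEG/EMG sleep staging in 10-s epochs with
    artifact exclusion, sleep-architecture and bout (fragmentation)
    metrics, state-specific Hann-periodogram band powers including
    slow-wave activity, ratiometric FRET (YFP/CFP) neuronal calcium
    quantification via the Hill relation with a control mean + 2 SD
    overload criterion, amyloid-plaque segmentation with count, size and
    burden summaries, 3D microglia-plaque proximity clustering at a
    25 micrometre radius, rectangular flow-cytometry gating with a
    control-derived positivity threshold, and behavioral scoring
    (contextual-fear freezing, Y-maze spontaneous alternation, open
    field).  Every input modality has a seeded synthetic generator with
    known ground truth so the whole pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    signal,
    igraph,
    yaml,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
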