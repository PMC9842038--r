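Package: CalciMorph
Title: Quantifying Calcification Morphology and Protein Localization in Valve Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for sex-specific valve calcification
    studies. Quantifies Von Kossa-stained histology (uniform thresholding and
    integrated density), summarizes mineral feature size through the radially
    averaged autocorrelation of binary masks and its integral (the correlation
    length, in micrometers), and measures protein localization in fluorescence
    z-stacks as the ratio of mean intensity over DAPI-anchored perinuclear
    ("cellular") pixels to mean intensity over the remaining extracellular
    matrix pixels. Ships a seeded synthetic micrograph generator (Boolean disk
    fields and nucleus/halo scenes with analytic ground truth) so every stage
    is testable without raw micrographs, plus Welch t, one-/two-way ANOVA with
    Dunnett or Tukey post hoc comparisons, and a study orchestrator that turns
    condition-labelled image sets into comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage,
    mvtnorm
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Software, CellBiology
RoxygenNote: 7.3.3
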