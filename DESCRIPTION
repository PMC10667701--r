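Package: physhab
Title: Transport-Network Morphology and Habituation Behaviour Analysis for
    Physarum Time-Lapse Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for habituation experiments in the
    plasmodium of Physarum polycephalum: behavioural indices (footprint area
    on an agar bridge and normalized crossing speed) from time-lapse image
    stacks, transport-tube orientation distributions by 2-D Fourier power
    spectrum analysis with weighted kernel density mode estimation,
    tree-versus-mesh network classification and daily-change typing,
    block-wise thickness-oscillation frequency mapping with a half-Nyquist
    noise cutoff, start-goal tube connection typing by skeleton analysis,
    and the gated multiple-comparison workflow (Shapiro/Bartlett gate, then
    Dunnett or Steel many-to-one tests, plus one-sided Mann-Whitney
    contrasts).  A synthetic movie and study-table generator with known
    ground truth makes every stage testable without raw microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    EBImage,
    multcomp,
    mvtnorm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
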