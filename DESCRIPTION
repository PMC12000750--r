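Package: osteochip
Title: Quantitative Analysis Pipelines for Osteochondral Organ-on-Chip Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantitative analyses used
    in sex-stratified osteochondral organ-on-chip studies: 3D nuclei-seeded
    single-cell segmentation and nascent-protein deposition classification
    (negative / restricted / secreting), live-dead viability counting,
    Hertz-model nanoindentation fitting and elasticity array maps, hydrogel
    diffusion-profile quantification with an analytic two-source transport
    model, and a cytokine multiplex preprocessing, PCA and correlation
    clustering pipeline. Ground-truthed synthetic generators for every input
    family (confocal z-stacks, load-indentation curves, cytokine tables,
    diffusion time-lapse series) support parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    yaml,
    ape,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
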