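Package: terrafoci
Title: Quantification of Telomeric RNA Foci and Single-Particle Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of telomeric
    repeat-containing RNA (TERRA) foci and single RNA particles in
    nematode germline microscopy. Provides 3D segmentation and
    measurement of fluorescent foci (volume, integrated density, average
    intensity), equal-volume sphere approximation of nuclei, three-zone
    radial localization analysis, object-based colocalization with a
    shuffle-null significance test, single-particle tracking analytics
    (mean square displacement in two conventions, diffusion-coefficient
    estimation, confinement-plateau detection, motility classification
    and within-track state segmentation), and qPCR delta-Ct relative
    quantification with primer-efficiency standard curves. A synthetic
    data module generates ground-truth image stacks, trajectories and Ct
    tables so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
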