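Package: fastfish
Title: Unstructured Hybridization Probe Design and Single-Molecule
    Transcription Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design of intrinsically unstructured three-base hybridization
    probe/target pairs by restricted-alphabet sampling and Lempel-Ziv
    complexity filtering, and simulation and analysis of single-molecule
    TIRF/CoSMoS transcription experiments. Includes a stochastic simulator
    of the transcription cycle (promoter binding, escape, per-nucleotide
    elongation, end dwell, run-off) with probe hybridization and an optical
    readout (PSF rendering, evanescent-field decay, camera integration,
    noise); spot detection and subpixel 2D Gaussian localization;
    co-localization analysis and active-locus selection; dwell-time
    histogramming and exponential / exponential-plus-Gaussian fitting;
    post-synchronized heat maps with rising-edge delay estimation and
    two-Gaussian detection-efficiency decomposition; and conversion of the
    measured delays into transcription-cycle rate constants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
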