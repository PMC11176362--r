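Package: fidnetr
Title: Virtual Decoupling and Resolution Enhancement of Methyl NMR Spectra
    with Gated Dilated Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for obtaining methyl-TROSY-like 13C-1H correlation spectra
    from uniformly 13C-labelled, protonated protein samples. Simulates methyl
    13C-1H free induction decays with one-bond 13C-13C scalar couplings and
    exponential relaxation, generates training pairs and realistic benchmark
    spectra with known ground truth, trains FID-Net-style gated dilated
    convolutional networks that virtually decouple 13C-13C couplings and
    sharpen peaks, runs the two-network 2D/3D enhancement pipeline with
    nmrPipe-format input and output, scores enhanced spectra with a
    peak-picking true/false-positive benchmark, and calibrates NOE cross-peak
    volumes against interproton distances with an inverse sixth-power fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
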