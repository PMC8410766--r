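Package: VoigtPicker
Title: Convolutional Peak Picking and Voigt Deconvolution of 1D/2D NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains a small point-wise convolutional neural network on
    synthetic pseudo-Voigt spectra of known composition and uses it to pick
    and deconvolve peaks in frequency-domain 1D spectra and 2D cross-peak
    maps (e.g. HSQC). Includes the synthetic training-set generator with
    nonlinear-fit decision boundaries for labeling strongly overlapped
    peaks, non-maximum suppression post-processing, a row/column
    combination algorithm for 2D cross-peaks with false-intersection
    removal and tilted-line splitting, an optional simultaneous
    least-squares refinement of clustered peaks, and readers/writers for
    NMRPipe and plain-text spectra plus TSV and Sparky peak lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, minpack.lm, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
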