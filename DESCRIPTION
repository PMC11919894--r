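Package: schoolECG
Title: Deep-Learning Screening of 12-Lead Electrocardiograms in School-Age
    Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for screening 12-lead resting
    electrocardiograms (ECGs) of school-age children for guideline-defined
    abnormalities. Raw 10-second, 500 Hz waveforms are reduced to a compact
    spectral representation: Pan-Tompkins QRS detection delimits a whole
    number of cardiac cycles, a discrete Fourier transform yields per-lead
    amplitude and phase spectra low-passed at 50 Hz, leads are arranged in
    the Cabrera sequence, and the spectra are resampled onto 400 frequency
    bins to form a 2 x 12 x 400 tensor. A multimodal VGG-style convolutional
    network (built on a compiled BLAS-backed engine included in the package)
    classifies overall abnormality from the tensor together with age and
    sex, trained with five-fold patient-level cross-validation. The package
    also provides a comparator-aware evaluation suite (ROC/AUC, Youden and
    matched-sensitivity operating points, bootstrap confidence intervals,
    McNemar's paired test, decision-curve analysis, per-finding reports),
    frequency-domain grad-CAM saliency mapped back to the time domain by
    inverse FFT, and a dipole-based synthetic pediatric ECG simulator with
    injectable abnormalities so the whole pipeline runs without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    png,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
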