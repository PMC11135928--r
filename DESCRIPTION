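Package: nirsmotor
Title: Motor-Cortex fNIRS Analysis: Task HRF Estimation and Resting-State Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous-wave functional near-infrared
    spectroscopy (fNIRS) recordings of the primary motor cortex, built around a
    finger-tapping / walking / resting-state protocol used in Parkinson's
    disease research. Provides probe-geometry and recording containers with
    SNIRF and delimited-text I/O, a forward simulator with known ground truth
    (evoked responses, systemic physiology, superficial contamination, motion
    artifacts, group-dependent interhemispheric coupling), Homer-style
    preprocessing (channel pruning, optical-density conversion, motion
    detection, spline and wavelet correction, trial rejection, zero-phase
    band-pass filtering), modified Beer-Lambert conversion, GLM estimation of
    the hemodynamic response with a Gaussian temporal basis, polynomial drift
    and short-separation nuisance regressors, HRF feature extraction,
    Tikhonov-regularized short-channel regression with inter- and
    intrahemispheric connectivity indices, and a nonparametric group/clinical
    statistical layer with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
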