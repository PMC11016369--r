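Package: wembo
Title: Rigid Alignment of 3D Density Maps via Wavelet Earth Mover's
    Distance and Bayesian Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers the rigid transform (rotation, optional reflection,
    and translation) between two cubic 3D density maps, such as cryo-EM
    reconstructions stored in MRC/CCP4 format.  The relative translation
    is removed by centering the thresholded maps at their center of mass;
    the rotation is then estimated by minimizing a wavelet approximation
    of the 1-Wasserstein distance (WEMD) over the rotation group SO(3)
    with Bayesian optimization, using a Gaussian-process interpolant with
    a squared-exponential kernel on the Frobenius embedding as the
    acquisition function, minimized by Riemannian steepest descent with
    early stopping.  An optional local refinement step polishes the
    estimate with the Nelder-Mead simplex method in Euclidean loss.
    Includes MRC map I/O, Fourier-based volume rotation, shifting and
    downsampling, a reproducible synthetic benchmark generator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
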