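Package: smoct
Title: Speckle-Modulating Optical Coherence Tomography Simulation and Analysis
Version: 0.1.0
Authors@R: person("smoct", "developers", email = "smoct@example.org", role = c("aut", "cre"))
Description: A physics-based spectral-domain optical coherence tomography (OCT)
    simulator with a rotating-diffuser speckle-modulation model (SM-OCT),
    together with the full downstream analysis chain: synthetic neural-tissue
    phantoms with known ground truth, interferogram simulation with dispersion
    and per-frame speckle decorrelation, k-linearized reconstruction with
    sharpness-based dispersion compensation, linear-scale frame compounding and
    speckle-contrast statistics, volume enhancement (vessel-shadow gain,
    three-dimensional anisotropic diffusion, histogram equalization, isotropic
    resampling, surface flattening), and intensity-based brain-tumor margin
    delineation with distance-to-truth error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
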