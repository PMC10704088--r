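Package: skindrs
Title: Three-Layer Skin Model Analysis of Diffuse Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of in vivo skin optical properties from two-separation
    diffuse reflectance spectra (475-850 nm) with a three-layer skin model:
    closed-form chromophore spectra (Mie/Rayleigh reduced scattering, melanin,
    vessel-packaged hemoglobin), a layered white Monte Carlo photon transport
    engine with per-layer pathlength recording, Beer-Lambert spectral synthesis
    with two-dimensional interpolation over epidermis thickness and scattering,
    a multi-start bounded inverse solver, a weighted-path sampling-depth
    statistic, a synthetic cohort generator, and nonparametric cohort
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    lhs,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
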