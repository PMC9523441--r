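Package: flakmap
Title: Predicting Post-Operative Corneal Axial Curvature After Arcuate Keratotomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the anterior corneal axial-curvature map after
    femtosecond laser arcuate keratotomy (FLAK). Reads and writes Pentacam-style
    raw curvature grids, converts radius of curvature to keratometric power,
    extracts simulated keratometry (flat/steep K, cylinder, axis) in central
    zones, performs Alpins-method astigmatism vector analysis (TIA, SIA,
    difference vector, correction index), and scores predicted against real
    maps with zone-masked MSE, PSNR and SSIM. Includes a synthetic cornea and
    surgery simulator producing paired pre/post-operative maps with known
    ground truth, and a natively implemented pix2pix-style conditional GAN
    (U-Net generator, patch discriminator, adversarial plus L1 objective,
    buffer-pool alternating training) mapping encoded pre-operative inputs to
    predicted post-operative maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
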