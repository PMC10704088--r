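# Forward model: Beer-Lambert spectral synthesis on the MC basis.

#' Full parameter set of the three-layer skin model
#'
#' Combines the scattering, epidermis and two dermis parameter blocks. The
#' two dermis layers share one oxygen saturation and the reduced scattering
#' spectrum is common to all layers.
#'
#' @param scattering A [scattering_params()].
#' @param epidermis An [epidermis_params()].
#' @param dermis_upper A [dermis_params()] with finite thickness
#'   (default 0.2 mm).
#' @param dermis_lower A [dermis_params()] with infinite thickness.
#' @return An object of class `skin_params`.
#' @export
skin_params <- function(scattering, epidermis, dermis_upper, dermis_lower) {
  stopifnot(inherits(scattering, "scattering_params"),
            inherits(epidermis, "epidermis_params"),
            inherits(dermis_upper, "dermis_params"),
            inherits(dermis_lower, "dermis_params"))
  if (!isTRUE(all.equal(dermis_upper$s, dermis_lower$s)))
    stop("the two dermis layers must share one oxygen saturation")
  structure(list(scattering = scattering, epidermis = epidermis,
                 dermis_upper = dermis_upper, dermis_lower = dermis_lower),
            class = "skin_params")
}

#' Construct skin parameters from a flat named vector
#'
#' Convenience constructor used by the inverse solver and cohort generator.
#'
#' @param theta Named numeric vector with elements `alpha`, `beta`, `gamma`,
#'   `t_epi`, `f_mel`, `beta_mel`, `f_blood1`, `f_blood2`, `s`.
#' @param vessel_radius Vessel radius (mm) for both dermis layers.
#' @param dermis1_thickness Upper dermis thickness (mm).
#' @return A `skin_params` object.
#' @export
skin_params_from_vector <- function(theta, vessel_radius = 0.005,
                                    dermis1_thickness = 0.2) {
  need <- c("alpha", "beta", "gamma", "t_epi", "f_mel", "beta_mel",
            "f_blood1", "f_blood2", "s")
  stopifnot(all(need %in% names(theta)))
  skin_params(
    scattering_params(theta[["alpha"]], theta[["beta"]], theta[["gamma"]]),
    epidermis_params(theta[["t_epi"]], theta[["f_mel"]], theta[["beta_mel"]]),
    dermis_params(theta[["f_blood1"]], theta[["s"]], vessel_radius,
                  thickness = dermis1_thickness),
    dermis_params(theta[["f_blood2"]], theta[["s"]], vessel_radius,
                  thickness = Inf))
}

#' Flatten skin parameters to the canonical 9-vector
#' @param params A `skin_params` object.
#' @return Named numeric vector (see [skin_params_from_vector()]).
#' @export
skin_params_to_vector <- function(params) {
  stopifnot(inherits(params, "skin_params"))
  c(alpha = params$scattering$alpha, beta = params$scattering$beta,
    gamma = params$scattering$gamma, t_epi = params$epidermis$t_epi,
    f_mel = params$epidermis$f_mel, beta_mel = params$epidermis$beta_mel,
    f_blood1 = params$dermis_upper$f_blood, f_blood2 = params$dermis_lower$f_blood,
    s = params$dermis_upper$s)
}

#' Default analysis wavelength grid
#'
#' 475-850 nm in `step` nm steps with the 770-810 nm notch-filter band
#' flagged invalid.
#'
#' @param step Grid step (nm), default 5.
#' @param notch Two-element masked band (nm), default `c(770, 810)`.
#' @return List with `wavelengths` and logical `mask` (`TRUE` = valid).
#' @export
default_wavelengths <- function(step = 5, notch = c(770, 810)) {
  wl <- seq(475, 850, by = step)
  list(wavelengths = wl,
       mask = !(wl >= notch[1] & wl <= notch[2]))
}

#' Two-separation reflectance spectrum container
#'
#' @param wavelengths Strictly increasing wavelengths (nm).
#' @param intensity Matrix (n_wavelengths x n_detectors) of intensities in
#'   arbitrary calibrated units; columns named by separation.
#' @param mask Logical validity mask (`TRUE` = valid channel); masked
#'   channels are carried but excluded from fitting.
#' @param separations Detector separations (mm).
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths, intensity, mask = NULL,
                                 separations = c(0.4, 1.2)) {
  intensity <- as.matrix(intensity)
  stopifnot(all(diff(wavelengths) > 0),
            nrow(intensity) == length(wavelengths),
            ncol(intensity) == length(separations))
  if (is.null(mask)) mask <- rep(TRUE, length(wavelengths))
  stopifnot(length(mask) == length(wavelengths))
  colnames(intensity) <- paste0("d", separations)
  structure(list(wavelengths = as.numeric(wavelengths), intensity = intensity,
                 mask = as.logical(mask),
                 separations = as.numeric(separations)),
            class = "reflectance_spectrum")
}

#' Write / read a reflectance spectrum as TSV
#'
#' Columns: `wavelength_nm`, `intensity_d04`, `intensity_d12`, `mask`.
#'
#' @param spectrum A `reflectance_spectrum` (two separations).
#' @param path File path.
#' @return `read_spectrum` returns the `reflectance_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"),
            ncol(spectrum$intensity) == 2)
  df <- data.frame(wavelength_nm = spectrum$wavelengths,
                   intensity_d04 = spectrum$intensity[, 1],
                   intensity_d12 = spectrum$intensity[, 2],
                   mask = as.integer(spectrum$mask))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  reflectance_spectrum(df$wavelength_nm,
                       cbind(df$intensity_d04, df$intensity_d12),
                       mask = df$mask == 1)
}

#' Per-layer absorption coefficients
#'
#' Evaluates the absorption triple (epidermis, upper dermis, lower dermis)
#' of the three-layer model at the given wavelengths:
#' `mu_a_epi = f_mel * mu_a_mel(lambda)`, and the two dermal coefficients
#' from the vessel-packaged hemoglobin model.
#'
#' @param params A `skin_params` object.
#' @param lambda_nm Wavelengths (nm); vectorized.
#' @param table A [hemoglobin_table()].
#' @return Matrix (length(lambda_nm) x 3) with columns `epi`, `dermis1`,
#'   `dermis2` (mm^-1).
#' @export
layer_absorptions <- function(params, lambda_nm, table) {
  stopifnot(inherits(params, "skin_params"))
  mu_epi <- params$epidermis$f_mel *
    melanin_absorption(lambda_nm, params$epidermis$beta_mel)
  mu1 <- dermis_absorption(lambda_nm, params$dermis_upper, table)
  mu2 <- dermis_absorption(lambda_nm, params$dermis_lower, table)
  cbind(epi = mu_epi, dermis1 = mu1, dermis2 = mu2)
}

# Locate a value on a grid axis; returns list(i, frac) for linear
# interpolation, erroring (or clamping) outside the range.
axis_bracket <- function(value, levels, name, clamp = FALSE) {
  if (clamp) value <- pmin(pmax(value, levels[1]), levels[length(levels)])
  if (any(value < levels[1]) || any(value > levels[length(levels)]))
    stop(sprintf("parameter outside basis grid on the %s axis [%g, %g]",
                 name, levels[1], levels[length(levels)]))
  i <- findInterval(value, levels, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(levels) - 1L)
  frac <- (value - levels[i]) / (levels[i + 1] - levels[i])
  list(i = i, frac = frac)
}

#' Model the two-separation reflectance spectrum
#'
#' Synthesizes the diffuse reflectance for arbitrary skin parameters by
#' applying Beer-Lambert absorption scaling to the stored per-layer photon
#' pathlengths of the four surrounding basis cells and interpolating
#' bilinearly in (epidermis thickness, log reduced scattering). Output is
#' the detected weight fraction per launched photon for each detector.
#'
#' @param params A `skin_params` object.
#' @param basis An `mc_basis`.
#' @param wavelengths Wavelengths (nm); default [default_wavelengths()].
#' @param table A [hemoglobin_table()]; compiled from the bundled fixture
#'   when omitted.
#' @param mask Logical validity mask matching `wavelengths`.
#' @param clamp Clamp out-of-grid `t_epi`/scattering to the grid edge
#'   instead of signalling an error (used inside the inverse solver).
#' @return A `reflectance_spectrum`.
#' @export
model_reflectance <- function(params, basis, wavelengths = NULL, table = NULL,
                              mask = NULL, clamp = FALSE) {
  stopifnot(inherits(params, "skin_params"), inherits(basis, "mc_basis"))
  if (is.null(table)) table <- compile_hemoglobin_table()
  if (is.null(wavelengths)) {
    grid <- default_wavelengths()
    wavelengths <- grid$wavelengths
    if (is.null(mask)) mask <- grid$mask
  }
  if (is.null(mask)) mask <- rep(TRUE, length(wavelengths))
  mua <- layer_absorptions(params, wavelengths, table)
  musp <- reduced_scattering(wavelengths, params$scattering)
  intensity <- bl_interp_intensity(basis, params$epidermis$t_epi, musp, mua,
                                   clamp = clamp)
  reflectance_spectrum(wavelengths, intensity, mask = mask,
                       separations = basis$probe$separations)
}

# Shared interpolation core: t_epi scalar, musp/mua per wavelength.
bl_interp_intensity <- function(basis, t_epi, musp, mua, clamp = FALSE) {
  n_det <- length(basis$probe$separations)
  tb <- axis_bracket(t_epi, basis$t_epi_levels, "epidermis thickness",
                     clamp = clamp)
  lm_levels <- log(basis$musp_levels)
  if (clamp) musp <- pmin(pmax(musp, basis$musp_levels[1]),
                          basis$musp_levels[length(basis$musp_levels)])
  mb <- axis_bracket(log(musp), lm_levels, "scattering", clamp = FALSE)
  nlam <- length(musp)
  out <- matrix(0, nlam, n_det)
  for (j in sort(unique(mb$i))) {
    sel <- mb$i == j
    u <- mb$frac[sel]                  # position along log-mus'
    a <- tb$frac                       # position along t_epi
    cells <- list(
      basis$cells[[tb$i]][[j]]$detectors,
      basis$cells[[tb$i]][[j + 1]]$detectors,
      basis$cells[[tb$i + 1]][[j]]$detectors,
      basis$cells[[tb$i + 1]][[j + 1]]$detectors)
    cellw <- cbind((1 - a) * (1 - u), (1 - a) * u, a * (1 - u), a * u)
    out[sel, ] <- bl_reflectance_cpp(cells, cellw,
                                     mua[sel, , drop = FALSE], n_det)
  }
  out
}
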