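# Closed-form chromophore spectra of the three-layer skin model.

#' Scattering parameters of the Mie/Rayleigh power-law model
#'
#' Parameter container for the reduced-scattering spectrum
#' \eqn{\mu_s'(\lambda) = \alpha((1-\gamma)(\lambda/600)^{-\beta} +
#' \gamma(\lambda/600)^{-4})}, where `alpha` is the reduced scattering
#' coefficient at 600 nm (mm^-1), `beta` the Mie scattering decay and
#' `gamma` the Rayleigh fraction.
#'
#' @param alpha Reduced scattering at 600 nm (mm^-1), > 0.
#' @param beta Mie scattering decay (dimensionless), >= 0.
#' @param gamma Rayleigh fraction in `[0, 1]`.
#' @return An object of class `scattering_params`.
#' @export
scattering_params <- function(alpha, beta, gamma) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            length(alpha) == 1L, length(beta) == 1L, length(gamma) == 1L)
  if (!is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a positive reduced scattering coefficient (mm^-1)")
  if (!is.finite(beta) || beta < 0) stop("'beta' must be >= 0")
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("'gamma' must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "scattering_params")
}

#' Epidermis parameters
#'
#' @param t_epi Epidermis thickness (mm), > 0.
#' @param f_mel Melanin content fraction in `[0, 1]`.
#' @param beta_mel Melanin spectral slope, > 0.
#' @return An object of class `epidermis_params`.
#' @export
epidermis_params <- function(t_epi, f_mel, beta_mel) {
  stopifnot(length(t_epi) == 1L, length(f_mel) == 1L, length(beta_mel) == 1L)
  if (!is.finite(t_epi) || t_epi <= 0) stop("'t_epi' must be > 0 (mm)")
  if (!is.finite(f_mel) || f_mel < 0 || f_mel > 1)
    stop("'f_mel' must lie in [0, 1]")
  if (!is.finite(beta_mel) || beta_mel <= 0) stop("'beta_mel' must be > 0")
  structure(list(t_epi = t_epi, f_mel = f_mel, beta_mel = beta_mel),
            class = "epidermis_params")
}

#' Dermis layer parameters
#'
#' @param f_blood Blood tissue fraction in `[0, 1]`.
#' @param s Hemoglobin oxygen saturation in `[0, 1]`.
#' @param vessel_radius Mean blood-vessel radius (mm) used in the vessel
#'   packaging correction; default 0.005 mm.
#' @param thickness Layer thickness (mm); `Inf` for the semi-infinite
#'   lower dermis.
#' @return An object of class `dermis_params`.
#' @export
dermis_params <- function(f_blood, s, vessel_radius = 0.005, thickness = Inf) {
  stopifnot(length(f_blood) == 1L, length(s) == 1L,
            length(vessel_radius) == 1L, length(thickness) == 1L)
  if (!is.finite(f_blood) || f_blood < 0 || f_blood > 1)
    stop("'f_blood' must lie in [0, 1]")
  if (!is.finite(s) || s < 0 || s > 1) stop("'s' must lie in [0, 1]")
  if (!is.finite(vessel_radius) || vessel_radius <= 0)
    stop("'vessel_radius' must be > 0 (mm)")
  if (thickness <= 0) stop("'thickness' must be > 0 (mm)")
  structure(list(f_blood = f_blood, s = s, vessel_radius = vessel_radius,
                 thickness = thickness),
            class = "dermis_params")
}

#' Reduced scattering coefficient spectrum
#'
#' Evaluates \eqn{\mu_s'(\lambda) = \alpha((1-\gamma)(\lambda/600)^{-\beta} +
#' \gamma(\lambda/600)^{-4})} (mm^-1). `alpha` equals the reduced scattering
#' coefficient at 600 nm by construction.
#'
#' @param lambda_nm Wavelengths (nm), > 0; vectorized.
#' @param p A [scattering_params()] object.
#' @return Reduced scattering coefficients (mm^-1), same length as
#'   `lambda_nm`.
#' @export
#' @examples
#' reduced_scattering(600, scattering_params(1.99, 0.82, 0.31))  # == 1.99
reduced_scattering <- function(lambda_nm, p) {
  stopifnot(inherits(p, "scattering_params"), is.numeric(lambda_nm))
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0))
    stop("'lambda_nm' must be positive")
  x <- lambda_nm / 600
  p$alpha * ((1 - p$gamma) * x^(-p$beta) + p$gamma * x^(-4))
}

#' Melanin absorption spectrum
#'
#' Evaluates \eqn{\mu_{a,mel}(\lambda) = 48.4 (\lambda/550)^{-\beta_{mel}}}
#' (mm^-1), the absorption spectrum of pure melanin; the epidermal absorption
#' coefficient is the melanin fraction `f_mel` times this value.
#'
#' @param lambda_nm Wavelengths (nm), > 0; vectorized.
#' @param beta_mel Melanin spectral slope, > 0.
#' @return Melanin absorption coefficients (mm^-1).
#' @export
melanin_absorption <- function(lambda_nm, beta_mel) {
  if (!is.numeric(beta_mel) || length(beta_mel) != 1L ||
      !is.finite(beta_mel) || beta_mel <= 0)
    stop("'beta_mel' must be a single positive number")
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0))
    stop("'lambda_nm' must be positive")
  48.4 * (lambda_nm / 550)^(-beta_mel)
}

#' Whole-blood absorption at a given oxygen saturation
#'
#' Linear mix \eqn{s\,\mu_{a,oxy}(\lambda) + (1-s)\,\mu_{a,deoxy}(\lambda)}
#' of the tabulated fully oxygenated and fully deoxygenated whole-blood
#' absorption spectra, linearly interpolated on the table grid.
#'
#' @param lambda_nm Wavelengths (nm) inside the table range; vectorized.
#' @param s Oxygen saturation in `[0, 1]`.
#' @param table A [hemoglobin_table()] object.
#' @return Whole-blood absorption coefficients (mm^-1).
#' @export
blood_absorption <- function(lambda_nm, s, table) {
  stopifnot(inherits(table, "hemoglobin_table"))
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1)
    stop("'s' must be a single saturation in [0, 1]")
  rng <- range(table$wavelengths)
  if (any(lambda_nm < rng[1]) || any(lambda_nm > rng[2]))
    stop(sprintf("wavelength outside hemoglobin table range [%g, %g] nm",
                 rng[1], rng[2]))
  oxy <- approx(table$wavelengths, table$mu_a_oxy, xout = lambda_nm)$y
  deoxy <- approx(table$wavelengths, table$mu_a_deoxy, xout = lambda_nm)$y
  s * oxy + (1 - s) * deoxy
}

#' Vessel packaging correction factor
#'
#' Mean-transmittance correction for hemoglobin confined to cylindrical
#' vessels of radius `vessel_radius` rather than homogeneously distributed:
#' \eqn{c_{vp} = (1 - e^{-2\mu_{a,bl}R}) / (2\mu_{a,bl}R)}, in `(0, 1]`,
#' with the \eqn{\mu_{a,bl} \to 0} limit handled analytically.
#'
#' @param mu_a_blood Whole-blood absorption coefficients (mm^-1), >= 0;
#'   vectorized.
#' @param vessel_radius Mean vessel radius (mm), > 0.
#' @return Packaging factors in `(0, 1]`.
#' @export
vessel_packing_factor <- function(mu_a_blood, vessel_radius) {
  if (!is.numeric(vessel_radius) || length(vessel_radius) != 1L ||
      vessel_radius <= 0)
    stop("'vessel_radius' must be a single positive radius (mm)")
  if (any(mu_a_blood < 0)) stop("'mu_a_blood' must be >= 0")
  x <- 2 * mu_a_blood * vessel_radius
  out <- ifelse(x < 1e-8, 1 - x / 2, (1 - exp(-x)) / pmax(x, 1e-300))
  out
}

#' Dermis absorption coefficient
#'
#' Evaluates \eqn{\mu_a(\lambda) = f_{blood}\, c_{vp}\,
#' (s\,\mu_{a,oxy} + (1-s)\,\mu_{a,deoxy})} for one dermis layer. The
#' packaging factor is evaluated at the saturation-mixed blood absorption.
#'
#' @param lambda_nm Wavelengths (nm); vectorized.
#' @param d A [dermis_params()] object.
#' @param table A [hemoglobin_table()] object.
#' @return Dermal absorption coefficients (mm^-1).
#' @export
dermis_absorption <- function(lambda_nm, d, table) {
  stopifnot(inherits(d, "dermis_params"))
  mu_bl <- blood_absorption(lambda_nm, d$s, table)
  d$f_blood * vessel_packing_factor(mu_bl, d$vessel_radius) * mu_bl
}
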