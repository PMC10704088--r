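# Simulation-based validation: generate synthetic subjects with the forward
# model and refit them with the inverse solver.

#' Parameter-recovery study on synthetic spectra
#'
#' Draws `n_subjects` cohort-like parameter sets, synthesizes their noisy
#' two-separation spectra with the forward model, refits every spectrum
#' with the multi-start inverse solver (warm-started subject to subject),
#' and reports per-subject recovery errors for the hemoglobin oxygen
#' saturation (absolute, percentage points) and the upper-dermis blood
#' tissue fraction (relative, percent).
#'
#' @param basis An `mc_basis` covering the cohort parameter range. The same
#'   basis drives generation and fitting, so reported errors isolate the
#'   effect of measurement noise and solver behaviour.
#' @param n_subjects Number of synthetic subjects.
#' @param seed Master seed for cohort draws, noise, and solver starts.
#' @param noise_sd Multiplicative per-channel noise SD.
#' @param config Optional [fit_config()]; a default tuned for 1% noise is
#'   used when omitted.
#' @param table Hemoglobin table; bundled fixture when omitted.
#' @param max_detected Photon cap applied to the basis via [thin_basis()]
#'   before the study (`Inf` to keep all photons).
#' @param progress Print per-subject fit progress.
#' @return List with `truth` (drawn parameters), `fits` (table from
#'   [fits_to_table()]), `err_s_pp` (absolute saturation errors,
#'   percentage points) and `err_fblood1_pct` (relative upper-dermis blood
#'   fraction errors, percent).
#' @export
recovery_study <- function(basis, n_subjects = 50, seed = 1,
                           noise_sd = 0.01, config = NULL, table = NULL,
                           max_detected = 600, progress = FALSE) {
  stopifnot(inherits(basis, "mc_basis"))
  if (is.null(table)) table <- compile_hemoglobin_table()
  if (is.finite(max_detected)) basis <- thin_basis(basis, max_detected)
  if (is.null(config)) config <- fit_config(seed = seed + 1)
  spec <- cohort_spec(n_subjects, seed = seed, noise_sd = noise_sd)
  dr <- draw_parameters(spec)
  spectra <- generate_spectra(dr$params, basis, spec, table = table)
  fits <- fit_cohort(spectra, basis, config, table = table,
                     progress = progress)
  tb <- fits_to_table(fits)
  list(truth = dr$truth, fits = tb,
       err_s_pp = 100 * abs(tb$s - dr$truth$s),
       err_fblood1_pct = 100 * abs(tb$f_blood1 - dr$truth$f_blood1) /
         dr$truth$f_blood1)
}

#' Default basis configuration for cohort studies
#'
#' Grid levels spanning the synthetic cohort's epidermis thicknesses and
#' the reduced-scattering spectra implied by its scattering parameters.
#'
#' @return List with `t_epi_levels` (mm) and `musp_levels` (mm^-1).
#' @export
cohort_basis_levels <- function() {
  list(t_epi_levels = c(0.01, 0.025, 0.06, 0.15, 0.3),
       musp_levels = exp(seq(log(0.45), log(6.7), length.out = 7)))
}
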