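# Synthetic cohort generation: parameter draws matching published
# median/IQR distributions, pushed through the forward model with noise.

#' Default cohort parameter quartiles
#'
#' Median and 25th/75th percentiles of the nine model parameters in a
#' middle-aged, primarily fair-skinned cohort (volar forearm), used to fit
#' the sampling distributions of [draw_parameters()].
#'
#' @return Data frame with columns `param`, `median`, `q25`, `q75`, `dist`.
#' @export
cohort_quartiles <- function() {
  data.frame(
    param  = c("alpha", "beta", "gamma", "t_epi", "f_mel", "beta_mel",
               "f_blood1", "f_blood2", "s"),
    median = c(1.99, 0.82, 0.31, 0.063, 0.050, 4.3, 0.011, 0.0075, 0.50),
    q25    = c(1.78, 0.55, 0.21, 0.013, 0.016, 2.9, 0.0071, 0.0058, 0.41),
    q75    = c(2.38, 1.20, 0.39, 0.191, 0.21, 5.8, 0.016, 0.010, 0.60),
    dist   = c("lognormal", "lognormal", "lognormal", "lognormal",
               "lognormal", "lognormal", "lognormal", "lognormal", "normal"),
    stringsAsFactors = FALSE)
}

# Truncation limits keeping draws inside a realistic, basis-coverable range.
default_cohort_limits <- function() {
  rbind(lower = c(alpha = 1.4, beta = 0.15, gamma = 0.08, t_epi = 0.012,
                  f_mel = 0.005, beta_mel = 1.2, f_blood1 = 0.002,
                  f_blood2 = 0.0015, s = 0.05),
        upper = c(alpha = 3.0, beta = 2.0, gamma = 0.60, t_epi = 0.28,
                  f_mel = 0.60, beta_mel = 7.5, f_blood1 = 0.05,
                  f_blood2 = 0.04, s = 0.95))
}

# Seasonal melanin multipliers (month effect on f_mel), scaled so that the
# epidermal melanin absorbance roughly triples from late winter to early
# summer; disabled by default.
month_melanin_multiplier <- c(0.80, 0.72, 0.66, 0.80, 1.20, 1.85, 1.80,
                              1.70, 1.50, 1.20, 1.00, 0.85)

#' Synthetic cohort specification
#'
#' @param n_subjects Number of subjects, >= 1.
#' @param seed Cohort seed; all draws are reproducible from it.
#' @param quartiles Parameter quartile table, see [cohort_quartiles()].
#' @param limits Two-row truncation matrix (`lower`/`upper`) per parameter.
#' @param noise_sd Multiplicative measurement noise (relative SD per
#'   channel), default 0.01.
#' @param noise_floor Additive Gaussian noise SD in intensity units,
#'   default 0.
#' @param month_effect Scale each subject's melanin fraction by a seasonal
#'   multiplier for their (random) measurement month.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed = 1, quartiles = cohort_quartiles(),
                        limits = default_cohort_limits(), noise_sd = 0.01,
                        noise_floor = 0, month_effect = FALSE) {
  stopifnot(n_subjects >= 1, noise_sd >= 0, noise_floor >= 0)
  if (any(!(quartiles$q25 < quartiles$median &
            quartiles$median < quartiles$q75)))
    stop("percentiles must satisfy q25 < median < q75: configuration error")
  structure(list(n_subjects = as.integer(n_subjects), seed = seed,
                 quartiles = quartiles, limits = limits, noise_sd = noise_sd,
                 noise_floor = noise_floor, month_effect = month_effect),
            class = "cohort_spec")
}

#' Fit a two-parameter distribution to a quartile pair
#'
#' Closed form: a log-normal (or normal) whose 25th and 75th percentiles
#' equal `q25`/`q75` exactly. The implied median is `sqrt(q25*q75)`
#' (log-normal) or `(q25+q75)/2` (normal), within a few percent of the
#' published medians for all parameters.
#'
#' @param q25,q75 Target quartiles.
#' @param dist `"lognormal"` or `"normal"`.
#' @return List with the distribution parameters (`meanlog`/`sdlog` or
#'   `mean`/`sd`).
#' @export
quartile_dist <- function(q25, q75, dist = c("lognormal", "normal")) {
  dist <- match.arg(dist)
  z <- qnorm(0.75)
  if (dist == "lognormal") {
    list(dist = dist, meanlog = (log(q25) + log(q75)) / 2,
         sdlog = (log(q75) - log(q25)) / (2 * z))
  } else {
    list(dist = dist, mean = (q25 + q75) / 2, sd = (q75 - q25) / (2 * z))
  }
}

# truncated draw by rejection, deterministic under the caller's RNG state
draw_truncated <- function(n, dd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- if (dd$dist == "lognormal")
      rlnorm(n, dd$meanlog, dd$sdlog) else rnorm(n, dd$mean, dd$sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Draw cohort skin-model parameters and covariates
#'
#' Each parameter is drawn independently from the two-parameter distribution
#' matching its quartiles (log-normal for the positive skewed parameters,
#' normal for the oxygen saturation), truncated to the spec limits by
#' rejection. Covariates (sex, age 50-65, BMI category, measurement month)
#' are drawn alongside; the optional month effect multiplies the melanin
#' fraction by a seasonal factor.
#'
#' @param spec A [cohort_spec()].
#' @return List with `params` (list of `skin_params`) and `truth` (data
#'   frame: the nine parameter columns plus covariates).
#' @export
draw_parameters <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  q <- spec$quartiles
  n <- spec$n_subjects
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  draws <- matrix(NA_real_, n, nrow(q), dimnames = list(NULL, q$param))
  for (i in seq_len(nrow(q))) {
    dd <- quartile_dist(q$q25[i], q$q75[i], q$dist[i])
    draws[, i] <- draw_truncated(n, dd, spec$limits["lower", q$param[i]],
                                 spec$limits["upper", q$param[i]])
  }
  truth <- as.data.frame(draws)
  truth$sex <- sample(c("male", "female"), n, replace = TRUE)
  truth$age <- runif(n, 50, 65)
  truth$bmi <- rnorm(n, 26.9, 4.4)
  truth$bmi_group <- cut(truth$bmi, c(-Inf, 18.5, 25, 30, Inf),
                         labels = c("underweight", "healthy", "overweight",
                                    "obese"), right = FALSE)
  truth$month <- sample(1:12, n, replace = TRUE)
  if (spec$month_effect) {
    truth$f_mel <- pmin(truth$f_mel *
                          month_melanin_multiplier[truth$month],
                        spec$limits["upper", "f_mel"])
  }
  params <- lapply(seq_len(n), function(i)
    skin_params_from_vector(unlist(truth[i, q$param])))
  list(params = params, truth = truth)
}

#' Generate noisy measured spectra for a cohort
#'
#' Pushes each subject's parameters through [model_reflectance()] and adds
#' per-channel multiplicative Gaussian noise (relative SD `noise_sd`) and an
#' optional additive Gaussian floor. Notch-masked channels carry data but
#' stay flagged invalid. Per-subject noise seeds derive from the cohort
#' seed.
#'
#' @param params List of `skin_params` (e.g. from [draw_parameters()]).
#' @param basis An `mc_basis` covering the drawn parameters.
#' @param spec The [cohort_spec()] holding the noise model.
#' @param table Hemoglobin table; bundled fixture when omitted.
#' @param wavelengths,mask Wavelength grid; default [default_wavelengths()].
#' @return List of `reflectance_spectrum` objects.
#' @export
generate_spectra <- function(params, basis, spec, table = NULL,
                             wavelengths = NULL, mask = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(table)) table <- compile_hemoglobin_table()
  if (is.null(wavelengths)) {
    grid <- default_wavelengths()
    wavelengths <- grid$wavelengths
    mask <- grid$mask
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  lapply(seq_along(params), function(i) {
    clean <- model_reflectance(params[[i]], basis, wavelengths = wavelengths,
                               table = table, mask = mask)
    set.seed((spec$seed * 1009 + i) %% .Machine$integer.max)
    noisy <- clean$intensity *
      (1 + spec$noise_sd * matrix(rnorm(length(clean$intensity)),
                                  nrow(clean$intensity)))
    if (spec$noise_floor > 0)
      noisy <- noisy + spec$noise_floor *
        matrix(rnorm(length(noisy)), nrow(noisy))
    reflectance_spectrum(wavelengths, noisy, mask = clean$mask,
                         separations = clean$separations)
  })
}
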