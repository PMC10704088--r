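# Multi-start bounded inverse solver for the three-layer skin model.
#
# The objective surface is strongly multimodal (the epidermis
# thickness/melanin product degeneracy creates families of near-equivalent
# local minima), so the solver works in stages: a large library of starting
# points concentrated on physiologically plausible parameter combinations is
# ranked by the objective, the best candidates receive a short
# Levenberg-Marquardt polish, the best of those are polished to convergence,
# and the whole pass is restarted from a fresh library while the residual
# stays above a noise-consistent threshold.

#' Default parameter bounds for the nine free parameters
#'
#' @return Two-row matrix (`lower`, `upper`) with one column per parameter.
#' @export
default_bounds <- function() {
  rbind(
    lower = c(alpha = 0.5, beta = 0, gamma = 0, t_epi = 0.01, f_mel = 0,
              beta_mel = 1, f_blood1 = 0, f_blood2 = 0, s = 0),
    upper = c(alpha = 5, beta = 4, gamma = 1, t_epi = 0.3, f_mel = 1,
              beta_mel = 8, f_blood1 = 0.1, f_blood2 = 0.1, s = 1))
}

#' Inverse-solver configuration
#'
#' @param bounds Two-row `lower`/`upper` matrix over the nine free
#'   parameters; see [default_bounds()].
#' @param n_probe Size of the starting-point library evaluated per pass.
#' @param n_short Candidates receiving a short polish per pass.
#' @param n_polish Candidates polished to convergence per pass (the
#'   returned optimum is the best over all polished starts; adding starts
#'   can only improve it).
#' @param short_maxiter,maxiter Levenberg-Marquardt iteration caps for the
#'   short and full polish stages.
#' @param ftol,ptol Convergence tolerances on the relative objective /
#'   parameter change.
#' @param restart_rms Restart with a fresh start library while the relative
#'   RMS residual exceeds this value (set it a little above the expected
#'   measurement noise level); `Inf` disables restarts.
#' @param min_passes,max_passes Floor and cap on start-library passes; the
#'   best result over all passes is kept. `min_passes = NULL` (default)
#'   means two passes where `max_passes` allows: the
#'   objective differences between competing local basins are comparable to
#'   the noise floor, so a single library draw picks the wrong basin too
#'   often.
#' @param prior_inflation Spread inflation of the physiological
#'   starting-point distributions relative to the cohort quartiles.
#' @param lhs_fraction Fraction of the library drawn by Latin hypercube over
#'   the full bounds box rather than from the physiological distributions.
#' @param seed Seed controlling the starting points (deterministic).
#' @param max_fit_error Exclusion threshold on the relative RMS residual
#'   (an invented default; the source analysis does not publish one).
#' @param min_fblood Exclusion threshold on the fitted upper-dermis blood
#'   fraction (likewise an invented default).
#' @param vessel_radius Fixed vessel radius (mm) used during fitting.
#' @param use_warm_start Use a supplied (or previous-subject) solution as an
#'   additional starting candidate.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bounds = default_bounds(), n_probe = 1200,
                       n_short = 10, n_polish = 6, short_maxiter = 35,
                       maxiter = 200, ftol = 1e-12, ptol = 1e-12,
                       restart_rms = 0.0105, min_passes = NULL,
                       max_passes = 3,
                       prior_inflation = 1.5, lhs_fraction = 0.25, seed = 1,
                       max_fit_error = 0.10, min_fblood = 0.002,
                       vessel_radius = 0.005, use_warm_start = TRUE) {
  if (is.null(min_passes)) min_passes <- min(2, max_passes)
  stopifnot(nrow(bounds) == 2, ncol(bounds) == 9, all(is.finite(bounds)),
            all(bounds[1, ] < bounds[2, ]), n_probe >= 1, n_short >= 1,
            n_polish >= 1, max_passes >= 1,
            min_passes >= 1, min_passes <= max_passes,
            lhs_fraction >= 0, lhs_fraction <= 1)
  structure(list(bounds = bounds, n_probe = n_probe, n_short = n_short,
                 n_polish = n_polish, short_maxiter = short_maxiter,
                 maxiter = maxiter, ftol = ftol, ptol = ptol,
                 restart_rms = restart_rms, min_passes = min_passes,
                 max_passes = max_passes,
                 prior_inflation = prior_inflation,
                 lhs_fraction = lhs_fraction, seed = seed,
                 max_fit_error = max_fit_error, min_fblood = min_fblood,
                 vessel_radius = vessel_radius,
                 use_warm_start = use_warm_start),
            class = "fit_config")
}

#' Fit objective: relative least squares with profiled detector scales
#'
#' Compares a measured and a modeled spectrum on the unmasked channels. For
#' each detector one multiplicative scale factor is profiled out in closed
#' form (the model has no absolute calibration), and the objective is the
#' sum over both detectors of squared relative residuals
#' `(1 - k * modeled / measured)^2`.
#'
#' @param measured,modeled `reflectance_spectrum` objects on identical
#'   wavelength grids and masks.
#' @return List with `value` (scalar objective), `scales` (per detector),
#'   `residuals` (vector over unmasked channels, both detectors), and
#'   `rms` (relative RMS residual).
#' @export
drs_objective <- function(measured, modeled) {
  stopifnot(inherits(measured, "reflectance_spectrum"),
            inherits(modeled, "reflectance_spectrum"))
  if (!isTRUE(all.equal(measured$wavelengths, modeled$wavelengths)) ||
      !identical(measured$mask, modeled$mask))
    stop("measured and modeled spectra must share the wavelength grid and mask")
  sel <- measured$mask
  n_det <- ncol(measured$intensity)
  res <- numeric(0)
  scales <- numeric(n_det)
  for (k in seq_len(n_det)) {
    m <- measured$intensity[sel, k]
    M <- modeled$intensity[sel, k]
    y <- M / m
    k_hat <- sum(y) / sum(y^2)
    if (!is.finite(k_hat)) k_hat <- 0
    scales[k] <- k_hat
    res <- c(res, 1 - k_hat * y)
  }
  list(value = sum(res^2), scales = scales, residuals = res,
       rms = sqrt(mean(res^2)))
}

# Residual function factory: precomputes everything reusable across
# evaluations of one measured spectrum. `channel_stride` thins the
# wavelength grid (used for cheap start-library ranking only).
make_residual_fn <- function(measured, basis, table, vessel_radius,
                             channel_stride = 1) {
  sel <- which(measured$mask)
  if (channel_stride > 1) sel <- sel[seq(1, length(sel), by = channel_stride)]
  wl <- measured$wavelengths[sel]
  m <- measured$intensity[sel, , drop = FALSE]
  n_det <- ncol(m)
  oxy <- approx(table$wavelengths, table$mu_a_oxy, xout = wl)$y
  deoxy <- approx(table$wavelengths, table$mu_a_deoxy, xout = wl)$y
  x550 <- wl / 550
  x600 <- wl / 600
  function(theta) {
    mu_bl <- theta[9] * oxy + (1 - theta[9]) * deoxy
    cvp <- vessel_packing_factor(mu_bl, vessel_radius)
    mua <- cbind(theta[5] * 48.4 * x550^(-theta[6]),
                 theta[7] * cvp * mu_bl,
                 theta[8] * cvp * mu_bl)
    musp <- theta[1] * ((1 - theta[3]) * x600^(-theta[2]) +
                          theta[3] * x600^(-4))
    M <- bl_interp_intensity(basis, theta[4], musp, mua, clamp = TRUE)
    res <- numeric(0)
    for (k in seq_len(n_det)) {
      y <- M[, k] / m[, k]
      k_hat <- sum(y) / sum(y^2)
      if (!is.finite(k_hat)) k_hat <- 0
      res <- c(res, 1 - k_hat * y)
    }
    res
  }
}

# Starting-point library: physiologically plausible draws (quartile-matched
# distributions with inflated spread) mixed with Latin-hypercube coverage of
# the full bounds box. Drawn under a local RNG seed.
start_library <- function(n, bounds, seed, prior_inflation = 1.5,
                          lhs_fraction = 0.25) {
  q <- cohort_quartiles()
  lower <- bounds[1, ]
  upper <- bounds[2, ]
  n_lhs <- round(n * lhs_fraction)
  n_prior <- n - n_lhs
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  prior <- sapply(seq_len(nrow(q)), function(i) {
    d <- quartile_dist(q$q25[i], q$q75[i], q$dist[i])
    if (d$dist == "lognormal")
      rlnorm(n_prior, d$meanlog, prior_inflation * d$sdlog)
    else rnorm(n_prior, d$mean, prior_inflation * d$sd)
  })
  box <- sweep(sweep(lhs::randomLHS(max(n_lhs, 1), 9), 2, upper - lower, "*"),
               2, lower, "+")
  out <- rbind(prior, box[seq_len(n_lhs), , drop = FALSE])
  colnames(out) <- q$param
  for (j in seq_len(9)) out[, j] <- pmin(pmax(out[, j], lower[j]), upper[j])
  out
}

#' Fit the three-layer skin model to a measured spectrum
#'
#' Bounded multi-start Levenberg-Marquardt minimization of
#' [drs_objective()]; see [fit_config()] for the staged search strategy.
#' Returns the best local optimum over all polished starts; the objective at
#' the result is never above the objective at any evaluated starting point.
#'
#' @param measured A `reflectance_spectrum` covering 475-850 nm.
#' @param basis An `mc_basis`.
#' @param config A [fit_config()].
#' @param warm_start Optional `skin_params` (or named 9-vector) used as an
#'   additional starting candidate.
#' @param table Hemoglobin table; bundled fixture when omitted.
#' @return An object of class `fit_result`: fitted `params`, `theta`
#'   (named vector), `objective`, `rms` (relative RMS residual), `scales`,
#'   `n_starts` (polished starts over all passes), `n_passes`,
#'   `start_objectives`, convergence info, and the `excluded` flag (set by
#'   [apply_exclusions()]).
#' @export
fit_spectrum <- function(measured, basis, config = fit_config(),
                         warm_start = NULL, table = NULL) {
  stopifnot(inherits(measured, "reflectance_spectrum"),
            inherits(basis, "mc_basis"), inherits(config, "fit_config"))
  if (is.null(table)) table <- compile_hemoglobin_table()
  lower <- config$bounds[1, ]
  upper <- config$bounds[2, ]
  rng <- upper - lower
  resid_fn <- make_residual_fn(measured, basis, table, config$vessel_radius)
  probe_fn <- make_residual_fn(measured, basis, table, config$vessel_radius,
                               channel_stride = 3)
  # unit-box coordinates keep the LM trust region well scaled
  as_unit <- function(th) (th - lower) / rng
  from_unit <- function(u) lower + pmin(pmax(u, 0), 1) * rng
  rfu <- function(u) resid_fn(from_unit(u))

  warm <- NULL
  if (!is.null(warm_start) && config$use_warm_start) {
    th0 <- if (inherits(warm_start, "skin_params"))
      skin_params_to_vector(warm_start) else warm_start
    warm <- pmin(pmax(th0[colnames(config$bounds)], lower), upper)
  }

  best <- NULL
  start_obj <- numeric(0)
  n_polished <- 0L
  pass <- 0L
  while (pass < config$max_passes) {
    pass <- pass + 1L
    lib <- start_library(config$n_probe, config$bounds,
                         seed = config$seed + 7907L * (pass - 1L),
                         prior_inflation = config$prior_inflation,
                         lhs_fraction = config$lhs_fraction)
    if (!is.null(warm) && pass == 1L) lib <- rbind(warm, lib)
    lib_u <- t(apply(lib, 1, as_unit))
    probe_val <- apply(lib_u, 1, function(u) sum(probe_fn(from_unit(u))^2))
    ord <- order(probe_val)[seq_len(min(config$n_short, nrow(lib_u)))]
    # force candidate diversity along the weakly identified epidermis
    # thickness: add the best-ranked probe from each thickness stratum
    t_bins <- exp(seq(log(lower[["t_epi"]]), log(upper[["t_epi"]]),
                      length.out = 6))
    strata <- findInterval(lib[, "t_epi"], t_bins,
                           rightmost.closed = TRUE)
    for (b in unique(strata)) {
      cand <- which(strata == b)
      bestb <- cand[which.min(probe_val[cand])]
      if (!(bestb %in% ord)) ord <- c(ord, bestb)
    }
    shorts <- lapply(ord, function(k) {
      tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(lib_u[k, ], lower = rep(0, 9),
                             upper = rep(1, 9), fn = rfu,
                             control = minpack.lm::nls.lm.control(
                               maxiter = config$short_maxiter))),
        error = function(e) NULL)
    })
    shorts <- Filter(Negate(is.null), shorts)
    if (length(shorts) == 0) next
    d1 <- vapply(shorts, function(f) f$deviance, numeric(1))
    for (f0 in shorts[order(d1)[seq_len(min(config$n_polish,
                                            length(shorts)))]]) {
      f <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(f0$par, lower = rep(0, 9), upper = rep(1, 9),
                             fn = rfu,
                             control = minpack.lm::nls.lm.control(
                               maxiter = config$maxiter, ftol = config$ftol,
                               ptol = config$ptol))),
        error = function(e) NULL)
      if (is.null(f)) next
      n_polished <- n_polished + 1L
      start_obj <- c(start_obj, f$deviance)
      if (is.null(best) || f$deviance < best$deviance) best <- f
    }
    if (pass >= config$min_passes && !is.null(best) &&
        sqrt(mean(best$fvec^2)) <= config$restart_rms) break
  }

  if (is.null(best)) {
    return(structure(list(params = NULL, theta = NULL, objective = Inf,
                          rms = Inf, scales = NULL, n_starts = 0L,
                          n_passes = pass, start_objectives = start_obj,
                          converged = FALSE, excluded = TRUE,
                          exclusion_reason = "fit failure"),
                     class = "fit_result"))
  }
  theta <- setNames(from_unit(best$par), colnames(config$bounds))
  params <- skin_params_from_vector(theta,
                                    vessel_radius = config$vessel_radius,
                                    dermis1_thickness =
                                      basis$dermis1_thickness)
  modeled <- model_reflectance(params, basis,
                               wavelengths = measured$wavelengths,
                               table = table, mask = measured$mask,
                               clamp = TRUE)
  obj <- drs_objective(measured, modeled)
  structure(list(params = params, theta = theta, objective = obj$value,
                 rms = obj$rms, scales = obj$scales,
                 n_starts = n_polished, n_passes = pass,
                 start_objectives = start_obj,
                 converged = TRUE, lm_info = best$info,
                 excluded = FALSE, exclusion_reason = NA_character_),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Three-layer skin model fit\n")
  if (!x$converged) {
    cat("  FAILED (no start converged)\n")
    return(invisible(x))
  }
  cat(sprintf("  objective %.3g (relative RMS %.3g), %d starts / %d passes\n",
              x$objective, x$rms, x$n_starts, x$n_passes))
  print(signif(x$theta, 4))
  if (isTRUE(x$excluded))
    cat(sprintf("  EXCLUDED: %s\n", x$exclusion_reason))
  invisible(x)
}

#' Apply the cohort exclusion rules to a fit
#'
#' Flags a fit as excluded when the relative RMS residual exceeds the
#' fit-error threshold or the fitted upper-dermis blood fraction falls below
#' the low-blood threshold (parameters poorly identified without blood
#' contrast).
#'
#' @param result A `fit_result`.
#' @param config The [fit_config()] holding the thresholds.
#' @return The `fit_result` with `excluded`/`exclusion_reason` set.
#' @export
apply_exclusions <- function(result, config) {
  stopifnot(inherits(result, "fit_result"), inherits(config, "fit_config"))
  if (!result$converged) {
    result$excluded <- TRUE
    result$exclusion_reason <- "fit failure"
    return(result)
  }
  if (result$rms > config$max_fit_error) {
    result$excluded <- TRUE
    result$exclusion_reason <- "fit error"
  } else if (result$theta[["f_blood1"]] < config$min_fblood) {
    result$excluded <- TRUE
    result$exclusion_reason <- "low blood"
  } else {
    result$excluded <- FALSE
    result$exclusion_reason <- NA_character_
  }
  result
}

#' Fit a sequence of spectra with warm starting
#'
#' Fits each spectrum in turn; when warm starting is enabled the previous
#' solution is used as an additional starting candidate for the next
#' spectrum (the measured spectra of consecutive subjects/time points are
#' often similar).
#'
#' @param spectra List of `reflectance_spectrum` objects.
#' @param basis An `mc_basis`.
#' @param config A [fit_config()].
#' @param table Hemoglobin table; bundled fixture when omitted.
#' @param progress Print one line per subject.
#' @return List of `fit_result` objects (exclusion rules applied).
#' @export
fit_cohort <- function(spectra, basis, config = fit_config(), table = NULL,
                       progress = FALSE) {
  if (is.null(table)) table <- compile_hemoglobin_table()
  out <- vector("list", length(spectra))
  prev <- NULL
  for (i in seq_along(spectra)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + 131L * i
    res <- fit_spectrum(spectra[[i]], basis, cfg_i, warm_start = prev,
                        table = table)
    res <- apply_exclusions(res, config)
    if (res$converged) prev <- res$theta
    out[[i]] <- res
    if (progress)
      message(sprintf("subject %d/%d: rms %.3g%s", i, length(spectra),
                      res$rms,
                      if (isTRUE(res$excluded))
                        paste0(" excluded (", res$exclusion_reason, ")")
                      else ""))
  }
  out
}

#' Collect fitted parameters into a data frame
#'
#' @param fits List of `fit_result` objects (e.g. from [fit_cohort()]).
#' @return Data frame with one row per fit: the nine parameters, the
#'   relative RMS residual, and the exclusion status.
#' @export
fits_to_table <- function(fits) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    th <- if (f$converged) f$theta else
      setNames(rep(NA_real_, 9), colnames(default_bounds()))
    data.frame(subject = i, t(th), rms = f$rms,
               excluded = isTRUE(f$excluded),
               reason = f$exclusion_reason %||% NA_character_)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
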