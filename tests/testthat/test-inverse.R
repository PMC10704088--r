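# Objective function and inverse solver.

make_modeled <- function(basis, tab, theta = NULL) {
  if (is.null(theta))
    theta <- c(alpha = 1.7, beta = 0.8, gamma = 0.3, t_epi = 0.06,
               f_mel = 0.04, beta_mel = 4, f_blood1 = 0.012,
               f_blood2 = 0.007, s = 0.55)
  model_reflectance(skin_params_from_vector(theta), basis, table = tab)
}

test_that("the objective is zero for identical and rescaled spectra", {
  basis <- unit_basis()
  tab <- hb_table()
  sp <- make_modeled(basis, tab)
  expect_equal(drs_objective(sp, sp)$value, 0)
  # independent per-detector rescaling is profiled away
  m2 <- sp
  m2$intensity <- sp$intensity %*% diag(c(2.4, 0.3))
  obj <- drs_objective(m2, sp)
  expect_equal(obj$value, 0, tolerance = 1e-20)
  expect_equal(obj$scales, c(2.4, 0.3), tolerance = 1e-12)
})

test_that("the objective ignores channels inside the notch mask", {
  basis <- unit_basis()
  tab <- hb_table()
  sp <- make_modeled(basis, tab)
  m2 <- sp
  notch <- !sp$mask
  expect_gt(sum(notch), 0)
  m2$intensity[notch, ] <- m2$intensity[notch, ] * 17
  expect_equal(drs_objective(m2, sp)$value, 0, tolerance = 1e-20)
})

test_that("mismatched grids are rejected", {
  basis <- unit_basis()
  tab <- hb_table()
  sp <- make_modeled(basis, tab)
  other <- reflectance_spectrum(sp$wavelengths + 1, sp$intensity, sp$mask)
  expect_error(drs_objective(sp, other), "grid")
})

test_that("noiseless spectra are recovered to numerical precision", {
  basis <- unit_basis()
  tab <- hb_table()
  truth <- c(alpha = 1.7, beta = 0.8, gamma = 0.3, t_epi = 0.06,
             f_mel = 0.04, beta_mel = 4, f_blood1 = 0.012,
             f_blood2 = 0.007, s = 0.55)
  sp <- make_modeled(basis, tab, truth)
  cfg <- fit_config(n_probe = 60, n_short = 2, n_polish = 1,
                    max_passes = 1, seed = 5)
  fit <- fit_spectrum(sp, basis, cfg, warm_start = truth, table = tab)
  expect_lt(fit$rms, 1e-6)
  # layer absorptions at 575 nm within 5% of truth
  mua_fit <- layer_absorptions(fit$params, 575, tab)
  mua_true <- layer_absorptions(skin_params_from_vector(truth), 575, tab)
  expect_equal(mua_fit[1, 2], mua_true[1, 2], tolerance = 0.05)
  expect_equal(mua_fit[1, 3], mua_true[1, 3], tolerance = 0.05)
  # the epidermal absorbance product is identified even when thickness and
  # melanin fraction individually are not
  prod_fit <- fit$theta[["t_epi"]] * fit$theta[["f_mel"]]
  expect_equal(prod_fit, truth[["t_epi"]] * truth[["f_mel"]],
               tolerance = 0.1)
})

test_that("multi-start search finds the noiseless optimum without hints", {
  basis <- unit_basis()
  tab <- hb_table()
  truth <- c(alpha = 2.1, beta = 0.7, gamma = 0.25, t_epi = 0.05,
             f_mel = 0.06, beta_mel = 4.5, f_blood1 = 0.010,
             f_blood2 = 0.006, s = 0.45)
  sp <- make_modeled(basis, tab, truth)
  cfg <- fit_config(n_probe = 600, n_short = 8, n_polish = 3,
                    max_passes = 2, restart_rms = 1e-4, seed = 3)
  fit <- fit_spectrum(sp, basis, cfg, table = tab)
  expect_lt(fit$rms, 1e-3)
  mua_fit <- layer_absorptions(fit$params, 575, tab)
  mua_true <- layer_absorptions(skin_params_from_vector(truth), 575, tab)
  expect_equal(mua_fit[1, 2], mua_true[1, 2], tolerance = 0.10)
  expect_equal(mua_fit[1, 3], mua_true[1, 3], tolerance = 0.10)
})

test_that("adding polished starts never worsens the returned objective", {
  basis <- unit_basis()
  tab <- hb_table()
  truth <- c(alpha = 1.8, beta = 0.9, gamma = 0.3, t_epi = 0.07,
             f_mel = 0.05, beta_mel = 3.5, f_blood1 = 0.013,
             f_blood2 = 0.008, s = 0.6)
  sp <- make_modeled(basis, tab, truth)
  objs <- vapply(c(1, 3), function(np) {
    cfg <- fit_config(n_probe = 200, n_short = 3, n_polish = np,
                      max_passes = 1, seed = 11)
    fit_spectrum(sp, basis, cfg, table = tab)$objective
  }, numeric(1))
  expect_lte(objs[2], objs[1] + 1e-15)
})

test_that("exclusion rules flag fit error and low blood with reasons", {
  cfg <- fit_config()
  ok <- structure(list(converged = TRUE, rms = 0.01,
                       theta = c(f_blood1 = 0.01)), class = "fit_result")
  r <- apply_exclusions(ok, cfg)
  expect_false(r$excluded)
  bad_fit <- ok; bad_fit$rms <- 0.2
  r <- apply_exclusions(bad_fit, cfg)
  expect_true(r$excluded)
  expect_equal(r$exclusion_reason, "fit error")
  low <- ok; low$theta <- c(f_blood1 = 0)
  r <- apply_exclusions(low, cfg)
  expect_true(r$excluded)
  expect_equal(r$exclusion_reason, "low blood")
})
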