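# Closed-form chromophore spectra.

test_that("reduced scattering matches its defining power law", {
  p <- scattering_params(1.99, 0.82, 0.31)
  # alpha is mu_s' at the 600 nm reference by construction
  expect_equal(reduced_scattering(600, p), 1.99, tolerance = 1e-12)
  # direct evaluation at 475 nm (frozen from the closed form)
  expect_equal(reduced_scattering(475, p), 3.2335, tolerance = 1e-4)
  # beta = 4 collapses both terms onto the Rayleigh power law
  lam <- seq(450, 900, by = 50)
  p4 <- scattering_params(2.5, 4, 0.37)
  expect_equal(reduced_scattering(lam, p4), 2.5 * (lam / 600)^-4,
               tolerance = 1e-12)
})

test_that("reduced scattering is positive, decreasing, and linear in alpha", {
  set.seed(1)
  lam <- seq(475, 850, by = 5)
  for (i in 1:20) {
    p <- scattering_params(runif(1, 0.5, 5), runif(1, 0.05, 4), runif(1))
    v <- reduced_scattering(lam, p)
    expect_true(all(v > 0))
    expect_true(all(diff(v) < 0))
    p2 <- scattering_params(3 * p$alpha, p$beta, p$gamma)
    expect_equal(reduced_scattering(lam, p2), 3 * v, tolerance = 1e-12)
  }
  expect_error(reduced_scattering(-5, p), "positive")
  expect_error(scattering_params(-1, 1, 0.3), "alpha")
  expect_error(scattering_params(2, 1, 1.3), "gamma")
})

test_that("melanin absorption has the 48.4 reference constant at 550 nm", {
  for (bm in c(1, 2.5, 4.3, 7.9))
    expect_equal(melanin_absorption(550, bm), 48.4, tolerance = 1e-12)
  expect_equal(melanin_absorption(1100, 1), 24.2, tolerance = 1e-12)
  expect_equal(melanin_absorption(275, 2), 193.6, tolerance = 1e-12)
  expect_error(melanin_absorption(550, -1), "beta_mel")
  expect_error(melanin_absorption(0, 2), "lambda")
})

test_that("blood absorption interpolates the table and is linear in s", {
  tab <- hb_table()
  lam <- c(500, 575, 633, 800, 850)
  expect_equal(blood_absorption(lam, 1, tab),
               approx(tab$wavelengths, tab$mu_a_oxy, lam)$y)
  expect_equal(blood_absorption(lam, 0, tab),
               approx(tab$wavelengths, tab$mu_a_deoxy, lam)$y)
  # linearity: three collinear points in s
  a <- blood_absorption(lam, 0.2, tab)
  b <- blood_absorption(lam, 0.5, tab)
  c3 <- blood_absorption(lam, 0.8, tab)
  expect_equal(b, (a + c3) / 2, tolerance = 1e-12)
  expect_error(blood_absorption(2000, 0.5, tab), "range")
})

test_that("absorption is saturation-independent at the isosbestic point", {
  tab <- hb_table()
  iso <- isosbestic_wavelength(tab)
  expect_gt(iso, 770)
  expect_lt(iso, 830)
  vals <- vapply(seq(0, 1, by = 0.25),
                 function(s) blood_absorption(iso, s, tab), numeric(1))
  expect_lt(diff(range(vals)) / mean(vals), 0.01)
})

test_that("vessel packaging factor matches its closed form and limits", {
  expect_equal(vessel_packing_factor(0, 0.005), 1)
  expect_equal(vessel_packing_factor(1e-12, 0.005), 1, tolerance = 1e-9)
  expect_equal(vessel_packing_factor(20, 0.01), (1 - exp(-0.4)) / 0.4,
               tolerance = 1e-12)
  # asymptotic regime: ~ 1/(2 mu R), tending to zero
  expect_equal(vessel_packing_factor(5000, 0.01), 1 / (2 * 5000 * 0.01),
               tolerance = 1e-6)
  x <- seq(0, 400, by = 5)
  v <- vessel_packing_factor(x, 0.005)
  expect_true(all(v > 0 & v <= 1))
  expect_true(all(diff(v) < 0))
  # quadrature oracle: mean transmittance over traversal lengths uniform on
  # (0, 2R) through the vessel cross-section
  for (mu in c(0.5, 5, 50, 500)) {
    num <- integrate(function(l) exp(-mu * l), 0, 2 * 0.005)$value / 0.01
    expect_equal(vessel_packing_factor(mu, 0.005), num, tolerance = 0.01)
  }
})

test_that("dermis absorption composes blood fraction, packaging and mixing", {
  tab <- hb_table()
  lam <- seq(475, 850, by = 25)
  expect_equal(dermis_absorption(lam, dermis_params(0, 0.5), tab),
               rep(0, length(lam)))
  # tiny vessels: packaging factor -> 1
  d0 <- dermis_params(0.02, 0.6, vessel_radius = 1e-7)
  expect_equal(dermis_absorption(lam, d0, tab),
               0.02 * blood_absorption(lam, 0.6, tab), tolerance = 1e-4)
  # at the isosbestic point with R -> 0 the value is f_blood times the
  # saturation-independent whole-blood absorption
  iso <- isosbestic_wavelength(tab)
  d1 <- dermis_params(0.011, 0.5, vessel_radius = 1e-7)
  expect_equal(dermis_absorption(iso, d1, tab),
               0.011 * blood_absorption(iso, 0.5, tab), tolerance = 1e-4)
  # monotone in f_blood
  fb <- seq(0, 0.1, by = 0.01)
  v <- vapply(fb, function(f)
    dermis_absorption(575, dermis_params(f, 0.5), tab), numeric(1))
  expect_true(all(diff(v) > 0))
  # median-parameter sanity: upper-dermis absorption at 575 nm lands within
  # a factor two of 0.18 mm^-1
  v575 <- dermis_absorption(575, dermis_params(0.011, 0.5), tab)
  expect_gt(v575, 0.09)
  expect_lt(v575, 0.36)
})

test_that("the compiled hemoglobin table is well-formed", {
  tab <- hb_table()
  expect_lte(min(tab$wavelengths), 450)
  expect_gte(max(tab$wavelengths), 900)
  expect_lte(max(diff(tab$wavelengths)), 1)
  expect_true(all(tab$mu_a_oxy > 0) && all(tab$mu_a_deoxy > 0))
  # qualitative oxyhemoglobin shape
  o575 <- approx(tab$wavelengths, tab$mu_a_oxy, 575)$y
  o650 <- approx(tab$wavelengths, tab$mu_a_oxy, 650)$y
  expect_gt(o575, o650)
  # extinction-to-absorption conversion is a wavelength-independent scaling
  raw <- read.table(tab$source, header = TRUE, sep = "\t", comment.char = "#")
  ratio <- approx(tab$wavelengths, tab$mu_a_oxy, raw$wavelength_nm)$y /
    raw$eps_oxy
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  expect_equal(mean(ratio), log(10) * (0.43 * 345 / 64500) / 10,
               tolerance = 1e-9)
  expect_error(compile_hemoglobin_table("no/such/file.tsv"), "fixture")
})
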