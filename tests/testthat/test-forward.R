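# Beer-Lambert forward model on the MC basis.

test_that("zero absorption reproduces the absorption-free basis response", {
  basis <- unit_basis()
  tab <- hb_table()
  # flat scattering at a grid node, no chromophores
  params <- skin_params(scattering_params(1.6, 0, 0),
                       epidermis_params(0.06, 0, 4),
                       dermis_params(0, 0.5, thickness = 0.2),
                       dermis_params(0, 0.5))
  sp <- model_reflectance(params, basis, wavelengths = c(500, 600, 700),
                          table = tab)
  for (k in 1:2) {
    node <- sum(basis$cells[[2]][[2]]$detectors[[k]]$weight)
    expect_equal(unname(sp$intensity[, k]), rep(node, 3), tolerance = 1e-9)
  }
})

test_that("interpolation is exact at grid nodes", {
  basis <- unit_basis()
  tab <- hb_table()
  params <- skin_params(scattering_params(3.2, 0, 0),
                       epidermis_params(0.15, 0.05, 4.3),
                       dermis_params(0.011, 0.5, thickness = 0.2),
                       dermis_params(0.0075, 0.5))
  wl <- c(520, 610)
  sp <- model_reflectance(params, basis, wavelengths = wl, table = tab)
  mua <- layer_absorptions(params, wl, tab)
  for (k in 1:2) {
    d <- basis$cells[[3]][[3]]$detectors[[k]]
    direct <- vapply(seq_along(wl), function(m)
      sum(skindrs:::bl_photon_weights_cpp(d$pathlengths, d$weight, mua[m, ])),
      numeric(1))
    expect_equal(unname(sp$intensity[, k]), direct, tolerance = 1e-9)
  }
})

test_that("reflectance decreases monotonically with absorption", {
  basis <- unit_basis()
  tab <- hb_table()
  fb <- c(0.001, 0.005, 0.02, 0.05)
  out <- sapply(fb, function(f) {
    p <- skin_params(scattering_params(2, 1, 0.3),
                     epidermis_params(0.06, 0.02, 4),
                     dermis_params(f, 0.5, thickness = 0.2),
                     dermis_params(0.0075, 0.5))
    model_reflectance(p, basis, wavelengths = 575, table = tab)$intensity
  })
  expect_true(all(diff(out[1, ]) < 0))   # 0.4 mm separation
  expect_true(all(diff(out[2, ]) < 0))   # 1.2 mm separation
})

test_that("the Beer-Lambert exponent is invariant under mu*c, L/c rescaling", {
  basis <- unit_basis()
  d <- basis$cells[[1]][[1]]$detectors[[1]]
  mua <- c(0.5, 0.08, 0.05)
  a <- skindrs:::bl_photon_weights_cpp(d$pathlengths, d$weight, mua * 3)
  b <- skindrs:::bl_photon_weights_cpp(d$pathlengths / 3, d$weight, mua * 9)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("thin epidermis with uniform optics matches a homogeneous medium", {
  tab <- hb_table()
  mua_u <- 0.05
  musp_u <- 1.6
  basis <- unit_basis()
  # melanin fraction chosen so the epidermal absorption equals the dermal
  f_mel <- mua_u / melanin_absorption(600, 4)
  d1 <- dermis_params(1, 0.5, vessel_radius = 1e-9, thickness = 0.2)
  # calibrate f_blood so dermal mu_a is exactly mua_u at 600 nm
  fb <- mua_u / blood_absorption(600, 0.5, tab)
  p <- skin_params(scattering_params(musp_u, 0, 0),
                   epidermis_params(0.02, f_mel, 4),
                   dermis_params(fb, 0.5, vessel_radius = 1e-9,
                                 thickness = 0.2),
                   dermis_params(fb, 0.5, vessel_radius = 1e-9))
  layered <- model_reflectance(p, basis, wavelengths = 600, table = tab)
  hom <- simulate_photons(layer_stack(Inf, mus = musp_u / 0.2),
                          probe_geometry(), 1e5, seed = 99, max_depth = 12)
  for (k in 1:2) {
    dd <- hom$detectors[[k]]
    r_hom <- sum(dd$weight * exp(-mua_u * rowSums(dd$pathlengths))) / 1e5
    expect_lt(abs(layered$intensity[1, k] / r_hom - 1),
              5 / sqrt(length(dd$weight)) + 0.05)
  }
})

test_that("out-of-grid parameters raise errors naming the axis", {
  basis <- unit_basis()
  tab <- hb_table()
  p <- median_params()
  p$epidermis$t_epi <- 0.25  # above the 0.15 grid maximum
  expect_error(model_reflectance(p, basis, wavelengths = 600, table = tab),
               "epidermis thickness")
  p2 <- median_params()
  p2$scattering$alpha <- 4.5  # pushes mus' beyond the grid
  expect_error(model_reflectance(p2, basis, wavelengths = 500, table = tab),
               "scattering")
  # clamped evaluation stays finite instead
  sp <- model_reflectance(p2, basis, wavelengths = 500, table = tab,
                          clamp = TRUE)
  expect_true(all(is.finite(sp$intensity)))
})

test_that("spectra round-trip through the TSV interface", {
  grid <- default_wavelengths()
  sp <- reflectance_spectrum(grid$wavelengths,
                             cbind(seq_along(grid$wavelengths) * 1e-4,
                                   seq_along(grid$wavelengths) * 2e-5),
                             mask = grid$mask)
  path <- tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(sp2$intensity, sp$intensity)
  expect_identical(sp2$mask, sp$mask)
  # the notch band is carried but flagged invalid
  notch <- grid$wavelengths >= 770 & grid$wavelengths <= 810
  expect_true(all(!sp2$mask[notch]))
  expect_true(all(is.finite(sp2$intensity[notch, ])))
  unlink(path)
})
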