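# White Monte Carlo photon transport.

test_that("launched weight is conserved and accounted exactly", {
  # matched-index semi-infinite medium with a deep cutoff: essentially all
  # weight returns through the surface
  stack <- layer_stack(Inf, mus = 15, g = 0.8, n = 1.4, n_external = 1.4)
  probe <- probe_geometry(src_radius = 0, src_na = 0)
  rec <- simulate_photons(stack, probe, 4e4, seed = 9, max_depth = 200,
                          max_events = 2e6)
  tt <- rec$totals
  # bookkeeping identity: every launched photon ends in exactly one bucket
  expect_equal(sum(tt[c("specular", "top_exit", "cutoff_lost",
                        "max_events_lost", "roulette_lost")]),
               tt[["launched"]], tolerance = 1e-12)
  # physical conservation: leakage below 0.5%
  expect_gt(tt[["top_exit"]] / tt[["launched"]], 0.995)
})

test_that("per-layer pathlengths sum to the geometric path length", {
  stack <- layer_stack(c(0.06, 0.2, Inf), mus = rep(12, 3))
  rec <- simulate_photons(stack, probe_geometry(), 3e4, seed = 4,
                          store_paths = TRUE, max_depth = 12)
  d <- rec$detectors[[1]]
  expect_gt(length(d$weight), 50)
  for (i in seq_len(min(200, length(d$weight)))) {
    a <- d$path_offsets[i] + 1
    b <- d$path_offsets[i + 1]
    seg <- diff(d$path_vertices[a:b, , drop = FALSE])
    arc <- sum(sqrt(rowSums(seg^2)))
    expect_equal(arc, sum(d$pathlengths[i, ]), tolerance = 1e-9)
  }
  expect_true(all(d$pathlengths >= 0))
  expect_true(all(d$weight > 0 & d$weight <= 1))
})

test_that("identical seeds reproduce bit-identical records", {
  stack <- layer_stack(c(0.05, 0.2, Inf), mus = rep(10, 3))
  r1 <- simulate_photons(stack, probe_geometry(), 2e4, seed = 77)
  r2 <- simulate_photons(stack, probe_geometry(), 2e4, seed = 77)
  r3 <- simulate_photons(stack, probe_geometry(), 2e4, seed = 78)
  expect_identical(r1$detectors[[1]]$pathlengths,
                   r2$detectors[[1]]$pathlengths)
  expect_identical(r1$detectors[[2]]$weight, r2$detectors[[2]]$weight)
  expect_false(identical(r1$detectors[[1]]$weight,
                         r3$detectors[[1]]$weight))
})

test_that("detection falls off with separation", {
  stack <- layer_stack(c(0.06, 0.2, Inf), mus = rep(12, 3))
  rec <- simulate_photons(stack, probe_geometry(), 5e4, seed = 12,
                          max_depth = 12)
  expect_gt(length(rec$detectors[[1]]$weight),
            length(rec$detectors[[2]]$weight))
})

test_that("spatially resolved reflectance agrees with diffusion theory", {
  # semi-infinite medium, mus' = 1 mm^-1, g = 0.8, tissue n = 1.4 against
  # air; compared at the 1.2 mm separation against the partial-current
  # diffusion closed form
  stack <- layer_stack(Inf, mus = 5, g = 0.8, n = 1.4, n_external = 1.0)
  probe <- probe_geometry(src_radius = 0, src_na = 0)
  rec <- simulate_photons(stack, probe, 2.5e5, seed = 21, store_exits = TRUE,
                          max_depth = 50, max_events = 2e6)
  bin <- c(1.1, 1.3)
  sel <- rec$exit_radius_all >= bin[1] & rec$exit_radius_all < bin[2]
  r_mc <- sum(rec$exit_weight_all[sel]) /
    (pi * (bin[2]^2 - bin[1]^2) * 2.5e5)
  r_th <- integrate(function(x)
    pc_diffusion_reflectance(x, 1, 0, 1.4) * 2 * pi * x,
    bin[1], bin[2])$value / (pi * (bin[2]^2 - bin[1]^2))
  expect_lt(abs(r_mc / r_th - 1), 0.15)
})

test_that("a transparent internal boundary does not change reflectance", {
  probe <- probe_geometry()
  one <- simulate_photons(layer_stack(Inf, mus = 10), probe, 8e4, seed = 3,
                          max_depth = 12)
  two <- simulate_photons(layer_stack(c(0.3, Inf), mus = c(10, 10)), probe,
                          8e4, seed = 1003, max_depth = 12)
  w1 <- sum(one$detectors[[1]]$weight)
  w2 <- sum(two$detectors[[1]]$weight)
  n1 <- length(one$detectors[[1]]$weight)
  # ~4 sigma band from the detected-count statistics
  expect_lt(abs(w1 - w2) / w1, 4 * sqrt(2 / n1))
})

test_that("Monte Carlo error shrinks with the photon budget as 1/sqrt(n)", {
  stack <- layer_stack(Inf, mus = 15)
  probe <- probe_geometry()
  wsum <- function(n, seed)
    sum(simulate_photons(stack, probe, n, seed, max_depth = 8)$
          detectors[[1]]$weight) / n
  seeds <- 1:40
  s_small <- sd(vapply(seeds, function(s) wsum(1000, s), numeric(1)))
  s_large <- sd(vapply(seeds, function(s) wsum(4000, 100 + s), numeric(1)))
  ratio <- s_small / s_large   # expected 2 for a 4x budget
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)
})

test_that("degenerate probe geometry is rejected", {
  expect_error(probe_geometry(separations = 0.1, fiber_radius = 0.1),
               "overlap")
  expect_error(build_mc_basis(t_epi_levels = 0.05, musp_levels = c(1, 2),
                              n_photons = 10), "two levels")
})

test_that("path compression draws uniform points along the path", {
  # one photon with a straight vertical path: depths must be uniform
  rec <- fake_records(list(cbind(0, 0, c(0, 1))), weights = 1)
  cl <- compress_paths(rec, points_per_photon = 1e4, seed = 5)
  ks <- suppressWarnings(ks.test(cl$depth, "punif"))
  expect_gt(ks$p.value, 0.01)
  # one photon at constant depth: all points at that depth
  rec2 <- fake_records(list(cbind(c(0, 1), 0, 0.4)), weights = 0.7)
  cl2 <- compress_paths(rec2, points_per_photon = 50, seed = 5)
  expect_equal(cl2$depth, rep(0.4, 50))
  expect_equal(cl2$weight, rep(0.7, 50))
  # zero-weight photons contribute no weight
  rec3 <- fake_records(list(cbind(0, 0, c(0, 1)), cbind(0, 0, c(0, 2))),
                       weights = c(0.5, 0))
  cl3 <- compress_paths(rec3, points_per_photon = 20, seed = 5)
  expect_equal(sum(cl3$weight), 20 * 0.5)
})

test_that("a basis round-trips losslessly through its cache format", {
  basis <- unit_basis()
  path <- tempfile(fileext = ".rds")
  write_basis(basis, path)
  basis2 <- read_basis(path)
  expect_identical(basis2$cells[[1]][[1]]$detectors[[1]]$weight,
                   basis$cells[[1]][[1]]$detectors[[1]]$weight)
  expect_identical(basis2$musp_levels, basis$musp_levels)
  unlink(path)
})
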