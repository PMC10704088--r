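# Shared fixtures, memoized across test files within one run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

hb_table <- function() memo("hb_table", compile_hemoglobin_table())

# Small MC basis for forward/inverse unit tests (not the acceptance runs).
unit_basis <- function() memo("unit_basis", {
  build_mc_basis(t_epi_levels = c(0.02, 0.06, 0.15),
                 musp_levels = c(0.8, 1.6, 3.2),
                 n_photons = 4e4, seed = 42, max_depth = 12)
})

# 2x2 basis with stored path vertices for sampling-depth tests.
paths_basis <- function() memo("paths_basis", {
  build_mc_basis(t_epi_levels = c(0.05, 0.1),
                 musp_levels = c(1.5, 3),
                 n_photons = 4e4, seed = 43, max_depth = 12,
                 store_paths = TRUE)
})

median_params <- function() {
  skin_params_from_vector(c(alpha = 1.99, beta = 0.82, gamma = 0.31,
                            t_epi = 0.063, f_mel = 0.05, beta_mel = 4.3,
                            f_blood1 = 0.011, f_blood2 = 0.0075, s = 0.5))
}

# Minimal photon_records stand-in with hand-built path chains.
fake_records <- function(verts_list, weights) {
  offs <- c(0L, cumsum(vapply(verts_list, nrow, integer(1))))
  structure(list(
    detectors = list(list(
      pathlengths = matrix(0, length(weights), 1),
      weight = weights,
      exit_radius = rep(0, length(weights)),
      path_vertices = do.call(rbind, verts_list),
      path_offsets = as.integer(offs))),
    totals = c(launched = length(weights)),
    store_paths = TRUE), class = "photon_records")
}
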