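# Layered white Monte Carlo transport: R-side containers and wrappers.

#' Layer stack for photon transport
#'
#' Defines the layered medium seen by the Monte Carlo engine. The last layer
#' is semi-infinite. Depth is measured positive downward from the surface,
#' with the source fiber centred on the origin.
#'
#' @param thickness Layer thicknesses (mm); the last entry may be `Inf`.
#' @param mus Scattering coefficients (mm^-1), one per layer, > 0.
#' @param g Henyey-Greenstein anisotropy factors in `[0, 1)`, recycled.
#' @param n Refractive indices, recycled.
#' @param n_external Refractive index of the medium above the surface
#'   (1.5 for a glass/fiber contact probe, 1.0 for air).
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(thickness, mus, g = 0.8, n = 1.4, n_external = 1.5) {
  nl <- length(thickness)
  stopifnot(nl >= 1, length(mus) == nl)
  g <- rep_len(g, nl); n <- rep_len(n, nl)
  if (any(thickness[-nl] <= 0) || thickness[nl] <= 0)
    stop("layer thicknesses must be > 0")
  if (any(mus <= 0)) stop("mus must be > 0 in every layer")
  if (any(g < 0 | g >= 1)) stop("g must lie in [0, 1)")
  structure(list(thickness = as.numeric(thickness), mus = as.numeric(mus),
                 g = as.numeric(g), n = as.numeric(n),
                 n_external = n_external),
            class = "layer_stack")
}

#' Probe geometry
#'
#' Fiber-optic probe description: a central source fiber and detector
#' fibers at fixed centre-to-centre separations, treated as annular
#' detection rings (rotational symmetry).
#'
#' @param separations Detector centre separations (mm); default
#'   `c(0.4, 1.2)`.
#' @param fiber_radius Detector fiber core radius (mm).
#' @param na Numerical aperture of the detection fibers.
#' @param src_radius Source fiber core radius (mm); 0 gives a pencil beam.
#' @param src_na Numerical aperture of the source fiber; 0 gives a
#'   collimated launch.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(separations = c(0.4, 1.2), fiber_radius = 0.1,
                           na = 0.37, src_radius = 0.1, src_na = 0.37) {
  stopifnot(length(separations) >= 1, fiber_radius > 0, na >= 0,
            src_radius >= 0, src_na >= 0)
  if (any(separations - fiber_radius <= src_radius))
    stop("detector annulus overlaps the source fiber: configuration error")
  structure(list(separations = as.numeric(separations),
                 fiber_radius = fiber_radius, na = na,
                 src_radius = src_radius, src_na = src_na),
            class = "probe_geometry")
}

#' Simulate absorption-free photon transport
#'
#' Runs the white Monte Carlo engine: photons are launched uniformly over
#' the source fiber face within its acceptance cone, refracted into the
#' medium, propagated with exponential free paths and Henyey-Greenstein
#' scattering, and Fresnel-reflected/refracted at boundaries. Photons
#' exiting the top surface inside a detector annulus within the acceptance
#' angle are recorded with their per-layer pathlengths (and, optionally,
#' their full path vertex chains). Absorption is applied downstream by
#' Beer-Lambert scaling of the stored pathlengths. Runs are bit-reproducible
#' for a fixed seed.
#'
#' @param stack A [layer_stack()].
#' @param probe A [probe_geometry()].
#' @param n_photons Number of photons to launch, >= 1.
#' @param seed Integer seed for the internal deterministic RNG.
#' @param store_paths Record path vertices of detected photons (needed for
#'   sampling-depth point clouds).
#' @param store_exits Record exit radius and weight of every photon leaving
#'   the top surface (for spatially resolved reflectance studies).
#' @param max_depth Depth cutoff (mm); photons beyond it are terminated and
#'   accounted as lost. Default 20.
#' @param max_events Scattering-event cap per photon.
#' @param roulette_threshold,roulette_survival Russian-roulette weight
#'   termination parameters (inactive while transport is absorption-free).
#' @return An object of class `photon_records`: list with `detectors` (per
#'   detector: `pathlengths` matrix, `weight`, `exit_radius`, optional
#'   `path_vertices`/`path_offsets`), `totals` (weight bookkeeping), and the
#'   simulation configuration.
#' @export
simulate_photons <- function(stack, probe, n_photons, seed,
                             store_paths = FALSE, store_exits = FALSE,
                             max_depth = 20, max_events = 1e6,
                             roulette_threshold = 1e-4,
                             roulette_survival = 10) {
  stopifnot(inherits(stack, "layer_stack"), inherits(probe, "probe_geometry"),
            n_photons >= 1)
  res <- mc_simulate_cpp(stack$thickness, stack$mus, stack$g, stack$n,
                         stack$n_external, probe$src_radius, probe$src_na,
                         probe$separations, probe$fiber_radius, probe$na,
                         as.integer(n_photons), max_depth,
                         as.integer(max_events), roulette_threshold,
                         roulette_survival, store_paths, store_exits,
                         as.numeric(seed))
  res$stack <- stack
  res$probe <- probe
  res$n_photons <- n_photons
  res$seed <- seed
  res$store_paths <- store_paths
  class(res) <- "photon_records"
  res
}

#' @export
print.photon_records <- function(x, ...) {
  nd <- vapply(x$detectors, function(d) length(d$weight), integer(1))
  cat("White Monte Carlo photon records\n")
  cat(sprintf("  layers: %d, photons launched: %g\n",
              length(x$stack$thickness), x$n_photons))
  cat(sprintf("  detected per separation (%s mm): %s\n",
              paste(x$probe$separations, collapse = ", "),
              paste(nd, collapse = ", ")))
  invisible(x)
}

# deterministic per-cell seed derivation (kept below 2^53)
cell_seed <- function(seed, i, j) {
  (as.numeric(seed) * 2654435761 + i * 40503 + j * 2654435769) %% 2^40
}

#' Build a white Monte Carlo basis over (epidermis thickness x scattering)
#'
#' Simulates the three-layer skin geometry (epidermis of thickness
#' `t_epi_levels[i]`, upper dermis of fixed thickness, semi-infinite lower
#' dermis, all sharing the same scattering) once per grid cell. The stored
#' per-layer photon pathlengths allow any absorption spectrum to be applied
#' afterwards by Beer-Lambert scaling, and reflectance to be interpolated
#' between grid cells.
#'
#' @param t_epi_levels Epidermis thickness grid (mm), strictly increasing,
#'   >= 2 levels.
#' @param musp_levels Reduced scattering grid (mm^-1), strictly increasing,
#'   >= 2 levels; converted internally to `mus = musp / (1 - g)`.
#' @param probe A [probe_geometry()].
#' @param n_photons Photons launched per grid cell.
#' @param seed Base seed; per-cell seeds are derived deterministically.
#' @param g Anisotropy factor (all layers).
#' @param n_tissue Tissue refractive index (all layers).
#' @param dermis1_thickness Upper dermis thickness (mm), default 0.2.
#' @param store_paths Keep path vertices (enables [depth_profile()]).
#' @param max_detected If finite, uniformly subsample each cell/detector
#'   record set down to this many photons, rescaling weights to preserve the
#'   total (keeps inverse-solver evaluations fast).
#' @param ... Passed to [simulate_photons()].
#' @return An object of class `mc_basis`.
#' @export
build_mc_basis <- function(t_epi_levels = c(0.025, 0.05, 0.075, 0.1, 0.15,
                                            0.2, 0.3),
                           musp_levels = exp(seq(log(0.5), log(5),
                                                 length.out = 10)),
                           probe = probe_geometry(),
                           n_photons = 2e5, seed = 1, g = 0.8, n_tissue = 1.4,
                           dermis1_thickness = 0.2, store_paths = FALSE,
                           max_detected = Inf, ...) {
  if (length(t_epi_levels) < 2 || length(musp_levels) < 2)
    stop("at least two levels per axis are required: configuration error")
  stopifnot(all(diff(t_epi_levels) > 0), all(diff(musp_levels) > 0),
            all(t_epi_levels > 0), all(musp_levels > 0))
  cells <- vector("list", length(t_epi_levels))
  for (i in seq_along(t_epi_levels)) {
    cells[[i]] <- vector("list", length(musp_levels))
    for (j in seq_along(musp_levels)) {
      stack <- layer_stack(
        thickness = c(t_epi_levels[i], dermis1_thickness, Inf),
        mus = rep(musp_levels[j] / (1 - g), 3), g = g, n = n_tissue,
        n_external = 1.5)
      rec <- simulate_photons(stack, probe, n_photons,
                              seed = cell_seed(seed, i, j),
                              store_paths = store_paths, ...)
      dets <- lapply(rec$detectors, function(d) {
        d$weight <- d$weight / n_photons # reflectance per launched photon
        nrec <- length(d$weight)
        if (is.finite(max_detected) && nrec > max_detected) {
          keep <- seq_len(nrec) %in%
            sample_deterministic(nrec, max_detected, cell_seed(seed, i, j))
          scale <- sum(d$weight) / sum(d$weight[keep])
          d$pathlengths <- d$pathlengths[keep, , drop = FALSE]
          d$weight <- d$weight[keep] * scale
          d$exit_radius <- d$exit_radius[keep]
          d$path_vertices <- NULL
          d$path_offsets <- NULL
        }
        d
      })
      cells[[i]][[j]] <- list(detectors = dets, totals = rec$totals,
                              seed = cell_seed(seed, i, j))
    }
  }
  structure(list(t_epi_levels = as.numeric(t_epi_levels),
                 musp_levels = as.numeric(musp_levels),
                 probe = probe, g = g, n_tissue = n_tissue,
                 dermis1_thickness = dermis1_thickness,
                 n_photons = n_photons, seed = seed,
                 store_paths = store_paths, cells = cells),
            class = "mc_basis")
}

#' Thin a basis for fast inverse-solver evaluations
#'
#' Uniformly subsamples each cell/detector record set down to
#' `max_detected` photons, rescaling weights to preserve the total detected
#' weight (unbiased for the synthesized reflectance). Path vertices are
#' dropped.
#'
#' @param basis An `mc_basis`.
#' @param max_detected Photon cap per cell and detector.
#' @return The thinned `mc_basis`.
#' @export
thin_basis <- function(basis, max_detected) {
  stopifnot(inherits(basis, "mc_basis"), max_detected >= 1)
  for (i in seq_along(basis$t_epi_levels)) {
    for (j in seq_along(basis$musp_levels)) {
      basis$cells[[i]][[j]]$detectors <-
        lapply(basis$cells[[i]][[j]]$detectors, function(d) {
          n <- length(d$weight)
          if (n > max_detected) {
            keep <- sample_deterministic(n, max_detected,
                                         cell_seed(basis$seed, i, j))
            scale <- sum(d$weight) / sum(d$weight[keep])
            d$pathlengths <- d$pathlengths[keep, , drop = FALSE]
            d$weight <- d$weight[keep] * scale
            d$exit_radius <- d$exit_radius[keep]
          }
          d$path_vertices <- NULL
          d$path_offsets <- NULL
          d
        })
    }
  }
  basis$store_paths <- FALSE
  basis
}

# deterministic uniform subsample without touching R's RNG state
sample_deterministic <- function(n, k, seed) {
  u <- (seq_len(n) * 2654435761 + as.numeric(seed)) %% 4294967296
  order(u)[seq_len(k)]
}

#' @export
print.mc_basis <- function(x, ...) {
  cat("White Monte Carlo basis\n")
  cat(sprintf("  t_epi levels (mm): %s\n",
              paste(signif(x$t_epi_levels, 3), collapse = ", ")))
  cat(sprintf("  mus' levels (mm^-1): %s\n",
              paste(signif(x$musp_levels, 3), collapse = ", ")))
  cat(sprintf("  photons per cell: %g; paths stored: %s\n",
              x$n_photons, x$store_paths))
  invisible(x)
}

#' Persist / reload a Monte Carlo basis
#'
#' The basis is cached with `saveRDS` (a runtime cache; rebuild rather than
#' distribute). The round trip is lossless.
#'
#' @param basis An `mc_basis`.
#' @param path File path.
#' @return `read_basis` returns the `mc_basis`.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "mc_basis"))
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  basis <- readRDS(path)
  stopifnot(inherits(basis, "mc_basis"))
  basis
}

#' Compress photon paths into a weighted depth point cloud
#'
#' For each detected photon, draws exactly `points_per_photon` positions
#' uniformly along the arc length of its path and returns their depths, each
#' carrying the photon's final weight (pass absorption-scaled weights via
#' `weights` to evaluate a specific wavelength).
#'
#' @param records A `photon_records` object simulated with
#'   `store_paths = TRUE`.
#' @param detector Detector index (1-based).
#' @param points_per_photon Points drawn per photon, >= 1.
#' @param seed RNG seed for the point positions.
#' @param weights Optional replacement weights (e.g. after Beer-Lambert
#'   scaling); defaults to the recorded detection weights.
#' @return A list with `depth` (mm) and `weight` vectors of length
#'   `n_photons * points_per_photon` (empty for an empty record set).
#' @export
compress_paths <- function(records, detector = 1, points_per_photon = 20,
                           seed = 1, weights = NULL) {
  stopifnot(inherits(records, "photon_records"))
  d <- records$detectors[[detector]]
  if (is.null(d$path_vertices))
    stop("records were simulated without store_paths = TRUE")
  if (points_per_photon < 1) stop("points_per_photon must be >= 1")
  if (is.null(weights)) weights <- d$weight
  if (length(weights) != length(d$weight))
    stop("weights must have one entry per detected photon")
  if (length(weights) == 0)
    return(list(depth = numeric(0), weight = numeric(0)))
  compress_paths_cpp(d$path_vertices, d$path_offsets, weights,
                     as.integer(points_per_photon), as.numeric(seed))
}
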