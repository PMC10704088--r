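# Sampling-depth statistic from weighted photon-path point clouds.

#' Sampling depth of a weighted depth point cloud
#'
#' Sorts the point cloud by depth and returns the depth at which the
#' cumulative point weight first reaches `1 - exp(-1)` (63%) of the total,
#' linearly interpolating between adjacent points at the crossing. The
#' first point's depth is returned when its weight alone reaches the
#' threshold.
#'
#' @param depth Point depths (mm), >= 0.
#' @param weight Point weights, same length, total > 0. Default: equal
#'   weights.
#' @param fraction Cumulative-weight threshold; default `1 - exp(-1)`.
#' @return Sampling depth (mm).
#' @export
sampling_depth <- function(depth, weight = NULL, fraction = 1 - exp(-1)) {
  if (length(depth) == 0) stop("empty point cloud")
  if (is.null(weight)) weight <- rep(1, length(depth))
  stopifnot(length(weight) == length(depth), all(weight >= 0))
  total <- sum(weight)
  if (total <= 0) stop("point cloud has no positive weight")
  o <- order(depth)
  d <- depth[o]
  cw <- cumsum(weight[o])
  thr <- fraction * total
  k <- which(cw >= thr)[1]
  if (k == 1L) return(d[1])
  # linear interpolation on the cumulative weight between points k-1 and k
  d[k - 1] + (d[k] - d[k - 1]) * (thr - cw[k - 1]) / (cw[k] - cw[k - 1])
}

#' Sampling depth per detector from a basis cell
#'
#' Applies Beer-Lambert absorption at wavelength `lambda_nm` to the stored
#' photon paths of the basis cell nearest to the parameters (in epidermis
#' thickness and log reduced scattering), builds the weighted depth point
#' cloud via [compress_paths()], and computes the sampling depth for each
#' detector. The basis must have been built with `store_paths = TRUE`.
#'
#' @param params A `skin_params` object.
#' @param basis An `mc_basis` built with `store_paths = TRUE`.
#' @param lambda_nm Single evaluation wavelength (nm).
#' @param table Hemoglobin table; bundled fixture when omitted.
#' @param points_per_photon Points per photon in the cloud, default 20.
#' @param seed Point-sampling seed.
#' @return Data frame with one row per separation: `separation`,
#'   `wavelength`, `depth_mm`, `n_photons`, `n_points`.
#' @export
depth_profile <- function(params, basis, lambda_nm, table = NULL,
                          points_per_photon = 20, seed = 1) {
  stopifnot(inherits(params, "skin_params"), inherits(basis, "mc_basis"),
            length(lambda_nm) == 1)
  if (!basis$store_paths)
    stop("basis was built without store_paths = TRUE")
  if (is.null(table)) table <- compile_hemoglobin_table()
  musp <- reduced_scattering(lambda_nm, params$scattering)
  i <- which.min(abs(basis$t_epi_levels - params$epidermis$t_epi))
  j <- which.min(abs(log(basis$musp_levels) - log(musp)))
  cell <- basis$cells[[i]][[j]]
  mua <- layer_absorptions(params, lambda_nm, table)[1, ]
  depth_from_cell(cell, basis$probe$separations, lambda_nm, mua,
                  points_per_photon, seed)
}

# shared by depth_profile and sampling_depth_mc
depth_from_cell <- function(cell, separations, lambda_nm, mua,
                            points_per_photon, seed) {
  out <- lapply(seq_along(separations), function(k) {
    d <- cell$detectors[[k]]
    if (length(d$weight) == 0)
      return(data.frame(separation = separations[k], wavelength = lambda_nm,
                        depth_mm = NA_real_, n_photons = 0L, n_points = 0L))
    w_abs <- bl_photon_weights_cpp(d$pathlengths, d$weight, mua)
    cloud <- compress_paths_cpp(d$path_vertices, d$path_offsets, w_abs,
                                as.integer(points_per_photon),
                                as.numeric(seed) + k)
    data.frame(separation = separations[k], wavelength = lambda_nm,
               depth_mm = sampling_depth(cloud$depth, cloud$weight),
               n_photons = length(d$weight), n_points = length(cloud$depth))
  })
  do.call(rbind, out)
}

#' Sampling depth by direct simulation at given optical properties
#'
#' Convenience wrapper for sampling-depth studies at explicit per-layer
#' optical properties (no interpolation): runs one white Monte Carlo
#' simulation of the three-layer stack with path storage, applies
#' Beer-Lambert weights for the given absorption triple, and evaluates the
#' sampling depth per separation.
#'
#' @param musp Reduced scattering coefficient (mm^-1), common to all layers.
#' @param mua Absorption triple (epidermis, upper dermis, lower dermis)
#'   (mm^-1).
#' @param t_epi Epidermis thickness (mm).
#' @param probe A [probe_geometry()].
#' @param n_photons Photons to launch.
#' @param seed Simulation seed.
#' @param g,n_tissue Anisotropy and tissue refractive index.
#' @param dermis1_thickness Upper dermis thickness (mm).
#' @param points_per_photon Points per photon in the cloud.
#' @param lambda_nm Wavelength label carried into the output.
#' @param ... Passed to [simulate_photons()].
#' @return Data frame as in [depth_profile()].
#' @export
sampling_depth_mc <- function(musp, mua, t_epi = 0.063,
                              probe = probe_geometry(), n_photons = 5e5,
                              seed = 1, g = 0.8, n_tissue = 1.4,
                              dermis1_thickness = 0.2,
                              points_per_photon = 20, lambda_nm = NA, ...) {
  stopifnot(length(mua) == 3, musp > 0)
  stack <- layer_stack(thickness = c(t_epi, dermis1_thickness, Inf),
                       mus = rep(musp / (1 - g), 3), g = g, n = n_tissue,
                       n_external = 1.5)
  rec <- simulate_photons(stack, probe, n_photons, seed, store_paths = TRUE,
                          ...)
  cell <- list(detectors = rec$detectors)
  depth_from_cell(cell, probe$separations, lambda_nm, mua,
                  points_per_photon, seed + 17)
}
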