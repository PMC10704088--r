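# Independent oracles used across the test suite.

# Spatially resolved diffuse reflectance of a semi-infinite medium from
# diffusion theory with the partial-current boundary condition: dipole
# fluence plus flux at the surface, weighted by Fresnel-integrated angular
# coefficients. Independent of the Monte Carlo engine.
pc_diffusion_reflectance <- function(rho, musp, mua, n_rel) {
  fres <- function(mu) {
    vapply(mu, function(ci) {
      st2 <- n_rel^2 * (1 - ci^2)
      if (st2 >= 1) return(1)
      ct <- sqrt(1 - st2)
      rs <- (n_rel * ci - ct) / (n_rel * ci + ct)
      rp <- (n_rel * ct - ci) / (n_rel * ct + ci)
      0.5 * (rs^2 + rp^2)
    }, numeric(1))
  }
  r_phi <- 2 * integrate(function(mu) fres(mu) * mu, 0, 1)$value
  r_j <- 3 * integrate(function(mu) fres(mu) * mu^2, 0, 1)$value
  r_eff <- (r_phi + r_j) / (2 - r_phi + r_j)
  a_fac <- (1 + r_eff) / (1 - r_eff)
  c_phi <- 0.25 * (1 - r_phi)
  c_j <- 0.5 * (1 - r_j)
  z0 <- 1 / (musp + mua)
  d_coef <- 1 / (3 * (musp + mua))
  zb <- 2 * a_fac * d_coef
  mueff <- sqrt(3 * mua * (mua + musp))
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  phi <- 1 / (4 * pi * d_coef) *
    (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2)
  jz <- 1 / (4 * pi) *
    (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
       (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
  c_phi * phi + c_j * jz
}

# Brute-force weighted 1-1/e quantile: cumulative sum scan without
# interpolation refinements (lower/upper bracket of the crossing point).
depth_quantile_bracket <- function(depth, weight, fraction = 1 - exp(-1)) {
  o <- order(depth)
  d <- depth[o]
  cw <- cumsum(weight[o])
  thr <- fraction * sum(weight)
  k <- which(cw >= thr)[1]
  c(lower = if (k == 1) d[1] else d[k - 1], upper = d[k])
}

# Exhaustive two-group Mann-Whitney oracle: enumerates all group-1
# assignments, returns the U statistic of the observed assignment and the
# exact two-sided permutation p-value.
mw_exhaustive <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  u_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Exhaustive Kruskal-Wallis oracle for three equal groups: enumerates all
# assignments of the pooled ranks to groups, returns the observed statistic
# and the exact upper-tail p-value.
kw_exhaustive <- function(x, g) {
  g <- factor(g)
  n <- table(g)
  stopifnot(length(n) == 3)
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_adj <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h_stat <- function(idx1, idx2, idx3) {
    (12 / (N * (N + 1)) *
       (sum(r[idx1])^2 / length(idx1) + sum(r[idx2])^2 / length(idx2) +
          sum(r[idx3])^2 / length(idx3)) - 3 * (N + 1)) / tie_adj
  }
  i1 <- which(g == levels(g)[1])
  i2 <- which(g == levels(g)[2])
  i3 <- which(g == levels(g)[3])
  h_obs <- h_stat(i1, i2, i3)
  c1 <- utils::combn(N, n[1])
  h_all <- numeric(0)
  for (a in seq_len(ncol(c1))) {
    rest <- setdiff(seq_len(N), c1[, a])
    c2 <- utils::combn(rest, n[2])
    for (b in seq_len(ncol(c2))) {
      h_all <- c(h_all, h_stat(c1[, a], c2[, b], setdiff(rest, c2[, b])))
    }
  }
  list(h = h_obs, p = mean(h_all >= h_obs - 1e-12))
}
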