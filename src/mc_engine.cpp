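// Layered white Monte Carlo photon transport with per-layer pathlength
// recording, annular fiber detection, path-vertex storage, and the
// Beer-Lambert spectral synthesis kernel.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (splitmix64-seeded xoshiro256+), independent of R's RNG
// so that identical seeds give bit-identical photon sets.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]
  inline double unif_open0() { return 1.0 - unif(); }
};

// Unpolarized Fresnel reflectance for incidence cosine cos_i going from
// index ni into nt; sets cos_t (transmitted cosine). Returns 1 on total
// internal reflection.
inline double fresnel(double ni, double nt, double cos_i, double &cos_t) {
  if (ni == nt) { cos_t = cos_i; return 0.0; }
  double sin_i2 = 1.0 - cos_i * cos_i;
  if (sin_i2 < 0) sin_i2 = 0;
  double sin_t2 = (ni * ni / (nt * nt)) * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;
  cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (ni * cos_i - nt * cos_t) / (ni * cos_i + nt * cos_t);
  double rp = (ni * cos_t - nt * cos_i) / (ni * cos_t + nt * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// ---------------------------------------------------------------------------
// Photon transport.
//
// Geometry: z positive downward, surface at z = 0, source fiber centred on
// the origin. Layers indexed from the surface; the last layer is
// semi-infinite. Detection is annular (rotational symmetry): a photon
// exiting the top surface at radius r with |r - sep| < det_radius and
// within the numerical aperture is recorded with its weight multiplied by
// the azimuthal arc fraction of the annulus covered by the fiber face.

// [[Rcpp::export]]
List mc_simulate_cpp(NumericVector thickness, NumericVector mus,
                     NumericVector g, NumericVector n_layer, double n_ext,
                     double src_radius, double src_na,
                     NumericVector det_sep, double det_radius, double det_na,
                     int n_photons, double max_depth, int max_events,
                     double roulette_threshold, double roulette_survival,
                     bool store_paths, bool store_exits, double seed) {
  const int nl = thickness.size();
  const int nd = det_sep.size();
  if (nl < 1) stop("at least one layer required");
  for (int i = 0; i < nl; ++i) {
    if (mus[i] <= 0) stop("mus must be > 0 in every layer");
    if (g[i] < 0 || g[i] >= 1) stop("g must lie in [0, 1)");
    if (i < nl - 1 && !(thickness[i] > 0)) stop("thicknesses must be > 0");
  }
  // interface depths: z_bot[i] is the lower boundary of layer i
  std::vector<double> z_bot(nl);
  {
    double acc = 0;
    for (int i = 0; i < nl; ++i) {
      acc += thickness[i];
      z_bot[i] = (i == nl - 1) ? R_PosInf : acc;
    }
    if (!std::isinf(thickness[nl - 1])) z_bot[nl - 1] = R_PosInf;
  }
  // launch cone in the external medium
  double sin_src = src_na / n_ext;
  if (sin_src > 1) sin_src = 1;
  const double cos_src_max = std::sqrt(1.0 - sin_src * sin_src);

  Xoshiro rng(static_cast<uint64_t>(seed));

  // per-detector accumulation
  std::vector<std::vector<double>> det_plm(nd), det_w(nd), det_r(nd),
      det_verts(nd);
  std::vector<std::vector<int>> det_off(nd);
  for (int k = 0; k < nd; ++k) det_off[k].push_back(0);
  std::vector<double> all_exit_r, all_exit_w;

  double w_specular = 0, w_top = 0, w_cutoff = 0, w_maxevt = 0, w_roulette = 0;

  std::vector<double> plm(nl);
  std::vector<double> verts; // x,y,z triples for the current photon

  for (int ph = 0; ph < n_photons; ++ph) {
    // launch position uniform over the source fiber face
    double x = 0, y = 0, z = 0;
    if (src_radius > 0) {
      double rr = src_radius * std::sqrt(rng.unif());
      double phi = 2 * M_PI * rng.unif();
      x = rr * std::cos(phi);
      y = rr * std::sin(phi);
    }
    // launch direction uniform in solid angle within the source cone
    double cos_ext = 1.0 - rng.unif() * (1.0 - cos_src_max);
    double sin_ext = std::sqrt(std::max(0.0, 1.0 - cos_ext * cos_ext));
    double phi0 = 2 * M_PI * rng.unif();
    // refract into the top layer
    double cos_t;
    double R0 = fresnel(n_ext, n_layer[0], cos_ext, cos_t);
    if (rng.unif() < R0) { w_specular += 1.0; continue; }
    double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
    double ux = sin_t * std::cos(phi0), uy = sin_t * std::sin(phi0),
           uz = cos_t;

    double w = 1.0;
    int layer = 0, events = 0;
    std::fill(plm.begin(), plm.end(), 0.0);
    if (store_paths) {
      verts.clear();
      verts.push_back(x); verts.push_back(y); verts.push_back(z);
    }
    double tau = -std::log(rng.unif_open0());
    bool alive = true;

    while (alive) {
      double musl = mus[layer];
      // distance to the layer boundary along the current direction
      double dbound = R_PosInf;
      int dir = 0;
      if (uz < 0) {
        double ztop = (layer == 0) ? 0.0 : z_bot[layer - 1];
        dbound = (z - ztop) / (-uz);
        dir = -1;
      } else if (uz > 0 && std::isfinite(z_bot[layer])) {
        dbound = (z_bot[layer] - z) / uz;
        dir = 1;
      }
      double s_free = tau / musl;
      if (s_free < dbound) {
        // interaction (scattering) event
        x += ux * s_free; y += uy * s_free; z += uz * s_free;
        plm[layer] += s_free;
        if (z > max_depth) { w_cutoff += w; break; }
        if (store_paths) {
          verts.push_back(x); verts.push_back(y); verts.push_back(z);
        }
        if (++events > max_events) { w_maxevt += w; break; }
        // Henyey-Greenstein deflection
        double gg = g[layer], cosT;
        if (gg < 1e-8) {
          cosT = 2.0 * rng.unif() - 1.0;
        } else {
          double f = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * rng.unif());
          cosT = (1.0 + gg * gg - f * f) / (2.0 * gg);
        }
        if (cosT > 1) cosT = 1; else if (cosT < -1) cosT = -1;
        double sinT = std::sqrt(1.0 - cosT * cosT);
        double psi = 2 * M_PI * rng.unif();
        double cp = std::cos(psi), sp = std::sin(psi);
        if (std::fabs(uz) > 0.99999) {
          ux = sinT * cp; uy = sinT * sp; uz = (uz >= 0 ? cosT : -cosT);
        } else {
          double t = std::sqrt(1.0 - uz * uz);
          double nux = sinT * (ux * uz * cp - uy * sp) / t + ux * cosT;
          double nuy = sinT * (uy * uz * cp + ux * sp) / t + uy * cosT;
          double nuz = -sinT * cp * t + uz * cosT;
          double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
          ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
        }
        tau = -std::log(rng.unif_open0());
        // Russian roulette (inactive while transport is absorption-free,
        // since the weight never decreases below the threshold)
        if (w < roulette_threshold) {
          if (rng.unif() * roulette_survival < 1.0) w *= roulette_survival;
          else { w_roulette += w; break; }
        }
      } else {
        // move to the boundary
        x += ux * dbound; y += uy * dbound; z += uz * dbound;
        plm[layer] += dbound;
        tau -= dbound * musl;
        if (tau < 0) tau = 0;
        if (store_paths) {
          verts.push_back(x); verts.push_back(y); verts.push_back(z);
        }
        if (dir < 0 && layer == 0) {
          // top surface
          z = 0;
          double cos_i = -uz, cos_tr;
          double Rf = fresnel(n_layer[0], n_ext, cos_i, cos_tr);
          if (rng.unif() < Rf) {
            uz = -uz; // internally reflected, continue
          } else {
            // photon exits through the surface
            w_top += w;
            double r_exit = std::sqrt(x * x + y * y);
            if (store_exits) {
              all_exit_r.push_back(r_exit);
              all_exit_w.push_back(w);
            }
            double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
            double na_eq = n_layer[0] * sin_i; // invariant across interface
            for (int k = 0; k < nd; ++k) {
              double sep = det_sep[k];
              if (std::fabs(r_exit - sep) < det_radius &&
                  na_eq <= det_na + 1e-12) {
                double frac;
                if (r_exit <= 1e-12) {
                  frac = (sep < det_radius) ? 1.0 : 0.0;
                } else {
                  double c = (r_exit * r_exit + sep * sep -
                              det_radius * det_radius) /
                             (2.0 * r_exit * sep);
                  if (c > 1) c = 1; else if (c < -1) c = -1;
                  frac = std::acos(c) / M_PI;
                }
                if (frac > 0) {
                  for (int l = 0; l < nl; ++l) det_plm[k].push_back(plm[l]);
                  det_w[k].push_back(w * frac);
                  det_r[k].push_back(r_exit);
                  if (store_paths) {
                    det_verts[k].insert(det_verts[k].end(), verts.begin(),
                                        verts.end());
                    det_off[k].push_back(
                        static_cast<int>(det_verts[k].size() / 3));
                  }
                }
                break; // annuli do not overlap
              }
            }
            alive = false;
          }
        } else if (dir > 0) {
          // downward internal interface
          if (n_layer[layer] == n_layer[layer + 1]) {
            ++layer;
          } else {
            double cos_i = uz, cos_tr;
            double Rf = fresnel(n_layer[layer], n_layer[layer + 1], cos_i,
                                cos_tr);
            if (rng.unif() < Rf) {
              uz = -uz;
            } else {
              double scale = n_layer[layer] / n_layer[layer + 1];
              ux *= scale; uy *= scale; uz = cos_tr;
              ++layer;
            }
          }
          if (z > max_depth) { w_cutoff += w; break; }
        } else {
          // upward internal interface
          if (n_layer[layer] == n_layer[layer - 1]) {
            --layer;
          } else {
            double cos_i = -uz, cos_tr;
            double Rf = fresnel(n_layer[layer], n_layer[layer - 1], cos_i,
                                cos_tr);
            if (rng.unif() < Rf) {
              uz = -uz;
            } else {
              double scale = n_layer[layer] / n_layer[layer - 1];
              ux *= scale; uy *= scale; uz = -cos_tr;
              --layer;
            }
          }
        }
      }
    }
  }

  // assemble per-detector records
  List detectors(nd);
  for (int k = 0; k < nd; ++k) {
    int nrec = static_cast<int>(det_w[k].size());
    NumericMatrix P(nrec, nl);
    for (int i = 0; i < nrec; ++i)
      for (int l = 0; l < nl; ++l)
        P(i, l) = det_plm[k][static_cast<size_t>(i) * nl + l];
    List d = List::create(
        _["pathlengths"] = P,
        _["weight"] = NumericVector(det_w[k].begin(), det_w[k].end()),
        _["exit_radius"] = NumericVector(det_r[k].begin(), det_r[k].end()));
    if (store_paths) {
      int nv = static_cast<int>(det_verts[k].size() / 3);
      NumericMatrix V(nv, 3);
      for (int i = 0; i < nv; ++i)
        for (int j = 0; j < 3; ++j) V(i, j) = det_verts[k][3 * i + j];
      d["path_vertices"] = V;
      d["path_offsets"] = IntegerVector(det_off[k].begin(), det_off[k].end());
    }
    detectors[k] = d;
  }
  List out = List::create(
      _["detectors"] = detectors,
      _["totals"] = NumericVector::create(
          _["launched"] = static_cast<double>(n_photons),
          _["specular"] = w_specular, _["top_exit"] = w_top,
          _["cutoff_lost"] = w_cutoff, _["max_events_lost"] = w_maxevt,
          _["roulette_lost"] = w_roulette));
  if (store_exits) {
    out["exit_radius_all"] = NumericVector(all_exit_r.begin(),
                                           all_exit_r.end());
    out["exit_weight_all"] = NumericVector(all_exit_w.begin(),
                                           all_exit_w.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Path point cloud: for each photon draw points_per_photon positions
// uniformly along the arc length of its vertex chain and return their
// depths, each carrying the photon's weight.

// [[Rcpp::export]]
List compress_paths_cpp(NumericMatrix verts, IntegerVector offsets,
                        NumericVector weights, int points_per_photon,
                        double seed) {
  const int np = offsets.size() - 1;
  if (points_per_photon < 1) stop("points_per_photon must be >= 1");
  if (weights.size() != np) stop("weights must match the number of photons");
  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<double> depth, wout;
  depth.reserve(static_cast<size_t>(np) * points_per_photon);
  wout.reserve(static_cast<size_t>(np) * points_per_photon);
  std::vector<double> cum;
  for (int p = 0; p < np; ++p) {
    int a = offsets[p], b = offsets[p + 1];
    int nseg = b - a - 1;
    if (nseg < 1) {
      // degenerate single-vertex path: all points at that vertex
      for (int j = 0; j < points_per_photon; ++j) {
        depth.push_back(verts(a, 2));
        wout.push_back(weights[p]);
      }
      continue;
    }
    cum.assign(nseg + 1, 0.0);
    for (int sIdx = 0; sIdx < nseg; ++sIdx) {
      double dx = verts(a + sIdx + 1, 0) - verts(a + sIdx, 0);
      double dy = verts(a + sIdx + 1, 1) - verts(a + sIdx, 1);
      double dz = verts(a + sIdx + 1, 2) - verts(a + sIdx, 2);
      cum[sIdx + 1] = cum[sIdx] + std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    double L = cum[nseg];
    for (int j = 0; j < points_per_photon; ++j) {
      double t = rng.unif() * L;
      // binary search for the segment containing arc length t
      int lo = 0, hi = nseg;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (cum[mid] <= t) lo = mid; else hi = mid;
      }
      double seglen = cum[lo + 1] - cum[lo];
      double f = seglen > 0 ? (t - cum[lo]) / seglen : 0.0;
      double zz = verts(a + lo, 2) +
                  f * (verts(a + lo + 1, 2) - verts(a + lo, 2));
      depth.push_back(zz);
      wout.push_back(weights[p]);
    }
  }
  return List::create(_["depth"] = NumericVector(depth.begin(), depth.end()),
                      _["weight"] = NumericVector(wout.begin(), wout.end()));
}

// ---------------------------------------------------------------------------
// Beer-Lambert synthesis over interpolation cells.
//
// cells: list of n_cell entries; each entry is a list over detectors with
// elements P (n_rec x n_layer pathlength matrix, already restricted to the
// detector) and w (weights normalized per launched photon).
// cellw: n_lambda x n_cell bilinear interpolation weights.
// mua: n_lambda x n_layer absorption coefficients.
// Returns n_lambda x n_det reflectance (detected weight fraction).

// [[Rcpp::export]]
NumericMatrix bl_reflectance_cpp(List cells, NumericMatrix cellw,
                                 NumericMatrix mua, int n_det) {
  const int ncell = cells.size();
  const int nlam = mua.nrow();
  const int nlay = mua.ncol();
  if (cellw.nrow() != nlam || cellw.ncol() != ncell)
    stop("cellw dimensions do not match");
  NumericMatrix out(nlam, n_det);
  for (int c = 0; c < ncell; ++c) {
    List cell = cells[c];
    if (cell.size() < n_det) stop("cell has too few detectors");
    for (int k = 0; k < n_det; ++k) {
      List det = cell[k];
      NumericMatrix P = det["pathlengths"];
      NumericVector w = det["weight"];
      const int nrec = P.nrow();
      if (P.ncol() != nlay) stop("pathlength/absorption layer mismatch");
      // contiguous copies for the inner loop
      std::vector<double> l1(nrec), l2(nrec), l3(nrec);
      for (int i = 0; i < nrec; ++i) {
        l1[i] = P(i, 0);
        l2[i] = nlay > 1 ? P(i, 1) : 0.0;
        l3[i] = nlay > 2 ? P(i, 2) : 0.0;
      }
      for (int m = 0; m < nlam; ++m) {
        double bw = cellw(m, c);
        if (bw == 0) continue;
        double a1 = mua(m, 0);
        double a2 = nlay > 1 ? mua(m, 1) : 0.0;
        double a3 = nlay > 2 ? mua(m, 2) : 0.0;
        double acc = 0;
        for (int i = 0; i < nrec; ++i)
          acc += w[i] * std::exp(-(a1 * l1[i] + a2 * l2[i] + a3 * l3[i]));
        out(m, k) += bw * acc;
      }
    }
  }
  return out;
}

// Per-photon Beer-Lambert weights for one cell/detector at one wavelength.
// [[Rcpp::export]]
NumericVector bl_photon_weights_cpp(NumericMatrix P, NumericVector w,
                                    NumericVector mua) {
  const int nrec = P.nrow();
  const int nlay = P.ncol();
  if (mua.size() != nlay) stop("mua length must equal the layer count");
  NumericVector out(nrec);
  for (int i = 0; i < nrec; ++i) {
    double e = 0;
    for (int l = 0; l < nlay; ++l) e += mua[l] * P(i, l);
    out[i] = w[i] * std::exp(-e);
  }
  return out;
}
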