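#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// xoshiro256+ generator: deterministic given a 64-bit seed, independent of
// R's RNG state so cached photon sets are reproducible across sessions.
namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 so log() is safe
  double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

} // namespace

//' @name mc_layered_paths
//' @title Layered-slab photon random walk (internal)
//' @description Traces photon packets through a stack of scattering layers
//'   with index-matched boundaries and isotropic scattering, recording the
//'   per-layer path length of every packet that exits the top surface inside
//'   a detector annulus. Absorption is NOT applied during tracking; it is
//'   applied afterwards by path-length reweighting, so one photon set serves
//'   every absorption vector.
//' @keywords internal
// [[Rcpp::export(name = ".mc_layered_paths")]]
List mc_layered_paths(double n_photons,
                      NumericVector mus,
                      NumericVector thickness,
                      double rho_min,
                      double rho_max,
                      double max_path_cm,
                      double seed) {
  const int nl = mus.size();
  if (thickness.size() != nl) stop("mus and thickness must have equal length");
  for (int i = 0; i < nl; ++i) {
    if (mus[i] <= 0 || thickness[i] <= 0) stop("mus and thickness must be positive");
  }
  std::vector<double> zb(nl + 1);
  zb[0] = 0.0;
  for (int i = 0; i < nl; ++i) zb[i + 1] = zb[i] + thickness[i];
  // the deepest layer extends to infinity (semi-infinite bottom)
  const double z_bottom = zb[nl];

  Xoshiro rng(static_cast<uint64_t>(seed));

  std::vector<double> paths;   // detected photons x nl, row-major
  std::vector<double> exit_r;
  std::vector<double> L(nl);

  const long np = static_cast<long>(n_photons);
  for (long ip = 0; ip < np; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    std::fill(L.begin(), L.end(), 0.0);
    double total = 0.0;
    int il = 0;
    bool alive = true, detected = false;

    while (alive) {
      double tau = -std::log(rng.runif());
      // consume optical depth tau, walking across layer boundaries
      while (tau > 0.0) {
        double s_free = tau / mus[il];
        // distance to the layer boundary along the current direction
        double d_b = R_PosInf;
        int next_il = il;
        if (uz > 1e-12) {
          if (z < z_bottom) { d_b = (zb[il + 1] - z) / uz; next_il = il + 1; }
          // below z_bottom: still "layer nl-1", no further boundary downward
        } else if (uz < -1e-12) {
          d_b = (zb[il] - z) / uz;
          next_il = il - 1;
        }
        double step = (s_free < d_b) ? s_free : d_b;
        x += step * ux; y += step * uy; z += step * uz;
        L[il] += step; total += step;
        if (total > max_path_cm) { alive = false; break; }
        if (s_free < d_b) {
          tau = 0.0;           // scattering site reached inside the layer
        } else {
          tau -= d_b * mus[il];
          if (next_il < 0) {   // crossed the top surface: photon escapes
            alive = false;
            double r = std::sqrt(x * x + y * y);
            if (r >= rho_min && r <= rho_max) detected = true;
            break;
          }
          il = next_il;
          if (il >= nl) il = nl - 1;  // bookkeeping for the semi-infinite tail
        }
      }
      if (!alive) break;
      // isotropic scattering (reduced-scattering similarity)
      double cz = 2.0 * rng.runif() - 1.0;
      double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
      double phi = 2.0 * M_PI * rng.runif();
      ux = sz * std::cos(phi); uy = sz * std::sin(phi); uz = cz;
    }

    if (detected) {
      for (int i = 0; i < nl; ++i) paths.push_back(L[i]);
      exit_r.push_back(std::sqrt(x * x + y * y));
    }
  }

  const int nd = static_cast<int>(exit_r.size());
  NumericMatrix P(nd, nl);
  for (int r = 0; r < nd; ++r)
    for (int c = 0; c < nl; ++c)
      P(r, c) = paths[static_cast<size_t>(r) * nl + c];
  return List::create(_["paths_cm"] = P,
                      _["exit_r_cm"] = NumericVector(exit_r.begin(), exit_r.end()),
                      _["n_launched"] = static_cast<double>(np));
}
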