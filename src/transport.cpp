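// Voxelized weighted-photon Monte Carlo transport kernel.
//
// Scheme: implicit capture (weight splitting by the single-scatter albedo at
// each interaction), Henyey-Greenstein deflection sampling, Russian roulette
// below a weight threshold, Fresnel or matched air-water surface, absorbing
// or mirrored lateral boundaries, absorbing bottom. Free paths are sampled as
// an optical depth -log(xi) and walked voxel-by-voxel so media changes along
// the path are handled exactly (residual optical depth carries across
// interfaces). Every photon has its own counter-based random stream keyed by
// (seed, photon index), so results are bit-identical for a given seed
// regardless of execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// splitmix64: counter-based generator, one independent stream per photon
struct Rng {
  uint64_t state;
  Rng(uint64_t seed, uint64_t stream) {
    state = (seed + 0x9E3779B97F4A7C15ULL) ^
            (stream * 0xBF58476D1CE4E5B9ULL + 0x94D049BB133111EBULL);
    next_u64(); next_u64();  // decorrelate nearby (seed, stream) pairs
  }
  uint64_t next_u64() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double u() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0, 1] -- safe for log()
  double u_open() { return ((next_u64() >> 11) + 1.0) * (1.0 / 9007199254740992.0); }
};

struct Ledger {
  double launched = 0, specular = 0, reflected_surface = 0,
         absorbed_water = 0, absorbed_debris = 0, escaped_bottom = 0,
         escaped_sides = 0, roulette_killed = 0;
};

inline double fresnel_unpolarized(double n1, double n2, double ci) {
  // ci = |cos(incidence angle)| in medium n1
  double st2 = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (st2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

inline double sample_hg(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

inline void spin_direction(double &ux, double &uy, double &uz,
                           double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

}  // namespace

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(IntegerVector labels, IntegerVector dims, double dx,
                      NumericVector mua, NumericVector mus, NumericVector gv,
                      double n_water,
                      int src_gaussian, double src_radius,
                      double src_cx, double src_cy, NumericVector src_dir,
                      int n_photons, double seed,
                      double roulette_threshold, double roulette_survival,
                      int fresnel_surface, int mirror_lateral,
                      double max_scatter, int tally_fluence) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double Lx = nx * dx, Ly = ny * dx, Lz = nz * dx;
  const int *lab = INTEGER(labels);
  const int nmedia = mua.size();
  for (int m = 0; m < nmedia; ++m) {
    if (!std::isfinite(mua[m]) || !std::isfinite(mus[m]) || !std::isfinite(gv[m]))
      stop("non-finite optical coefficients for medium %d", m);
    if (mua[m] + mus[m] <= 0.0)
      stop("zero total interaction coefficient (vacuum) for medium %d", m);
  }
  NumericMatrix refl(nx, ny);
  NumericVector fluence(tally_fluence ? (R_xlen_t)nx * ny * nz : 0);
  Ledger led;
  const double sdx = src_dir[0], sdy = src_dir[1], sdz = src_dir[2];
  const uint64_t useed = (uint64_t)seed;

  for (int ip = 0; ip < n_photons; ++ip) {
    Rng rng(useed, (uint64_t)ip);
    // launch position
    double x, y;
    if (src_gaussian) {
      int tries = 0;
      do {
        double r = src_radius * std::sqrt(-std::log(rng.u_open()) * 0.5);
        double ph = 2.0 * M_PI * rng.u();
        x = src_cx + r * std::cos(ph);
        y = src_cy + r * std::sin(ph);
        if (++tries > 100000) stop("source acceptance too low: beam misses the domain");
      } while (x < 0 || x >= Lx || y < 0 || y >= Ly);
    } else {
      x = rng.u() * Lx;
      y = rng.u() * Ly;
    }
    double z = 0.0;
    double ux = sdx, uy = sdy, uz = sdz;
    double w = 1.0;
    led.launched += 1.0;
    // air -> water interface
    if (fresnel_surface) {
      double ci = uz;  // downward component = cos incidence for this convention
      double R = fresnel_unpolarized(1.0, n_water, ci);
      led.specular += w * R;
      w *= (1.0 - R);
      // Snell refraction of the transmitted direction
      double st2 = (1.0 / n_water) * (1.0 / n_water) * (1.0 - ci * ci);
      double ct = std::sqrt(1.0 - st2);
      double k = 1.0 / n_water;
      ux = k * ux; uy = k * uy;
      uz = ct;  // downward normal component after refraction
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;
    }
    int ix = (int)(x / dx); if (ix >= nx) ix = nx - 1;
    int iy = (int)(y / dx); if (iy >= ny) iy = ny - 1;
    int iz = 0;
    long nscat = 0;
    bool alive = true;

    while (alive) {
      double tau = -std::log(rng.u_open());
      // walk the optical depth through the voxel grid
      bool interact = false;
      while (true) {
        int l = lab[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        double mt = mua[l] + mus[l];
        // distances to the voxel faces along the direction of flight
        double sx = (ux > 0) ? ((ix + 1) * dx - x) / ux :
                    (ux < 0) ? (ix * dx - x) / ux : 1e30;
        double sy = (uy > 0) ? ((iy + 1) * dx - y) / uy :
                    (uy < 0) ? (iy * dx - y) / uy : 1e30;
        double sz = (uz > 0) ? ((iz + 1) * dx - z) / uz :
                    (uz < 0) ? (iz * dx - z) / uz : 1e30;
        if (sx < 0) sx = 0; if (sy < 0) sy = 0; if (sz < 0) sz = 0;
        double sb = sx < sy ? (sx < sz ? sx : sz) : (sy < sz ? sy : sz);
        double si = tau / mt;
        if (si <= sb) {
          x += si * ux; y += si * uy; z += si * uz;
          interact = true;
          break;
        }
        x += sb * ux; y += sb * uy; z += sb * uz;
        tau -= sb * mt;
        if (sb == sx) {
          ix += (ux > 0) ? 1 : -1;
          if (ix < 0 || ix >= nx) {
            if (mirror_lateral) { ux = -ux; ix = (ix < 0) ? 0 : nx - 1; }
            else { led.escaped_sides += w; alive = false; break; }
          }
        } else if (sb == sy) {
          iy += (uy > 0) ? 1 : -1;
          if (iy < 0 || iy >= ny) {
            if (mirror_lateral) { uy = -uy; iy = (iy < 0) ? 0 : ny - 1; }
            else { led.escaped_sides += w; alive = false; break; }
          }
        } else {
          iz += (uz > 0) ? 1 : -1;
          if (iz >= nz) { led.escaped_bottom += w; alive = false; break; }
          if (iz < 0) {
            // reached the surface moving upward
            int px = (int)(x / dx); if (px < 0) px = 0; if (px >= nx) px = nx - 1;
            int py = (int)(y / dx); if (py < 0) py = 0; if (py >= ny) py = ny - 1;
            if (fresnel_surface) {
              double R = fresnel_unpolarized(n_water, 1.0, -uz);
              double t = w * (1.0 - R);
              refl(px, py) += t;
              led.reflected_surface += t;
              w -= t;
              if (w <= 0) { alive = false; break; }
              uz = -uz;  // internally reflected part continues
              iz = 0;
              z = 0.0;
            } else {
              refl(px, py) += w;
              led.reflected_surface += w;
              alive = false;
              break;
            }
          }
        }
      }
      if (!alive) break;
      if (!interact) continue;  // boundary event consumed the flight

      // interaction: deposit the absorbed fraction, scatter the survivor
      int l = lab[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      double mt = mua[l] + mus[l];
      double fa = mua[l] / mt;
      double dep = w * fa;
      if (l == 0) led.absorbed_water += dep; else led.absorbed_debris += dep;
      if (tally_fluence)
        fluence[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] += dep;
      w -= dep;
      if (w <= 0) { alive = false; break; }
      double ct = sample_hg(gv[l], rng.u());
      double phi = 2.0 * M_PI * rng.u();
      spin_direction(ux, uy, uz, ct, phi);
      if (++nscat > (long)max_scatter) {
        led.roulette_killed += w;
        alive = false;
        break;
      }
      // Russian roulette; the ledger records the net weight change so the
      // balance is exact, not just exact in expectation
      if (w < roulette_threshold) {
        if (rng.u() < roulette_survival) {
          led.roulette_killed += w - w / roulette_survival;
          w /= roulette_survival;
        } else {
          led.roulette_killed += w;
          alive = false;
        }
      }
    }
    if (ip % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  List ledger = List::create(
    _["launched"] = led.launched, _["specular"] = led.specular,
    _["reflected_surface"] = led.reflected_surface,
    _["absorbed_water"] = led.absorbed_water,
    _["absorbed_debris"] = led.absorbed_debris,
    _["escaped_bottom"] = led.escaped_bottom,
    _["escaped_sides"] = led.escaped_sides,
    _["roulette_killed"] = led.roulette_killed);
  return List::create(_["reflectance"] = refl,
                      _["fluence"] = fluence,
                      _["ledger"] = ledger);
}
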