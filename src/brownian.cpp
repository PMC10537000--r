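#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Self-contained, platform-independent RNG for the Brownian propagator:
// xoshiro256++ uniforms feeding a ziggurat normal sampler. Runs are
// bit-reproducible given the integer seed, independent of the R session RNG.
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
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }

  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
};

// Marsaglia-Tsang ziggurat (128 layers) over xoshiro256++; tables built at
// construction, so the sampler is self-contained and platform-independent.
struct ZigNormal {
  Xoshiro rng;
  double wn[128], fn[128];
  uint64_t kn[128];

  explicit ZigNormal(uint64_t seed) : rng(seed) {
    const double m = 9007199254740992.0;      // 2^53
    const double vn = 9.91256303526217e-3;    // area of each layer
    double dn = 3.442619855899, tn = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint64_t)((dn / q) * m);
    kn[1] = 0;
    wn[0] = q / m;
    wn[127] = dn / m;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint64_t)((dn / tn) * m);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m;
    }
  }

  double normal() {
    for (;;) {
      const uint64_t u = rng.next();
      const int i = (int)(u & 127);
      const int64_t iz = ((int64_t)(u >> 8) - (int64_t)(1ULL << 55)) >> 2;
      const double x = iz * wn[i];
      if ((uint64_t)std::llabs(iz) < kn[i]) return x;
      if (i == 0) {                          // tail, Marsaglia's method
        const double r = 3.442619855899;
        double xx, yy;
        do {
          xx = -std::log(rng.unif()) / r;
          yy = -std::log(rng.unif());
        } while (yy + yy < xx * xx);
        return (iz > 0) ? r + xx : -(r + xx);
      }
      if (fn[i] + rng.unif() * (fn[i - 1] - fn[i]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

inline double wrap0(double x, double L) {
  x -= L * std::floor(x / L);
  return (x >= L) ? x - L : x;   // guard against floor rounding at the edge
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List bd_simulate_cpp(NumericMatrix pos0,        // N x 3, wrapped nm
                     NumericVector box,         // Lx, Ly, Lz
                     double plane,              // restraint plane position (nm)
                     double r, double k, bool inverted,
                     NumericVector D,           // per-particle diffusion nm^2/ps
                     double kT,                 // kJ/mol
                     double dt,                 // ps
                     double nsteps_d,           // total steps (double to allow > 2^31)
                     int record_every,          // steps between records
                     double seed) {
  const int N = pos0.nrow();
  const long long nsteps = (long long)nsteps_d;
  if (record_every < 1) stop("record_every must be >= 1");
  if (nsteps % record_every != 0) stop("nsteps must be a multiple of record_every");
  const long long F = nsteps / record_every + 1;  // includes the initial frame

  std::vector<double> x(N), y(N), z(N), sig(N), mob(N);
  for (int i = 0; i < N; ++i) {
    x[i] = wrap0(pos0(i, 0), box[0]);
    y[i] = wrap0(pos0(i, 1), box[1]);
    z[i] = wrap0(pos0(i, 2), box[2]);
    sig[i] = std::sqrt(2.0 * D[i] * dt);
    mob[i] = D[i] / kT;               // 1/gamma, nm^2 ps^-1 / (kJ/mol)
  }
  const double Lx = box[0], Ly = box[1], Lz = box[2];

  NumericVector coords((R_xlen_t)F * N * 3);   // dim (F, N, 3)
  NumericVector times(F);
  ZigNormal rng((uint64_t)seed);

  auto record = [&](long long f) {
    for (int i = 0; i < N; ++i) {
      coords[f + F * (R_xlen_t)i]               = x[i];
      coords[f + F * ((R_xlen_t)i + N)]         = y[i];
      coords[f + F * ((R_xlen_t)i + 2L * N)]    = z[i];
    }
  };
  record(0);
  times[0] = 0.0;

  const double halfLz = 0.5 * Lz;
  for (long long step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < N; ++i) {
      double fz = 0.0;
      if (k > 0.0) {
        // positions stay wrapped, so one conditional recovers the image
        double d = z[i] - plane;
        if (d > halfLz) d -= Lz; else if (d < -halfLz) d += Lz;
        const double ad = (d >= 0.0) ? d : -d;
        if (inverted) {
          if (ad < r && ad > 0.0)
            fz = k * (r - ad) * (d > 0 ? 1.0 : -1.0);
        } else {
          if (ad > r)
            fz = -k * (ad - r) * (d > 0 ? 1.0 : -1.0);
        }
      }
      // per-step displacements are tiny relative to the box, so wrapping is
      // a single conditional add/subtract
      double nx = x[i] + sig[i] * rng.normal();
      if (nx < 0.0) nx += Lx; else if (nx >= Lx) nx -= Lx;
      x[i] = nx;
      double ny = y[i] + sig[i] * rng.normal();
      if (ny < 0.0) ny += Ly; else if (ny >= Ly) ny -= Ly;
      y[i] = ny;
      double nz = z[i] + mob[i] * fz * dt + sig[i] * rng.normal();
      if (nz < 0.0) nz += Lz; else if (nz >= Lz) nz -= Lz;
      z[i] = nz;
    }
    if (step % record_every == 0) {
      const long long f = step / record_every;
      record(f);
      times[f] = step * dt;
    }
  }

  coords.attr("dim") = IntegerVector::create((int)F, N, 3);
  return List::create(_["coords"] = coords, _["times"] = times);
}

// The restraint plane and all its periodic images form a lattice p = plane +
// m*L. A crossing is recorded whenever the minimal-image path between two
// consecutive frames passes strictly through a lattice plane; a frame landing
// exactly on a plane is held pending and resolved by the sign of the next
// non-zero displacement (it counts only if the particle continues through).
//' @noRd
// [[Rcpp::export]]
List count_crossings_cpp(NumericMatrix zmat,   // F x N wrapped z
                         double L, double plane) {
  const int F = zmat.nrow(), N = zmat.ncol();
  std::vector<int> ev_particle, ev_frame, ev_dir;
  auto emit = [&](int i, int f, int dir) {
    ev_particle.push_back(i + 1); ev_frame.push_back(f + 1); ev_dir.push_back(dir);
  };
  for (int i = 0; i < N; ++i) {
    double u = zmat(0, i) - plane;        // unwrapped position relative to plane
    int pending = 0;                      // side arrived from when exactly on a plane
    for (int f = 1; f < F; ++f) {
      double d = zmat(f, i) - zmat(f - 1, i);
      d -= L * std::nearbyint(d / L);     // minimal-image displacement
      if (d == 0.0) continue;
      const double b = u + d;
      const double va = u / L, vb = b / L;
      const bool a_lat = (va == std::floor(va));
      if (a_lat) {
        if (pending == -1 && d > 0) emit(i, f, +1);
        else if (pending == +1 && d < 0) emit(i, f, -1);
        pending = 0;
      }
      if (d > 0) {
        const long long lo = (long long)std::floor(va) + 1;
        const long long hi = (long long)std::ceil(vb) - 1;
        for (long long m = lo; m <= hi; ++m) emit(i, f, +1);
      } else {
        const long long lo = (long long)std::ceil(va) - 1;
        const long long hi = (long long)std::floor(vb) + 1;
        for (long long m = lo; m >= hi; --m) emit(i, f, -1);
      }
      if (vb == std::floor(vb)) pending = (d > 0) ? -1 : +1;
      u = b;
    }
  }
  return List::create(_["particle"] = wrap(ev_particle),
                      _["frame"] = wrap(ev_frame),
                      _["direction"] = wrap(ev_dir));
}
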