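// Core fixed-step stochastic integrator for a single actin filament gliding
// over a bed of myosin motors.
//
// Conventions (nm, s, pN):
//  * The filament glides pointed-end-leading along +x; the barbed (growing)
//    end is the trailing edge at x_b.  The pointed edge sits at
//    x_b + 2.7 * length_su.
//  * A motor binds one subunit; its "site" (distance from the barbed end)
//    changes only through subunit gain/loss at the ends, never by advection.
//  * Motor cycle: attach (driving, zero strain) -> power stroke at linear
//    force-velocity up to F_stall over d_stroke of sliding -> resisting
//    (elastic anchor loaded at kappa * (v_f - F/xi_anchor)) -> detach at the
//    catch-slip rate k(F).  xi_anchor = Inf encodes motors immobilized on
//    glass.
//  * Barbed-end chemistry runs as an exact Gillespie sub-loop within each
//    step (rates frozen over the step), so that with motors disabled the
//    process is exactly the two-rate birth-death process.
//
// Two independent RNG streams (motor bed / filament-end chemistry) keep
// paired simulations that differ only in end-chemistry parameters maximally
// coupled on the motor side.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

namespace {

// splitmix64: seed expander for the xorshift generator below
inline std::uint64_t splitmix64(std::uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++ — small, fast, well-defined across platforms
struct Rng {
  std::uint64_t s[4];
  explicit Rng(std::uint64_t seed) {
    std::uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
  // Knuth Poisson; fine for the small means used for attachment sampling
  int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    // normal approximation for large means
    double u1 = unif(), u2 = unif();
    double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
    double x = lambda + std::sqrt(lambda) * z;
    return x < 0.0 ? 0 : (int)std::lround(x);
  }
};

struct Motor {
  double s_raw;   // site minus global offset (nm from barbed end)
  double F;       // strain force when resisting (pN)
  double prog;    // stroke progress when driving (nm)
  double t0;      // attachment time (s)
  bool driving;
};

inline double clampExp(double x) { return std::exp(x > 30.0 ? 30.0 : x); }

} // namespace

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_glide(List par) {
  const double v0_max   = par["v0_max"];
  const double K_ATP    = par["K_ATP"];
  const double ATP      = par["ATP"];
  const double attach   = par["attach_rate"];
  const double F_stall  = par["F_stall"];
  const double kappa    = par["kappa"];
  const double k_det_c  = par["k_det_c"];
  const double F_c      = par["F_c"];
  const double k_det_s  = par["k_det_s"];
  const double F_s      = par["F_s"];
  const double xi_a     = par["xi_anchor"];
  const double d_stroke = par["d_stroke"];
  const double k_on     = par["k_on"];
  const double k_off0   = par["k_off0"];
  const double delta    = par["delta"];
  const double ell_tip  = par["ell_tip"];
  const double kBT      = par["kBT"];
  const double C_m      = par["C_m"];
  const double density  = par["motor_density"];     // per um^2
  const double halfw    = par["capture_halfwidth"]; // nm
  const double eta_b    = par["eta_b"];             // Pa s
  const double crowd    = par["crowding"];
  const double L0_su    = par["initial_length"];
  const double duration = par["duration"];
  const double dt       = par["dt"];
  const double sample_dt = par["sample_dt"];
  const double p_off_rate = par["pointed_off_rate"];
  const int    seed     = par["seed"];
  const int    ev_cap   = par["n_event_max"];

  const double SU = 2.7; // nm per subunit
  const double mm = (ATP + K_ATP) > 0.0 ? ATP / (ATP + K_ATP) : 0.0;
  const double v0 = v0_max * mm;
  const bool mobile = R_finite(xi_a);
  const double beta = (mobile && xi_a > 0.0 && v0 > 0.0)
                        ? F_stall / (xi_a * v0) : 0.0;
  const double rho_lin = density * 1e-6 * 2.0 * halfw; // motors per nm of filament

  Rng rng_m((std::uint64_t)seed * 2ULL + 0ULL + 0x9E3779B9ULL);
  Rng rng_b((std::uint64_t)seed * 2ULL + 1ULL + 0x632BE5ABULL);

  std::vector<Motor> mot;
  mot.reserve(1024);

  double t = 0.0, x_b = 0.0, s_off = 0.0;
  long L_su = (long)std::lround(L0_su);
  long n_on = 0, n_off = 0, n_p = 0;

  const int n_steps = (int)std::ceil(duration / dt - 1e-9);
  std::vector<double> rec_t, rec_x, rec_v;
  std::vector<double> rec_L;
  std::vector<int> rec_on, rec_offv, rec_p, rec_nd, rec_nr;
  std::vector<double> ev_t; std::vector<int> ev_k;
  rec_t.reserve(n_steps / 16 + 2);

  double next_sample = 0.0;
  bool dead = false;
  double v = 0.0;

  auto record = [&](double vel) {
    int nd = 0, nr = 0;
    for (const Motor &m : mot) { if (m.driving) ++nd; else ++nr; }
    rec_t.push_back(t); rec_x.push_back(x_b); rec_L.push_back((double)L_su);
    rec_on.push_back((int)n_on); rec_offv.push_back((int)n_off);
    rec_p.push_back((int)n_p);
    rec_nd.push_back(nd); rec_nr.push_back(nr); rec_v.push_back(vel);
  };

  for (int step = 0; step < n_steps && !dead; ++step) {
    if (t >= next_sample - 1e-12) { record(v); next_sample += sample_dt; }

    const double L_nm = SU * (double)L_su;
    if (L_su <= 0) break;

    // slender-body bulk drag, pN s / nm
    const double xi_b = (eta_b > 0.0 && L_nm > 8.0)
      ? 4.0 * M_PI * eta_b * crowd * L_nm / std::log(2.0 * L_nm / 4.0) * 1e-6
      : 0.0;

    // --- force balance -> instantaneous sliding velocity -------------------
    int n_d = 0;
    double S_res = 0.0;
    for (const Motor &m : mot) {
      if (m.driving) ++n_d; else S_res += m.F;
    }
    if (n_d > 0 && v0 > 0.0) {
      const double drive = (double)n_d * F_stall / (1.0 + beta);
      v = (drive - S_res) / (xi_b + drive / v0);
      if (v < 0.0) v = 0.0;
      if (v > v0) v = v0;
    } else {
      v = 0.0;
    }
    const double F_drv = F_stall * (v0 > 0.0 ? (1.0 - v / v0) : 0.0) / (1.0 + beta);

    // --- tip load: resisting motor closest to the barbed end ---------------
    double F_tip = 0.0, s_min = ell_tip;
    for (const Motor &m : mot) {
      if (!m.driving) {
        const double s = m.s_raw + s_off;
        if (s < s_min) { s_min = s; F_tip = m.F; }
      }
    }

    // --- barbed/pointed-end chemistry: Gillespie within the step -----------
    const double r_on  = k_on * C_m;
    const double r_off = (L_su > 0) ? k_off0 * clampExp(F_tip * delta / kBT) : 0.0;
    const double r_p   = (L_su > 0) ? p_off_rate : 0.0;
    double r_tot = r_on + r_off + r_p;
    if (r_tot > 0.0) {
      double t_ev = rng_b.expo(r_tot);
      while (t_ev < dt && !dead) {
        const double u = rng_b.unif() * r_tot;
        int kind;
        if (u < r_on) {
          ++L_su; ++n_on; s_off += SU; x_b -= SU; kind = 1;
        } else if (u < r_on + r_off) {
          --L_su; ++n_off; s_off -= SU; x_b += SU; kind = 2;
        } else {
          --L_su; ++n_p; kind = 3;
        }
        if ((int)ev_t.size() < ev_cap) { ev_t.push_back(t + t_ev); ev_k.push_back(kind); }
        if (L_su <= 0) { dead = true; break; }
        t_ev += rng_b.expo(r_tot);
      }
    }
    const double L_nm_new = SU * (double)L_su;

    // --- motor bed update ---------------------------------------------------
    for (std::size_t i = 0; i < mot.size();) {
      Motor &m = mot[i];
      const double s_now = m.s_raw + s_off;
      bool gone = false;
      if (s_now < 0.0 || s_now > L_nm_new) {
        gone = true; // bound subunit lost at an end
      } else if (m.driving) {
        // stroke progress is head-anchor relative displacement: filament
        // sliding plus backward anchor slip under the driving reaction force
        const double vmd = (mobile && xi_a > 0.0) ? F_drv / xi_a : 0.0;
        m.prog += (v + vmd) * dt;
        const double k_det = mm * (k_det_c * std::exp(-F_drv / F_c) +
                                   k_det_s * clampExp(F_drv / F_s));
        if (rng_m.unif() < 1.0 - std::exp(-k_det * dt)) gone = true;
        else if (m.prog >= d_stroke) { m.driving = false; m.F = 0.0; }
      } else {
        const double vm = mobile && xi_a > 0.0 ? m.F / xi_a : 0.0;
        m.F += kappa * (v - vm) * dt;
        if (m.F < 0.0) m.F = 0.0;
        const double k_det = mm * (k_det_c * std::exp(-m.F / F_c) +
                                   k_det_s * clampExp(m.F / F_s));
        if (rng_m.unif() < 1.0 - std::exp(-k_det * dt)) gone = true;
      }
      if (gone) { mot[i] = mot.back(); mot.pop_back(); } else ++i;
    }

    // --- attachments (Poisson limit of per-site Bernoulli sampling) --------
    if (rho_lin > 0.0 && attach > 0.0 && !dead) {
      const double n_avail = rho_lin * L_nm_new - (double)mot.size();
      if (n_avail > 0.0) {
        const int K = rng_m.poisson(n_avail * (1.0 - std::exp(-attach * dt)));
        for (int k = 0; k < K; ++k) {
          Motor m;
          m.s_raw = rng_m.unif() * L_nm_new - s_off;
          m.F = 0.0; m.prog = 0.0; m.t0 = t; m.driving = true;
          mot.push_back(m);
        }
      }
    }

    x_b += v * dt;
    t += dt;
  }
  record(v);

  return List::create(
    _["times"] = rec_t, _["x_b"] = rec_x, _["length_su"] = rec_L,
    _["n_on"] = rec_on, _["n_off"] = rec_offv, _["n_p_off"] = rec_p,
    _["n_driving"] = rec_nd, _["n_resisting"] = rec_nr, _["v_inst"] = rec_v,
    _["event_times"] = ev_t, _["event_kind"] = ev_k,
    _["absorbed"] = dead);
}
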