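// Structure-based coarse-grained CA model: Langevin dynamics, constant-speed
// pulling, potential-energy evaluation. Reduced units: energy eps, length
// Angstrom, time tau, mass 1, k_B = 1.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Model {
  int n;
  std::vector<double> x;           // 3n coords
  std::vector<double> bond_r0;     // n-1
  std::vector<int> ci, cj;         // contacts (0-based)
  std::vector<double> cr0;
  std::vector<double> chir0;       // n-3 native chirality values
  double eps, bond_k, chir_k, rep_sigma, d0;
};

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// potential energy and forces; repulsive pairs come from a neighbor list
static double forces(const Model& m, const std::vector<double>& x,
                     const std::vector<std::pair<int, int>>& rep_pairs,
                     std::vector<double>& f) {
  const int n = m.n;
  std::fill(f.begin(), f.end(), 0.0);
  double epot = 0.0;

  // harmonic bonds
  for (int i = 0; i < n - 1; ++i) {
    double d[3] = {x[3 * i + 3] - x[3 * i], x[3 * i + 4] - x[3 * i + 1],
                   x[3 * i + 5] - x[3 * i + 2]};
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double dr = r - m.bond_r0[i];
    epot += 0.5 * m.bond_k * dr * dr;
    double c = m.bond_k * dr / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] += c * d[k];
      f[3 * i + 3 + k] -= c * d[k];
    }
  }

  // native contacts: LJ 12-6 with minimum -eps at r0
  for (size_t t = 0; t < m.ci.size(); ++t) {
    int i = m.ci[t], j = m.cj[t];
    double d[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                   x[3 * j + 2] - x[3 * i + 2]};
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    double r = std::sqrt(r2);
    double s = m.cr0[t] / r;
    double s6 = s * s * s * s * s * s;
    epot += m.eps * (s6 * s6 - 2.0 * s6);
    // dV/dr = 12 eps (s6 - s12)/r ; force on j is -dV/dr * d/r
    double dvdr = 12.0 * m.eps * (s6 - s6 * s6) / r;
    double c = -dvdr / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * j + k] += c * d[k];
      f[3 * i + k] -= c * d[k];
    }
  }

  // excluded volume for non-contact, non-local pairs (truncated & shifted LJ)
  double sig = m.rep_sigma;
  double sig2 = sig * sig;
  for (auto& pr : rep_pairs) {
    int i = pr.first, j = pr.second;
    double d[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                   x[3 * j + 2] - x[3 * i + 2]};
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= sig2) continue;
    double r = std::sqrt(r2);
    double s = sig / r;
    double s6 = s * s * s * s * s * s;
    epot += m.eps * (s6 * s6 - 2.0 * s6 + 1.0);
    double dvdr = 12.0 * m.eps * (s6 - s6 * s6) / r;
    double c = -dvdr / r;
    for (int k = 0; k < 3; ++k) {
      f[3 * j + k] += c * d[k];
      f[3 * i + k] -= c * d[k];
    }
  }

  // local chirality: C_i = ((v_i x v_{i+1}) . v_{i+2}) / d0^3
  double d03 = m.d0 * m.d0 * m.d0;
  for (int i = 0; i + 3 < n; ++i) {
    double a[3], b[3], c[3];
    for (int k = 0; k < 3; ++k) {
      a[k] = x[3 * (i + 1) + k] - x[3 * i + k];
      b[k] = x[3 * (i + 2) + k] - x[3 * (i + 1) + k];
      c[k] = x[3 * (i + 3) + k] - x[3 * (i + 2) + k];
    }
    double axb[3], bxc[3], cxa[3];
    cross3(a, b, axb);
    cross3(b, c, bxc);
    cross3(c, a, cxa);
    double S = axb[0] * c[0] + axb[1] * c[1] + axb[2] * c[2];
    double C = S / d03;
    double dC = C - m.chir0[i];
    epot += 0.5 * m.chir_k * dC * dC;
    double g = m.chir_k * dC / d03;   // dV/dS
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] -= g * (-bxc[k]);
      f[3 * (i + 1) + k] -= g * (bxc[k] - cxa[k]);
      f[3 * (i + 2) + k] -= g * (cxa[k] - axb[k]);
      f[3 * (i + 3) + k] -= g * (axb[k]);
    }
  }
  return epot;
}

static void build_neighbor_list(const Model& m, const std::vector<double>& x,
                                double cutoff,
                                std::vector<std::pair<int, int>>& rep_pairs) {
  rep_pairs.clear();
  const int n = m.n;
  double c2 = cutoff * cutoff;
  std::vector<std::vector<bool>> is_contact(n);
  // mark native contacts to exclude them from repulsion
  std::vector<std::pair<int, int>> nat;
  nat.reserve(m.ci.size());
  for (size_t t = 0; t < m.ci.size(); ++t) nat.push_back({m.ci[t], m.cj[t]});
  for (int i = 0; i < n; ++i) {
    for (int j = i + 3; j < n; ++j) {
      double d[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                     x[3 * j + 2] - x[3 * i + 2]};
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < c2) {
        bool native = false;
        for (auto& p : nat)
          if (p.first == i && p.second == j) { native = true; break; }
        if (!native) rep_pairs.push_back({i, j});
      }
    }
  }
}

static Model model_from_list(List ml) {
  Model m;
  NumericMatrix x0 = ml["coords"];
  m.n = x0.nrow();
  m.x.resize(3 * m.n);
  for (int i = 0; i < m.n; ++i)
    for (int k = 0; k < 3; ++k) m.x[3 * i + k] = x0(i, k);
  m.bond_r0 = as<std::vector<double>>(ml["bond_r0"]);
  IntegerVector ci = ml["contact_i"], cj = ml["contact_j"];
  NumericVector cr = ml["contact_r0"];
  for (int t = 0; t < ci.size(); ++t) {
    m.ci.push_back(ci[t] - 1);
    m.cj.push_back(cj[t] - 1);
    m.cr0.push_back(cr[t]);
  }
  m.chir0 = as<std::vector<double>>(ml["chir0"]);
  m.eps = as<double>(ml["eps"]);
  m.bond_k = as<double>(ml["bond_k"]);
  m.chir_k = as<double>(ml["chir_k"]);
  m.rep_sigma = as<double>(ml["rep_sigma"]);
  m.d0 = as<double>(ml["d0"]);
  return m;
}

// [[Rcpp::export]]
double cpp_go_energy(List model, NumericMatrix coords) {
  Model m = model_from_list(model);
  std::vector<double> x(3 * m.n);
  for (int i = 0; i < m.n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  std::vector<std::pair<int, int>> rep;
  build_neighbor_list(m, x, m.rep_sigma, rep);
  std::vector<double> f(3 * m.n);
  return forces(m, x, rep, f);
}

// Langevin dynamics (BAOAB splitting). mode 0 = free dynamics, 1 = pulling.
// Returns trajectory snapshots, energy samples, and (for pulls) the binned
// force-displacement record plus per-contact last-rupture displacements.
// [[Rcpp::export]]
List cpp_go_run(List model, double temperature, double gamma, double dt,
                long n_steps, int seed, int mode,
                double spring_k, double v_pull, double end_fraction,
                double break_factor, int traj_stride, int sample_stride,
                double force_bin) {
  Model m = model_from_list(model);
  const int n = m.n;
  std::vector<double> x = m.x, v(3 * n, 0.0), f(3 * n, 0.0);
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // pulling setup
  double u[3] = {0, 0, 0};
  double anchor0[3], anchor1_0[3];
  double contour = 0.0;
  for (int i = 0; i < n - 1; ++i) contour += m.bond_r0[i];
  if (mode == 1) {
    double e2e = 0.0;
    for (int k = 0; k < 3; ++k) {
      anchor0[k] = x[k];
      anchor1_0[k] = x[3 * (n - 1) + k];
      u[k] = x[3 * (n - 1) + k] - x[k];
      e2e += u[k] * u[k];
    }
    e2e = std::sqrt(e2e);
    for (int k = 0; k < 3; ++k) u[k] /= e2e;
  }

  // thermal start: draw velocities at the target temperature
  if (temperature > 0) {
    double sd = std::sqrt(temperature);
    for (int k = 0; k < 3 * n; ++k) v[k] = sd * gauss(rng);
  }

  const double c1 = std::exp(-gamma * dt);
  const double c2 = (gamma > 0 && temperature > 0)
                        ? std::sqrt((1.0 - c1 * c1) * temperature)
                        : 0.0;

  std::vector<std::pair<int, int>> rep;
  double skin = 2.0;
  build_neighbor_list(m, x, m.rep_sigma + skin, rep);
  int rebuild_every = 40;

  double epot = forces(m, x, rep, f);
  auto add_springs = [&](double t_now) -> double {
    // returns measured force (spring extension along u * spring_k)
    double fmeas = 0.0;
    if (mode == 1) {
      for (int k = 0; k < 3; ++k) {
        f[k] += -spring_k * (x[k] - anchor0[k]);
      }
      double anc[3];
      for (int k = 0; k < 3; ++k) anc[k] = anchor1_0[k] + v_pull * t_now * u[k];
      double dotp = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dxk = anc[k] - x[3 * (n - 1) + k];
        f[3 * (n - 1) + k] += spring_k * dxk;
        dotp += dxk * u[k];
      }
      fmeas = spring_k * dotp;
    }
    return fmeas;
  };
  double fmeas = add_springs(0.0);

  // recorders
  std::vector<double> traj;
  std::vector<double> traj_t;
  std::vector<double> e_samples, ke_samples, t_samples;
  int n_bins = (mode == 1)
                   ? (int)std::ceil((contour + 10.0) / force_bin) + 1
                   : 0;
  std::vector<double> fsum(n_bins, 0.0);
  std::vector<long> fcnt(n_bins, 0);
  std::vector<double> last_break(m.ci.size(), NA_REAL);
  std::vector<bool> above(m.ci.size(), false);
  long steps_done = 0;
  bool diverged = false;
  long diverge_step = -1;

  for (long s = 0; s < n_steps; ++s) {
    double t_now = s * dt;
    // B
    for (int k = 0; k < 3 * n; ++k) v[k] += 0.5 * dt * f[k];
    // A
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    // O
    if (gamma > 0) {
      for (int k = 0; k < 3 * n; ++k) v[k] = c1 * v[k] + c2 * gauss(rng);
    }
    // A
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    // rebuild neighbor list
    if (s % rebuild_every == 0) build_neighbor_list(m, x, m.rep_sigma + skin, rep);
    // B
    epot = forces(m, x, rep, f);
    fmeas = add_springs((s + 1) * dt);
    for (int k = 0; k < 3 * n; ++k) v[k] += 0.5 * dt * f[k];

    steps_done = s + 1;
    if (!std::isfinite(x[0]) || !std::isfinite(x[3 * n - 1])) {
      diverged = true;
      diverge_step = steps_done;
      break;
    }

    if (mode == 1) {
      double d_now = v_pull * (s + 1) * dt;
      int b = (int)(d_now / force_bin);
      if (b >= 0 && b < n_bins) {
        fsum[b] += fmeas;
        fcnt[b] += 1;
      }
      if (s % 20 == 0) {
        for (size_t t = 0; t < m.ci.size(); ++t) {
          int i = m.ci[t], j = m.cj[t];
          double dd = 0.0;
          for (int k = 0; k < 3; ++k) {
            double dk = x[3 * j + k] - x[3 * i + k];
            dd += dk * dk;
          }
          bool now_above = std::sqrt(dd) > break_factor * m.cr0[t];
          if (now_above && !above[t]) last_break[t] = d_now;
          above[t] = now_above;
        }
      }
      // termination: extension reaches end_fraction of contour length
      double ext = 0.0;
      for (int k = 0; k < 3; ++k)
        ext += (x[3 * (n - 1) + k] - x[k]) * u[k];
      if (ext >= end_fraction * contour) break;
    }

    if (traj_stride > 0 && s % traj_stride == 0) {
      for (int k = 0; k < 3 * n; ++k) traj.push_back(x[k]);
      traj_t.push_back((s + 1) * dt);
    }
    if (sample_stride > 0 && s % sample_stride == 0) {
      double ke = 0.0;
      for (int k = 0; k < 3 * n; ++k) ke += 0.5 * v[k] * v[k];
      e_samples.push_back(epot + ke);
      ke_samples.push_back(ke);
      t_samples.push_back((s + 1) * dt);
    }
  }

  NumericMatrix final_x(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) final_x(i, k) = x[3 * i + k];

  List out = List::create(
      _["final_coords"] = final_x, _["steps_done"] = (double)steps_done,
      _["diverged"] = diverged, _["diverge_step"] = (double)diverge_step,
      _["traj"] = traj, _["traj_t"] = traj_t, _["energy"] = e_samples,
      _["kinetic"] = ke_samples, _["sample_t"] = t_samples,
      _["contour"] = contour);
  if (mode == 1) {
    out["force_sum"] = fsum;
    out["force_cnt"] = fcnt;
    out["force_bin"] = force_bin;
    out["last_break"] = last_break;
  }
  return out;
}
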