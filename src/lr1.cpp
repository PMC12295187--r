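// Core numerical kernels: Luo-Rudy 1991 ionic model with the Mahajan fast
// transient-outward current, Rush-Larsen gate integration, explicit
// finite-difference monodomain solver (1D cable, 2D sheet, conservative
// no-flux boundaries), cross-field spiral induction, phase-singularity detection and
// pseudo-ECG sampling.
//
// State vector layout (length 10): V, m, h, j, d, f, x, xtof, ytof, Cai.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const int NSTATE = 10;
static const int G_M = 0, G_H = 1, G_J = 2, G_D = 3, G_F = 4, G_X = 5,
                 G_XTOF = 6, G_YTOF = 7;

struct Params {
  double Cm, GNa, Gsi, GK, GK1, GKp, Gb, Gtof, kd, kf;
  double ENa, EK, EK1, EKp, Eb, Etof;
};

static Params as_params(const List& p) {
  Params q;
  q.Cm = p["Cm"];   q.GNa = p["GNa"]; q.Gsi = p["Gsi"]; q.GK = p["GK"];
  q.GK1 = p["GK1"]; q.GKp = p["GKp"]; q.Gb = p["Gb"];   q.Gtof = p["Gtof"];
  q.kd = p["kd"];   q.kf = p["kf"];
  q.ENa = p["ENa"]; q.EK = p["EK"];   q.EK1 = p["EK1"]; q.EKp = p["EKp"];
  q.Eb = p["Eb"];   q.Etof = p["Etof"];
  if (q.Cm <= 0) stop("Cm must be positive");
  return q;
}

// ---------------------------------------------------------------------------
// Gate kinetics.  m,h,j,d,f,x follow LR1 alpha/beta rate functions; xtof,ytof
// follow the Mahajan Ito,f formulation (steady state + time constant).
// kd, kf multiply tau_d and tau_f only.
// ---------------------------------------------------------------------------
static void gate_rate(int g, double V, double kd, double kf,
                      double* yinf, double* tau) {
  double a, b;
  switch (g) {
  case G_M: {
    double dv = V + 47.13;
    a = std::fabs(dv) < 1e-7 ? 3.2 : 0.32 * dv / (1.0 - std::exp(-0.1 * dv));
    b = 0.08 * std::exp(-V / 11.0);
    *yinf = a / (a + b); *tau = 1.0 / (a + b); break;
  }
  case G_H: {
    if (V >= -40.0) {
      a = 0.0;
      b = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / (-11.1))));
    } else {
      a = 0.135 * std::exp((80.0 + V) / (-6.8));
      b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    }
    *yinf = a / (a + b); *tau = 1.0 / (a + b); break;
  }
  case G_J: {
    if (V >= -40.0) {
      a = 0.0;
      b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
          * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    *yinf = a / (a + b); *tau = 1.0 / (a + b); break;
  }
  case G_D: {
    a = 0.095 * std::exp(-0.01 * (V - 5.0)) / (1.0 + std::exp(-0.072 * (V - 5.0)));
    b = 0.07 * std::exp(-0.017 * (V + 44.0)) / (1.0 + std::exp(0.05 * (V + 44.0)));
    *yinf = a / (a + b); *tau = kd / (a + b); break;
  }
  case G_F: {
    a = 0.012 * std::exp(-0.008 * (V + 28.0)) / (1.0 + std::exp(0.15 * (V + 28.0)));
    b = 0.0065 * std::exp(-0.02 * (V + 30.0)) / (1.0 + std::exp(-0.2 * (V + 30.0)));
    *yinf = a / (a + b); *tau = kf / (a + b); break;
  }
  case G_X: {
    a = 0.0005 * std::exp(0.083 * (V + 50.0)) / (1.0 + std::exp(0.057 * (V + 50.0)));
    b = 0.0013 * std::exp(-0.06 * (V + 20.0)) / (1.0 + std::exp(-0.04 * (V + 20.0)));
    *yinf = a / (a + b); *tau = 1.0 / (a + b); break;
  }
  case G_XTOF: {
    *yinf = 1.0 / (1.0 + std::exp(-(V + 3.0) / 15.0));
    *tau = 3.5 * std::exp(-(V / 30.0) * (V / 30.0)) + 1.5; break;
  }
  case G_YTOF: {
    *yinf = 1.0 / (1.0 + std::exp((V + 33.5) / 10.0));
    *tau = 20.0 / (1.0 + std::exp((V + 33.5) / 10.0)) + 20.0; break;
  }
  default: stop("unknown gate index");
  }
}

// IK time-independent rectification factor (Xi of LR1)
static inline double xi_of(double V) {
  if (V <= -100.0) return 1.0;
  double dv = V + 77.0;
  if (std::fabs(dv) < 1e-7)
    return 2.837 * 0.04 / std::exp(0.04 * (V + 35.0));
  return 2.837 * (std::exp(0.04 * dv) - 1.0) / (dv * std::exp(0.04 * (V + 35.0)));
}

static inline double k1inf_of(double V, double EK1) {
  double a = 1.02 / (1.0 + std::exp(0.2385 * (V - EK1 - 59.215)));
  double b = (0.49124 * std::exp(0.08032 * (V - EK1 + 5.476))
              + std::exp(0.06175 * (V - EK1 - 594.31)))
             / (1.0 + std::exp(-0.5143 * (V - EK1 + 4.753)));
  return a / (a + b);
}

static inline double kp_of(double V) {
  return 1.0 / (1.0 + std::exp((7.488 - V) / 5.98));
}

static inline double esi_of(double Cai) {
  return 7.7 - 13.0287 * std::log(Cai);
}

// out: INa, ISi, IK, IK1, IKp, Ib, Itof, Iion, ESi
static void currents_of(const double* s, const Params& p, double* out) {
  double V = s[0];
  double esi = esi_of(s[9]);
  out[0] = p.GNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - p.ENa);
  out[1] = p.Gsi * s[4] * s[5] * (V - esi);
  out[2] = p.GK * s[6] * xi_of(V) * (V - p.EK);
  out[3] = p.GK1 * k1inf_of(V, p.EK1) * (V - p.EK1);
  out[4] = p.GKp * kp_of(V) * (V - p.EKp);
  out[5] = p.Gb * (V - p.Eb);
  out[6] = p.Gtof * s[7] * s[8] * (V - p.Etof);
  out[7] = out[0] + out[1] + out[2] + out[3] + out[4] + out[5] + out[6];
  out[8] = esi;
}

// Exact (table-free) single step: forward Euler on V and Cai, Rush-Larsen on
// gates, all rates evaluated at the pre-step voltage.  Returns false on
// numerical blow-up.
static inline bool step_exact(double* s, double Istim, double dt, const Params& p) {
  double cur[9];
  currents_of(s, p, cur);
  double V0 = s[0];
  for (int g = 0; g < 8; ++g) {
    double yinf, tau;
    gate_rate(g, V0, p.kd, p.kf, &yinf, &tau);
    s[1 + g] = yinf + (s[1 + g] - yinf) * std::exp(-dt / tau);
  }
  s[9] += dt * (-1e-4 * cur[1] + 0.07 * (1e-4 - s[9]));
  s[0] += dt * (-(cur[7] - Istim) / p.Cm);
  return std::isfinite(s[0]) && s[9] > 0.0 && std::fabs(s[0]) < 300.0;
}

// ---------------------------------------------------------------------------
// Voltage-indexed lookup tables (fixed dt): per row the 8 gate steady states,
// the 8 Rush-Larsen factors exp(-dt/tau), and the voltage-only current
// factors.  Linear interpolation in V.
// ---------------------------------------------------------------------------
static const int TW = 20;  // row width

struct Tables {
  double Vmin, Vmax, dv, inv_dv, dt, Cm, Gsi;
  int n;
  std::vector<double> t;
};

static void build_tables(Tables& T, const Params& p, double dt) {
  T.Vmin = -130.0; T.Vmax = 100.0; T.dv = 0.02;
  T.inv_dv = 1.0 / T.dv;
  T.dt = dt; T.Cm = p.Cm; T.Gsi = p.Gsi;
  T.n = (int)std::floor((T.Vmax - T.Vmin) / T.dv) + 2;
  T.t.resize((size_t)T.n * TW);
  for (int iv = 0; iv < T.n; ++iv) {
    double V = T.Vmin + iv * T.dv;
    double* r = &T.t[(size_t)iv * TW];
    for (int g = 0; g < 8; ++g) {
      double yinf, tau;
      gate_rate(g, V, p.kd, p.kf, &yinf, &tau);
      r[g] = yinf;
      r[8 + g] = std::exp(-dt / tau);
    }
    r[16] = p.GNa * (V - p.ENa);
    r[17] = p.GK * xi_of(V) * (V - p.EK);
    r[18] = p.GK1 * k1inf_of(V, p.EK1) * (V - p.EK1)
          + p.GKp * kp_of(V) * (V - p.EKp)
          + p.Gb * (V - p.Eb);
    r[19] = p.Gtof * (V - p.Etof);
  }
}

// Ionic step for one site: returns Iion evaluated at the pre-step state and
// advances gates and Cai in place.  Caller updates V.
static inline double site_ionic(const Tables& T, double V, double* g8, double* Cai) {
  double x = (V - T.Vmin) * T.inv_dv;
  if (x < 0.0) x = 0.0;
  double xmax = (double)(T.n - 2);
  if (x > xmax) x = xmax;
  int i0 = (int)x;
  double w = x - i0;
  const double* r0 = &T.t[(size_t)i0 * TW];
  const double* r1 = r0 + TW;
  double m3hj = g8[0] * g8[0] * g8[0] * g8[1] * g8[2];
  double cNa = r0[16] + w * (r1[16] - r0[16]);
  double cKx = r0[17] + w * (r1[17] - r0[17]);
  double cKo = r0[18] + w * (r1[18] - r0[18]);
  double cTo = r0[19] + w * (r1[19] - r0[19]);
  double ISi = T.Gsi * g8[3] * g8[4] * (V - 7.7 + 13.0287 * std::log(*Cai));
  double Iion = cNa * m3hj + ISi + cKx * g8[5] + cKo + cTo * g8[6] * g8[7];
  for (int k = 0; k < 8; ++k) {
    double yinf = r0[k] + w * (r1[k] - r0[k]);
    double rl = r0[8 + k] + w * (r1[8 + k] - r0[8 + k]);
    double dy = (g8[k] - yinf) * rl;
    // quiescent sites decay geometrically toward y_inf; snap before the
    // difference underflows into (slow) denormal arithmetic
    g8[k] = (dy > 1e-24 || dy < -1e-24) ? yinf + dy : yinf;
  }
  *Cai += T.dt * (-1e-4 * ISi + 0.07 * (1e-4 - *Cai));
  return Iion;
}

// ---------------------------------------------------------------------------
// Exported: gate kinetics and current breakdown
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cw_gate_kinetics(double V, double kd, double kf) {
  if (!std::isfinite(V)) stop("V must be finite");
  NumericMatrix out(8, 2);
  for (int g = 0; g < 8; ++g) {
    double yinf, tau;
    gate_rate(g, V, kd, kf, &yinf, &tau);
    out(g, 0) = yinf;
    out(g, 1) = tau;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cw_currents(NumericVector state, List params) {
  if (state.size() != NSTATE) stop("state must have length 10");
  if (state[9] <= 0) stop("Cai must be positive");
  Params p = as_params(params);
  double out[9];
  currents_of(REAL(state), p, out);
  NumericVector r(9);
  for (int i = 0; i < 9; ++i) r[i] = out[i];
  r.attr("names") = CharacterVector::create("INa", "ISi", "IK", "IK1", "IKp",
                                            "Ib", "Itof", "Iion", "ESi");
  return r;
}

// [[Rcpp::export]]
NumericVector cw_cell_step(NumericVector state, double Istim, double dt, List params) {
  if (state.size() != NSTATE) stop("state must have length 10");
  if (dt <= 0) stop("dt must be positive");
  Params p = as_params(params);
  NumericVector s = clone(state);
  if (!step_exact(REAL(s), Istim, dt, p))
    stop("numerical blow-up in cell step");
  return s;
}

// ---------------------------------------------------------------------------
// Single-cell run with a train of rectangular stimulus pulses.
// stim_onsets must be sorted ascending.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cw_cell_run(NumericVector state, List params, double dt, double t_total,
                 NumericVector stim_onsets, double stim_amp, double stim_dur,
                 double record_dt, bool use_tables) {
  if (state.size() != NSTATE) stop("state must have length 10");
  if (dt <= 0 || t_total <= 0) stop("dt and t_total must be positive");
  Params p = as_params(params);
  Tables T;
  if (use_tables) build_tables(T, p, dt);

  double s[NSTATE];
  std::memcpy(s, REAL(state), sizeof(s));

  long nsteps = (long)std::llround(t_total / dt);
  long rec_every = record_dt > 0 ? (long)std::llround(record_dt / dt) : 0;
  std::vector<double> rec_t, rec_v, rec_cai;
  if (rec_every > 0) {
    rec_t.reserve(nsteps / rec_every + 2);
    rec_v.reserve(nsteps / rec_every + 2);
    rec_cai.reserve(nsteps / rec_every + 2);
  }

  int k = 0, nstim = stim_onsets.size();
  bool blowup = false;
  long step = 0;
  for (; step < nsteps; ++step) {
    double t = step * dt;
    if (rec_every > 0 && step % rec_every == 0) {
      rec_t.push_back(t); rec_v.push_back(s[0]); rec_cai.push_back(s[9]);
    }
    while (k < nstim && t >= stim_onsets[k] + stim_dur) ++k;
    double Istim = (k < nstim && t >= stim_onsets[k]) ? stim_amp : 0.0;
    bool ok;
    if (use_tables) {
      double Iion = site_ionic(T, s[0], s + 1, s + 9);
      s[0] += dt * (-(Iion - Istim) / p.Cm);
      ok = std::isfinite(s[0]) && s[9] > 0 && std::fabs(s[0]) < 300.0;
    } else {
      ok = step_exact(s, Istim, dt, p);
    }
    if (!ok) { blowup = true; break; }
  }
  if (rec_every > 0 && !blowup) {
    rec_t.push_back(nsteps * dt); rec_v.push_back(s[0]); rec_cai.push_back(s[9]);
  }

  NumericVector fs(NSTATE);
  for (int i = 0; i < NSTATE; ++i) fs[i] = s[i];
  List out = List::create(
    _["final_state"] = fs,
    _["blowup"] = blowup,
    _["t_blowup"] = blowup ? (double)(step * dt) : NA_REAL);
  if (rec_every > 0) {
    out["t"] = NumericVector(rec_t.begin(), rec_t.end());
    out["V"] = NumericVector(rec_v.begin(), rec_v.end());
    out["Cai"] = NumericVector(rec_cai.begin(), rec_cai.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// 1D cable: explicit diffusion with conservative no-flux boundaries.
// Stimulus applied to sites 0..stim_sites-1 during [0, stim_dur).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cw_cable_run(NumericVector state, int n, double dx, double D, List params,
                  double dt, double t_total, int stim_sites, double stim_amp,
                  double stim_dur, IntegerVector record_sites, double record_dt) {
  if (state.size() != NSTATE) stop("state must have length 10");
  if (n < 3) stop("cable needs at least 3 sites");
  if (D > 0 && dt >= dx * dx / (4.0 * D))
    stop("dt violates the explicit diffusion stability bound dx^2/(4D)");
  Params p = as_params(params);
  Tables T;
  build_tables(T, p, dt);

  std::vector<double> V(n), Vnew(n), Cai(n), G((size_t)n * 8);
  for (int i = 0; i < n; ++i) {
    V[i] = state[0];
    Cai[i] = state[9];
    for (int g = 0; g < 8; ++g) G[(size_t)i * 8 + g] = state[1 + g];
  }

  long nsteps = (long)std::llround(t_total / dt);
  long rec_every = (long)std::llround(record_dt / dt);
  if (rec_every < 1) rec_every = 1;
  int nrec = (int)(nsteps / rec_every) + 1;
  int ns = record_sites.size();
  NumericMatrix traces(nrec, ns);
  NumericVector trace_t(nrec);
  int irec = 0;
  double idx2 = D / (dx * dx);
  bool blowup = false;

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    if (step % rec_every == 0 && irec < nrec) {
      trace_t[irec] = t;
      for (int q = 0; q < ns; ++q) traces(irec, q) = V[record_sites[q] - 1];
      ++irec;
    }
    double Istim = (t < stim_dur) ? stim_amp : 0.0;
    for (int i = 0; i < n; ++i) {
      double Vl = V[i > 0 ? i - 1 : 0];
      double Vr = V[i < n - 1 ? i + 1 : n - 1];
      double lap = (Vl + Vr - 2.0 * V[i]) * idx2;
      double Iion = site_ionic(T, V[i], &G[(size_t)i * 8], &Cai[i]);
      double Is = (i < stim_sites) ? Istim : 0.0;
      Vnew[i] = V[i] + dt * (lap - (Iion - Is) / p.Cm);
    }
    std::swap(V, Vnew);
    if (step % 1000 == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]) || std::fabs(V[i]) > 300.0) { blowup = true; break; }
      if (blowup) break;
    }
  }

  NumericVector vfin(V.begin(), V.end());
  return List::create(
    _["t"] = trace_t[Range(0, std::max(irec - 1, 0))],
    _["traces"] = traces(Range(0, std::max(irec - 1, 0)), _),
    _["V_final"] = vfin,
    _["blowup"] = blowup);
}

// ---------------------------------------------------------------------------
// Phase-singularity detection by time-delay embedding:
// phase = atan2(Vlag - Vstar, Vnow - Vstar); a tip sits on any elementary
// plaquette whose summed (wrapped) phase differences wind by +-2*pi.
// Returns triples (x, y, chirality) in 0-based grid units at plaquette centers.
// ---------------------------------------------------------------------------
static int detect_tips_core(const double* Vn, const double* Vl, int ny, int nx,
                            double vstar, std::vector<double>& out, int max_tips) {
  std::vector<double> ph((size_t)ny * nx);
  for (size_t q = 0; q < (size_t)ny * nx; ++q)
    ph[q] = std::atan2(Vl[q] - vstar, Vn[q] - vstar);
  int count = 0;
  for (int j = 0; j < nx - 1; ++j) {
    for (int i = 0; i < ny - 1; ++i) {
      double p00 = ph[i + (size_t)ny * j];
      double p01 = ph[i + (size_t)ny * (j + 1)];
      double p11 = ph[i + 1 + (size_t)ny * (j + 1)];
      double p10 = ph[i + 1 + (size_t)ny * j];
      double s = std::remainder(p01 - p00, 2.0 * M_PI)
               + std::remainder(p11 - p01, 2.0 * M_PI)
               + std::remainder(p10 - p11, 2.0 * M_PI)
               + std::remainder(p00 - p10, 2.0 * M_PI);
      if (std::fabs(s) > M_PI) {
        ++count;
        if ((int)(out.size() / 3) < max_tips) {
          out.push_back(j + 0.5);
          out.push_back(i + 0.5);
          out.push_back(s > 0 ? 1.0 : -1.0);
        }
      }
    }
  }
  return count;
}

// [[Rcpp::export]]
NumericMatrix cw_detect_tips(NumericMatrix Vnow, NumericMatrix Vlag, double vstar) {
  if (Vnow.nrow() != Vlag.nrow() || Vnow.ncol() != Vlag.ncol())
    stop("field shapes differ");
  std::vector<double> out;
  detect_tips_core(REAL(Vnow), REAL(Vlag), Vnow.nrow(), Vnow.ncol(), vstar,
                   out, 100000);
  int k = out.size() / 3;
  NumericMatrix m(k, 3);
  for (int i = 0; i < k; ++i) {
    m(i, 0) = out[3 * i]; m(i, 1) = out[3 * i + 1]; m(i, 2) = out[3 * i + 2];
  }
  colnames(m) = CharacterVector::create("x", "y", "chirality");
  return m;
}

// ---------------------------------------------------------------------------
// Pseudo-ECG: phi = sum_sites grad(V) . grad(1/|r_site - r_probe|) dA.
// Site (row i, col j) sits at (x = j*dx, y = i*dx, z = 0).
// ---------------------------------------------------------------------------
static void ecg_kernel(int ny, int nx, double dx, double px, double py, double pz,
                       std::vector<double>& gx, std::vector<double>& gy) {
  gx.resize((size_t)ny * nx);
  gy.resize((size_t)ny * nx);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double sx = j * dx, sy = i * dx;
      double rx = sx - px, ry = sy - py, rz = -pz;
      double r = std::sqrt(rx * rx + ry * ry + rz * rz);
      if (r < 1e-9) stop("probe coincides with a lattice site");
      double r3 = r * r * r;
      gx[i + (size_t)ny * j] = -rx / r3;
      gy[i + (size_t)ny * j] = -ry / r3;
    }
  }
}

static double ecg_eval(const double* V, int ny, int nx, double dx,
                       const std::vector<double>& gx, const std::vector<double>& gy) {
  double acc = 0.0;
  double i2dx = 1.0 / (2.0 * dx);
  for (int j = 0; j < nx; ++j) {
    int jl = j > 0 ? j - 1 : 0;
    int jr = j < nx - 1 ? j + 1 : nx - 1;
    for (int i = 0; i < ny; ++i) {
      int il = i > 0 ? i - 1 : 0;
      int ir = i < ny - 1 ? i + 1 : ny - 1;
      double dvdx = (V[i + (size_t)ny * jr] - V[i + (size_t)ny * jl]) * i2dx;
      double dvdy = (V[ir + (size_t)ny * j] - V[il + (size_t)ny * j]) * i2dx;
      size_t q = i + (size_t)ny * j;
      acc += dvdx * gx[q] + dvdy * gy[q];
    }
  }
  return acc * dx * dx;
}

// [[Rcpp::export]]
double cw_ecg_sample(NumericMatrix V, double dx, NumericVector probe) {
  if (probe.size() != 3) stop("probe must be (x, y, z)");
  std::vector<double> gx, gy;
  ecg_kernel(V.nrow(), V.ncol(), dx, probe[0], probe[1], probe[2], gx, gy);
  return ecg_eval(REAL(V), V.nrow(), V.ncol(), dx, gx, gy);
}

// ---------------------------------------------------------------------------
// Single explicit tissue step on an R-level field (list of 10 ny-x-nx
// matrices).  Exact (table-free) ionic path; optional diffusion-only mode
// and stimulus matrix.  Used by the step-level API and the solver tests.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cw_tissue_step(List field, List params, double dt, double D, double dx,
                    Nullable<NumericMatrix> stim, bool diffusion_only) {
  Params p = as_params(params);
  CharacterVector nm = CharacterVector::create("V", "m", "h", "j", "d", "f",
                                               "x", "xtof", "ytof", "Cai");
  NumericMatrix F[NSTATE];
  for (int q = 0; q < NSTATE; ++q) F[q] = as<NumericMatrix>(field[std::string(nm[q])]);
  int ny = F[0].nrow(), nx = F[0].ncol();
  if (D > 0 && dt >= dx * dx / (4.0 * D))
    stop("dt violates the explicit diffusion stability bound dx^2/(4D)");
  NumericMatrix S(ny, nx);
  bool has_stim = stim.isNotNull();
  if (has_stim) S = NumericMatrix(stim);

  List out(NSTATE);
  NumericMatrix O[NSTATE];
  for (int q = 0; q < NSTATE; ++q) O[q] = NumericMatrix(ny, nx);

  const double* V = REAL(F[0]);
  double idx2 = D / (dx * dx);
  for (int j = 0; j < nx; ++j) {
    int jl = j > 0 ? j - 1 : 0;
    int jr = j < nx - 1 ? j + 1 : nx - 1;
    for (int i = 0; i < ny; ++i) {
      int il = i > 0 ? i - 1 : 0;
      int ir = i < ny - 1 ? i + 1 : ny - 1;
      size_t q0 = i + (size_t)ny * j;
      double lap = (V[i + (size_t)ny * jl] + V[i + (size_t)ny * jr]
                  + V[il + (size_t)ny * j] + V[ir + (size_t)ny * j]
                  - 4.0 * V[q0]) * idx2;
      double s[NSTATE];
      for (int q = 0; q < NSTATE; ++q) s[q] = F[q][q0];
      double Istim = has_stim ? S[q0] : 0.0;
      if (diffusion_only) {
        s[0] += dt * lap;
      } else {
        double cur[9];
        currents_of(s, p, cur);
        double V0 = s[0];
        for (int g = 0; g < 8; ++g) {
          double yinf, tau;
          gate_rate(g, V0, p.kd, p.kf, &yinf, &tau);
          s[1 + g] = yinf + (s[1 + g] - yinf) * std::exp(-dt / tau);
        }
        s[9] += dt * (-1e-4 * cur[1] + 0.07 * (1e-4 - s[9]));
        s[0] += dt * (lap - (cur[7] - Istim) / p.Cm);
      }
      for (int q = 0; q < NSTATE; ++q) O[q][q0] = s[q];
    }
  }
  for (int q = 0; q < NSTATE; ++q) out[q] = O[q];
  out.attr("names") = nm;
  return out;
}

// ---------------------------------------------------------------------------
// Full 2D run: uniform pre-paced initial state, left-edge plane-wave pacing,
// optional cross-field clamp triggered by the center cell (depolarize above
// then fall below trigger_level; then the bottom half of the sheet is held at
// clamp_v for clamp_dur ms), tip counting, pseudo-ECG sampling, site traces
// and voltage snapshots.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cw_tissue_run(NumericVector state, int nx, int ny, double dx, double D,
                   List params, double dt, double t_total,
                   int stim_cols, double stim_amp, double stim_dur,
                   bool cross_field, double trigger_level, double clamp_v,
                   double clamp_dur, double trigger_timeout,
                   double frame_dt, double lag_ms, double vstar,
                   NumericMatrix probes, double ecg_dt,
                   IntegerVector trace_sites, double trace_dt,
                   NumericVector snapshot_times, int max_tips_store) {
  if (state.size() != NSTATE) stop("state must have length 10");
  if (nx < 3 || ny < 3) stop("grid too small");
  if (D > 0 && dt >= dx * dx / (4.0 * D))
    stop("dt violates the explicit diffusion stability bound dx^2/(4D)");
  Params p = as_params(params);
  Tables T;
  build_tables(T, p, dt);

  size_t N = (size_t)nx * ny;
  std::vector<double> V(N), Vnew(N), Cai(N), G(N * 8), Vlag;
  for (size_t q = 0; q < N; ++q) {
    V[q] = state[0];
    Cai[q] = state[9];
    for (int g = 0; g < 8; ++g) G[q * 8 + g] = state[1 + g];
  }

  long nsteps = (long)std::llround(t_total / dt);
  long frame_every = (long)std::llround(frame_dt / dt);
  long lag_steps = (long)std::llround(lag_ms / dt);
  long ecg_every = ecg_dt > 0 ? (long)std::llround(ecg_dt / dt) : 0;
  long trace_every = trace_dt > 0 ? (long)std::llround(trace_dt / dt) : 0;

  // pseudo-ECG kernels
  int np = probes.nrow();
  std::vector<std::vector<double> > gx(np), gy(np);
  for (int k = 0; k < np; ++k)
    ecg_kernel(ny, nx, dx, probes(k, 0), probes(k, 1), probes(k, 2), gx[k], gy[k]);
  std::vector<double> ecg_t;
  std::vector<std::vector<double> > ecg_v(np);

  // traces
  int nts = trace_sites.size();
  std::vector<double> tr_t;
  std::vector<std::vector<double> > tr_v(nts);

  // tips
  std::vector<double> tip_t;
  std::vector<int> tip_n;
  List tip_xy_all;
  std::vector<NumericMatrix> tip_frames;

  // snapshots
  int nsnap = snapshot_times.size();
  std::vector<long> snap_steps(nsnap);
  for (int k = 0; k < nsnap; ++k)
    snap_steps[k] = (long)std::llround(snapshot_times[k] / dt);
  List snaps(nsnap);
  NumericVector snap_t(nsnap);
  int isnap = 0;

  // protocol state machine
  size_t center = (size_t)(ny / 2) + (size_t)ny * (nx / 2);
  bool seen_up = false, seen_down = false, clamping = false, clamp_done = false;
  double t_up = NA_REAL, t_down = NA_REAL, t_clamp_on = NA_REAL, t_clamp_off = NA_REAL;
  long clamp_end_step = -1;
  int half_row = ny / 2;

  Vlag.assign(N, state[0]);
  long next_frame = frame_every;
  bool blowup = false;
  double t_blow = NA_REAL;
  double idx2 = D / (dx * dx);

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;

    // stash the lagged field ahead of each analysis frame
    if (step == next_frame - lag_steps) std::memcpy(Vlag.data(), V.data(), N * sizeof(double));

    double Istim = (t < stim_dur) ? stim_amp : 0.0;
    bool stim_on = Istim != 0.0 && stim_cols > 0;

    for (int j = 0; j < nx; ++j) {
      int jl = j > 0 ? j - 1 : 0;
      int jr = j < nx - 1 ? j + 1 : nx - 1;
      const double* Vcl = &V[(size_t)ny * jl];
      const double* Vcr = &V[(size_t)ny * jr];
      const double* Vc = &V[(size_t)ny * j];
      double* Vo = &Vnew[(size_t)ny * j];
      double Is = (stim_on && j < stim_cols) ? Istim : 0.0;
      for (int i = 0; i < ny; ++i) {
        int il = i > 0 ? i - 1 : 0;
        int ir = i < ny - 1 ? i + 1 : ny - 1;
        double lap = (Vcl[i] + Vcr[i] + Vc[il] + Vc[ir] - 4.0 * Vc[i]) * idx2;
        size_t q = i + (size_t)ny * j;
        double Iion = site_ionic(T, Vc[i], &G[q * 8], &Cai[q]);
        Vo[i] = Vc[i] + dt * (lap - (Iion - Is) / p.Cm);
      }
    }
    std::swap(V, Vnew);

    // cross-field state machine (post-update voltages)
    if (cross_field && !clamp_done) {
      if (clamping) {
        for (int j = 0; j < nx; ++j)
          for (int i = half_row; i < ny; ++i) V[i + (size_t)ny * j] = clamp_v;
        if (step + 1 >= clamp_end_step) {
          clamping = false; clamp_done = true;
          t_clamp_off = (step + 1) * dt;
        }
      } else {
        double vc = V[center];
        if (!seen_up && vc > trigger_level) { seen_up = true; t_up = t; }
        else if (seen_up && !seen_down && vc < trigger_level) {
          seen_down = true; t_down = t;
          clamping = true;
          t_clamp_on = t;
          clamp_end_step = step + 1 + (long)std::llround(clamp_dur / dt);
          for (int j = 0; j < nx; ++j)
            for (int i = half_row; i < ny; ++i) V[i + (size_t)ny * j] = clamp_v;
        }
        if (!seen_down && t > trigger_timeout) {
          return List::create(_["error"] = "no plane wave detected",
                              _["t"] = t);
        }
      }
    }

    double tpost = (step + 1) * dt;

    if (trace_every > 0 && (step + 1) % trace_every == 0) {
      tr_t.push_back(tpost);
      for (int q = 0; q < nts; ++q) tr_v[q].push_back(V[trace_sites[q] - 1]);
    }
    if (ecg_every > 0 && (step + 1) % ecg_every == 0) {
      ecg_t.push_back(tpost);
      for (int k = 0; k < np; ++k)
        ecg_v[k].push_back(ecg_eval(V.data(), ny, nx, dx, gx[k], gy[k]));
    }
    if (step + 1 == next_frame) {
      // blow-up scan piggybacks on the analysis frame
      for (size_t q = 0; q < N; ++q)
        if (!std::isfinite(V[q]) || std::fabs(V[q]) > 300.0) { blowup = true; break; }
      if (blowup) { t_blow = tpost; break; }
      std::vector<double> tips;
      int cnt = detect_tips_core(V.data(), Vlag.data(), ny, nx, vstar, tips,
                                 max_tips_store);
      tip_t.push_back(tpost);
      tip_n.push_back(cnt);
      int k = tips.size() / 3;
      NumericMatrix m(k, 3);
      for (int z = 0; z < k; ++z) {
        m(z, 0) = tips[3 * z]; m(z, 1) = tips[3 * z + 1]; m(z, 2) = tips[3 * z + 2];
      }
      tip_frames.push_back(m);
      next_frame += frame_every;
    }
    if (isnap < nsnap && step + 1 == snap_steps[isnap]) {
      NumericMatrix sv(ny, nx);
      std::memcpy(REAL(sv), V.data(), N * sizeof(double));
      snaps[isnap] = sv;
      snap_t[isnap] = tpost;
      ++isnap;
    }
  }

  int nf = tip_frames.size();
  List tip_xy(nf);
  for (int z = 0; z < nf; ++z) tip_xy[z] = tip_frames[z];

  NumericMatrix ecg_m(ecg_t.size(), np);
  for (int k = 0; k < np; ++k)
    for (size_t z = 0; z < ecg_t.size(); ++z) ecg_m(z, k) = ecg_v[k][z];

  NumericMatrix tr_m(tr_t.size(), nts);
  for (int q = 0; q < nts; ++q)
    for (size_t z = 0; z < tr_t.size(); ++z) tr_m(z, q) = tr_v[q][z];

  NumericMatrix vfin(ny, nx);
  std::memcpy(REAL(vfin), V.data(), N * sizeof(double));

  return List::create(
    _["events"] = List::create(_["t_trigger_up"] = t_up, _["t_trigger_down"] = t_down,
                               _["t_clamp_on"] = t_clamp_on, _["t_clamp_off"] = t_clamp_off),
    _["tip_t"] = NumericVector(tip_t.begin(), tip_t.end()),
    _["tip_count"] = IntegerVector(tip_n.begin(), tip_n.end()),
    _["tip_xy"] = tip_xy,
    _["ecg_t"] = NumericVector(ecg_t.begin(), ecg_t.end()),
    _["ecg"] = ecg_m,
    _["trace_t"] = NumericVector(tr_t.begin(), tr_t.end()),
    _["traces"] = tr_m,
    _["snapshot_t"] = snap_t,
    _["snapshots"] = snaps,
    _["V_final"] = vfin,
    _["blowup"] = blowup,
    _["t_blowup"] = t_blow);
}
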