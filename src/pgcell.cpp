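// Compartmental Hodgkin-Huxley core for the periglomerular cell model.
//
// Channel kinetics are evaluated here (single source of truth, also exposed
// to R through cpp_gating_curves) and the coupled voltage/gating/calcium
// system is advanced with a Crank-Nicolson voltage update, staggered
// exponential-Euler gating, and a Hines-ordered tree solve for the axial
// coupling.  Units: mV, ms, S/cm2, mA/cm2, uF/cm2, mM, pA for injections.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// channel indices (order shared with R/channels.R)
enum Chan { cNA = 0, cK = 1, cKA = 2, cKCA = 3, cH = 4, cCAL = 5, cCAT = 6,
            cCAN = 7, NCHAN = 8 };

static const int    CH_A[NCHAN]    = { 3, 4, 1, 2, 1, 2, 2, 2 };
static const int    CH_B[NCHAN]    = { 1, 0, 1, 0, 0, 1, 1, 0 };
static const double CH_PHIM[NCHAN] = { 0.24, 0.24, 0.46, 1.12, 0.35, 1.00, 0.85, 1.12 };
static const double CH_PHIH[NCHAN] = { 0.24, 0.00, 0.46, 0.00, 0.00, 1.00, 0.90, 0.00 };

static const double FARADAY  = 96485.33212;  // C/mol
static const double GAS_CONST = 8.31446262;  // J/(mol K)

// x / (1 - exp(-x/k)) with the removable singularity at x = 0 handled by a
// guarded series branch (|x/k| < 1e-7); the limit is k.
static inline double vtrap(double x, double k) {
  double u = x / k;
  if (std::fabs(u) < 1e-7) return k * (1.0 + 0.5 * u + u * u / 12.0);
  return x / (1.0 - std::exp(-u));
}

struct Curves {
  double minf, taum, hinf, tauh;
  bool has_h;       // channel carries an inactivation gate
  bool h_instant;   // inactivation set algebraically (Ca(L))
};

static inline Curves chan_curves(int ch, double v, double ca) {
  Curves c;
  c.has_h = (CH_B[ch] > 0);
  c.h_instant = false;
  c.hinf = NA_REAL;
  c.tauh = NA_REAL;
  switch (ch) {
  case cNA: {
    double am = 0.32 * vtrap(v + 39.0, 4.0);
    double bm = 0.28 * vtrap(-(v + 12.0), 5.0);
    c.minf = am / (am + bm);
    c.taum = 1.0 / (am + bm);
    double ah = 0.128 * std::exp(-(v + 35.0) / 18.0);
    double bh = 4.0 / (1.0 + std::exp(-(v + 12.0) / 5.0));
    c.hinf = ah / (ah + bh);
    c.tauh = 1.0 / (ah + bh);
    break;
  }
  case cK: {
    double am = 0.032 * vtrap(v + 37.0, 5.0);
    double bm = 0.5 * std::exp(-(v + 42.0) / 40.0);
    c.minf = am / (am + bm);
    c.taum = 1.0 / (am + bm);
    break;
  }
  case cKA: {
    double am = std::exp(-0.118 * (v + 33.6));
    double bm = std::exp(-0.071 * (v + 33.6));
    c.minf = 1.0 / (1.0 + am);
    c.taum = 50.0 * bm / (1.0 + am);
    double ah = std::exp(0.157 * (v + 83.0));
    c.hinf = 1.0 / (1.0 + ah);
    c.tauh = 12.5 * ah / (1.0 + ah);
    break;
  }
  case cKCA: {
    double c2 = ca * ca;
    c.minf = c2 / (6.25e-4 + c2);
    double t = 0.021 / (6.25e-4 + c2);
    c.taum = (t < 0.1) ? 0.1 : t;
    break;
  }
  case cH: {
    c.minf = 1.0 / (1.0 + std::exp((v + 80.0) / 10.0));
    c.taum = 1176.5 * std::exp((v + 65.0) / 23.5) /
             (1.0 + std::exp((v + 65.0) / 11.8));
    break;
  }
  case cCAL: {
    c.minf = 1.0 / (1.0 + std::exp(-(v + 30.0) / 6.0));
    c.taum = 20.0;
    c.hinf = 1.245 / (1.245 + ca);
    c.tauh = NA_REAL;  // instantaneous
    c.h_instant = true;
    break;
  }
  case cCAT: {
    c.minf = 1.0 / (1.0 + std::exp(-(v + 49.0) / 7.4));
    c.taum = 3.0 + 1.0 / (std::exp((v + 24.0) / 10.0) +
                          std::exp(-(v + 99.0) / 15.0));
    c.hinf = 1.0 / (1.0 + std::exp((v + 77.0) / 5.0));
    c.tauh = 85.0 + 1.0 / (std::exp((v + 45.0) / 4.0) +
                           std::exp(-(v + 404.0) / 50.0));
    break;
  }
  case cCAN: {
    double c2 = ca * ca;
    c.minf = c2 / (1e-4 + c2);
    double t = 1.0 / (2e-3 + 20.0 * c2);
    c.taum = (t < 0.1) ? 0.1 : t;
    break;
  }
  default:
    stop("unknown channel index");
  }
  return c;
}

static inline double powi(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// Steady-state curves and time constants for one channel on a voltage grid.
// ca is recycled if scalar.  Phi is NOT applied here (state-update only).
// [[Rcpp::export]]
List cpp_gating_curves(int ch, NumericVector v, NumericVector ca) {
  int n = v.size();
  NumericVector minf(n), taum(n), hinf(n), tauh(n);
  for (int i = 0; i < n; ++i) {
    double cai = ca[ca.size() == 1 ? 0 : i];
    Curves c = chan_curves(ch, v[i], cai);
    minf[i] = c.minf;
    taum[i] = c.taum;
    hinf[i] = c.has_h ? c.hinf : NA_REAL;
    tauh[i] = (c.has_h && !c.h_instant) ? c.tauh : NA_REAL;
  }
  return List::create(_["m_inf"] = minf, _["tau_m"] = taum,
                      _["h_inf"] = hinf, _["tau_h"] = tauh);
}

// ---------------------------------------------------------------------------

struct Model {
  int n;                        // compartments, Hines-ordered (parent < child)
  std::vector<double> area;     // cm2
  std::vector<int> parent;      // -1 for root
  std::vector<double> gax;      // S, to parent
  std::vector<double> cm;       // uF/cm2
  std::vector<double> gleak;    // S/cm2
  std::vector<double> eleak;    // mV
  std::vector<double> gnic;     // S/cm2
  std::vector<double> gbar;     // n x NCHAN, column-major [ch*n + i], S/cm2
  double ena, ek, eh, ecan, enic;
  double cao, tempK, cabasal, catau, cadepth;
  int inj;                      // injection compartment
};

struct State {
  std::vector<double> v, casub;
  std::vector<double> m[NCHAN], h[NCHAN];
};

static inline double eca_nernst(double cao, double cai, double tempK) {
  return 1e3 * GAS_CONST * tempK / (2.0 * FARADAY) * std::log(cao / cai);
}

static void init_state(const Model& mod, State& st, double v0) {
  st.v.assign(mod.n, v0);
  st.casub.assign(mod.n, mod.cabasal);
  for (int ch = 0; ch < NCHAN; ++ch) {
    st.m[ch].assign(mod.n, 0.0);
    st.h[ch].assign(mod.n, 1.0);
    for (int i = 0; i < mod.n; ++i) {
      Curves c = chan_curves(ch, v0, mod.cabasal);
      st.m[ch][i] = c.minf;
      if (c.has_h) st.h[ch][i] = c.hinf;
    }
  }
}

// advance nsteps; returns max |dV|/dt over the final step
static double advance(const Model& mod, State& st, double dt, long nsteps,
                      const NumericMatrix& stim,   // amp_pA, onset, dur
                      bool use_stim, double t0,
                      const double* noise, long noise_len, double noise_dt,
                      // recording (ignored when rec_every == 0)
                      long rec_every, long rec_offset,
                      NumericMatrix* rec_v, NumericVector* rec_ca,
                      NumericMatrix* rec_g, int rec_comp,
                      const std::vector<int>& rec_ch) {
  int n = mod.n;
  std::vector<double> diag(n), rhs(n), gsum(n), gesum(n), icadrv(n);
  // static per-connection coefficients (S/cm2-equivalents after area norm)
  std::vector<double> kpar(n, 0.0);   // row i, coupling to parent / area_i
  std::vector<double> kchild(n, 0.0); // row parent, coupling to child i / area_parent
  for (int i = 1; i < n; ++i) {
    kpar[i] = mod.gax[i] / mod.area[i];
    kchild[i] = mod.gax[i] / mod.area[mod.parent[i]];
  }
  double dvmax = 0.0;
  for (long s = 0; s < nsteps; ++s) {
    double t = t0 + s * dt;
    // --- gating update (exponential relaxation, Phi-scaled rates) ---
    for (int i = 0; i < n; ++i) {
      double v = st.v[i], ca = st.casub[i];
      gsum[i] = mod.gleak[i] + mod.gnic[i];
      gesum[i] = mod.gleak[i] * mod.eleak[i] + mod.gnic[i] * mod.enic;
      double gca = 0.0;
      double eca = 0.0;
      bool need_eca = false;
      for (int ch = 0; ch < NCHAN; ++ch) {
        double gb = mod.gbar[ch * n + i];
        if (gb <= 0.0) continue;
        Curves c = chan_curves(ch, v, ca);
        st.m[ch][i] = c.minf + (st.m[ch][i] - c.minf) *
                      std::exp(-dt * CH_PHIM[ch] / c.taum);
        if (c.has_h) {
          if (c.h_instant) {
            st.h[ch][i] = c.hinf;
          } else {
            st.h[ch][i] = c.hinf + (st.h[ch][i] - c.hinf) *
                          std::exp(-dt * CH_PHIH[ch] / c.tauh);
          }
        }
        double g = gb * powi(st.m[ch][i], CH_A[ch]);
        if (c.has_h) g *= powi(st.h[ch][i], CH_B[ch]);
        double e;
        switch (ch) {
        case cNA: e = mod.ena; break;
        case cK: case cKA: case cKCA: e = mod.ek; break;
        case cH: e = mod.eh; break;
        case cCAN: e = mod.ecan; break;
        default:
          if (!need_eca) { eca = eca_nernst(mod.cao, ca, mod.tempK); need_eca = true; }
          e = eca;
          gca += g;
          break;
        }
        gsum[i] += g;
        gesum[i] += g * e;
      }
      // calcium drive uses the pre-update voltage (evaluated after V solve)
      icadrv[i] = gca;  // store summed Ca conductance; current computed below
    }
    // --- injected current densities (mA/cm2) ---
    double inj_pA = 0.0;
    if (use_stim) {
      for (int k = 0; k < stim.nrow(); ++k) {
        if (t >= stim(k, 1) && t < stim(k, 1) + stim(k, 2)) inj_pA += stim(k, 0);
      }
      if (noise_len > 0) {
        long ni = (long)std::floor(t / noise_dt);
        if (ni >= noise_len) ni = noise_len - 1;
        inj_pA += noise[ni];
      }
    }
    // --- Crank-Nicolson linear system (Hines solve) ---
    for (int i = 0; i < n; ++i) {
      double c_dt = mod.cm[i] * 1e-3 / dt;   // (uF/cm2 -> mA/(cm2 mV/ms))
      diag[i] = c_dt + 0.5 * gsum[i];
      rhs[i] = c_dt * st.v[i] - 0.5 * gsum[i] * st.v[i] + gesum[i];
      if (i == mod.inj) rhs[i] += inj_pA * 1e-9 / mod.area[i];
    }
    for (int i = 1; i < n; ++i) {
      int p = mod.parent[i];
      diag[i] += 0.5 * kpar[i];
      diag[p] += 0.5 * kchild[i];
      rhs[i] += 0.5 * kpar[i] * (st.v[p] - st.v[i]);
      rhs[p] += 0.5 * kchild[i] * (st.v[i] - st.v[p]);
    }
    // eliminate children (parent index < child index by construction)
    for (int i = n - 1; i >= 1; --i) {
      int p = mod.parent[i];
      double offr = -0.5 * kpar[i];    // row i, col p
      double offp = -0.5 * kchild[i];  // row p, col i
      double f = offp / diag[i];
      diag[p] -= f * offr;
      rhs[p] -= f * rhs[i];
    }
    std::vector<double>& vnew = gsum;  // reuse buffer
    vnew[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      int p = mod.parent[i];
      vnew[i] = (rhs[i] + 0.5 * kpar[i] * vnew[p]) / diag[i];
    }
    dvmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double dv = std::fabs(vnew[i] - st.v[i]) / dt;
      if (dv > dvmax) dvmax = dv;
      st.v[i] = vnew[i];
    }
    if (!std::isfinite(st.v[0]))
      stop("simulation diverged (non-finite voltage) at t = %f ms", t);
    // --- perimembrane calcium update (exponential, influx only) ---
    for (int i = 0; i < n; ++i) {
      double gca = icadrv[i];
      if (gca > 0.0) {
        double eca = eca_nernst(mod.cao, st.casub[i], mod.tempK);
        double ica = gca * (st.v[i] - eca);              // mA/cm2
        double drive = -1e4 * ica / (2.0 * FARADAY * mod.cadepth);  // mM/ms
        if (drive < 0.0) drive = 0.0;
        double target = mod.cabasal + drive * mod.catau;
        st.casub[i] = target + (st.casub[i] - target) * std::exp(-dt / mod.catau);
      } else if (st.casub[i] > mod.cabasal) {
        st.casub[i] = mod.cabasal + (st.casub[i] - mod.cabasal) *
                      std::exp(-dt / mod.catau);
      }
    }
    // --- recording ---
    if (rec_every > 0 && ((s + 1) % rec_every == 0)) {
      long r = rec_offset + (s + 1) / rec_every;
      if (r < rec_v->nrow()) {
        for (int i = 0; i < n; ++i) (*rec_v)(r, i) = st.v[i];
        (*rec_ca)[r] = st.casub[rec_comp];
        for (size_t k = 0; k < rec_ch.size(); ++k) {
          int ch = rec_ch[k];
          double g = mod.gbar[ch * n + rec_comp] *
                     powi(st.m[ch][rec_comp], CH_A[ch]);
          if (CH_B[ch] > 0) g *= powi(st.h[ch][rec_comp], CH_B[ch]);
          (*rec_g)(r, (int)k) = g;
        }
      }
    }
  }
  return dvmax;
}

static Model unpack_model(const List& model) {
  Model mod;
  NumericVector area = model["area"], gax = model["gax"], cm = model["cm"],
                gleak = model["gleak"], eleak = model["eleak"],
                gnic = model["gnic"];
  IntegerVector parent = model["parent"];
  NumericMatrix gbar = model["gbar"];
  mod.n = area.size();
  mod.area.assign(area.begin(), area.end());
  mod.parent.assign(parent.begin(), parent.end());
  mod.gax.assign(gax.begin(), gax.end());
  mod.cm.assign(cm.begin(), cm.end());
  mod.gleak.assign(gleak.begin(), gleak.end());
  mod.eleak.assign(eleak.begin(), eleak.end());
  mod.gnic.assign(gnic.begin(), gnic.end());
  if (gbar.nrow() != mod.n || gbar.ncol() != NCHAN)
    stop("gbar must be n_comp x 8");
  mod.gbar.assign(gbar.begin(), gbar.end());
  mod.ena = model["ena"]; mod.ek = model["ek"]; mod.eh = model["eh"];
  mod.ecan = model["ecan"]; mod.enic = model["enic"];
  mod.cao = model["cao"]; mod.tempK = model["tempK"];
  mod.cabasal = model["cabasal"]; mod.catau = model["catau"];
  mod.cadepth = model["cadepth"];
  mod.inj = as<int>(model["inj"]);
  for (int i = 1; i < mod.n; ++i)
    if (mod.parent[i] >= i || mod.parent[i] < 0)
      stop("compartments must be ordered parent-before-child");
  return mod;
}

// Full current-clamp run: settle (no stimulus/noise) then stimulus phase.
// [[Rcpp::export]]
List cpp_simulate(List model, NumericMatrix stim, double tstop, double dt,
                  double settle_ms, double settle_tol, double settle_max_ms,
                  NumericVector noise_pA, double noise_dt,
                  int record_every, int record_comp, IntegerVector record_ch,
                  double v_init) {
  Model mod = unpack_model(model);
  State st;
  init_state(mod, st, v_init);
  NumericMatrix dummy_v;
  NumericVector dummy_ca;
  NumericMatrix dummy_g;
  std::vector<int> no_ch;

  // settle phase: run settle_ms, then extend in 500 ms blocks if needed
  long nsettle = (long)std::llround(settle_ms / dt);
  double dvmax = advance(mod, st, dt, nsettle, stim, false, 0.0,
                         nullptr, 0, 0.0, 0, 0,
                         &dummy_v, &dummy_ca, &dummy_g, 0, no_ch);
  double settled = settle_ms;
  while (dvmax > settle_tol && settled < settle_max_ms) {
    long nb = (long)std::llround(500.0 / dt);
    dvmax = advance(mod, st, dt, nb, stim, false, 0.0,
                    nullptr, 0, 0.0, 0, 0,
                    &dummy_v, &dummy_ca, &dummy_g, 0, no_ch);
    settled += 500.0;
  }
  double v_rest = st.v[0];

  // stimulus phase
  long nsteps = (long)std::llround(tstop / dt);
  long nrec = nsteps / record_every + 1;
  NumericMatrix rec_v(nrec, mod.n);
  NumericVector rec_ca(nrec);
  NumericMatrix rec_g(nrec, record_ch.size());
  std::vector<int> rch(record_ch.begin(), record_ch.end());
  // record initial state (post-settle)
  for (int i = 0; i < mod.n; ++i) rec_v(0, i) = st.v[i];
  rec_ca[0] = st.casub[record_comp];
  for (size_t k = 0; k < rch.size(); ++k) {
    int ch = rch[k];
    double g = mod.gbar[ch * mod.n + record_comp] *
               powi(st.m[ch][record_comp], CH_A[ch]);
    if (CH_B[ch] > 0) g *= powi(st.h[ch][record_comp], CH_B[ch]);
    rec_g(0, (int)k) = g;
  }
  advance(mod, st, dt, nsteps, stim, true, 0.0,
          noise_pA.size() ? noise_pA.begin() : nullptr,
          noise_pA.size(), noise_dt,
          record_every, 0, &rec_v, &rec_ca, &rec_g, record_comp, rch);

  NumericVector tgrid(nrec);
  for (long r = 0; r < nrec; ++r) tgrid[r] = r * record_every * dt;
  return List::create(
    _["time"] = tgrid, _["v"] = rec_v, _["ca"] = rec_ca, _["g"] = rec_g,
    _["v_rest"] = v_rest, _["settle_dvmax"] = dvmax,
    _["settle_ms"] = settled);
}

// Nernst potential for a divalent ion (mV)
// [[Rcpp::export]]
double cpp_nernst_ca(double cai, double cao, double tempK) {
  return eca_nernst(cao, cai, tempK);
}
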