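// Fixed-step integrator for single-compartment conductance-based neurons
// (Hodgkin-Huxley squid kinetics and the Wang-Buzsaki fast-spiking
// interneuron) with single-exponential synapses.
//
// Units: V in mV, t in ms, capacitance in nF, conductances in uS
// (so currents come out in nA and dV/dt in mV/ms).
//
// Scheme: gating variables advance by the exponential (Rush-Larsen)
// update; the membrane equation, linear in V for fixed gates and
// conductances, advances by a trapezoid-consistent (Crank-Nicolson)
// update. Synaptic conductances decay analytically between grid points;
// each event adds its weight at the first grid time at or after its
// timestamp. Spikes are upward 0 mV crossings with sub-step linear
// interpolation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const int HH = 0;
const int WB = 1;

struct Model {
  int kind;
  double C;                       // nF
  double gna, gk, gl;             // uS (absolute)
  double ena, ek, el;             // mV
  double wexc, winh;              // uS per event
  double tau_exc, tau_inh;        // ms
  double e_exc, e_inh;            // mV
  double phi;                     // WB temperature-like rate scale
};

Model as_model(const List& p) {
  Model m;
  m.kind    = as<int>(p["kind"]);
  m.C       = as<double>(p["c_nF"]);
  m.gna     = as<double>(p["gna_uS"]);
  m.gk      = as<double>(p["gk_uS"]);
  m.gl      = as<double>(p["gl_uS"]);
  m.ena     = as<double>(p["ena"]);
  m.ek      = as<double>(p["ek"]);
  m.el      = as<double>(p["el"]);
  m.wexc    = as<double>(p["weight_exc"]);
  m.winh    = as<double>(p["weight_inh"]);
  m.tau_exc = as<double>(p["tau_exc"]);
  m.tau_inh = as<double>(p["tau_inh"]);
  m.e_exc   = as<double>(p["e_exc"]);
  m.e_inh   = as<double>(p["e_inh"]);
  m.phi     = as<double>(p["phi"]);
  return m;
}

// x / (1 - exp(-x/y)) with its removable singularity at x = 0 filled in.
inline double vtrap(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 + 0.5 * r);
  return x / (1.0 - std::exp(-r));
}

struct Rates { double am, bm, ah, bh, an, bn; };

inline Rates hh_rates(double v) {
  Rates r;
  r.am = 0.1 * vtrap(v + 40.0, 10.0);
  r.bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
  r.ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  r.an = 0.01 * vtrap(v + 55.0, 10.0);
  r.bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  return r;
}

// WB: m is instantaneous; h and n rates are scaled by phi.
inline Rates wb_rates(double v, double phi) {
  Rates r;
  r.am = 0.1 * vtrap(v + 35.0, 10.0);
  r.bm = 4.0 * std::exp(-(v + 60.0) / 18.0);
  r.ah = phi * 0.07 * std::exp(-(v + 58.0) / 20.0);
  r.bh = phi * 1.0 / (1.0 + std::exp(-(v + 28.0) / 10.0));
  r.an = phi * 0.01 * vtrap(v + 34.0, 10.0);
  r.bn = phi * 0.125 * std::exp(-(v + 44.0) / 80.0);
  return r;
}

inline Rates model_rates(const Model& mod, double v) {
  return mod.kind == HH ? hh_rates(v) : wb_rates(v, mod.phi);
}

struct State { double v, m, h, n, ge, gi; };

// One step of dt: gates first (Rush-Larsen), then V (Crank-Nicolson with
// the updated gates), then exponential synaptic decay.
inline void step(const Model& mod, State& s, double dt,
                 double dec_e, double dec_i) {
  Rates r = model_rates(mod, s.v);
  double sm = r.am + r.bm, sh = r.ah + r.bh, sn = r.an + r.bn;
  if (mod.kind == HH) {
    s.m += (r.am / sm - s.m) * (1.0 - std::exp(-dt * sm));
  } else {
    s.m = r.am / sm;  // instantaneous
  }
  s.h += (r.ah / sh - s.h) * (1.0 - std::exp(-dt * sh));
  s.n += (r.an / sn - s.n) * (1.0 - std::exp(-dt * sn));

  double gna = mod.gna * s.m * s.m * s.m * s.h;
  double gk  = mod.gk * s.n * s.n * s.n * s.n;
  double G = gna + gk + mod.gl + s.ge + s.gi;
  double I = gna * mod.ena + gk * mod.ek + mod.gl * mod.el +
             s.ge * mod.e_exc + s.gi * mod.e_inh;
  double a = mod.C / dt;
  s.v = (s.v * (a - 0.5 * G) + I) / (a + 0.5 * G);

  s.ge *= dec_e;
  s.gi *= dec_i;
}

// Grid index (>= 0) of the first sample at or after time t (relative to t0).
inline int grid_index(double t, double t0, double dt) {
  double x = (t - t0) / dt;
  int i = (int)std::ceil(x - 1e-9);
  return i < 0 ? 0 : i;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_integrate")]]
List cpp_integrate(List params, NumericVector init, double init_ge,
                   double init_gi, NumericVector ev_times,
                   IntegerVector ev_exc, double t0, double t_end, double dt,
                   bool record) {
  Model mod = as_model(params);
  int nsamp = (int)std::floor((t_end - t0) / dt + 1e-9) + 1;
  if (nsamp < 2) stop("integration window must contain at least 2 samples");

  State s;
  s.v = init[0]; s.m = init[1]; s.h = init[2]; s.n = init[3];
  if (mod.kind == WB) {
    Rates r = wb_rates(s.v, mod.phi);
    s.m = r.am / (r.am + r.bm);
  }
  s.ge = init_ge; s.gi = init_gi;

  int nev = ev_times.size();
  std::vector<int> ev_idx(nev);
  for (int e = 0; e < nev; ++e) {
    ev_idx[e] = grid_index(ev_times[e], t0, dt);
    if (ev_idx[e] > nsamp - 1) ev_idx[e] = nsamp - 1;
  }

  double dec_e = std::exp(-dt / mod.tau_exc);
  double dec_i = std::exp(-dt / mod.tau_inh);

  NumericVector vm, gm, gh, gn, sge, sgi;
  if (record) {
    vm = NumericVector(nsamp); gm = NumericVector(nsamp);
    gh = NumericVector(nsamp); gn = NumericVector(nsamp);
    sge = NumericVector(nsamp); sgi = NumericVector(nsamp);
  }
  std::vector<double> spikes;

  int e = 0;
  double v_prev = s.v;
  for (int i = 0; i < nsamp; ++i) {
    while (e < nev && ev_idx[e] == i) {
      if (ev_exc[e]) s.ge += mod.wexc; else s.gi += mod.winh;
      ++e;
    }
    if (i > 0 && v_prev < 0.0 && s.v >= 0.0) {
      double tc = t0 + (i - 1) * dt + dt * (0.0 - v_prev) / (s.v - v_prev);
      spikes.push_back(tc);
    }
    if (record) {
      vm[i] = s.v; gm[i] = s.m; gh[i] = s.h; gn[i] = s.n;
      sge[i] = s.ge; sgi[i] = s.gi;
    }
    if (i < nsamp - 1) {
      v_prev = s.v;
      step(mod, s, dt, dec_e, dec_i);
    }
  }

  List out = List::create(
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["nsamp"] = nsamp);
  if (record) {
    NumericVector tt(nsamp);
    for (int i = 0; i < nsamp; ++i) tt[i] = t0 + i * dt;
    out["times"] = tt; out["vm"] = vm; out["m"] = gm; out["h"] = gh;
    out["n_gate"] = gn; out["g_exc"] = sge; out["g_inh"] = sgi;
  }
  return out;
}

// Batch next-spike-time: integrate the same (relative-time) event window
// from each initialization frame and return, per frame, the time from the
// last event (t_last) to the first spike strictly after it, or Inf.
// frames: k x 4 matrix, columns vm, m, h, n_gate.
// [[Rcpp::export(name = ".cpp_batch_nst")]]
NumericVector cpp_batch_nst(List params, NumericMatrix frames,
                            NumericVector ev_times, IntegerVector ev_exc,
                            double t_last, double t_total, double dt) {
  Model mod = as_model(params);
  int nsamp = (int)std::floor(t_total / dt + 1e-9) + 1;
  if (nsamp < 2) stop("integration window must contain at least 2 samples");

  int nev = ev_times.size();
  std::vector<int> ev_idx(nev);
  for (int e = 0; e < nev; ++e) {
    ev_idx[e] = grid_index(ev_times[e], 0.0, dt);
    if (ev_idx[e] > nsamp - 1) ev_idx[e] = nsamp - 1;
  }
  double dec_e = std::exp(-dt / mod.tau_exc);
  double dec_i = std::exp(-dt / mod.tau_inh);

  int k = frames.nrow();
  NumericVector out(k);
  for (int f = 0; f < k; ++f) {
    State s;
    s.v = frames(f, 0); s.m = frames(f, 1);
    s.h = frames(f, 2); s.n = frames(f, 3);
    if (mod.kind == WB) {
      Rates r = wb_rates(s.v, mod.phi);
      s.m = r.am / (r.am + r.bm);
    }
    s.ge = 0.0; s.gi = 0.0;

    int e = 0;
    double v_prev = s.v;
    double nst = R_PosInf;
    for (int i = 0; i < nsamp; ++i) {
      while (e < nev && ev_idx[e] == i) {
        if (ev_exc[e]) s.ge += mod.wexc; else s.gi += mod.winh;
        ++e;
      }
      if (i > 0 && v_prev < 0.0 && s.v >= 0.0) {
        double tc = (i - 1) * dt + dt * (0.0 - v_prev) / (s.v - v_prev);
        if (tc > t_last + 1e-9) { nst = tc - t_last; break; }
      }
      if (i < nsamp - 1) {
        v_prev = s.v;
        step(mod, s, dt, dec_e, dec_i);
      }
    }
    out[f] = nst;
  }
  return out;
}
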