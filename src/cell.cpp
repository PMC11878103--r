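#include <Rcpp.h>
#include <cmath>
#include "cell.h"

using namespace Rcpp;

// Minimal six-current ventricular-type cell:
//   I_ion = I_Na + I_to + I_CaL + I_Kr + I_Kur + I_K1
// Each current is (conductance scale) x (gate product) x (V - E_rev); all
// gates are first-order with sigmoid steady states and constant time
// constants, so Rush-Larsen decay factors are scalars per gate. C_m is
// normalised to 1, hence currents carry units mV/ms.

CellPars parse_cell_params(const NumericVector &p) {
  CellPars cp;
  cp.gNa  = p["gNa"];  cp.gto  = p["gto"];  cp.gCaL = p["gCaL"];
  cp.gKr  = p["gKr"];  cp.gKur = p["gKur"]; cp.gK1  = p["gK1"];
  cp.ENa  = p["ENa"];  cp.EK   = p["EK"];   cp.ECa  = p["ECa"];
  const char *gates[N_GATES] = {"m", "h", "d", "f", "r", "s", "xr", "xur"};
  for (int g = 0; g < N_GATES; ++g) {
    std::string nm(gates[g]);
    cp.vh[g]  = p[std::string("vh_") + nm];
    cp.k[g]   = p[std::string("k_") + nm];
    cp.tau[g] = p[std::string("tau_") + nm];
  }
  cp.k1_vh = p["vh_k1"];
  cp.k1_k  = p["k_k1"];
  return cp;
}

double sigmoid_ss(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((vh - v) / k));
}

void gate_ss_all(const CellPars &cp, double v, double *ss) {
  for (int g = 0; g < N_GATES; ++g) ss[g] = sigmoid_ss(v, cp.vh[g], cp.k[g]);
}

// Total ionic current (mV/ms, outward positive) for explicit gate values.
double ionic_current_raw(const CellPars &cp, double v, const double *x,
                         double up_scale, double apd_scale) {
  const double k1inf = sigmoid_ss(v, cp.k1_vh, cp.k1_k);
  const double iNa  = cp.gNa * up_scale * x[G_M] * x[G_M] * x[G_M] * x[G_H] * (v - cp.ENa);
  const double ito  = (cp.gto / apd_scale) * x[G_R] * x[G_S] * (v - cp.EK);
  const double iCaL = cp.gCaL * x[G_D] * x[G_F] * (v - cp.ECa);
  const double iKr  = (cp.gKr / apd_scale) * x[G_XR] * (v - cp.EK);
  const double iKur = (cp.gKur / apd_scale) * x[G_XUR] * (v - cp.EK);
  const double iK1  = cp.gK1 * k1inf * (v - cp.EK);
  return iNa + ito + iCaL + iKr + iKur + iK1;
}

//' @noRd
// [[Rcpp::export(name = ".cell_rhs_cpp")]]
List cell_rhs_cpp(double v, NumericVector gates, NumericVector params,
                  double up_scale, double apd_scale) {
  if (gates.size() != N_GATES) stop("expected %d gate values", N_GATES);
  CellPars cp = parse_cell_params(params);
  double x[N_GATES], ss[N_GATES];
  for (int g = 0; g < N_GATES; ++g) x[g] = gates[g];
  gate_ss_all(cp, v, ss);
  NumericVector rates(N_GATES), ssv(N_GATES);
  for (int g = 0; g < N_GATES; ++g) {
    rates[g] = (ss[g] - x[g]) / cp.tau[g];
    ssv[g] = ss[g];
  }
  double cur = ionic_current_raw(cp, v, x, up_scale, apd_scale);
  return List::create(_["current"] = cur, _["gate_rates"] = rates,
                      _["gate_ss"] = ssv);
}

//' @noRd
// [[Rcpp::export(name = ".gate_ss_cpp")]]
NumericVector gate_ss_cpp(double v, NumericVector params) {
  CellPars cp = parse_cell_params(params);
  double ss[N_GATES];
  gate_ss_all(cp, v, ss);
  NumericVector out(N_GATES);
  for (int g = 0; g < N_GATES; ++g) out[g] = ss[g];
  out.attr("names") = CharacterVector::create("m", "h", "d", "f", "r", "s",
                                              "xr", "xur");
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".step_cell_cpp")]]
List step_cell_cpp(double v, NumericVector gates, NumericVector params,
                   double up_scale, double apd_scale, double dt,
                   double stim) {
  CellPars cp = parse_cell_params(params);
  double x[N_GATES], ss[N_GATES];
  for (int g = 0; g < N_GATES; ++g) x[g] = gates[g];
  double cur = ionic_current_raw(cp, v, x, up_scale, apd_scale);
  double v_new = v + dt * (stim - cur);
  gate_ss_all(cp, v, ss);
  NumericVector xn(N_GATES);
  for (int g = 0; g < N_GATES; ++g) {
    // Rush-Larsen exponential update; exact for frozen V over the step
    double a = std::exp(-dt / cp.tau[g]);
    double val = ss[g] + (x[g] - ss[g]) * a;
    if (val < 0) val = 0;
    if (val > 1) val = 1;
    xn[g] = val;
  }
  if (!std::isfinite(v_new)) stop("non-finite membrane potential after step");
  return List::create(_["v"] = v_new, _["gates"] = xn);
}

//' @noRd
// [[Rcpp::export(name = ".simulate_cell_cpp")]]
NumericMatrix simulate_cell_cpp(NumericVector params, double up_scale,
                                double apd_scale, double v0,
                                NumericVector gates0, double dt, int n_steps,
                                double stim_start, double stim_dur,
                                double stim_amp, int record_stride) {
  CellPars cp = parse_cell_params(params);
  double x[N_GATES], ss[N_GATES], rl[N_GATES];
  if (gates0.size() == N_GATES) {
    for (int g = 0; g < N_GATES; ++g) x[g] = gates0[g];
  } else {
    gate_ss_all(cp, v0, x);
  }
  for (int g = 0; g < N_GATES; ++g) rl[g] = std::exp(-dt / cp.tau[g]);
  if (record_stride < 1) record_stride = 1;
  int n_rec = n_steps / record_stride + 1;
  NumericMatrix out(n_rec, 2);
  colnames(out) = CharacterVector::create("t", "v");
  double v = v0;
  int rec = 0;
  out(rec, 0) = 0.0; out(rec, 1) = v; ++rec;
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    double stim = (t >= stim_start && t < stim_start + stim_dur) ? stim_amp : 0.0;
    double cur = ionic_current_raw(cp, v, x, up_scale, apd_scale);
    double v_new = v + dt * (stim - cur);
    gate_ss_all(cp, v, ss);
    for (int g = 0; g < N_GATES; ++g) {
      double val = ss[g] + (x[g] - ss[g]) * rl[g];
      x[g] = val < 0 ? 0 : (val > 1 ? 1 : val);
    }
    v = v_new;
    if (!std::isfinite(v) || std::fabs(v) > 200.0)
      stop("membrane potential diverged at step %d", s + 1);
    if ((s + 1) % record_stride == 0 && rec < n_rec) {
      out(rec, 0) = (s + 1) * dt; out(rec, 1) = v; ++rec;
    }
  }
  return out;
}
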