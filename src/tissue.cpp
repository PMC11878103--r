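#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "cell.h"

using namespace Rcpp;

// Explicit monodomain stepper over a precomputed tissue graph (CSR edge
// lists with symmetric interface conductances, 1/ms). Voltage-dependent
// sigmoids are tabulated on a fine Vm grid; gate time constants are
// constant, so the Rush-Larsen decay factors are scalars. Single-threaded
// and order-stable: identical inputs give identical outputs.

static const double TAB_VMIN = -150.0;
static const double TAB_VMAX = 100.0;
static const double TAB_STEP = 0.025;

//' @noRd
// [[Rcpp::export(name = ".simulate_tissue_cpp")]]
List simulate_tissue_cpp(IntegerVector edge_ptr, IntegerVector edge_idx,
                         NumericVector edge_w, NumericVector up,
                         NumericVector apd, NumericVector params,
                         NumericVector v_init, double dt, int n_steps,
                         IntegerVector stim_idx, double stim_start,
                         double stim_dur, double stim_amp, double v_thresh,
                         double early_stop_ms, int snapshot_stride) {
  const int n = edge_ptr.size() - 1;
  if (up.size() != n || apd.size() != n)
    stop("region scale vectors must have one entry per tissue node");
  CellPars cp = parse_cell_params(params);

  // sigmoid tables: 8 gate steady states + inward-rectifier open fraction
  const int ntab = (int)std::floor((TAB_VMAX - TAB_VMIN) / TAB_STEP) + 2;
  std::vector<double> tab(9 * (size_t)ntab);
  for (int i = 0; i < ntab; ++i) {
    double v = TAB_VMIN + i * TAB_STEP;
    for (int g = 0; g < N_GATES; ++g)
      tab[(size_t)g * ntab + i] = sigmoid_ss(v, cp.vh[g], cp.k[g]);
    tab[(size_t)8 * ntab + i] = sigmoid_ss(v, cp.k1_vh, cp.k1_k);
  }
  double rl[N_GATES];
  for (int g = 0; g < N_GATES; ++g) rl[g] = std::exp(-dt / cp.tau[g]);

  std::vector<double> v_old(n), v_new(n), gates((size_t)n * N_GATES);
  for (int i = 0; i < n; ++i)
    v_old[i] = v_init.size() == 1 ? v_init[0] : v_init[i];
  for (int i = 0; i < n; ++i) {
    double ss[N_GATES];
    gate_ss_all(cp, v_old[i], ss);
    for (int g = 0; g < N_GATES; ++g) gates[(size_t)i * N_GATES + g] = ss[g];
  }
  std::vector<char> is_stim(n, 0);
  for (int s = 0; s < stim_idx.size(); ++s) {
    if (stim_idx[s] < 0 || stim_idx[s] >= n) stop("stimulus node out of range");
    is_stim[stim_idx[s]] = 1;
  }

  NumericVector act(n, NA_REAL);
  int n_act = 0;
  double last_event = stim_start + stim_dur;

  int n_snap = snapshot_stride > 0 ? n_steps / snapshot_stride + 1 : 0;
  NumericMatrix snaps(snapshot_stride > 0 ? n : 0, n_snap);
  NumericVector snap_t(n_snap);
  int snap_i = 0;
  if (snapshot_stride > 0) {
    for (int i = 0; i < n; ++i) snaps(i, snap_i) = v_old[i];
    snap_t[snap_i++] = 0.0;
  }

  const double inv_step = 1.0 / TAB_STEP;
  int steps_run = 0;
  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const bool stim_on = (t >= stim_start && t < stim_start + stim_dur);
    for (int i = 0; i < n; ++i) {
      const double v = v_old[i];
      // diffusion: sum of symmetric edge fluxes (no-flux elsewhere)
      double lap = 0.0;
      const int e0 = edge_ptr[i], e1 = edge_ptr[i + 1];
      for (int e = e0; e < e1; ++e) lap += edge_w[e] * (v_old[edge_idx[e]] - v);
      // tabulated sigmoids at v
      double vc = v < TAB_VMIN ? TAB_VMIN : (v > TAB_VMAX ? TAB_VMAX : v);
      double pos = (vc - TAB_VMIN) * inv_step;
      int i0 = (int)pos;
      if (i0 > ntab - 2) i0 = ntab - 2;
      double frac = pos - i0;
      double ss[9];
      for (int g = 0; g < 9; ++g) {
        const double *row = &tab[(size_t)g * ntab];
        ss[g] = row[i0] + frac * (row[i0 + 1] - row[i0]);
      }
      double *x = &gates[(size_t)i * N_GATES];
      const double iNa = cp.gNa * up[i] * x[G_M] * x[G_M] * x[G_M] * x[G_H] *
                         (v - cp.ENa);
      const double ik = (v - cp.EK);
      const double irep = ((cp.gto / apd[i]) * x[G_R] * x[G_S] +
                           (cp.gKr / apd[i]) * x[G_XR] +
                           (cp.gKur / apd[i]) * x[G_XUR] + cp.gK1 * ss[8]) * ik;
      const double iCaL = cp.gCaL * x[G_D] * x[G_F] * (v - cp.ECa);
      double dv = lap - (iNa + irep + iCaL);
      if (stim_on && is_stim[i]) dv += stim_amp;
      const double vn = v + dt * dv;
      for (int g = 0; g < N_GATES; ++g) {
        double val = ss[g] + (x[g] - ss[g]) * rl[g];
        x[g] = val < 0 ? 0 : (val > 1 ? 1 : val);
      }
      if (!std::isfinite(vn) || std::fabs(vn) > 200.0)
        stop("membrane potential diverged at step %d (node %d)", s + 1, i + 1);
      v_new[i] = vn;
      if (vn >= v_thresh && ISNA(act[i])) {
        act[i] = (s + 1) * dt;
        ++n_act;
        last_event = (s + 1) * dt;
      }
    }
    v_old.swap(v_new);
    steps_run = s + 1;
    if (snapshot_stride > 0 && (s + 1) % snapshot_stride == 0 &&
        snap_i < n_snap) {
      for (int i = 0; i < n; ++i) snaps(i, snap_i) = v_old[i];
      snap_t[snap_i++] = (s + 1) * dt;
    }
    if (early_stop_ms > 0) {
      const double tn = (s + 1) * dt;
      if (n_act == n) break;
      if (tn > stim_start + stim_dur && tn - last_event > early_stop_ms) break;
    }
  }

  NumericVector vf(n);
  for (int i = 0; i < n; ++i) vf[i] = v_old[i];
  List out = List::create(
      _["activation"] = act, _["steps_run"] = steps_run, _["v_final"] = vf,
      _["n_activated"] = n_act);
  if (snapshot_stride > 0) {
    if (snap_i < n_snap) {
      snaps = snaps(_, Range(0, snap_i - 1));
      snap_t = snap_t[Range(0, snap_i - 1)];
    }
    out["snapshots"] = snaps;
    out["snapshot_times"] = snap_t;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  // 6-connected (face) component labelling by BFS over a 3D mask
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int comp = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++comp;
    queue.clear();
    queue.push_back(start);
    lab[start] = comp;
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nb] && !lab[nb]) {
          lab[nb] = comp;
          queue.push_back(nb);
        }
      }
    }
  }
  lab.attr("n_components") = comp;
  return lab;
}
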