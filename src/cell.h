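#ifndef CCSIM_CELL_H
#define CCSIM_CELL_H

#include <Rcpp.h>

#define N_GATES 8
enum Gate { G_M = 0, G_H, G_D, G_F, G_R, G_S, G_XR, G_XUR };

struct CellPars {
  double gNa, gto, gCaL, gKr, gKur, gK1;
  double ENa, EK, ECa;
  double vh[N_GATES], k[N_GATES], tau[N_GATES];
  double k1_vh, k1_k;
};

CellPars parse_cell_params(const Rcpp::NumericVector &p);
double sigmoid_ss(double v, double vh, double k);
void gate_ss_all(const CellPars &cp, double v, double *ss);
double ionic_current_raw(const CellPars &cp, double v, const double *x,
                         double up_scale, double apd_scale);

#endif
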