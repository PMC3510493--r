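#ifndef SRNASCREEN_ENERGY_H
#define SRNASCREEN_ENERGY_H

#include <Rcpp.h>
#include <cmath>

// Base encoding: A=0, C=1, G=2, U=3.
// Pair-type encoding: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5, non-canonical=-1.
inline int pair_index(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 2 && y == 1) return 2;
  if (x == 1 && y == 2) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

// Thermodynamic parameters, mirrored from the R-side energy_model object.
struct EnergyPar {
  double RT;
  double stack[6][6];      // kcal/mol, stack[outer][inner]
  double h_init, h_slope;  // hairpin: h_init + h_slope * (size - min_hairpin)
  double i_init, i_slope;  // interior: i_init + i_slope * (s1 + s2)
  double b_init, b_slope;  // bulge: b_init + b_slope * (size - 1)
  double duplex_init;
  int min_hairpin;

  double hairpin_w(int s) const {
    return std::exp(-(h_init + h_slope * (s - min_hairpin)) / RT);
  }
  // Loop energy (kcal/mol) for an interior/bulge loop with s1, s2 unpaired
  // nucleotides on the two sides (not both zero).
  double loop_e(int s1, int s2) const {
    int s = s1 + s2;
    if (s1 == 0 || s2 == 0) return b_init + b_slope * (s - 1);
    return i_init + i_slope * s;
  }
  double loop_w(int s1, int s2) const { return std::exp(-loop_e(s1, s2) / RT); }
};

inline EnergyPar make_par(Rcpp::List par) {
  EnergyPar p;
  p.RT = Rcpp::as<double>(par["RT"]);
  Rcpp::NumericMatrix st = par["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) p.stack[a][b] = st(a, b);
  p.h_init = Rcpp::as<double>(par["hairpin_init"]);
  p.h_slope = Rcpp::as<double>(par["hairpin_slope"]);
  p.i_init = Rcpp::as<double>(par["interior_init"]);
  p.i_slope = Rcpp::as<double>(par["interior_slope"]);
  p.b_init = Rcpp::as<double>(par["bulge_init"]);
  p.b_slope = Rcpp::as<double>(par["bulge_slope"]);
  p.duplex_init = Rcpp::as<double>(par["duplex_init"]);
  p.min_hairpin = Rcpp::as<int>(par["min_hairpin"]);
  return p;
}

#endif
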