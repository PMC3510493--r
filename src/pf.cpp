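#include <Rcpp.h>
#include <vector>
#include "energy.h"

using namespace Rcpp;

// McCaskill-style partition function over nested secondary structures.
//
// Model conventions (shared with the R enumeration oracle):
//  - canonical pairs only (AU, UA, GC, CG, GU, UG);
//  - minimum hairpin loop of min_hairpin unpaired nt (a pair (i,j) requires
//    j - i - 1 >= min_hairpin);
//  - base-pair span j - i + 1 <= max_span (0 = unlimited);
//  - energies are assigned per loop: hairpin and interior/bulge loops carry
//    affine penalties, helix stacks (adjacent pairs) carry the stacking
//    energy, multiloops and the exterior loop are free;
//  - lonely pairs allowed, pseudoknots excluded;
//  - positions in `forced` may not pair (forced-unpaired constraint).
//
// Inside recursions (1-based, Q(i, i-1) = 1):
//   QB(i,j) = hairpin + sum_{single child (k,l)} loop_w * QB(k,l)
//           + [Q(i+1,j-1) - 1 - S1(i+1,j-1)]        (>=2 children, free ML)
//   Q(i,j)  = Q(i,j-1) + sum_k QB(k,j) Q(i,k-1)
//   S1(i,j) = sum over exactly-one-top-level-pair configurations
// Outside recursion (for pair probabilities):
//   QO(i,j) = Q(1,i-1) Q(j+1,n)
//           + sum_{(k,l) innermost enclosing} QO(k,l) *
//               [ loop_w(i-k-1, l-j-1) + (Q(k+1,i-1) Q(j+1,l-1) - 1) ]
//   P(i,j)  = QB(i,j) QO(i,j) / Z

// [[Rcpp::export(name = ".pf_cpp")]]
List pf_cpp(IntegerVector seq, List par, int max_span, LogicalVector forced,
            bool want_bp) {
  const int n = seq.size();
  if (n < 1) stop("sequence must have length >= 1");
  EnergyPar p = make_par(par);
  const int span = (max_span <= 0 || max_span > n) ? n : max_span;
  const int mh = p.min_hairpin;

  std::vector<int> s(n + 1);
  std::vector<bool> fu(n + 2, false);
  for (int i = 1; i <= n; ++i) {
    s[i] = seq[i - 1];
    fu[i] = forced[i - 1];
  }

  const int W = n + 2;
  std::vector<double> Q(W * W, 0.0), S1(W * W, 0.0), QB(W * W, 0.0);
  auto id = [W](int i, int j) { return i * W + j; };
  // empty intervals
  for (int i = 1; i <= n + 1; ++i)
    for (int j = 0; j < i; ++j) Q[id(i, j)] = 1.0;

  auto allowed = [&](int i, int j) -> bool {
    if (j - i - 1 < mh) return false;
    if (j - i + 1 > span) return false;
    if (fu[i] || fu[j]) return false;
    return pair_index(s[i], s[j]) >= 0;
  };

  for (int d = 0; d <= n - 1; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      const int j = i + d;
      if (d == 0) {
        Q[id(i, j)] = 1.0;
        continue;
      }
      // --- QB ---
      if (allowed(i, j)) {
        const int pt = pair_index(s[i], s[j]);
        double qb = p.hairpin_w(j - i - 1);
        // exactly one child (k,l)
        for (int k = i + 1; k <= j - 1 - mh; ++k) {
          for (int l = k + mh + 1; l <= j - 1; ++l) {
            const double inner = QB[id(k, l)];
            if (inner == 0.0) continue;
            double w;
            if (k == i + 1 && l == j - 1)
              w = std::exp(-p.stack[pt][pair_index(s[k], s[l])] / p.RT);
            else
              w = p.loop_w(k - i - 1, j - l - 1);
            qb += w * inner;
          }
        }
        // >= 2 children, multiloop free
        double multi = Q[id(i + 1, j - 1)] - 1.0 - S1[id(i + 1, j - 1)];
        if (multi > 0.0) qb += multi;
        QB[id(i, j)] = qb;
      }
      // --- Q, S1 ---
      double q = Q[id(i, j - 1)];
      double s1 = S1[id(i, j - 1)];
      const int lo = std::max(i, j - span + 1);
      for (int k = lo; k <= j - 1 - mh; ++k) {
        const double qb = QB[id(k, j)];
        if (qb == 0.0) continue;
        q += qb * Q[id(i, k - 1)];
        s1 += qb;
      }
      Q[id(i, j)] = q;
      S1[id(i, j)] = s1;
    }
  }

  const double Z = Q[id(1, n)];
  List out = List::create(_["Z"] = Z);

  if (want_bp) {
    std::vector<double> QO(W * W, 0.0);
    NumericMatrix bp(n, n);
    const int dmax = std::min(n - 1, span - 1);
    for (int d = dmax; d >= mh + 1; --d) {
      for (int i = 1; i + d <= n; ++i) {
        const int j = i + d;
        if (QB[id(i, j)] == 0.0) continue;
        double qo = Q[id(1, i - 1)] * Q[id(j + 1, n)];
        // innermost enclosing pair (k,l)
        const int klo = std::max(1, j + 2 - span);
        for (int k = klo; k <= i - 1; ++k) {
          const int lhi = std::min(n, k + span - 1);
          for (int l = j + 1; l <= lhi; ++l) {
            if (!allowed(k, l)) continue;
            if (QO[id(k, l)] == 0.0) continue;
            double lw;
            if (k == i - 1 && l == j + 1)
              lw = std::exp(
                  -p.stack[pair_index(s[k], s[l])][pair_index(s[i], s[j])] /
                  p.RT);
            else
              lw = p.loop_w(i - k - 1, l - j - 1);
            double ml = Q[id(k + 1, i - 1)] * Q[id(j + 1, l - 1)] - 1.0;
            if (ml < 0.0) ml = 0.0;
            qo += QO[id(k, l)] * (lw + ml);
          }
        }
        QO[id(i, j)] = qo;
        const double pr = QB[id(i, j)] * qo / Z;
        bp(i - 1, j - 1) = pr;
        bp(j - 1, i - 1) = pr;
      }
    }
    out["bp"] = bp;
  }
  return out;
}
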