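#include <Rcpp.h>
#include <vector>
#include <limits>
#include "energy.h"

using namespace Rcpp;

// Seed-constrained intermolecular duplex dynamic program.
//
// Both sequences are 5'->3'. A duplex is an ordered set of canonical pairs
// (i_t on a, j_t on b) with i strictly increasing and j strictly decreasing
// (antiparallel, non-crossing), interior/bulge loops of at most max_bulge
// unpaired nt per side, and no intramolecular structure inside the site
// (accessibility is charged separately as opening energies).
//
// E_hybrid = duplex_init + sum over consecutive pair steps of either the
// stacking energy (adjacent pairs) or the interior/bulge penalty.
//
// The seed constraint requires >= seed_len consecutive pairs joined purely by
// stacking steps; with seed_gu = false, GU/UG pairs do not count towards (and
// interrupt) the seed run, although they may still occur in the duplex.
//
// DP state: for each cell (i,j) with a[i] pairing b[j],
//   Ens[r]: best energy of a duplex whose rightmost pair is (i,j), current
//           trailing seed-eligible stacked run of length r (0..seed_len-1),
//           no seed completed yet;
//   Es:     best energy with the seed already satisfied.
// Backpointers allow reconstruction of the optimal seeded duplex.

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".duplex_cpp")]]
List duplex_cpp(IntegerVector aseq, IntegerVector bseq, List par, int seed_len,
                bool seed_gu, int max_bulge, LogicalVector forbidden_b) {
  const int m = aseq.size(), n = bseq.size();
  EnergyPar p = make_par(par);
  if (seed_len < 2) stop("seed_len must be >= 2");
  const int R = seed_len;  // run states 0..R-1, plus seeded layer

  std::vector<int> a(m + 1), b(n + 1);
  std::vector<bool> fb(n + 1, false);
  for (int i = 1; i <= m; ++i) a[i] = aseq[i - 1];
  for (int j = 1; j <= n; ++j) {
    b[j] = bseq[j - 1];
    fb[j] = forbidden_b[j - 1];
  }

  std::vector<int> pt(static_cast<size_t>(m + 1) * (n + 1), -1);
  auto cid = [n](int i, int j) { return static_cast<size_t>(i) * (n + 1) + j; };
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j)
      if (!fb[j]) pt[cid(i, j)] = pair_index(a[i], b[j]);

  const size_t NC = static_cast<size_t>(m + 1) * (n + 1);
  std::vector<double> Ens(NC * R, INF), Es(NC, INF), EnsMin(NC, INF);
  // backpointers: encode predecessor as (i, j, state) with state = r in
  // 0..R-1 for the no-seed layer, R for the seeded layer, -1 for duplex start
  std::vector<int> BPns(NC * R, -1), BPs(NC, -1), BPnsArg(NC * R, -1),
      BPsArg(NC, -1);
  auto enc = [&](int i, int j, int st) { return (int)((cid(i, j)) * (R + 1) + st); };

  double bestE = INF;
  int bestCell = -1;

  for (int i = 1; i <= m; ++i) {
    for (int j = n; j >= 1; --j) {
      const int pij = pt[cid(i, j)];
      if (pij < 0) continue;
      const bool elig = seed_gu || pij < 4;
      const size_t c = cid(i, j);

      // start a new duplex at (i,j)
      {
        int r0 = elig ? 1 : 0;
        if (r0 >= R) {  // seed_len == 1 impossible (checked), keep for safety
          if (p.duplex_init < Es[c]) Es[c] = p.duplex_init;
        } else if (p.duplex_init < Ens[c * R + r0]) {
          Ens[c * R + r0] = p.duplex_init;
          BPns[c * R + r0] = -1;
        }
      }

      // stacked extension from (i-1, j+1)
      if (i > 1 && j < n) {
        const size_t cp = cid(i - 1, j + 1);
        const int q = pt[cp];
        if (q >= 0) {
          const double st = p.stack[q][pij];
          for (int r = 0; r < R; ++r) {
            const double e = Ens[cp * R + r];
            if (e == INF) continue;
            const double e2 = e + st;
            if (elig) {
              const int r2 = r + 1;
              if (r2 >= R) {
                if (e2 < Es[c]) {
                  Es[c] = e2;
                  BPs[c] = enc(i - 1, j + 1, r);
                }
              } else if (e2 < Ens[c * R + r2]) {
                Ens[c * R + r2] = e2;
                BPns[c * R + r2] = enc(i - 1, j + 1, r);
              }
            } else if (e2 < Ens[c * R + 0]) {
              Ens[c * R + 0] = e2;
              BPns[c * R + 0] = enc(i - 1, j + 1, r);
            }
          }
          const double es = Es[cp];
          if (es != INF && es + st < Es[c]) {
            Es[c] = es + st;
            BPs[c] = enc(i - 1, j + 1, R);
          }
        }
      }

      // loop extension from (k,l), gaps 0..max_bulge per side, not both 0
      for (int k = i - 1; k >= std::max(1, i - 1 - max_bulge); --k) {
        const int ga = i - k - 1;
        for (int l = j + 1; l <= std::min(n, j + 1 + max_bulge); ++l) {
          const int gb = l - j - 1;
          if (ga == 0 && gb == 0) continue;
          const size_t cp = cid(k, l);
          if (pt[cp] < 0) continue;
          const double le = p.loop_e(ga, gb);
          // run resets across a loop
          const double ens = EnsMin[cp];
          if (ens != INF) {
            const double e2 = ens + le;
            const int r0 = elig ? 1 : 0;
            if (e2 < Ens[c * R + r0]) {
              Ens[c * R + r0] = e2;
              // find which r attained EnsMin (first hit, deterministic)
              int rarg = -1;
              for (int r = 0; r < R; ++r)
                if (Ens[cp * R + r] == ens) { rarg = r; break; }
              BPns[c * R + r0] = enc(k, l, rarg);
            }
          }
          const double es = Es[cp];
          if (es != INF && es + le < Es[c]) {
            Es[c] = es + le;
            BPs[c] = enc(k, l, R);
          }
        }
      }

      double mn = INF;
      for (int r = 0; r < R; ++r) mn = std::min(mn, Ens[c * R + r]);
      EnsMin[c] = mn;

      if (Es[c] < bestE) {
        bestE = Es[c];
        bestCell = (int)c;
      }
    }
  }

  if (bestCell < 0 || !(bestE < 0.0))
    return List::create(_["found"] = false);

  // reconstruct pairs from the best seeded end cell
  std::vector<int> pi, pj;
  int i = bestCell / (n + 1), j = bestCell % (n + 1), st = R;
  while (true) {
    pi.push_back(i);
    pj.push_back(j);
    const size_t c = cid(i, j);
    int bp = (st == R) ? BPs[c] : BPns[c * R + st];
    if (bp < 0) break;
    const int pst = bp % (R + 1);
    const size_t pc = bp / (R + 1);
    i = (int)(pc / (n + 1));
    j = (int)(pc % (n + 1));
    st = pst;
  }
  const int np = pi.size();
  IntegerMatrix pairing(np, 2);
  for (int t = 0; t < np; ++t) {  // reverse into 5'->3' order on a
    pairing(t, 0) = pi[np - 1 - t];
    pairing(t, 1) = pj[np - 1 - t];
  }
  return List::create(_["found"] = true, _["E"] = bestE,
                      _["pairing"] = pairing);
}

// Scan the antiparallel diagonals of a x b for runs of >= min_run consecutive
// canonical pairs (used for seed anchoring, the synthetic-data sanitizer and
// structural seed verification). With wobble = false, GU/UG do not count.
// [[Rcpp::export(name = ".pair_runs_cpp")]]
IntegerMatrix pair_runs_cpp(IntegerVector aseq, IntegerVector bseq,
                            int min_run, bool wobble = true,
                            Nullable<LogicalVector> forbidden_b =
                                R_NilValue) {
  const int m = aseq.size(), n = bseq.size();
  std::vector<bool> fb(n + 1, false);
  if (forbidden_b.isNotNull()) {
    LogicalVector f(forbidden_b);
    for (int j = 1; j <= n; ++j) fb[j] = f[j - 1];
  }
  std::vector<int> starts_i, starts_j, lens;
  for (int c = 2; c <= m + n; ++c) {  // i + j = c, i ascending, j descending
    int run = 0, ri = 0, rj = 0;
    const int ilo = std::max(1, c - n), ihi = std::min(m, c - 1);
    for (int i = ilo; i <= ihi; ++i) {
      const int j = c - i;
      const int p = fb[j] ? -1 : pair_index(aseq[i - 1], bseq[j - 1]);
      if (p >= 0 && (wobble || p < 4)) {
        if (run == 0) { ri = i; rj = j; }
        ++run;
      } else {
        if (run >= min_run) {
          starts_i.push_back(ri);
          starts_j.push_back(rj);
          lens.push_back(run);
        }
        run = 0;
      }
    }
    if (run >= min_run) {
      starts_i.push_back(ri);
      starts_j.push_back(rj);
      lens.push_back(run);
    }
  }
  IntegerMatrix out(starts_i.size(), 3);
  for (size_t k = 0; k < starts_i.size(); ++k) {
    out(k, 0) = starts_i[k];
    out(k, 1) = starts_j[k];
    out(k, 2) = lens[k];
  }
  colnames(out) = CharacterVector::create("a_start", "b_start", "length");
  return out;
}
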