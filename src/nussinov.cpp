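#include <Rcpp.h>
using namespace Rcpp;

// Pair energy in kcal/mol; values > 0 mark a non-pairable combination.
static inline double pair_energy(char a, char b, double e_gc, double e_au,
                                 double e_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return e_gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return e_au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return e_gu;
  return 1.0;
}

// Nussinov-style minimum free energy over all nested secondary structures.
// E[i][j] = min energy of the subsequence i..j (0-based, inclusive) with a
// minimum hairpin loop of `min_loop` unpaired bases; the open chain scores 0,
// so the result is always <= 0. Sequences must be uppercase RNA (A,C,G,U).
// [[Rcpp::export]]
NumericVector nussinov_mfe(CharacterVector seqs, double e_gc, double e_au,
                           double e_gu, int min_loop) {
  int m = seqs.size();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    std::string q = as<std::string>(seqs[s]);
    int n = (int)q.size();
    if (n < min_loop + 2) {
      out[s] = 0.0;
      continue;
    }
    std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
    for (int len = min_loop + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double best = E[i + 1][j];  // position i left unpaired
        for (int l = i + min_loop + 1; l <= j; ++l) {
          double e = pair_energy(q[i], q[l], e_gc, e_au, e_gu);
          if (e > 0) continue;  // not a valid pair
          double cand = e + E[i + 1][l - 1];
          if (l + 1 <= j) cand += E[l + 1][j];
          if (cand < best) best = cand;
        }
        E[i][j] = best;
      }
    }
    out[s] = E[0][n - 1];
  }
  return out;
}
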