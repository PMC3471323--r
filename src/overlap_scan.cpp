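#include <Rcpp.h>
using namespace Rcpp;

// Nucleotide codes: 1=A, 2=C, 3=G, 4=T, 5=N.
//
// Scores every candidate overlap length c between a forward read and a
// reverse-complemented mate. Positions outside the overlap contribute the
// uniform prior (log 1/4); overlapping positions contribute log_pe when the
// aligned bases agree, log_pu when they disagree, and log 1/4 when either is
// uncalled. The three log terms are computed in R from the closed-form match
// probabilities at the fixed overlap-stage error rate and passed in, so a
// candidate's score is a pure count-weighted sum and ties are exact.
//
// [[Rcpp::export]]
NumericVector overlap_scan_cpp(IntegerVector fwd, IntegerVector rvc,
                               int min_overlap,
                               double log_pe, double log_pu, double log_q) {
  const int lf = fwd.size(), lr = rvc.size();
  const int cmax = lf < lr ? lf : lr;
  if (min_overlap < 1 || cmax < min_overlap) return NumericVector(0);
  const int nc = cmax - min_overlap + 1;
  NumericVector scores(nc);
  for (int c = min_overlap; c <= cmax; ++c) {
    const int f = lf - c, r = lr - c;
    int n_eq = 0, n_ne = 0, n_n = 0;
    for (int i = 0; i < c; ++i) {
      const int x = fwd[f + i], y = rvc[i];
      if (x == 5 || y == 5) ++n_n;
      else if (x == y) ++n_eq;
      else ++n_ne;
    }
    scores[c - min_overlap] =
      (f + r) * log_q + n_eq * log_pe + n_ne * log_pu + n_n * log_q;
  }
  return scores;
}

// Largest overlap length at which every aligned position is an exact,
// called (non-N) match; 0 when no such overlap exists. Backs the naive
// perfect-match merging baseline.
//
// [[Rcpp::export]]
int exact_overlap_cpp(IntegerVector fwd, IntegerVector rvc, int min_overlap) {
  const int lf = fwd.size(), lr = rvc.size();
  const int cmax = lf < lr ? lf : lr;
  for (int c = cmax; c >= min_overlap && c >= 1; --c) {
    const int f = lf - c;
    bool ok = true;
    for (int i = 0; i < c; ++i) {
      const int x = fwd[f + i], y = rvc[i];
      if (x == 5 || y == 5 || x != y) { ok = false; break; }
    }
    if (ok) return c;
  }
  return 0;
}
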