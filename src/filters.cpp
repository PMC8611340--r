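#include <Rcpp.h>
using namespace Rcpp;

// Exponential-decay trajectory over one block.
//   V_t = w0 + sum_{j<=t} wS[g_j] * gamma[g_j]^(t-j) * S_j
// grp is a 0-based group index per stimulus (relevance class); the decay of a
// stimulus' contribution is governed by its own group's gamma, while the
// exponent t-j counts all intervening stimuli. gamma = 0 reproduces the
// "most recent stimulus only" limit because the fresh contribution is added
// after the decay step (0^0 == 1).
// [[Rcpp::export]]
NumericVector ed_filter_cpp(NumericVector s, IntegerVector grp, double w0,
                            NumericVector wS, NumericVector gamma) {
  const int n = s.size(), G = wS.size();
  NumericVector out(n);
  std::vector<double> acc(G, 0.0);
  for (int t = 0; t < n; ++t) {
    for (int g = 0; g < G; ++g) acc[g] *= gamma[g];
    acc[grp[t]] += s[t];
    double v = w0;
    for (int g = 0; g < G; ++g) v += wS[g] * acc[g];
    out[t] = v;
  }
  return out;
}

// Weighted-impact (delta-rule) trajectory over one block.
//   V_t = V_{t-1} + beta[g_t] * (S_t - V_{t-1}),  V at block start = x0
// [[Rcpp::export]]
NumericVector wi_filter_cpp(NumericVector s, IntegerVector grp, double x0,
                            NumericVector beta) {
  const int n = s.size();
  NumericVector out(n);
  double v = x0;
  for (int t = 0; t < n; ++t) {
    v += beta[grp[t]] * (s[t] - v);
    out[t] = v;
  }
  return out;
}
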