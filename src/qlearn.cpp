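#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Tabular Q-learning over an observed transition list.
//
// Transitions are replayed in a freshly shuffled order each sweep; the
// per-pair learning rate follows alpha0 / (1 + decay * n(s,a)) where n is
// the update count of that state-action pair. Iteration stops when the
// largest absolute *net* Q change over a full sweep drops below tol: the
// net change sums every sample of a pair once, so sampling noise around
// the empirical fixed point cancels instead of keeping the loop alive.
//
// s, a, s2 are 1-based; r is the full immediate reward of the transition
// (intermediate penalty plus any terminal bonus of s2). Terminal states
// contribute zero future value. Only admissible pairs are updated; the
// caller filters the transition list accordingly.
// [[Rcpp::export]]
List qlearn_cpp(IntegerVector s, IntegerVector a, IntegerVector s2,
                NumericVector r, int nS, int nA,
                LogicalMatrix admissible, LogicalVector terminal,
                double gamma, double alpha0, double decay,
                double tol, int max_sweeps, int seed) {
  const int m = s.size();
  NumericMatrix Q(nS, nA);
  std::fill(Q.begin(), Q.end(), R_NegInf);
  IntegerMatrix nvisit(nS, nA);
  for (int i = 0; i < nS; ++i)
    for (int j = 0; j < nA; ++j)
      if (admissible(i, j)) Q(i, j) = 0.0;

  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::mt19937 rng(static_cast<unsigned>(seed));

  double max_change = R_PosInf;
  int sweep = 0;
  NumericMatrix Qprev(nS, nA);
  while (sweep < max_sweeps) {
    ++sweep;
    std::copy(Q.begin(), Q.end(), Qprev.begin());
    std::shuffle(order.begin(), order.end(), rng);
    for (int ii = 0; ii < m; ++ii) {
      const int i = order[ii];
      const int si = s[i] - 1, ai = a[i] - 1, sj = s2[i] - 1;
      double vnext = 0.0;
      if (!terminal[sj]) {
        double best = R_NegInf;
        for (int j = 0; j < nA; ++j)
          if (admissible(sj, j) && Q(sj, j) > best) best = Q(sj, j);
        vnext = best;  // every non-terminal state has an admissible action
      }
      const int n = ++nvisit(si, ai);
      const double alpha = alpha0 / (1.0 + decay * (n - 1));
      Q(si, ai) += alpha * (r[i] + gamma * vnext - Q(si, ai));
    }
    max_change = 0.0;
    for (int i = 0; i < nS; ++i)
      for (int j = 0; j < nA; ++j)
        if (admissible(i, j)) {
          const double d = std::fabs(Q(i, j) - Qprev(i, j));
          if (d > max_change) max_change = d;
        }
    if (max_change < tol) break;
  }
  return List::create(_["Q"] = Q, _["sweeps"] = sweep,
                      _["max_change"] = max_change,
                      _["converged"] = max_change < tol);
}
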