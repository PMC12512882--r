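#include <Rcpp.h>
using namespace Rcpp;

// Shared convergence bookkeeping: Gauss-Seidel sweeps update V in place and
// track the per-state change; the sweep stops when either the span or the
// sup-norm of the change vector drops below epsilon * (1 - gamma) / gamma
// (the usual epsilon-optimality bound; plain epsilon when gamma == 0).
static double stop_threshold(double gamma, double epsilon) {
  return (gamma > 0.0) ? epsilon * (1.0 - gamma) / gamma : epsilon;
}

static bool sweep_converged(const std::vector<double>& delta, bool span_crit,
                            double thresh) {
  double mx = delta[0], mn = delta[0];
  for (size_t s = 1; s < delta.size(); ++s) {
    if (delta[s] > mx) mx = delta[s];
    if (delta[s] < mn) mn = delta[s];
  }
  double err = span_crit ? (mx - mn) : std::max(std::fabs(mx), std::fabs(mn));
  return err < thresh;
}

// Generic Gauss-Seidel value iteration over a ragged sparse successor
// structure. succ/prob hold the concatenated successor lists for all
// (state, action) pairs; offset[k]..offset[k+1]-1 indexes the list of pair
// k = s * A + a. All indices 0-based.
// [[Rcpp::export]]
List gs_vi_sparse_cpp(NumericMatrix R, IntegerVector succ, NumericVector prob,
                      IntegerVector offset, double gamma, double epsilon,
                      int max_iter, bool span_crit) {
  const int S = R.nrow(), A = R.ncol();
  std::vector<double> V(S, 0.0), delta(S, 0.0);
  const double thresh = stop_threshold(gamma, epsilon);
  int iter = 0;
  bool converged = false;
  while (iter < max_iter && !converged) {
    ++iter;
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf;
      for (int a = 0; a < A; ++a) {
        const int k = s * A + a;
        double q = R(s, a);
        for (int t = offset[k]; t < offset[k + 1]; ++t)
          q += gamma * prob[t] * V[succ[t]];
        if (q > best) best = q;
      }
      delta[s] = best - V[s];
      V[s] = best;
    }
    converged = sweep_converged(delta, span_crit, thresh);
  }
  NumericMatrix Q(S, A);
  for (int s = 0; s < S; ++s) {
    for (int a = 0; a < A; ++a) {
      const int k = s * A + a;
      double q = R(s, a);
      for (int t = offset[k]; t < offset[k + 1]; ++t)
        q += gamma * prob[t] * V[succ[t]];
      Q(s, a) = q;
    }
  }
  return List::create(_["V"] = NumericVector(V.begin(), V.end()),
                      _["Q"] = Q, _["iterations"] = iter,
                      _["converged"] = converged);
}

// Factored kernel: states are (uf configuration, competency configuration)
// with index s = uf * n_ec + ec (uf high-order). Competency successors are
// deterministic (ecnext, 0-based ec index per state-action); the next uf
// configuration is drawn from P(uf' | uf, group(a)), stored as an
// n_uf x n_groups x n_uf array in R's column-major layout.
// [[Rcpp::export]]
List gs_vi_factored_cpp(NumericMatrix R, IntegerMatrix ecnext, NumericVector P,
                        IntegerVector group, int n_ec, double gamma,
                        double epsilon, int max_iter, bool span_crit) {
  const int S = R.nrow(), A = R.ncol();
  const int n_uf = S / n_ec;
  const int n_groups = P.size() / (n_uf * n_uf);
  std::vector<double> V(S, 0.0), delta(S, 0.0);
  const double thresh = stop_threshold(gamma, epsilon);
  int iter = 0;
  bool converged = false;
  while (iter < max_iter && !converged) {
    ++iter;
    for (int s = 0; s < S; ++s) {
      const int uf = s / n_ec;
      double best = R_NegInf;
      for (int a = 0; a < A; ++a) {
        const int g = group[a];
        double q = R(s, a);
        const int ecn = ecnext(s, a);
        for (int ufn = 0; ufn < n_uf; ++ufn) {
          const double p = P[uf + n_uf * (g + n_groups * ufn)];
          if (p > 0.0) q += gamma * p * V[ufn * n_ec + ecn];
        }
        if (q > best) best = q;
      }
      delta[s] = best - V[s];
      V[s] = best;
    }
    converged = sweep_converged(delta, span_crit, thresh);
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix Q(S, A);
  for (int s = 0; s < S; ++s) {
    const int uf = s / n_ec;
    for (int a = 0; a < A; ++a) {
      const int g = group[a];
      double q = R(s, a);
      const int ecn = ecnext(s, a);
      for (int ufn = 0; ufn < n_uf; ++ufn) {
        const double p = P[uf + n_uf * (g + n_groups * ufn)];
        if (p > 0.0) q += gamma * p * V[ufn * n_ec + ecn];
      }
      Q(s, a) = q;
    }
  }
  return List::create(_["V"] = NumericVector(V.begin(), V.end()),
                      _["Q"] = Q, _["iterations"] = iter,
                      _["converged"] = converged);
}
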