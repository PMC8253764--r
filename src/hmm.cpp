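#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward pass for one sequence. obs is 0-based symbol indices.
// Fills alpha (T x S, scaled so each row sums to 1) and scale (length T).
// Returns log-likelihood, or -Inf if the sequence has probability zero.
static double forward_scaled(const std::vector<int>& obs,
                             const NumericVector& pi,
                             const NumericMatrix& A,
                             const NumericMatrix& B,
                             NumericMatrix& alpha,
                             NumericVector& scale) {
  const int T = obs.size(), S = pi.size();
  double ll = 0.0;
  double c = 0.0;
  for (int i = 0; i < S; ++i) {
    alpha(0, i) = pi[i] * B(i, obs[0]);
    c += alpha(0, i);
  }
  if (c <= 0.0) return R_NegInf;
  scale[0] = c;
  for (int i = 0; i < S; ++i) alpha(0, i) /= c;
  ll += std::log(c);
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < S; ++j) {
      double s = 0.0;
      for (int i = 0; i < S; ++i) s += alpha(t - 1, i) * A(i, j);
      double v = s * B(j, obs[t]);
      alpha(t, j) = v;
      c += v;
    }
    if (c <= 0.0) return R_NegInf;
    scale[t] = c;
    for (int j = 0; j < S; ++j) alpha(t, j) /= c;
    ll += std::log(c);
  }
  return ll;
}

// Scaled backward pass using the forward scaling constants.
static void backward_scaled(const std::vector<int>& obs,
                            const NumericMatrix& A,
                            const NumericMatrix& B,
                            const NumericVector& scale,
                            NumericMatrix& beta) {
  const int T = obs.size(), S = A.nrow();
  for (int i = 0; i < S; ++i) beta(T - 1, i) = 1.0 / scale[T - 1];
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < S; ++i) {
      double s = 0.0;
      for (int j = 0; j < S; ++j)
        s += A(i, j) * B(j, obs[t + 1]) * beta(t + 1, j);
      beta(t, i) = s / scale[t];
    }
  }
}

static std::vector<std::vector<int> > as_obs(const List& seqs) {
  std::vector<std::vector<int> > out;
  out.reserve(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) {
    IntegerVector v = seqs[k];
    out.push_back(std::vector<int>(v.begin(), v.end()));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_loglik(List seqs, NumericVector pi, NumericMatrix A,
                         NumericMatrix B) {
  std::vector<std::vector<int> > obs = as_obs(seqs);
  const int S = pi.size();
  NumericVector out(obs.size());
  for (size_t k = 0; k < obs.size(); ++k) {
    NumericMatrix alpha(obs[k].size(), S);
    NumericVector scale(obs[k].size());
    out[k] = forward_scaled(obs[k], pi, A, B, alpha, scale);
  }
  return out;
}

// Baum-Welch EM across a corpus of sequences. Sufficient statistics are
// summed over sequences each iteration. Returns the final parameters, the
// per-iteration log-likelihood trace and a convergence flag.
// [[Rcpp::export]]
List cpp_baum_welch(List seqs, NumericVector pi0, NumericMatrix A0,
                    NumericMatrix B0, int max_iter, double tol) {
  std::vector<std::vector<int> > obs = as_obs(seqs);
  const int S = pi0.size(), M = B0.ncol();
  NumericVector pi = clone(pi0);
  NumericMatrix A = clone(A0), B = clone(B0);
  std::vector<double> trace;
  bool converged = false;
  double prev_ll = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    NumericVector pi_acc(S);
    NumericMatrix A_num(S, S), B_num(S, M);
    NumericVector A_den(S), B_den(S);
    double total_ll = 0.0;

    for (size_t k = 0; k < obs.size(); ++k) {
      const std::vector<int>& o = obs[k];
      const int T = o.size();
      NumericMatrix alpha(T, S), beta(T, S);
      NumericVector scale(T);
      double ll = forward_scaled(o, pi, A, B, alpha, scale);
      if (!R_finite(ll)) {
        return List::create(_["pi"] = pi, _["A"] = A, _["B"] = B,
                            _["loglik"] = R_NegInf,
                            _["trace"] = NumericVector(trace.begin(), trace.end()),
                            _["converged"] = false, _["iterations"] = iter,
                            _["zero_prob"] = true);
      }
      total_ll += ll;
      backward_scaled(o, A, B, scale, beta);

      // gamma_t(i) = alpha_t(i) * beta_t(i) * scale_t  (already normalized)
      for (int i = 0; i < S; ++i)
        pi_acc[i] += alpha(0, i) * beta(0, i) * scale[0];
      for (int t = 0; t < T; ++t) {
        for (int i = 0; i < S; ++i) {
          double g = alpha(t, i) * beta(t, i) * scale[t];
          B_num(i, o[t]) += g;
          B_den[i] += g;
          if (t < T - 1) A_den[i] += g;
        }
      }
      for (int t = 0; t < T - 1; ++t) {
        for (int i = 0; i < S; ++i) {
          double ai = alpha(t, i);
          if (ai == 0.0) continue;
          for (int j = 0; j < S; ++j) {
            // xi_t(i,j); beta already carries 1/scale_{t+1}
            A_num(i, j) += ai * A(i, j) * B(j, o[t + 1]) * beta(t + 1, j);
          }
        }
      }
    }

    trace.push_back(total_ll);
    // M-step
    double pisum = 0.0;
    for (int i = 0; i < S; ++i) pisum += pi_acc[i];
    for (int i = 0; i < S; ++i) pi[i] = pi_acc[i] / pisum;
    for (int i = 0; i < S; ++i) {
      if (A_den[i] > 0.0)
        for (int j = 0; j < S; ++j) A(i, j) = A_num(i, j) / A_den[i];
      if (B_den[i] > 0.0)
        for (int m = 0; m < M; ++m) B(i, m) = B_num(i, m) / B_den[i];
    }

    if (iter > 0 && std::fabs(total_ll - prev_ll) < tol) {
      converged = true;
      prev_ll = total_ll;
      break;
    }
    prev_ll = total_ll;
  }

  // log-likelihood of the final (post M-step) parameters
  double final_ll = 0.0;
  for (size_t k = 0; k < obs.size(); ++k) {
    NumericMatrix alpha(obs[k].size(), S);
    NumericVector scale(obs[k].size());
    final_ll += forward_scaled(obs[k], pi, A, B, alpha, scale);
  }

  return List::create(_["pi"] = pi, _["A"] = A, _["B"] = B,
                      _["loglik"] = final_ll,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged,
                      _["iterations"] = (int)trace.size(),
                      _["zero_prob"] = false);
}

// Log-space Viterbi. Ties broken toward the lower state index at every
// maximization (including the final state), so an all-uniform model decodes
// to the constant lowest state.
// [[Rcpp::export]]
List cpp_viterbi(IntegerVector obs, NumericVector pi, NumericMatrix A,
                 NumericMatrix B) {
  const int T = obs.size(), S = pi.size();
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);
  for (int i = 0; i < S; ++i)
    delta(0, i) = std::log(pi[i]) + std::log(B(i, obs[0]));
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        double v = delta(t - 1, i) + std::log(A(i, j));
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + std::log(B(j, obs[t]));
      psi(t, j) = arg;
    }
  }
  double best = R_NegInf;
  int arg = 0, first_impossible = -1;
  for (int i = 0; i < S; ++i)
    if (delta(T - 1, i) > best) { best = delta(T - 1, i); arg = i; }
  if (!R_finite(best)) {
    // locate the first position where every state dies
    for (int t = 0; t < T && first_impossible < 0; ++t) {
      bool any = false;
      for (int i = 0; i < S; ++i) if (R_finite(delta(t, i))) any = true;
      if (!any) first_impossible = t + 1;  // 1-based
    }
  }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return List::create(_["path"] = path, _["logprob"] = best,
                      _["first_impossible"] = first_impossible);
}
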