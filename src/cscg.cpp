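// Clone-structured causal graph (cloned HMM) inference core.
//
// States are grouped in contiguous clone blocks: symbol s owns states
// [s*M, s*M + M). Emissions are deterministic (state i emits its block's
// symbol with probability 1), so forward/backward messages live on the
// M states of the observed symbol at each step; the scaled recursions below
// exploit that and never touch states outside the active blocks.

#include <Rcpp.h>
using namespace Rcpp;

// scaled forward-backward on one sequence.
// x: 0-based symbol indices. Accumulates transition counts into `counts`
// (S x S) and initial-state counts into `pi_counts` when provided.
// Returns log-likelihood; fills gamma (N x S, dense) if gamma != nullptr.
static double fb_one(const NumericMatrix& T, const NumericVector& pi,
                     const IntegerVector& x, const int M,
                     NumericMatrix* counts, NumericVector* pi_counts,
                     NumericMatrix* gamma) {
  const int N = x.size();
  NumericMatrix alpha(N, M);
  NumericVector cs(N);

  int b0 = x[0] * M;
  double c = 0.0;
  for (int j = 0; j < M; ++j) { alpha(0, j) = pi[b0 + j]; c += alpha(0, j); }
  if (c <= 0) return R_NegInf;
  for (int j = 0; j < M; ++j) alpha(0, j) /= c;
  cs[0] = c;

  for (int n = 1; n < N; ++n) {
    const int bp = x[n - 1] * M, bc = x[n] * M;
    c = 0.0;
    for (int j = 0; j < M; ++j) {
      double a = 0.0;
      for (int i = 0; i < M; ++i) a += alpha(n - 1, i) * T(bp + i, bc + j);
      alpha(n, j) = a;
      c += a;
    }
    if (c <= 0) return R_NegInf;
    for (int j = 0; j < M; ++j) alpha(n, j) /= c;
    cs[n] = c;
  }

  double ll = 0.0;
  for (int n = 0; n < N; ++n) ll += std::log(cs[n]);

  // backward pass with the same scaling
  NumericVector beta(M, 1.0), beta_next(M);
  if (gamma) {
    const int bN = x[N - 1] * M;
    for (int i = 0; i < M; ++i) (*gamma)(N - 1, bN + i) = alpha(N - 1, i);
  }
  for (int n = N - 2; n >= 0; --n) {
    const int bc = x[n] * M, bn = x[n + 1] * M;
    for (int j = 0; j < M; ++j) beta_next[j] = beta[j];
    for (int i = 0; i < M; ++i) {
      double b = 0.0;
      for (int j = 0; j < M; ++j) b += T(bc + i, bn + j) * beta_next[j];
      beta[i] = b / cs[n + 1];
    }
    if (counts) {
      for (int i = 0; i < M; ++i) {
        const double ai = alpha(n, i);
        if (ai == 0) continue;
        for (int j = 0; j < M; ++j)
          (*counts)(bc + i, bn + j) +=
            ai * T(bc + i, bn + j) * beta_next[j] / cs[n + 1];
      }
    }
    if (gamma)
      for (int i = 0; i < M; ++i) (*gamma)(n, bc + i) = alpha(n, i) * beta[i];
  }
  if (pi_counts) {
    const int b = x[0] * M;
    for (int i = 0; i < M; ++i) (*pi_counts)[b + i] += alpha(0, i) * beta[i];
  }
  return ll;
}

// [[Rcpp::export]]
List cscg_fb_cpp(const NumericMatrix T, const NumericVector pi,
                 const IntegerVector x, const int M) {
  const int S = T.nrow(), N = x.size();
  NumericMatrix gamma(N, S), counts(S, S);
  double ll = fb_one(T, pi, x, M, &counts, nullptr, &gamma);
  return List::create(_["gamma"] = gamma, _["loglik"] = ll,
                      _["xi_counts"] = counts);
}

// n_iters EM iterations over a batch of sequences. Log-likelihoods are
// recorded under the transition matrix in force at the *start* of each
// iteration, so the returned series must be non-decreasing.
// [[Rcpp::export]]
List cscg_em_cpp(NumericMatrix T, NumericVector pi, const List seqs,
                 const int M, const int n_iters, const double pseudo,
                 const bool update_pi) {
  const int S = T.nrow();
  if (seqs.size() == 0) stop("empty batch");
  NumericMatrix Tcur = clone(T);
  NumericVector picur = clone(pi);
  NumericVector lls(n_iters);

  for (int it = 0; it < n_iters; ++it) {
    NumericMatrix counts(S, S);
    NumericVector pic(S);
    double total = 0.0;
    for (int s = 0; s < seqs.size(); ++s) {
      IntegerVector x = seqs[s];
      total += fb_one(Tcur, picur, x, M, &counts, update_pi ? &pic : nullptr,
                      nullptr);
    }
    lls[it] = total;
    for (int i = 0; i < S; ++i) {
      double rs = 0.0;
      for (int j = 0; j < S; ++j) rs += counts(i, j) + pseudo;
      for (int j = 0; j < S; ++j) Tcur(i, j) = (counts(i, j) + pseudo) / rs;
    }
    if (update_pi) {
      double ps = 0.0;
      for (int i = 0; i < S; ++i) ps += pic[i] + pseudo;
      for (int i = 0; i < S; ++i) picur[i] = (pic[i] + pseudo) / ps;
    }
  }
  return List::create(_["T"] = Tcur, _["pi"] = picur, _["loglik"] = lls);
}

// Viterbi path (0-based state ids). Ties broken toward the lowest state id.
// [[Rcpp::export]]
List cscg_viterbi_cpp(const NumericMatrix T, const NumericVector pi,
                      const IntegerVector x, const int M) {
  const int N = x.size();
  NumericMatrix delta(N, M);
  IntegerMatrix psi(N, M);
  const int b0 = x[0] * M;
  for (int j = 0; j < M; ++j)
    delta(0, j) = pi[b0 + j] > 0 ? std::log(pi[b0 + j]) : R_NegInf;
  for (int n = 1; n < N; ++n) {
    const int bp = x[n - 1] * M, bc = x[n] * M;
    for (int j = 0; j < M; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < M; ++i) {
        const double tij = T(bp + i, bc + j);
        const double v = delta(n - 1, i) +
          (tij > 0 ? std::log(tij) : R_NegInf);
        if (v > best) { best = v; arg = i; }  // strict > keeps lowest id
      }
      delta(n, j) = best;
      psi(n, j) = arg;
    }
  }
  double best = R_NegInf;
  int arg = 0;
  for (int j = 0; j < M; ++j)
    if (delta(N - 1, j) > best) { best = delta(N - 1, j); arg = j; }
  IntegerVector path(N);
  path[N - 1] = x[N - 1] * M + arg;
  int cur = arg;
  for (int n = N - 1; n > 0; --n) {
    cur = psi(n, cur);
    path[n - 1] = x[n - 1] * M + cur;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Hard-assignment (Viterbi) re-estimation of T over a set of sequences.
// [[Rcpp::export]]
List cscg_viterbi_train_cpp(NumericMatrix T, NumericVector pi,
                            const List seqs, const int M, const int n_iters,
                            const double pseudo, const bool update_pi) {
  const int S = T.nrow();
  NumericMatrix Tcur = clone(T);
  NumericVector picur = clone(pi);
  NumericVector lps(n_iters);
  for (int it = 0; it < n_iters; ++it) {
    NumericMatrix counts(S, S);
    NumericVector pic(S);
    double total = 0.0;
    for (int s = 0; s < seqs.size(); ++s) {
      IntegerVector x = seqs[s];
      List v = cscg_viterbi_cpp(Tcur, picur, x, M);
      total += as<double>(v["logprob"]);
      IntegerVector path = v["path"];
      for (int n = 0; n + 1 < path.size(); ++n)
        counts(path[n], path[n + 1]) += 1.0;
      pic[path[0]] += 1.0;
    }
    lps[it] = total;
    for (int i = 0; i < S; ++i) {
      double rs = 0.0;
      for (int j = 0; j < S; ++j) rs += counts(i, j) + pseudo;
      for (int j = 0; j < S; ++j) Tcur(i, j) = (counts(i, j) + pseudo) / rs;
    }
    if (update_pi) {
      double ps = 0.0;
      for (int i = 0; i < S; ++i) ps += pic[i] + pseudo;
      for (int i = 0; i < S; ++i) picur[i] = (pic[i] + pseudo) / ps;
    }
  }
  return List::create(_["T"] = Tcur, _["pi"] = picur, _["logprob"] = lps);
}

// forward-filtered (causal) state occupancies: normalized alpha, N x S
// [[Rcpp::export]]
NumericMatrix cscg_filter_cpp(const NumericMatrix T, const NumericVector pi,
                              const IntegerVector x, const int M) {
  const int S = T.nrow(), N = x.size();
  NumericMatrix out(N, S);
  NumericVector a(M), anew(M);
  const int b0 = x[0] * M;
  double c = 0.0;
  for (int j = 0; j < M; ++j) { a[j] = pi[b0 + j]; c += a[j]; }
  if (c <= 0) stop("zero-probability sequence start");
  for (int j = 0; j < M; ++j) { a[j] /= c; out(0, b0 + j) = a[j]; }
  for (int n = 1; n < N; ++n) {
    const int bp = x[n - 1] * M, bc = x[n] * M;
    c = 0.0;
    for (int j = 0; j < M; ++j) {
      double v = 0.0;
      for (int i = 0; i < M; ++i) v += a[i] * T(bp + i, bc + j);
      anew[j] = v;
      c += v;
    }
    if (c <= 0) stop("zero-probability transition at step ", n + 1);
    for (int j = 0; j < M; ++j) { a[j] = anew[j] / c; out(n, bc + j) = a[j]; }
  }
  return out;
}
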