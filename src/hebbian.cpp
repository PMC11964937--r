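// Spiking soft-winner-take-all network with a local Hebbian rule,
// simulated at a 1-ms resolution. Uses R's RNG so runs are reproducible
// under set.seed().
//
// Per 1-ms step t (stimulus held for ms_per_symbol steps):
//   x_trace <- x_trace * exp(-dt/tau) + input_spikes(t)
//   u_k = sum_i W[k,i] x_trace_i + sum_j V[k,j] y_trace_j   (y through t-1)
//   f = softmax(u); spike_k ~ Bernoulli(f_k) unless refractory
//   plasticity (rows with a postsynaptic spike only, traces pre-update):
//     W[k,] += alpha * (exp(-W[k,]) * x_trace - offset), clipped at 0
//     V[k,] += alpha * (exp(-V[k,]) * y_trace - offset), clipped at 0
//   y_trace <- y_trace * exp(-dt/tau) + spikes; refractory clocks advance.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List hebbian_run_cpp(const NumericMatrix W0, const NumericMatrix V0,
                     const IntegerVector schedule,   // stimulus index per step
                     const int group_size, const int ms_per_symbol,
                     const double tau_ms, const int refractory_ms,
                     const double alpha, const double offset,
                     const double input_prob,        // per-ms Bernoulli rate
                     const bool plastic,
                     const NumericVector xtr0, const NumericVector ytr0,
                     const IntegerVector refrac0,
                     const bool record_detail,
                     Nullable<IntegerMatrix> input_spikes_ = R_NilValue) {
  const int K = W0.nrow(), n_in = W0.ncol();
  const int n_steps = schedule.size();
  const long total_ms = (long)n_steps * ms_per_symbol;
  const double decay = std::exp(-1.0 / tau_ms);

  NumericMatrix W = clone(W0), V = clone(V0);
  NumericVector xtr = clone(xtr0), ytr = clone(ytr0);
  IntegerVector refrac = clone(refrac0);
  NumericVector u(K), f(K);
  IntegerVector spk(K);

  NumericMatrix pos_counts(K, n_steps);  // spikes per neuron per symbol step
  IntegerMatrix raster, xin;
  NumericMatrix fhist, xtrh, ytrh;
  if (record_detail) {
    raster = IntegerMatrix(K, total_ms);
    xin = IntegerMatrix(n_in, total_ms);
    fhist = NumericMatrix(K, total_ms);
    xtrh = NumericMatrix(n_in, total_ms);
    ytrh = NumericMatrix(K, total_ms);
  }
  const bool given_input = input_spikes_.isNotNull();
  IntegerMatrix given;
  if (given_input) {
    given = IntegerMatrix(input_spikes_);
    if (given.nrow() != n_in || given.ncol() != total_ms)
      stop("input_spikes must be n_inputs x total_ms");
  }

  GetRNGstate();
  for (long t = 0; t < total_ms; ++t) {
    const int step = (int)(t / ms_per_symbol);
    const int stim = schedule[step];
    const int gstart = stim * group_size;

    // input spikes and x trace
    for (int i = 0; i < n_in; ++i) {
      int s = 0;
      if (given_input) {
        s = given(i, t);
      } else if (i >= gstart && i < gstart + group_size) {
        s = (unif_rand() < input_prob) ? 1 : 0;
      }
      xtr[i] = xtr[i] * decay + s;
      if (record_detail) { xin(i, t) = s; xtrh(i, t) = xtr[i]; }
    }

    // membrane potential and softmax firing probability
    double umax = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double uk = 0.0;
      for (int i = 0; i < n_in; ++i) uk += W(k, i) * xtr[i];
      for (int j = 0; j < K; ++j) uk += V(k, j) * ytr[j];
      u[k] = uk;
      if (uk > umax) umax = uk;
    }
    double z = 0.0;
    for (int k = 0; k < K; ++k) { f[k] = std::exp(u[k] - umax); z += f[k]; }
    for (int k = 0; k < K; ++k) f[k] /= z;

    // spike generation with refractoriness
    for (int k = 0; k < K; ++k) {
      spk[k] = (refrac[k] == 0 && unif_rand() < f[k]) ? 1 : 0;
      if (record_detail) { raster(k, t) = spk[k]; fhist(k, t) = f[k]; }
      if (spk[k]) pos_counts(k, step) += 1.0;
    }

    // local Hebbian updates on rows with a postsynaptic spike
    if (plastic) {
      for (int k = 0; k < K; ++k) {
        if (!spk[k]) continue;
        for (int i = 0; i < n_in; ++i) {
          double w = W(k, i) + alpha * (std::exp(-W(k, i)) * xtr[i] - offset);
          W(k, i) = w > 0 ? w : 0.0;
        }
        for (int j = 0; j < K; ++j) {
          double v = V(k, j) + alpha * (std::exp(-V(k, j)) * ytr[j] - offset);
          V(k, j) = v > 0 ? v : 0.0;
        }
      }
    }

    // recurrent trace and refractory clocks
    for (int k = 0; k < K; ++k) {
      ytr[k] = ytr[k] * decay + spk[k];
      if (record_detail) ytrh(k, t) = ytr[k];
      if (spk[k]) refrac[k] = refractory_ms;
      else if (refrac[k] > 0) refrac[k] -= 1;
    }
  }
  PutRNGstate();

  List out = List::create(_["W"] = W, _["V"] = V, _["x_trace"] = xtr,
                          _["y_trace"] = ytr, _["refractory"] = refrac,
                          _["pos_counts"] = pos_counts);
  if (record_detail) {
    out["raster"] = raster;
    out["input_raster"] = xin;
    out["f_history"] = fhist;
    out["x_trace_history"] = xtrh;
    out["y_trace_history"] = ytrh;
  }
  return out;
}

// rolling min/max over a centred window (used by the maximin dF/F0 baseline)
// [[Rcpp::export]]
NumericVector roll_extreme_cpp(const NumericVector x, const int window,
                               const bool do_max) {
  const int n = x.size();
  NumericVector out(n);
  const int half = window / 2;
  for (int i = 0; i < n; ++i) {
    int lo = i - half; if (lo < 0) lo = 0;
    int hi = i + half; if (hi >= n) hi = n - 1;
    double v = x[lo];
    for (int j = lo + 1; j <= hi; ++j)
      if (do_max ? (x[j] > v) : (x[j] < v)) v = x[j];
    out[i] = v;
  }
  return out;
}
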