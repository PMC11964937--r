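#' Parameters for the spiking soft-WTA Hebbian network
#'
#' A recurrent network of `K` spiking neurons driven by `n_stimuli *
#' group_size` feedforward input neurons, with global softmax (soft
#' winner-take-all) inhibition. Each of the 8 sensory stimuli drives its own
#' disjoint group of 12 input neurons (96 inputs in total). Spike trains are
#' exponentially filtered (time constant 20 ms), the simulation advances in
#' 1-ms steps, neurons are refractory for 10 ms after a spike, and when a
#' neuron spikes its afferent weights move by
#' `alpha * (exp(-w) * trace - offset)` with `alpha = 0.1`, `offset = 0.1`,
#' clipped at zero so all weights stay excitatory. Feedforward weights start
#' at N(0, 3.5^2) and recurrent weights at N(0, 2.5^2), clipped at zero.
#'
#' @param K recurrent neurons (default 100).
#' @param n_stimuli distinct sensory stimuli (default 8).
#' @param group_size input neurons per stimulus (default 12).
#' @param tau_ms trace time constant, ms (default 20).
#' @param refractory_ms refractory period, ms (default 10).
#' @param alpha Hebbian learning rate (default 0.1).
#' @param offset plasticity offset (default 0.1).
#' @param input_rate_hz Poisson rate of active input neurons (default 50).
#' @param ms_per_symbol stimulus presentation time per track segment, ms
#'   (default 20, about one trace time constant, so that context-selected
#'   winners rather than whole stimulus assemblies dominate each segment).
#' @param sd_w,sd_v initialization s.d. of feedforward / recurrent weights.
#' @return a list of class `spiking_net_params`.
#' @export
spiking_net_params <- function(K = 100, n_stimuli = 8, group_size = 12,
                               tau_ms = 20, refractory_ms = 10, alpha = 0.1,
                               offset = 0.1, input_rate_hz = 50,
                               ms_per_symbol = 20, sd_w = 3.5, sd_v = 2.5) {
  stopifnot(K >= 1, n_stimuli >= 1, group_size >= 1, tau_ms > 0)
  structure(list(K = as.integer(K), n_stimuli = as.integer(n_stimuli),
                 group_size = as.integer(group_size),
                 n_inputs = as.integer(n_stimuli * group_size),
                 tau_ms = tau_ms,
                 refractory_ms = refractory_ms, alpha = alpha,
                 offset = offset, input_rate_hz = input_rate_hz,
                 ms_per_symbol = ms_per_symbol, sd_w = sd_w, sd_v = sd_v),
            class = "spiking_net_params")
}

#' Initialize the spiking network state
#'
#' @param params a `spiking_net_params`.
#' @param seed seed for the weight initialization.
#' @return an object of class `spiking_net_state`: list with `W` (K x
#'   n_inputs feedforward), `V` (K x K recurrent), filtered traces
#'   `x_trace`, `y_trace`, per-neuron `refractory` clocks, and `params`.
#' @export
init_spiking_net <- function(params = spiking_net_params(), seed = 1L) {
  local_rng(seed)
  W <- matrix(pmax(0, rnorm(params$K * params$n_inputs, 0, params$sd_w)),
              params$K, params$n_inputs)
  V <- matrix(pmax(0, rnorm(params$K * params$K, 0, params$sd_v)),
              params$K, params$K)
  structure(list(W = W, V = V,
                 x_trace = rep(0, params$n_inputs),
                 y_trace = rep(0, params$K),
                 refractory = rep(0L, params$K),
                 params = params, seed = seed),
            class = "spiking_net_state")
}

#' @export
print.spiking_net_state <- function(x, ...) {
  cat(sprintf("<spiking_net_state> K=%d, inputs=%d (%d stimuli x %d)\n",
              x$params$K, x$params$n_inputs, x$params$n_stimuli,
              x$params$group_size))
  invisible(x)
}

#' Encode a stimulus as input spike trains
#'
#' Inputs are orthogonal across stimuli: symbol `j` drives only its dedicated
#' group of `group_size` neurons, each firing as an independent Poisson
#' (Bernoulli per 1-ms step) process at `input_rate_hz`.
#'
#' @param symbol symbol id in `0:(n_stimuli - 1)`.
#' @param params a `spiking_net_params`.
#' @param n_ms number of 1-ms steps to generate.
#' @param seed optional seed.
#' @return binary matrix `n_inputs x n_ms`.
#' @export
encode_stimulus <- function(symbol, params = spiking_net_params(),
                            n_ms = params$ms_per_symbol, seed = NULL) {
  if (!(symbol %in% 0:(params$n_stimuli - 1)))
    stop("symbol outside the stimulus alphabet: ", symbol)
  local_rng(seed)
  out <- matrix(0L, params$n_inputs, n_ms)
  grp <- symbol * params$group_size + seq_len(params$group_size)
  p <- params$input_rate_hz / 1000
  out[grp, ] <- matrix(rbinom(length(grp) * n_ms, 1L, p), length(grp), n_ms)
  out
}

run_hebbian_core <- function(state, schedule, plastic, record_detail,
                             input_spikes = NULL, ms_per_symbol = NULL) {
  p <- state$params
  if (is.null(ms_per_symbol)) ms_per_symbol <- p$ms_per_symbol
  if (ms_per_symbol < 1) stop("ms_per_symbol must be >= 1 ms")
  hebbian_run_cpp(state$W, state$V, as.integer(schedule), p$group_size,
                  as.integer(ms_per_symbol), p$tau_ms,
                  as.integer(p$refractory_ms), p$alpha, p$offset,
                  p$input_rate_hz / 1000, plastic,
                  state$x_trace, state$y_trace, state$refractory,
                  record_detail, input_spikes)
}

#' Advance the network by one stimulus presentation
#'
#' Runs `n_ms` 1-ms updates under one stimulus (or externally supplied input
#' spikes), recording membrane softmax probabilities, spike rasters and
#' filtered traces. Plasticity is optional so pure dynamics can be examined.
#'
#' @param state a `spiking_net_state`.
#' @param symbol stimulus id presented during the step.
#' @param n_ms duration in ms (default 1: a single elementary update).
#' @param plastic apply the Hebbian rule (default TRUE).
#' @param input_spikes optional binary `n_inputs x n_ms` matrix overriding
#'   internal Poisson input generation.
#' @return list with the updated `state` and `record` (`raster`,
#'   `f_history`, `x_trace_history`, `y_trace_history`, `input_raster`).
#' @export
hebbian_step <- function(state, symbol, n_ms = 1, plastic = TRUE,
                         input_spikes = NULL) {
  res <- run_hebbian_core(state, rep(as.integer(symbol), 1), plastic,
                          record_detail = TRUE, input_spikes = input_spikes,
                          ms_per_symbol = n_ms)
  state$W <- res$W; state$V <- res$V
  state$x_trace <- res$x_trace; state$y_trace <- res$y_trace
  state$refractory <- res$refractory
  list(state = state,
       record = res[c("raster", "f_history", "x_trace_history",
                      "y_trace_history", "input_raster")])
}

#' Run the spiking network over a symbol schedule
#'
#' Presents each symbol of each trial for `ms_per_symbol` milliseconds while
#' the Hebbian rule shapes the weights (unless `plastic = FALSE`), and logs
#' per-neuron spike counts for every symbol step. Deterministic given the
#' seed.
#'
#' @param state a `spiking_net_state`.
#' @param schedule a `session_schedule` (cscg dialect) or list of
#'   `trial_sequence`; symbols must be in `0:(n_stimuli-1)`.
#' @param ms_per_symbol presentation time per symbol (default from params).
#' @param plastic apply plasticity (default TRUE).
#' @param seed seed for all spiking randomness.
#' @param record_detail also return full rasters and traces (memory-heavy;
#'   for short runs only).
#' @return list of class `hebbian_run`: updated `state`, `counts` (K x total
#'   symbol steps spike counts), `trial_types`, `trial_lengths`, and the
#'   detail records when requested.
#' @export
run_session <- function(state, schedule, ms_per_symbol = NULL, plastic = TRUE,
                        seed = NULL, record_detail = FALSE) {
  trials <- if (inherits(schedule, "session_schedule")) schedule$trials
            else schedule
  if (length(trials) == 0) stop("empty schedule")
  sym <- unlist(lapply(trials, function(tr)
    if (inherits(tr, "trial_sequence")) tr$symbols else as.integer(tr)))
  if (any(sym < 0 | sym >= state$params$n_stimuli))
    stop("schedule symbol outside the stimulus alphabet")
  local_rng(seed)
  res <- run_hebbian_core(state, sym, plastic, record_detail,
                          ms_per_symbol = ms_per_symbol)
  state$W <- res$W; state$V <- res$V
  state$x_trace <- res$x_trace; state$y_trace <- res$y_trace
  state$refractory <- res$refractory
  out <- list(state = state, counts = res$pos_counts,
              trial_types = vapply(trials, function(tr)
                if (inherits(tr, "trial_sequence")) tr$trial_type
                else NA_character_, ""),
              trial_lengths = vapply(trials, function(tr)
                if (inherits(tr, "trial_sequence")) length(tr$symbols)
                else length(tr), 0L))
  if (record_detail)
    out <- c(out, res[c("raster", "input_raster", "f_history",
                        "x_trace_history", "y_trace_history")])
  structure(out, class = "hebbian_run")
}

#' Trial-averaged population vector from a spiking run
#'
#' Averages per-position spike counts over all complete trials of one type,
#' yielding a positions x neurons matrix comparable with clone-occupancy and
#' hidden-state PVs.
#'
#' @param run a `hebbian_run` from [run_session()].
#' @param trial_type `"near"` or `"far"`.
#' @param trials optional integer subset of trial indices (e.g. only the
#'   final trials after learning has converged).
#' @return a `position_pv` (positions x K neurons, mean spike counts).
#' @export
representation_pv <- function(run, trial_type, trials = NULL) {
  sel <- which(run$trial_types == trial_type)
  if (!is.null(trials)) sel <- intersect(sel, trials)
  if (length(sel) == 0) stop("no complete trial of type ", trial_type)
  len <- unique(run$trial_lengths[sel])
  if (length(len) != 1) stop("trials of mixed lengths cannot be averaged")
  offsets <- c(0, cumsum(run$trial_lengths))
  acc <- matrix(0, len, nrow(run$counts))
  for (i in sel)
    acc <- acc + t(run$counts[, offsets[i] + seq_len(len), drop = FALSE])
  position_pv(acc / length(sel), positions_cm = 10 * (seq_len(len) - 1L),
              trial_type = trial_type, source = "hebbian")
}
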