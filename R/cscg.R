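#' Initialize a clone-structured causal graph
#'
#' A CSCG is a hidden Markov model whose hidden states ("clones") each emit
#' exactly one observation symbol: `p(x = j | z = i)` is 1 when clone `i`
#' belongs to symbol `j` and 0 otherwise. The emission structure is fixed;
#' learning only reshapes the `S x S` transition matrix, where
#' `S = n_symbols * clones_per_symbol`. The transition matrix is initialized
#' to seeded random positive row-stochastic values and the initial state
#' distribution to uniform.
#'
#' @param alphabet a `symbol_alphabet` (see [task_alphabet()]), or an integer
#'   giving the number of symbols (ids `0:(n-1)`).
#' @param clones_per_symbol clones per observation symbol (default 100).
#' @param seed integer seed for the random initialization.
#' @param concentration Dirichlet concentration of the random transition
#'   rows (default 0.3). Values below 1 give sparse rows, which break the
#'   clone-permutation symmetry that otherwise leaves expectation
#'   maximization on a saddle where near/far branches never separate;
#'   near-uniform rows (large values) make EM slow and prone to symmetric
#'   local optima.
#' @return an object of class `cscg_model`: list with `T` (S x S row
#'   stochastic), `pi` (length S), `M` (clones per symbol), `symbol_ids`,
#'   `seed`, and a `trained` flag.
#' @export
init_cscg <- function(alphabet, clones_per_symbol = 100, seed = 1L,
                      concentration = 0.3) {
  if (clones_per_symbol < 1) stop("clones_per_symbol must be >= 1")
  symbol_ids <- if (inherits(alphabet, "symbol_alphabet"))
    sort(alphabet$symbols$id) else 0:(as.integer(alphabet) - 1L)
  n_sym <- length(symbol_ids)
  S <- n_sym * clones_per_symbol
  local_rng(seed)
  T_ <- matrix(stats::rgamma(S * S, shape = concentration), S, S)
  T_ <- row_normalize(T_, pseudo = .Machine$double.eps)
  structure(list(T = T_, pi = rep(1 / S, S), M = as.integer(clones_per_symbol),
                 symbol_ids = symbol_ids, seed = seed, trained = FALSE),
            class = "cscg_model")
}

#' @export
print.cscg_model <- function(x, ...) {
  cat(sprintf("<cscg_model> %d symbols x %d clones = %d states%s\n",
              length(x$symbol_ids), x$M, nrow(x$T),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# map observed symbol ids to 0-based block indices, validating membership
symbols_to_index <- function(model, sequence) {
  sym <- if (inherits(sequence, "trial_sequence")) sequence$symbols
         else as.integer(sequence)
  idx <- match(sym, model$symbol_ids)
  if (anyNA(idx)) stop("symbol outside the model alphabet: ",
                       paste(unique(sym[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' Forward-backward posterior for one observation sequence
#'
#' Scaled (underflow-safe) forward-backward respecting the deterministic
#' clone emissions: posterior mass at step `n` is confined to the clones of
#' the observed symbol, and each row of `gamma` sums to 1.
#'
#' @param model a `cscg_model`.
#' @param sequence a `trial_sequence` or integer symbol vector.
#' @return list with `gamma` (steps x states), `xi_counts` (expected
#'   transition counts summed over steps), and `loglik` (natural log).
#' @export
forward_backward <- function(model, sequence) {
  x <- symbols_to_index(model, sequence)
  res <- cscg_fb_cpp(model$T, model$pi, x, model$M)
  structure(res, class = "cscg_posterior")
}

#' Train a CSCG by batched Baum-Welch expectation maximization
#'
#' Training proceeds in steps; at each step a seeded batch of `batch_trials`
#' trials is drawn from the schedule and `n_em_iters` EM iterations are run
#' on it (transition pseudocount `pseudo` keeps rows stochastic). Within a
#' step the batch log-likelihood is non-decreasing across iterations. Model
#' snapshots are kept every `checkpoint_every` steps so representational
#' trajectories can be computed over learning.
#'
#' @param model a `cscg_model`.
#' @param schedule a `session_schedule` (or list of `trial_sequence`).
#' @param n_steps number of training steps (default 20).
#' @param n_em_iters EM iterations per step (default 20).
#' @param batch_trials trials per batch (default 20).
#' @param checkpoint_every snapshot cadence in steps (default 1).
#' @param checkpoint_iters snapshot after every EM iteration instead of
#'   every step (default FALSE); gives the fine-grained time axis needed to
#'   resolve decorrelation order, which mostly unfolds within the first
#'   training step.
#' @param include_initial prepend the untrained model as checkpoint 0
#'   (default TRUE), anchoring trajectories at the fully correlated state.
#' @param pseudo additive transition pseudocount per M step (default 1e-10).
#' @param update_pi also re-estimate the initial distribution (default TRUE).
#' @param seed seed for batch sampling.
#' @return the trained `cscg_model`, with `checkpoints` (list of models),
#'   `loglik` (matrix steps x iterations) and `checkpoint_steps` attached.
#' @export
baum_welch_train <- function(model, schedule, n_steps = 20, n_em_iters = 20,
                             batch_trials = 20, checkpoint_every = 1,
                             checkpoint_iters = FALSE, include_initial = TRUE,
                             pseudo = 1e-10, update_pi = TRUE, seed = NULL) {
  trials <- if (inherits(schedule, "session_schedule")) schedule$trials
            else schedule
  if (length(trials) == 0) stop("empty schedule")
  if (n_em_iters < 1) stop("n_em_iters must be >= 1")
  if (batch_trials < 1) stop("empty batch")
  local_rng(seed)
  checkpoints <- if (include_initial) list(model) else list()
  cp_steps <- if (include_initial) 0 else numeric(0)
  ll <- matrix(NA_real_, n_steps, n_em_iters)
  for (s in seq_len(n_steps)) {
    pick <- sample.int(length(trials), batch_trials,
                       replace = batch_trials > length(trials))
    seqs <- lapply(trials[pick], function(tr) symbols_to_index(model, tr))
    if (checkpoint_iters) {
      for (it in seq_len(n_em_iters)) {
        fit <- cscg_em_cpp(model$T, model$pi, seqs, model$M, 1L, pseudo,
                           update_pi)
        model$T <- fit$T
        model$pi <- fit$pi
        ll[s, it] <- fit$loglik[1]
        snap <- model
        snap$trained <- TRUE
        checkpoints[[length(checkpoints) + 1L]] <- snap
        cp_steps <- c(cp_steps, s - 1 + it / n_em_iters)
      }
    } else {
      fit <- cscg_em_cpp(model$T, model$pi, seqs, model$M, n_em_iters, pseudo,
                         update_pi)
      model$T <- fit$T
      model$pi <- fit$pi
      ll[s, ] <- fit$loglik
      if (s %% checkpoint_every == 0) {
        snap <- model
        snap$trained <- TRUE
        checkpoints[[length(checkpoints) + 1L]] <- snap
        cp_steps <- c(cp_steps, s)
      }
    }
  }
  model$trained <- TRUE
  attr(model, "checkpoints") <- checkpoints
  attr(model, "checkpoint_steps") <- cp_steps
  attr(model, "loglik") <- ll
  model
}

#' Viterbi training refinement
#'
#' Hard-assignment re-estimation: transition counts are taken along the
#' Viterbi paths of the supplied sequences and the transition matrix updated
#' from them (with pseudocount smoothing so no row becomes degenerate). The
#' joint log probability of the Viterbi paths is non-decreasing across
#' refinement iterations. Ties in the path are broken toward the lowest
#' state index.
#'
#' @inheritParams baum_welch_train
#' @param sequences list of `trial_sequence` or integer vectors.
#' @param n_iters refinement iterations (default 5).
#' @return the refined model with attribute `viterbi_logprob` (per-iteration
#'   joint log probability, computed before each update).
#' @export
viterbi_refine <- function(model, sequences, n_iters = 5, pseudo = 1e-10,
                           update_pi = FALSE) {
  if (!model$trained) stop("model must be trained before Viterbi refinement")
  seqs <- lapply(sequences, function(s) symbols_to_index(model, s))
  fit <- cscg_viterbi_train_cpp(model$T, model$pi, seqs, model$M, n_iters,
                                pseudo, update_pi)
  model$T <- fit$T
  if (update_pi) model$pi <- fit$pi
  attr(model, "viterbi_logprob") <- fit$logprob
  model
}

#' Viterbi path for one sequence
#'
#' @inheritParams forward_backward
#' @return list with `path` (1-based state ids) and `logprob`.
#' @export
viterbi_path <- function(model, sequence) {
  x <- symbols_to_index(model, sequence)
  v <- cscg_viterbi_cpp(model$T, model$pi, x, model$M)
  list(path = v$path + 1L, logprob = v$logprob)
}

# union of Viterbi states over a set of trials (the "used" clones)
used_clones <- function(model, sequences) {
  sort(unique(unlist(lapply(sequences, function(s) viterbi_path(model, s)$path))))
}

#' Extract the learned transition graph
#'
#' Nodes are the clones on the Viterbi paths of the supplied trials (the
#' clones actually used to represent the task); directed edges carry
#' transition probabilities at or above `prob_floor`. After training on the
#' standard task the graph shows two trial-type-specific chains that merge
#' into the shared start/teleport segment.
#'
#' @inheritParams viterbi_refine
#' @param prob_floor minimum transition probability for an edge (default 0.05).
#' @return an [igraph::graph] with vertex attributes `state` (1-based id) and
#'   `symbol` (emitted symbol id), and edge attribute `weight`.
#' @export
extract_graph <- function(model, sequences, prob_floor = 0.05) {
  nodes <- used_clones(model, sequences)
  sub <- model$T[nodes, nodes, drop = FALSE]
  sub[sub < prob_floor] <- 0
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "directed",
                                           weighted = TRUE)
  igraph::V(g)$state <- nodes
  igraph::V(g)$symbol <- model$symbol_ids[(nodes - 1L) %/% model$M + 1L]
  igraph::V(g)$name <- paste0("s", nodes)
  g
}

#' Clone-occupancy population vector for one trial
#'
#' The model analogue of a position-binned population vector: row `n` holds
#' the clone-occupancy distribution at sequence step `n` (each row sums to
#' 1), so near/far trials can be compared with the same Pearson
#' cross-correlation machinery used for neural data. The default
#' `"filtered"` occupancy is the causal forward probability - influenced by
#' current and past stimuli only, like the animal's online state estimate -
#' so the shared track start stays identical across trial types until the
#' indicator is seen. `"posterior"` gives the smoothed forward-backward
#' occupancy and `"viterbi"` one-hot indicators of the Viterbi path.
#' `states` restricts columns to a subset (e.g. the used clones).
#'
#' @inheritParams forward_backward
#' @param method `"filtered"` (default), `"posterior"`, or `"viterbi"`.
#' @param states optional integer vector of 1-based state ids to keep.
#' @return a `position_pv` object (see [position_pv()]).
#' @export
state_occupancy_pv <- function(model, trial,
                               method = c("filtered", "posterior", "viterbi"),
                               states = NULL) {
  method <- match.arg(method)
  sym <- if (inherits(trial, "trial_sequence")) trial$symbols
         else as.integer(trial)
  if (method == "filtered") {
    mat <- cscg_filter_cpp(model$T, model$pi, symbols_to_index(model, sym),
                           model$M)
  } else if (method == "posterior") {
    mat <- forward_backward(model, sym)$gamma
  } else {
    p <- viterbi_path(model, sym)$path
    mat <- matrix(0, length(sym), nrow(model$T))
    mat[cbind(seq_along(sym), p)] <- 1
  }
  if (!is.null(states)) mat <- mat[, states, drop = FALSE]
  position_pv(mat, positions_cm = 10 * (seq_along(sym) - 1L),
              trial_type = if (inherits(trial, "trial_sequence"))
                trial$trial_type else NA_character_,
              source = paste0("cscg_", method))
}
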