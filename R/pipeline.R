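#' Train a CSCG on the task and track its representational trajectory
#'
#' End-to-end model experiment: builds a trial schedule in the requested
#' dialect, trains a clone-structured causal graph by batched Baum-Welch EM
#' with checkpoints, computes near/far clone-occupancy population vectors at
#' every checkpoint (restricted to the clones used by the Viterbi paths of
#' the two canonical trials), and summarizes the per-region decorrelation
#' trajectory and its time-to-threshold ordering.
#'
#' @param seed experiment seed (schedule, initialization, batches).
#' @param dialect `"cscg_visual_first"` (default) or another cscg dialect.
#' @param clones clones per symbol (default 100).
#' @param n_trials schedule length (default 200).
#' @param n_steps,n_em_iters,batch_trials training-step structure
#'   (defaults 10 steps of 20 EM iterations on 20-trial batches).
#' @param threshold decorrelation threshold (default 0.3).
#' @param refine apply Viterbi refinement before graph extraction.
#' @param max_restarts EM sometimes freezes in a symmetric local optimum in
#'   which one branch-ambiguous region never decorrelates (its trial-type
#'   occupancies are exactly degenerate, so no likelihood signal remains).
#'   Such non-converged runs are detected - a key region never crossing the
#'   threshold - and retrained from a fresh random initialization, up to
#'   this many times (default 4), as is standard practice for EM local
#'   optima. The last attempt is returned either way, with a `converged`
#'   flag.
#' @return list with `model`, `graph`, `trajectory` (a `decorr_trajectory`),
#'   `order` (from [decorrelation_order()]), `final_ccm`, `final_regions`,
#'   `loglik`, `converged`, `attempts`.
#' @export
run_cscg_experiment <- function(seed = 1L, dialect = "cscg_visual_first",
                                clones = 100, n_trials = 200, n_steps = 10,
                                n_em_iters = 20, batch_trials = 20,
                                threshold = 0.3, refine = TRUE,
                                max_restarts = 4) {
  sched <- sample_session(n_trials, seed = seed, dialect = dialect)
  alph <- task_alphabet(dialect)
  near <- make_trial("near", dialect)
  far <- make_trial("far", dialect)
  regions <- region_spec(near$positions_cm)
  for (attempt in 0:max_restarts) {
    init_seed <- seed + 7919L * attempt
    model <- init_cscg(alph, clones_per_symbol = clones, seed = init_seed)
    model <- baum_welch_train(model, sched, n_steps = n_steps,
                              n_em_iters = n_em_iters,
                              batch_trials = batch_trials,
                              checkpoint_iters = TRUE, seed = init_seed + 1L)
    ccms <- lapply(attr(model, "checkpoints"), function(m)
      pv_cross_correlation(state_occupancy_pv(m, near),
                           state_occupancy_pv(m, far)))
    # snapshots are large (a full transition matrix each); once the
    # correlation trajectory is computed they are no longer needed
    attr(model, "checkpoints") <- NULL
    traj <- decorrelation_trajectory(ccms, regions, threshold = threshold)
    converged <- all(traj$crossed[c("off_diagonal", "pre_r2", "pre_r1")])
    if (converged) break
  }
  ord <- decorrelation_order(traj)
  graph <- NULL
  if (refine) {
    refined <- viterbi_refine(model, list(near, far))
    graph <- extract_graph(refined, list(near, far))
  }
  list(model = model, graph = graph, trajectory = traj, order = ord,
       final_ccm = ccms[[length(ccms)]],
       final_regions = region_correlations(ccms[[length(ccms)]],
                                           regions)$region_means,
       loglik = attr(model, "loglik"),
       converged = converged, attempts = attempt + 1L)
}

#' Train the Hebbian spiking network on the task
#'
#' Runs the soft-WTA spiking network over a cscg-dialect trial schedule with
#' plasticity on, then computes near/far population vectors from the final
#' trials (after learning has converged) and their cross-correlation.
#'
#' @param seed experiment seed.
#' @param n_trials schedule length (default 120).
#' @param pv_trials number of final trials per type averaged into the PV
#'   (default 20).
#' @param params a [spiking_net_params()].
#' @param ms_per_symbol presentation time per symbol (default from params).
#' @return list with `run`, `final_ccm`, `final_regions`.
#' @export
run_hebbian_experiment <- function(seed = 1L, n_trials = 120, pv_trials = 20,
                                   params = spiking_net_params(),
                                   ms_per_symbol = NULL) {
  sched <- sample_session(n_trials, seed = seed, dialect = "cscg_visual_first")
  state <- init_spiking_net(params, seed = seed)
  run <- run_session(state, sched, ms_per_symbol = ms_per_symbol,
                     seed = seed + 1L)
  last <- (n_trials - ceiling(n_trials / 3)):n_trials
  pv_n <- representation_pv(run, "near",
                            trials = tail(intersect(last,
                              which(run$trial_types == "near")), pv_trials))
  pv_f <- representation_pv(run, "far",
                            trials = tail(intersect(last,
                              which(run$trial_types == "far")), pv_trials))
  ccm <- pv_cross_correlation(pv_n, pv_f)
  regions <- region_spec(pv_n$positions_cm)
  list(run = run, final_ccm = ccm,
       final_regions = region_correlations(ccm, regions)$region_means)
}

#' Train a gradient net on the task and summarize its representation
#'
#' @param spec a [net_spec()].
#' @param seed experiment seed.
#' @param n_trials session length (default 80; half train, half test).
#' @param config optional [train_config()] overrides.
#' @return list with `net`, `accuracy` (held-out overall),
#'   `accuracy_reward` (reward-determining positions), `final_ccm`,
#'   `final_regions`.
#' @export
run_net_experiment <- function(spec, seed = 1L, n_trials = 80,
                               config = NULL) {
  sched <- sample_session(n_trials, seed = seed, dialect = "rnn")
  if (is.null(config)) config <- train_config(seed = seed)
  else config$seed <- seed
  net <- train_net(spec, config, sched)
  test <- net$trials[net$test_idx]
  near <- make_trial("near", "rnn")
  far <- make_trial("far", "rnn")
  ccm <- pv_cross_correlation(hidden_pv(net, near), hidden_pv(net, far))
  regions <- region_spec(near$positions_cm)
  list(net = net,
       accuracy = next_symbol_accuracy(net, test),
       accuracy_reward = next_symbol_accuracy(net, test,
                                              reward_determined_positions()),
       final_ccm = ccm,
       final_regions = region_correlations(ccm, regions)$region_means)
}

#' Run a full model-comparison experiment
#'
#' Orchestrates generate-train-extract-compare for a set of models and
#' seeds, producing per-model final near/far region correlations (and, for
#' the CSCG, the decorrelation ordering), plus a machine-readable summary.
#'
#' @param config list with elements `models` (list; each entry a list with
#'   `type` in `"cscg"`, `"hebbian"`, `"rate_rnn"`, `"lstm"`,
#'   `"transformer"` plus type-specific fields such as `activation`,
#'   `regularizer`, `hidden`, or `dialect`), `seeds` (integer vector), and
#'   optional `out_dir` plus per-type size overrides (`n_trials`,
#'   `cscg_steps`, ...).
#' @return list of class `experiment_bundle`: `summary` (data frame: model,
#'   seed, region means, order match, accuracy), `results` (nested), and
#'   `provenance`.
#' @export
run_experiment <- function(config) {
  stopifnot(is.list(config$models), length(config$seeds) >= 1)
  rows <- list(); results <- list()
  for (m in config$models) {
    label <- m$label
    if (is.null(label))
      label <- paste(c(m$type, m$activation, m$regularizer), collapse = "_")
    for (seed in config$seeds) {
      res <- switch(m$type,
        cscg = run_cscg_experiment(
          seed = seed,
          dialect = if (is.null(m$dialect)) "cscg_visual_first" else m$dialect,
          clones = if (is.null(m$clones)) 100 else m$clones,
          n_trials = if (is.null(config$n_trials)) 200 else config$n_trials,
          n_steps = if (is.null(config$cscg_steps)) 12 else config$cscg_steps,
          refine = FALSE),
        hebbian = run_hebbian_experiment(
          seed = seed,
          n_trials = if (is.null(m$n_trials)) 120 else m$n_trials,
          params = if (is.null(m$params)) spiking_net_params() else m$params,
          ms_per_symbol = m$ms_per_symbol),
        {
          spec <- net_spec(family = m$type, hidden = m$hidden,
                           activation = m$activation,
                           regularizer = m$regularizer,
                           n_layers = if (is.null(m$n_layers)) 4
                                      else m$n_layers,
                           n_heads = if (is.null(m$n_heads)) 4 else m$n_heads,
                           embed = if (is.null(m$embed)) 256 else m$embed,
                           context_length = if (is.null(m$context_length)) 23
                                            else m$context_length)
          run_net_experiment(spec, seed = seed,
                             n_trials = if (is.null(m$n_trials)) 80
                                        else m$n_trials,
                             config = m$train)
        })
      results[[label]][[as.character(seed)]] <- res
      fr <- res$final_regions
      rows[[length(rows) + 1L]] <- data.frame(
        model = label, seed = seed,
        pre_r1 = fr[["pre_r1"]], pre_r2 = fr[["pre_r2"]],
        off_diagonal = fr[["off_diagonal"]],
        initial = fr[["initial"]], end = fr[["end"]],
        order_match = if (!is.null(res$order)) res$order$match else NA,
        accuracy = if (!is.null(res$accuracy)) res$accuracy else NA)
    }
  }
  summary <- do.call(rbind, rows)
  bundle <- structure(
    list(summary = summary, results = results,
         provenance = list(package_version =
                             as.character(utils::packageVersion("osmlab")),
                           seeds = config$seeds,
                           date = format(Sys.time(), "%Y-%m-%d"))),
    class = "experiment_bundle")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = summary,
                              provenance = bundle$provenance),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("<experiment_bundle>\n")
  agg <- stats::aggregate(cbind(pre_r1, pre_r2, off_diagonal) ~ model,
                          data = x$summary, FUN = mean)
  print(agg, digits = 3)
  invisible(x)
}
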