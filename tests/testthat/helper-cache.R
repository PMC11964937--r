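# fixtures computed once per test run and shared across files

.osmlab_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .osmlab_cache)) {
    assign(key, force(expr), envir = .osmlab_cache)
  }
  get(key, envir = .osmlab_cache)
}

# a five-stage synthetic learning course with persistent cells
cached_course <- function() {
  cached("course", {
    cfg <- synth_config(n_cells = 400, noise_sd = 0.02, seed = 11)
    simulate_learning_course(cfg, stages = c(0, 1, 2, 3, 4), n_trials = 30)
  })
}

# per-session near/far tuning PVs and cross-correlation matrices
cached_course_ccms <- function() {
  cached("course_ccms", {
    course <- cached_course()
    lapply(course$sessions, function(ses) {
      pp <- preprocess_session(ses)
      list(pp = pp,
           tcn = tuning_curve(pp, ses, "near"),
           tcf = tuning_curve(pp, ses, "far"))
    })
  })
}

course_ccm <- function(k) {
  cs <- cached_course_ccms()[[k]]
  pv_cross_correlation(tuning_pv(cs$tcn), tuning_pv(cs$tcf))
}

# CSCG decorrelation experiments shared between the ordering and the
# model-ranking analyses
cached_cscg_runs <- function(seeds = 1:10) {
  cached("cscg_runs", lapply(seeds, function(s)
    run_cscg_experiment(seed = s, n_steps = 8, refine = FALSE)))
}
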