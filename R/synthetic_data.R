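#' Configuration for synthetic 2ACDC sessions
#'
#' The generator emulates the statistical structure the analyses assume:
#' position/speed/lick traces at 10 Hz across the four licking-strategy
#' stages, and calcium-like dF/F0 with stage-dependent tuning. Learning
#' stages: 0 (unstructured, broad sensory tuning), 1 (sensory/hub: cells
#' tuned to one grey region echo in the other grey regions), 2 (within-track
#' decorrelated: single-region tuning, still shared across trial types), 3
#' (pre-R2/R2 tuning splits by trial type), 4 = `"expert"` (all mid-track
#' regions split into trial-type-specific state cells). Cell categories in
#' split regions follow the planted splitter/place/remapping mixture;
#' splitter and remapping cells live between the indicator and R2, place
#' cells anywhere, so track start/end stay correlated at every stage.
#'
#' @param n_cells number of cells (default 500).
#' @param stage 0-4 or `"expert"`.
#' @param mixture named fractions `splitter`, `place`, `remapping` (sum 1;
#'   default 0.6/0.3/0.1).
#' @param rise_s,decay_s calcium kernel time constants (defaults 0.05, 0.7:
#'   GCaMP6f-like).
#' @param noise_sd fluorescence noise s.d. as a fraction of baseline
#'   (default 0.03).
#' @param amp_dff peak dF/F0 per transient event (default 1).
#' @param event_rate_hz peak in-field event rate (default 8).
#' @param base_speed running speed, cm/s (default 25).
#' @param licks_per_trial mean lick count (default 20).
#' @param lick_floor uniform contamination fraction of lick positions
#'   (default 0.05).
#' @param lick_strategy NULL (derived from stage: 0 random, 1 both_rewards,
#'   2 lick_stop, 3/4 expert) or one of the four strategy names.
#' @param seed integer seed.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 500, stage = "expert",
                         mixture = c(splitter = 0.6, place = 0.3,
                                     remapping = 0.1),
                         rise_s = 0.05, decay_s = 0.7, noise_sd = 0.03,
                         amp_dff = 1, event_rate_hz = 8, base_speed = 25,
                         licks_per_trial = 20, lick_floor = 0.05,
                         lick_strategy = NULL, seed = 1L) {
  stage <- if (identical(stage, "expert")) 4L else as.integer(stage)
  stopifnot(stage %in% 0:4, abs(sum(mixture) - 1) < 1e-8)
  structure(list(n_cells = n_cells, stage = stage, mixture = mixture,
                 rise_s = rise_s, decay_s = decay_s, noise_sd = noise_sd,
                 amp_dff = amp_dff, event_rate_hz = event_rate_hz,
                 base_speed = base_speed, licks_per_trial = licks_per_trial,
                 lick_floor = lick_floor, lick_strategy = lick_strategy,
                 seed = seed),
            class = "synth_config")
}

stage_strategy <- function(stage)
  c("random", "both_rewards", "lick_stop", "expert", "expert")[stage + 1L]

#' Simulate behaviour for one session
#'
#' Position advances at the configured running speed with brief slow-downs
#' (below the 5 cm/s analysis threshold) inside the reward zones; trials are
#' separated by a 2-s dark teleport gap. Licks are drawn from the stage's
#' strategy basis function plus a uniform noise floor.
#'
#' @param config a `synth_config`.
#' @param n_trials number of trials.
#' @return a list of class `synth_behavior`: per-frame `position`, `speed`,
#'   `trial_type` (NA in teleport gaps), `licks` (frame indices), `trials`
#'   table, `frame_rate`, `track_length_cm`, `strategy`.
#' @export
simulate_behavior <- function(config, n_trials = 60) {
  local_rng(config$seed)
  fr <- 10; dt <- 1 / fr
  strategy <- if (is.null(config$lick_strategy))
    stage_strategy(config$stage) else config$lick_strategy
  sched <- sample_session(n_trials, seed = config$seed + 7L, dialect = "rnn")
  rz <- reward_zone_cm("standard")
  basis <- strategy_basis(bin_cm = 5)
  nb <- length(basis$bin_start_cm)

  position <- numeric(0); speed <- numeric(0); ttype <- character(0)
  licks <- integer(0)
  trials <- data.frame(trial = integer(0), type = character(0),
                       start = integer(0), end = integer(0),
                       variant = character(0))
  for (i in seq_len(n_trials)) {
    ty <- sched$trial_types[i]
    pos <- 0; ps <- c(); sp <- c()
    pause1 <- 0L; pause2 <- 0L
    while (pos < 229.999) {
      v <- max(0.5, config$base_speed + rnorm(1, 0, 2))
      if (pos >= rz$r1[1] && pos < rz$r1[2] && pause1 < 2L * fr) {
        v <- 2; pause1 <- pause1 + 1L
      }
      if (pos >= rz$r2[1] && pos < rz$r2[2] && pause2 < 2L * fr) {
        v <- 2; pause2 <- pause2 + 1L
      }
      ps <- c(ps, pos); sp <- c(sp, v)
      pos <- min(pos + v * dt, 230)
    }
    start <- length(position) + 1L
    position <- c(position, ps); speed <- c(speed, sp)
    ttype <- c(ttype, rep(ty, length(ps)))
    end <- length(position)
    trials <- rbind(trials, data.frame(trial = i, type = ty, start = start,
                                       end = end, variant = "standard"))
    # licks from the strategy density for this trial type
    dens <- basis$X[if (ty == "near") seq_len(nb) else nb + seq_len(nb),
                    strategy]
    dens <- (1 - config$lick_floor) * dens / sum(dens) +
      config$lick_floor / nb
    n_lk <- rpois(1, config$licks_per_trial)
    if (n_lk > 0) {
      bins <- sample.int(nb, n_lk, replace = TRUE, prob = dens)
      lk_pos <- basis$bin_start_cm[bins] + runif(n_lk, 0, basis$bin_cm)
      fidx <- vapply(lk_pos, function(p) {
        k <- which(ps >= p)[1]
        if (is.na(k)) length(ps) else k
      }, 0L)
      licks <- c(licks, start - 1L + fidx)
    }
    # 2-s teleport gap
    gap <- 2L * fr
    position <- c(position, rep(230, gap)); speed <- c(speed, rep(0, gap))
    ttype <- c(ttype, rep(NA_character_, gap))
  }
  structure(list(position = position, speed = speed, trial_type = ttype,
                 licks = sort(licks), trials = trials, frame_rate = fr,
                 track_length_cm = 230, strategy = strategy),
            class = "synth_behavior")
}

grey_regions_cm <- function() list(initial = c(0, 60), pre_r1 = c(100, 130),
                                   pre_r2 = c(150, 180), end = c(200, 220))

# persistent cell identities shared across the sessions of a learning course
draw_cells <- function(config) {
  local_rng(config$seed + 101L)
  n <- config$n_cells
  category <- sample(names(config$mixture), n, replace = TRUE,
                     prob = config$mixture)
  center <- numeric(n)
  # splitters live between the indicator and R2; place cells concentrate at
  # the track start and end (the pattern seen at the expert stage)
  for (i in seq_len(n)) {
    center[i] <- if (category[i] %in% c("splitter", "remapping"))
      runif(1, 60, 188)
    else if (runif(1) < 0.92) {
      if (runif(1) < 0.75) runif(1, 0, 100) else runif(1, 200, 220)
    } else runif(1, 100, 200)
  }
  # state cells carry compact fields; place fields are broader
  width <- ifelse(category == "place", runif(n, 10, 18), runif(n, 8, 13))
  pref <- sample(c("near", "far"), n, replace = TRUE)
  shift <- runif(n, 15, 40) * sample(c(-1, 1), n, replace = TRUE)
  amp <- exp(rnorm(n, 0, 0.45))  # transient dF/F0 amplitude (expression)
  base <- runif(n, 0.2, 1)      # cell-specific excitability scale
  data.frame(cell = seq_len(n), category = category, center = center,
             width = width, pref = pref, shift = shift, amp = amp,
             base = base)
}

region_of_cm <- function(pos) {
  lay <- track_layout("standard")
  segs <- lay$segments
  segs$region[pmin(floor(pos / 10) + 1L, nrow(segs))]
}

# per-cell rate fields for one stage: list with near/far center, gains, echoes
stage_fields <- function(cells, stage) {
  n <- nrow(cells)
  region <- region_of_cm(cells$center)
  split_regions <- if (stage >= 4) c("pre_r1", "r1", "pre_r2", "r2")
                   else if (stage == 3) c("r1", "pre_r2", "r2")
                   else character(0)
  g_near <- rep(1, n); g_far <- rep(1, n)
  c_near <- cells$center; c_far <- cells$center
  # indicator cells are sensory-driven and trial-type specific from the start
  ind <- region == "indicator"
  g_near[ind & cells$pref == "far"] <- 0.1
  g_far[ind & cells$pref == "near"] <- 0.1
  split <- region %in% split_regions
  sp <- split & cells$category == "splitter"
  g_near[sp & cells$pref == "far"] <- 0.05
  g_far[sp & cells$pref == "near"] <- 0.05
  rm_ <- split & cells$category == "remapping"
  c_far[rm_] <- pmin(pmax(cells$center[rm_] + cells$shift[rm_], 60), 199)
  echo <- if (stage <= 1) 0.3 else 0
  # fields sharpen with learning: broad, sensory-like tuning early, compact
  # state-cell tuning at the expert stage; cue (indicator) cells stay sharp
  width_factor <- rep(c(2.2, 1.8, 1.4, 1.1, 1)[stage + 1L], n)
  width_factor[ind] <- 0.5
  # position-independent excitability floor (events/s scale, relative) and
  # weak tuning while the map is unstructured; tuning dominates once cells
  # are position/state specific
  base_level <- c(0.26, 0.26, 0.02, 0, 0)[stage + 1L]
  amp_factor <- c(0.07, 0.08, 1, 1, 1)[stage + 1L]
  list(c_near = c_near, c_far = c_far, g_near = g_near, g_far = g_far,
       echo = echo, width_factor = width_factor, base_level = base_level,
       amp_factor = amp_factor, region = region, split = split)
}

# Gaussian field value; grey-tuned cells optionally keep moderate ("hub")
# activity throughout the other grey regions, the shared-grey signature of
# early learning
field_rate <- function(pos, center, width, echo, region) {
  v <- exp(-(pos - center)^2 / (2 * width^2))
  if (echo > 0 && region %in% names(grey_regions_cm())) {
    gr <- grey_regions_cm()
    for (nm in setdiff(names(gr), region)) {
      g <- gr[[nm]]
      v <- v + echo * (pos >= g[1] & pos < g[2])
    }
  }
  v
}

#' Simulate calcium fluorescence for a behaviour session
#'
#' Converts per-cell positional rate fields (stage-dependent tuning, see
#' [synth_config()]) into Poisson events, convolves with a
#' rise/decay calcium kernel, and adds Gaussian noise around a baseline of
#' 100, sampled at 10 Hz.
#'
#' @param config a `synth_config`.
#' @param behavior a `synth_behavior` from [simulate_behavior()].
#' @param cells optional persistent cell table from a learning course.
#' @return list with `session` (a [calcium_session()]) and `ground_truth`
#'   (cell table with per-type centers and gains, stage, strategy).
#' @export
simulate_neural <- function(config, behavior, cells = NULL) {
  if (is.null(cells)) cells <- draw_cells(config)
  local_rng(config$seed + 211L)
  fl <- stage_fields(cells, config$stage)
  nfr <- length(behavior$position)
  fr <- behavior$frame_rate
  # calcium kernel at the frame rate
  tk <- seq(0, 3, by = 1 / fr)
  kern <- (1 - exp(-tk / config$rise_s)) * exp(-tk / config$decay_s)
  kern <- kern / max(kern)

  pos <- behavior$position
  ty <- behavior$trial_type
  F0b <- 100
  Fmat <- matrix(0, config$n_cells, nfr)
  near_f <- which(ty == "near"); far_f <- which(ty == "far")
  for (i in seq_len(config$n_cells)) {
    rate <- numeric(nfr)
    w <- cells$width[i] * fl$width_factor[i]
    floor_i <- fl$base_level * cells$base[i]
    if (length(near_f))
      rate[near_f] <- fl$amp_factor * fl$g_near[i] *
        field_rate(pos[near_f], fl$c_near[i], w, fl$echo, fl$region[i]) +
        floor_i
    if (length(far_f))
      rate[far_f] <- fl$amp_factor * fl$g_far[i] *
        field_rate(pos[far_f], fl$c_far[i], w, fl$echo, fl$region[i]) +
        floor_i
    events <- rpois(nfr, config$event_rate_hz * rate / fr)
    dff_true <- config$amp_dff * cells$amp[i] *
      stats::convolve(events, rev(kern), type = "open")[seq_len(nfr)]
    Fmat[i, ] <- F0b * (1 + dff_true) + rnorm(nfr, 0, config$noise_sd * F0b)
  }
  gt <- cells
  gt$center_near <- fl$c_near; gt$center_far <- fl$c_far
  gt$gain_near <- fl$g_near; gt$gain_far <- fl$g_far
  gt$region <- fl$region; gt$split <- fl$split
  list(session = calcium_session(Fmat, behavior$position, behavior$speed,
                                 behavior$licks, behavior$trials,
                                 frame_rate = fr,
                                 track_length_cm = behavior$track_length_cm),
       ground_truth = list(cells = gt, stage = config$stage,
                           strategy = behavior$strategy))
}

#' Simulate a multi-session learning course
#'
#' One session per stage with persistent cell identities, so region
#' correlations decorrelate in the planted order (off-diagonal grey pairs at
#' stage 2, pre-R2 at stage 3, pre-R1 at the expert stage) and the dominant
#' licking strategy progresses random, both-rewards, lick-stop, expert.
#'
#' @param config a `synth_config` (its `stage` field is ignored).
#' @param stages stage schedule (default `c(0, 1, 2, 3, 4)`).
#' @param n_trials trials per session.
#' @return list of class `synth_course`: `sessions` (list of
#'   [calcium_session()]), `ground_truth` (persistent `cells`, `stages`,
#'   `strategies`, `planted_order`).
#' @export
simulate_learning_course <- function(config, stages = c(0, 1, 2, 3, 4),
                                     n_trials = 60) {
  stages <- vapply(stages, function(s)
    if (identical(s, "expert")) 4L else as.integer(s), 0L)
  cells <- draw_cells(config)
  sessions <- vector("list", length(stages))
  strategies <- character(length(stages))
  for (k in seq_along(stages)) {
    cfg <- config
    cfg$stage <- stages[k]
    cfg$seed <- config$seed + 1000L * k
    beh <- simulate_behavior(cfg, n_trials)
    res <- simulate_neural(cfg, beh, cells)
    sessions[[k]] <- res$session
    strategies[k] <- res$ground_truth$strategy
  }
  structure(list(sessions = sessions,
                 ground_truth = list(cells = cells, stages = stages,
                                     strategies = strategies,
                                     planted_order = c("off_diagonal",
                                                       "pre_r2", "pre_r1"))),
            class = "synth_course")
}
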