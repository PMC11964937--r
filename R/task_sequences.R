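#' Symbol alphabets for the 2ACDC task
#'
#' The two-alternative cue-delay-choice (2ACDC) task is encoded as a sequence
#' of discrete sensory symbols, one per 10-cm track segment. Two encoding
#' dialects exist: the compact 7-symbol `rnn` dialect used by the gradient
#' nets (no brick wall, single teleport symbol) and the 8-symbol `cscg`
#' dialects used by the cloned hidden Markov model (brick wall plus a
#' teleport symbol repeated three times). The `cscg_water_first` dialect
#' presents the water symbol before the reward-zone visual symbol, and
#' `cscg_conjunctive` fuses water and reward-zone visuals into combined
#' codes (near code 6, far code 8).
#'
#' @param dialect one of `"rnn"`, `"cscg_visual_first"`, `"cscg_water_first"`,
#'   `"cscg_conjunctive"`.
#' @return an object of class `symbol_alphabet`: a list with `dialect` and a
#'   data frame `symbols` (integer `id`, character `label`).
#' @export
task_alphabet <- function(dialect = c("rnn", "cscg_visual_first",
                                      "cscg_water_first", "cscg_conjunctive")) {
  dialect <- match.arg(dialect)
  base <- data.frame(
    id = 0:7,
    label = c("teleport", "grey", "near_indicator", "far_indicator",
              "r1_visual", "r2_visual", "water", "wall"),
    stringsAsFactors = FALSE
  )
  symbols <- switch(dialect,
    rnn = base[base$id <= 6, ],
    cscg_visual_first = base,
    cscg_water_first = base,
    cscg_conjunctive = {
      out <- base
      out$label[out$id == 6] <- "water_r1_conjunctive"
      rbind(out, data.frame(id = 8, label = "water_r2_conjunctive"))
    }
  )
  stopifnot(!anyDuplicated(symbols$id))
  structure(list(dialect = dialect, symbols = symbols),
            class = "symbol_alphabet")
}

#' Canonical track layout
#'
#' Segment-to-region assignment for the 230-cm track (10 cm per segment,
#' 0-based cm, half-open bins) and its 330-cm stretched variant in which the
#' two grey gaps after the indicator and between the reward zones are each
#' extended by 50 cm, moving the near reward zone to \[180, 200) cm (the far
#' reward location of the standard track) and the far zone to \[280, 300) cm.
#'
#' @param variant `"standard"` or `"stretched"`.
#' @return a list with `segments` (data frame: `segment` 1-based index,
#'   `start_cm`, `region`) and `track_length_cm`.
#' @export
track_layout <- function(variant = c("standard", "stretched")) {
  variant <- match.arg(variant)
  regions <- if (variant == "standard") {
    c(rep("initial", 6), rep("indicator", 4), rep("pre_r1", 3), rep("r1", 2),
      rep("pre_r2", 3), rep("r2", 2), rep("end", 2), "teleport")
  } else {
    c(rep("initial", 6), rep("indicator", 4), rep("pre_r1", 8), rep("r1", 2),
      rep("pre_r2", 8), rep("r2", 2), rep("end", 2), "teleport")
  }
  n <- length(regions)
  list(segments = data.frame(segment = seq_len(n),
                             start_cm = 10 * (seq_len(n) - 1L),
                             region = regions, stringsAsFactors = FALSE),
       track_length_cm = 10 * n)
}

novel_pair_ids <- function(dialect, pair) {
  base <- if (dialect == "rnn") 7L else 8L
  k <- match(pair, c("B", "C", "D", "E"))
  if (is.na(k)) stop("unknown novel indicator pair: ", pair)
  c(near = base + 2L * (k - 1L), far = base + 2L * (k - 1L) + 1L)
}

#' Generate one symbolic 2ACDC trial
#'
#' Returns the symbol sequence a mouse experiences on a single traversal of
#' the virtual track, one symbol per 10-cm segment. In the standard `rnn`
#' dialect a trial has 23 symbols; the `cscg` dialects append a brick-wall
#' symbol and a teleport symbol repeated three times (26 symbols). Grey (1)
#' fills all segments outside the indicator block (near 2 / far 3), the two
#' reward-zone blocks, and the trial end. In the rewarded zone the visual
#' cue is presented first and the water symbol (6) second
#' (`cscg_visual_first` and `rnn`); `cscg_water_first` swaps that order;
#' `cscg_conjunctive` replaces the pair by (visual, combined water+visual
#' code). The unrewarded zone shows its visual symbol twice.
#'
#' @param trial_type `"near"` or `"far"`.
#' @param dialect see [task_alphabet()].
#' @param variant `"standard"`, `"stretched"`, or one of `"novel_pair_B"` ..
#'   `"novel_pair_E"` (fresh indicator symbol ids; the rest of the trial is
#'   unchanged).
#' @return an object of class `trial_sequence`: list with integer `symbols`,
#'   `trial_type`, `dialect`, `variant`, and `positions_cm` (segment start
#'   positions, strictly increasing by 10).
#' @export
make_trial <- function(trial_type = c("near", "far"),
                       dialect = c("rnn", "cscg_visual_first",
                                   "cscg_water_first", "cscg_conjunctive"),
                       variant = "standard") {
  trial_type <- match.arg(trial_type)
  dialect <- match.arg(dialect)
  ok <- c("standard", "stretched", paste0("novel_pair_", c("B", "C", "D", "E")))
  if (!variant %in% ok) stop("unknown variant: ", variant)
  if (variant == "stretched" && dialect != "rnn")
    stop("stretched trials are only defined for the rnn dialect ",
         "(the stretched geometry is specified behaviourally)")

  ind <- if (trial_type == "near") c(near = 2L, far = 3L)[["near"]] else 3L
  if (startsWith(variant, "novel_pair_")) {
    pair <- sub("novel_pair_", "", variant)
    ids <- novel_pair_ids(dialect, pair)
    ind <- unname(ids[[trial_type]])
  }

  # reward-zone blocks: (R1 zone, R2 zone), two symbols each
  zones <- switch(dialect,
    rnn = ,
    cscg_visual_first = if (trial_type == "near")
      list(c(4L, 6L), c(5L, 5L)) else list(c(4L, 4L), c(5L, 6L)),
    cscg_water_first = if (trial_type == "near")
      list(c(6L, 4L), c(5L, 5L)) else list(c(4L, 4L), c(6L, 5L)),
    cscg_conjunctive = if (trial_type == "near")
      list(c(4L, 6L), c(5L, 5L)) else list(c(4L, 4L), c(5L, 8L))
  )

  gap1 <- if (variant == "stretched") 8L else 3L  # indicator -> R1 greys
  gap2 <- if (variant == "stretched") 8L else 3L  # R1 -> R2 greys
  symbols <- c(rep(1L, 6), rep(ind, 4), rep(1L, gap1), zones[[1]],
               rep(1L, gap2), zones[[2]], rep(1L, 2))
  symbols <- if (dialect == "rnn") c(symbols, 0L) else c(symbols, 7L, 0L, 0L, 0L)

  structure(list(symbols = symbols, trial_type = trial_type,
                 dialect = dialect, variant = variant,
                 positions_cm = 10 * (seq_along(symbols) - 1L)),
            class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence> %s / %s / %s (%d symbols)\n",
              x$trial_type, x$dialect, x$variant, length(x$symbols)))
  cat(" ", paste(x$symbols, collapse = ","), "\n")
  invisible(x)
}

#' @export
as.data.frame.trial_sequence <- function(x, row.names = NULL, optional = FALSE,
                                         trial_id = 1L, ...) {
  data.frame(trial_id = trial_id, t = seq_along(x$symbols) - 1L,
             symbol = x$symbols, label = x$trial_type,
             position_cm = x$positions_cm)
}

# Poisson(lambda) conditioned on 1..max_repeats
rtrunc_pois <- function(n, lambda, max_repeats) {
  p <- stats::dpois(seq_len(max_repeats), lambda)
  sample.int(max_repeats, n, replace = TRUE, prob = p / sum(p))
}

#' Sample a session of interleaved near/far trials
#'
#' Trial types come in runs whose lengths are drawn from a Poisson
#' distribution truncated to `[1, max_repeats]` ("random limited Poisson
#' sampling"), alternating between near and far runs so that no run of one
#' type exceeds `max_repeats` and the long-run near-trial frequency is 0.5.
#' Optionally, stretched trials are inserted after every 5th or 6th regular
#' trial (alternating deterministically given the seed).
#'
#' @param n_trials number of (regular) trials, >= 1.
#' @param lambda Poisson rate for run lengths (default 0.7).
#' @param max_repeats run-length cap (default 3).
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @param dialect,variant passed to [make_trial()].
#' @param insert_stretched if `TRUE` (rnn dialect only), insert a stretched
#'   trial of random type after every 5 or 6 regular trials.
#' @return an object of class `session_schedule`: list with `trial_types`,
#'   `trials` (list of `trial_sequence`), `params`, `seed`.
#' @export
sample_session <- function(n_trials, lambda = 0.7, max_repeats = 3, seed = 1L,
                           dialect = "rnn", variant = "standard",
                           insert_stretched = FALSE) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (max_repeats < 1) stop("max_repeats must be >= 1")
  rng <- local_rng(seed)
  types <- character(0)
  cur <- sample(c("near", "far"), 1)
  while (length(types) < n_trials) {
    run <- rtrunc_pois(1, lambda, max_repeats)
    types <- c(types, rep(cur, run))
    cur <- if (cur == "near") "far" else "near"
  }
  types <- types[seq_len(n_trials)]
  variants <- rep(variant, n_trials)
  if (insert_stretched) {
    gaps <- rep(c(5L, 6L), length.out = n_trials)
    if (sample(2, 1) == 2) gaps <- rep(c(6L, 5L), length.out = n_trials)
    pos <- cumsum(gaps)
    pos <- pos[pos <= n_trials]
    out_types <- character(0); out_var <- character(0)
    last <- 0L
    for (p in pos) {
      out_types <- c(out_types, types[(last + 1L):p],
                     sample(c("near", "far"), 1))
      out_var <- c(out_var, variants[(last + 1L):p], "stretched")
      last <- p
    }
    if (last < n_trials) {
      out_types <- c(out_types, types[(last + 1L):n_trials])
      out_var <- c(out_var, variants[(last + 1L):n_trials])
    }
    types <- out_types; variants <- out_var
  }
  trials <- mapply(function(tt, vv) make_trial(tt, dialect, vv),
                   types, variants, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  structure(list(trial_types = types, variants = variants, trials = trials,
                 params = list(lambda = lambda, max_repeats = max_repeats,
                               dialect = dialect, variant = variant),
                 seed = seed),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %d trials (%s), %.0f%% near, seed %s\n",
              length(x$trial_types), x$params$dialect,
              100 * mean(x$trial_types == "near"), format(x$seed)))
  invisible(x)
}

#' @export
as.data.frame.session_schedule <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x$trials), function(i)
    as.data.frame(x$trials[[i]], trial_id = i)))
}

#' N-gram context-ambiguity analysis
#'
#' For each context length `L`, enumerates every within-trial length-`L`
#' symbol context of the supplied trials together with its observed next
#' symbols. A position is *trial-type-determined* when its next symbol lies
#' in a reward zone (R1 or R2 block): there the next symbol is fixed by the
#' trial type, unlike the indicator onset or the post-teleport trial start,
#' which are sampled at random. A context is *ambiguous* at length `L` when
#' it occurs at determined positions yet maps to different next symbols on
#' near versus far trials, so a predictor with an `L`-symbol memory cannot
#' resolve the reward location. `max_ambiguous_L` is the largest such `L`;
#' contexts longer than that suffice to solve the task.
#'
#' @param sequences list of `trial_sequence` objects over a shared alphabet
#'   (contexts never cross trial boundaries).
#' @param L_max maximum context length examined, >= 1.
#' @return list with `maps` (one data frame per L: `context`, `next_symbols`,
#'   `trial_types`, `determined`, `ambiguous`) and `max_ambiguous_L`
#'   (0 when no determined context is ambiguous at any examined length).
#' @export
context_ambiguity <- function(sequences, L_max = 10) {
  if (length(sequences) == 0) stop("empty sequence list")
  if (L_max < 1) stop("L_max must be >= 1")
  dialects <- vapply(sequences, function(s) s$dialect, "")
  if (length(unique(dialects)) != 1)
    stop("sequences must share one alphabet/dialect")

  reward_segments <- function(trial) {
    lay <- track_layout(if (trial$variant == "stretched") "stretched"
                        else "standard")
    segs <- lay$segments
    which(segs$region %in% c("r1", "r2"))[
      seq_len(min(length(trial$symbols), nrow(segs)))
      ] -> idx
    idx <- segs$segment[segs$region %in% c("r1", "r2")]
    idx[idx <= length(trial$symbols)]
  }

  maps <- vector("list", L_max)
  max_amb <- 0L
  for (L in seq_len(L_max)) {
    rows <- list()
    for (s in sequences) {
      sym <- s$symbols
      rz <- reward_segments(s)
      n <- length(sym)
      if (n <= L) next
      for (p in L:(n - 1L)) {
        ctx <- paste(sym[(p - L + 1L):p], collapse = ",")
        rows[[length(rows) + 1L]] <- data.frame(
          context = ctx, next_symbol = sym[p + 1L],
          trial_type = s$trial_type,
          determined = (p + 1L) %in% rz, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    agg <- lapply(split(df, df$context), function(g) data.frame(
      context = g$context[1],
      next_symbols = paste(sort(unique(g$next_symbol)), collapse = ","),
      trial_types = paste(sort(unique(g$trial_type)), collapse = ","),
      determined = any(g$determined),
      ambiguous = any(g$determined) &&
        length(unique(g$next_symbol[g$determined])) > 1L,
      stringsAsFactors = FALSE))
    agg <- do.call(rbind, agg)
    rownames(agg) <- NULL
    maps[[L]] <- agg
    if (any(agg$ambiguous)) max_amb <- L
  }
  list(maps = maps, max_ambiguous_L = max_amb)
}
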