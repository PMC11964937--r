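#' Assemble a calcium imaging session container
#'
#' Time-aligned fluorescence and behaviour sampled at a common frame rate
#' (10 Hz by default): raw fluorescence per cell, track position and running
#' speed per frame, lick frames, and a trial table with start/end frames and
#' trial types. This is the container consumed by the dF/F0, tuning,
#' place-field, splitter and behaviour analyses, and the one emitted by the
#' synthetic generator.
#'
#' @param F cells x frames fluorescence matrix.
#' @param position per-frame track position (cm).
#' @param speed per-frame running speed (cm/s).
#' @param licks integer frame indices of licks.
#' @param trials data frame with columns `trial`, `type` ("near"/"far"),
#'   `start`, `end` (frame indices), and optionally `variant`.
#' @param frame_rate frames per second (default 10).
#' @param track_length_cm track length (default 230).
#' @return an object of class `calcium_session`.
#' @export
calcium_session <- function(F, position, speed, licks, trials,
                            frame_rate = 10, track_length_cm = 230) {
  F <- as.matrix(F)
  stopifnot(ncol(F) == length(position), length(position) == length(speed))
  if (any(position < 0 | position > track_length_cm, na.rm = TRUE))
    stop("positions outside [0, track length]")
  if (is.null(trials$variant)) trials$variant <- "standard"
  structure(list(F = F, position = position, speed = speed,
                 licks = as.integer(licks), trials = trials,
                 frame_rate = frame_rate, track_length_cm = track_length_cm),
            class = "calcium_session")
}

#' @export
print.calcium_session <- function(x, ...) {
  cat(sprintf("<calcium_session> %d cells x %d frames (%.0f Hz), %d trials\n",
              nrow(x$F), ncol(x$F), x$frame_rate, nrow(x$trials)))
  invisible(x)
}

gaussian_smooth <- function(x, sigma_frames) {
  half <- max(1L, ceiling(3 * sigma_frames))
  k <- dnorm(-half:half, sd = sigma_frames)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Baseline, dF/F0 and significant transients
#'
#' The per-cell baseline F0 is a 5-s Gaussian smooth followed by a "maximin"
#' filter (rolling maximum of the rolling minimum, 30-s windows). dF/F0 is
#' `(F - F0) / F0`. The baseline noise scale sigma is the standard deviation
#' of dF/F0 over the frames falling in the lower 25th percentile of each 5-s
#' bin. Significant transients start when dF/F0 exceeds 5 sigma and end when
#' it returns within 1 sigma of baseline.
#'
#' @param session a `calcium_session`.
#' @param gauss_s Gaussian filter width (s), interpreted as full width
#'   (sigma = width/4, ~1.25 s at the 5-s default).
#' @param maximin_s maximin window (s, default 30).
#' @param bin_s sigma estimation bin (s, default 5).
#' @return an object of class `dff_traces`: list with `dff` (cells x
#'   frames), `F0`, `sigma` (per cell, floored at 1e-6 and flagged in
#'   `sigma_degenerate`), and `transients` (per-cell data frame of
#'   onset/offset frames).
#' @export
preprocess_session <- function(session, gauss_s = 5, maximin_s = 30,
                               bin_s = 5) {
  fr <- session$frame_rate
  n <- ncol(session$F)
  sigma_frames <- gauss_s * fr / 4
  win <- max(3L, as.integer(maximin_s * fr))
  F0 <- t(apply(session$F, 1, function(x) {
    sm <- gaussian_smooth(x, sigma_frames)
    roll_extreme_cpp(roll_extreme_cpp(sm, win, FALSE), win, TRUE)
  }))
  F0 <- pmax(F0, 1e-6)
  dff <- (session$F - F0) / F0

  binw <- max(2L, as.integer(bin_s * fr))
  bins <- ceiling(seq_len(n) / binw)
  sigma <- apply(dff, 1, function(x) {
    low <- unlist(lapply(split(x, bins), function(b)
      b[b <= stats::quantile(b, 0.25)]))
    stats::sd(low)
  })
  deg <- !is.finite(sigma) | sigma <= 0
  sigma[deg] <- 1e-6

  transients <- lapply(seq_len(nrow(dff)), function(ci)
    find_transients(dff[ci, ], sigma[ci]))
  structure(list(dff = dff, F0 = F0, sigma = sigma, sigma_degenerate = deg,
                 transients = transients, frame_rate = fr),
            class = "dff_traces")
}

# 5-sigma onset / 1-sigma offset transient detection on one trace
find_transients <- function(x, sigma) {
  on <- integer(0); off <- integer(0)
  i <- 1L; n <- length(x)
  while (i <= n) {
    if (x[i] >= 5 * sigma) {
      j <- i
      while (j < n && x[j + 1L] > sigma) j <- j + 1L
      on <- c(on, i); off <- c(off, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(onset = on, offset = off)
}

transient_mask <- function(transients, n) {
  m <- logical(n)
  if (nrow(transients))
    for (k in seq_len(nrow(transients)))
      m[transients$onset[k]:transients$offset[k]] <- TRUE
  m
}

# frames belonging to active trials of a type, moving faster than speed_min
qualifying_frames <- function(session, trial_type, speed_min = 5,
                              active_only = TRUE, variant = "standard") {
  tr <- session$trials
  sel <- tr$type == trial_type & tr$variant == variant
  if (active_only) {
    rz <- reward_zone_cm(variant)
    active <- vapply(seq_len(nrow(tr)), function(i) {
      lk <- session$licks[session$licks >= tr$start[i] &
                          session$licks <= tr$end[i]]
      any(in_any_zone(session$position[lk], rz))
    }, TRUE)
    sel <- sel & active
  }
  if (!any(sel)) stop("no qualifying trials of type ", trial_type)
  frames <- unlist(lapply(which(sel), function(i) tr$start[i]:tr$end[i]))
  frames[session$speed[frames] > speed_min & !is.na(session$position[frames])]
}

reward_zone_cm <- function(variant = "standard") {
  lay <- track_layout(variant)
  segs <- lay$segments
  lapply(c(r1 = "r1", r2 = "r2"), function(r) {
    s <- segs$start_cm[segs$region == r]
    c(min(s), max(s) + 10)
  })
}

in_any_zone <- function(pos, zones) {
  out <- rep(FALSE, length(pos))
  for (z in zones) out <- out | (pos >= z[1] & pos < z[2])
  out
}

#' Positional tuning curves
#'
#' Mean dF/F0 per 5-cm position bin, per cell, computed over frames from
#' active trials (at least one lick in a reward zone) of the requested type
#' while the animal ran faster than 5 cm/s.
#'
#' @param dff a `dff_traces` (or a cells x frames dF/F0 matrix).
#' @param session the `calcium_session` the traces came from.
#' @param trial_type `"near"` or `"far"`.
#' @param bin_cm spatial bin (default 5 cm).
#' @param speed_min running-speed threshold, cm/s (default 5).
#' @param active_only restrict to active trials (default TRUE).
#' @param variant restrict to trials of this variant (default "standard").
#' @return an object of class `tuning_curves`: list with `curves` (cells x
#'   bins), `occupancy` (frames per bin), `bin_start_cm`, `trial_type`.
#' @export
tuning_curve <- function(dff, session, trial_type, bin_cm = 5, speed_min = 5,
                         active_only = TRUE, variant = "standard") {
  mat <- if (inherits(dff, "dff_traces")) dff$dff else as.matrix(dff)
  frames <- qualifying_frames(session, trial_type, speed_min, active_only,
                              variant)
  track_len <- if (variant == "stretched") 330 else session$track_length_cm
  nb <- ceiling(track_len / bin_cm)
  bi <- pmin(floor(session$position[frames] / bin_cm) + 1L, nb)
  occ <- tabulate(bi, nb)
  sums <- rowsum(t(mat[, frames, drop = FALSE]), bi)
  curves <- matrix(0, nrow(mat), nb)
  curves[, as.integer(rownames(sums))] <-
    t(sums / pmax(occ[as.integer(rownames(sums))], 1))
  structure(list(curves = curves, occupancy = occ,
                 bin_start_cm = bin_cm * (seq_len(nb) - 1L),
                 bin_cm = bin_cm, trial_type = trial_type, variant = variant),
            class = "tuning_curves")
}

#' Population vector from tuning curves
#'
#' @param tc a `tuning_curves`.
#' @return a `position_pv` (bins x cells).
#' @export
tuning_pv <- function(tc) {
  position_pv(t(tc$curves), positions_cm = tc$bin_start_cm,
              trial_type = tc$trial_type, source = "calcium")
}

# putative fields on one curve: contiguous bins above 25% of (peak - p25),
# width within [15,120] cm, in/out mean ratio >= 4
putative_fields <- function(curve, bin_cm, min_cm = 15, max_cm = 120,
                            ratio_min = 4) {
  p25 <- stats::quantile(curve, 0.25, names = FALSE)
  thr <- p25 + 0.25 * (max(curve) - p25)
  above <- curve > thr
  if (!any(above) || all(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  for (k in which(r$values)) {
    w <- r$lengths[k] * bin_cm
    if (w < min_cm || w > max_cm) next
    inside <- starts[k]:ends[k]
    m_in <- mean(curve[inside]); m_out <- mean(curve[-inside])
    if (m_out > 0 && m_in / m_out < ratio_min) next
    if (m_out <= 0 && m_in <= 0) next
    out <- rbind(out, data.frame(start_bin = starts[k], end_bin = ends[k],
                                 start_cm = (starts[k] - 1L) * bin_cm,
                                 end_cm = ends[k] * bin_cm, width_cm = w))
  }
  out
}

#' Place-field detection with a block-shuffle null
#'
#' Applies the 25%-of-peak contiguity rule to a cell's tuning curve, keeps
#' fields 15-120 cm wide whose in-field mean dF/F0 is at least 4 times the
#' out-of-field mean and within which significant transients cover at least
#' 20% of the occupied frames, then builds a null by shuffling 10-s blocks
#' of the calcium trace relative to position and repeating the analysis. A
#' cell is significant when qualifying fields arise in fewer than 5% of
#' shuffles.
#'
#' @param cell cell index.
#' @param dff a `dff_traces` from [preprocess_session()].
#' @param session the matching `calcium_session`.
#' @param trial_type trial type analysed (default "near").
#' @param n_shuffles shuffle count (default 1000; >= 100 for a scaled-down
#'   run).
#' @param seed seed for the shuffles.
#' @param block_s shuffle block length in seconds (default 10).
#' @param occupancy_min minimum in-field transient occupancy (default 0.2).
#' @return an object of class `place_field_result`: list with `fields`
#'   (data frame, possibly empty), `p_shuffle`, `significant`,
#'   `n_shuffles`.
#' @export
detect_place_fields <- function(cell, dff, session, trial_type = "near",
                                n_shuffles = 1000, seed = 1L, block_s = 10,
                                occupancy_min = 0.2) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  fr <- session$frame_rate
  block <- as.integer(block_s * fr)
  if (ncol(session$F) < block) stop("session shorter than one shuffle block")
  frames <- qualifying_frames(session, trial_type)
  nb <- ceiling(session$track_length_cm / 5)
  bi <- pmin(floor(session$position[frames] / 5) + 1L, nb)
  occ <- tabulate(bi, nb)
  trace <- dff$dff[cell, ]
  tmask <- transient_mask(dff$transients[[cell]], length(trace))

  eval_one <- function(x, tm) {
    sums <- rowsum(x[frames], bi)
    curve <- rep(0, nb)
    curve[as.integer(rownames(sums))] <-
      sums[, 1] / pmax(occ[as.integer(rownames(sums))], 1)
    flds <- putative_fields(curve, 5)
    if (is.null(flds)) return(NULL)
    keep <- vapply(seq_len(nrow(flds)), function(k) {
      inb <- bi >= flds$start_bin[k] & bi <= flds$end_bin[k]
      sum(inb) > 0 && mean(tm[frames][inb]) >= occupancy_min
    }, TRUE)
    if (!any(keep)) return(NULL)
    flds[keep, , drop = FALSE]
  }

  fields <- eval_one(trace, tmask)
  local_rng(seed)
  n <- length(trace)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block))
  hits <- 0L
  for (s in seq_len(n_shuffles)) {
    perm <- unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
    if (!is.null(eval_one(trace[perm], tmask[perm]))) hits <- hits + 1L
  }
  p <- hits / n_shuffles
  structure(list(fields = if (is.null(fields))
                   data.frame(start_bin = integer(0), end_bin = integer(0),
                              start_cm = numeric(0), end_cm = numeric(0),
                              width_cm = numeric(0)) else fields,
                 p_shuffle = p,
                 significant = !is.null(fields) && p < 0.05,
                 n_shuffles = n_shuffles),
            class = "place_field_result")
}

#' Spatial dispersion index
#'
#' Shannon entropy (bits) of the area-normalized positional tuning curve: 0
#' for a cell active in a single bin, log2(n_bins) for uniform activity.
#'
#' @param curve nonnegative tuning curve (vector over position bins).
#' @return entropy in bits.
#' @export
spatial_dispersion <- function(curve) {
  if (any(curve < 0)) stop("curve must be nonnegative")
  s <- sum(curve)
  if (s <= 0) stop("all-zero curve")
  p <- curve / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Splitter-cell score and category
#'
#' Compares a cell's near and far tuning curves: `r` is their Pearson
#' correlation and `D = |A_near - A_far| / max(A_near, A_far)` the
#' fractional difference of the peak activities. Cells are categorized by
#' the thresholds r = 0.2, D = 0.5: place/place-splitter responses (high r,
#' low D), splitter responses (high D), remapping-splitter responses (low r,
#' low D: equal-amplitude peaks at different positions).
#'
#' @param curve_near,curve_far tuning curves of one cell.
#' @param r_threshold,d_threshold category thresholds (defaults 0.2, 0.5).
#' @return an object of class `splitter_score`: list with `r`, `D`,
#'   `A_near`, `A_far`, `category` (`"place"`, `"splitter"`,
#'   `"remapping_splitter"`, or NA with `excluded = TRUE` when both peaks
#'   are zero).
#' @export
splitter_score <- function(curve_near, curve_far, r_threshold = 0.2,
                           d_threshold = 0.5) {
  A_near <- max(curve_near); A_far <- max(curve_far)
  if (A_near <= 0 && A_far <= 0)
    return(structure(list(r = NA_real_, D = NA_real_, A_near = A_near,
                          A_far = A_far, category = NA_character_,
                          excluded = TRUE), class = "splitter_score"))
  r <- as.numeric(safe_pearson(curve_near, curve_far))
  D <- abs(A_near - A_far) / max(A_near, A_far)
  category <- if (D >= d_threshold) "splitter"
              else if (r > r_threshold) "place" else "remapping_splitter"
  structure(list(r = r, D = D, A_near = A_near, A_far = A_far,
                 category = category, excluded = FALSE),
            class = "splitter_score")
}

#' Classify all cells of a session by splitter score
#'
#' @param tc_near,tc_far `tuning_curves` for near and far trials.
#' @param activity_sd peak-activity filter: a cell is scored only if its
#'   peak exceeds `activity_sd` standard deviations above its mean curve
#'   (default 2).
#' @return data frame with one row per cell: `cell`, `r`, `D`, `category`,
#'   `included`.
#' @export
classify_cells <- function(tc_near, tc_far, activity_sd = 2) {
  n <- nrow(tc_near$curves)
  out <- lapply(seq_len(n), function(ci) {
    cn <- tc_near$curves[ci, ]; cf <- tc_far$curves[ci, ]
    both <- c(cn, cf)
    act <- max(both) > mean(both) + activity_sd * stats::sd(both)
    if (!act || !is.finite(act))
      return(data.frame(cell = ci, r = NA, D = NA, category = NA,
                        included = FALSE))
    s <- splitter_score(cn, cf)
    data.frame(cell = ci, r = s$r, D = s$D,
               category = if (s$excluded) NA else s$category,
               included = !s$excluded)
  })
  do.call(rbind, out)
}

#' Tuning-peak shift between standard and stretched trials
#'
#' Pairs each cell's tuning peak location in standard trials with its peak
#' in stretched trials of the same type. Cells lacking a field (peak below
#' `min_peak`) in either condition are excluded and counted. Histograms of
#' stretched-trial field locations inside the two inserted segments are
#' returned for inspection of persistent versus shifted tuning.
#'
#' @param tc_normal,tc_stretched `tuning_curves` for the same cells in
#'   standard and stretched trials.
#' @param min_peak minimum peak dF/F0 for a cell to count as having a field.
#' @return list with `pairs` (data frame `cell`, `normal_peak_cm`,
#'   `stretched_peak_cm`), `n_excluded`, and `stretch_histograms` (field
#'   location counts in the two inserted regions).
#' @export
field_shift_analysis <- function(tc_normal, tc_stretched, min_peak = 0.1) {
  stopifnot(nrow(tc_normal$curves) == nrow(tc_stretched$curves))
  n <- nrow(tc_normal$curves)
  rows <- list(); excluded <- 0L
  for (ci in seq_len(n)) {
    cn <- tc_normal$curves[ci, ]; cs <- tc_stretched$curves[ci, ]
    if (max(cn) < min_peak || max(cs) < min_peak) {
      excluded <- excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell = ci,
      normal_peak_cm = tc_normal$bin_start_cm[which.max(cn)],
      stretched_peak_cm = tc_stretched$bin_start_cm[which.max(cs)])
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), normal_peak_cm = numeric(0),
               stretched_peak_cm = numeric(0))
  # inserted segments of the stretched track: [130,180) and [230,280) cm
  h1 <- pairs$stretched_peak_cm[pairs$stretched_peak_cm >= 130 &
                                pairs$stretched_peak_cm < 180]
  h2 <- pairs$stretched_peak_cm[pairs$stretched_peak_cm >= 230 &
                                pairs$stretched_peak_cm < 280]
  list(pairs = pairs, n_excluded = excluded,
       stretch_histograms = list(first_gap = h1, second_gap = h2))
}
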