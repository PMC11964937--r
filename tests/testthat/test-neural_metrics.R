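# calcium-trace analysis: baselines, transients, tuning, fields, splitters

# minimal hand-built session: constant running on a 230-cm track
make_toy_session <- function(F, n_laps = 4, frames_per_lap = NULL,
                             lick_at = 140) {
  n <- ncol(F)
  if (is.null(frames_per_lap)) frames_per_lap <- n / n_laps
  position <- rep(seq(0, 229.99, length.out = frames_per_lap), n_laps)
  speed <- rep(230 / (frames_per_lap / 10), n) # cm/s, constant, > 5
  starts <- seq(1, n, by = frames_per_lap)
  trials <- data.frame(trial = seq_len(n_laps),
                       type = rep(c("near", "far"), length.out = n_laps),
                       start = starts,
                       end = pmin(starts + frames_per_lap - 1, n))
  licks <- vapply(seq_len(n_laps), function(i) {
    fr <- trials$start[i]:trials$end[i]
    fr[which(position[fr] >= lick_at)[1]]
  }, 0L)
  calcium_session(F, position, speed, licks, trials)
}

test_that("a constant trace yields zero dF/F0 and no transients", {
  F <- matrix(100, 2, 400)
  ses <- make_toy_session(F)
  pp <- preprocess_session(ses)
  expect_true(all(abs(pp$dff) < 1e-9))
  expect_true(all(pp$sigma_degenerate))
  expect_equal(nrow(pp$transients[[1]]), 0)
})

test_that("a planted transient is detected with a tight onset", {
  set.seed(21)
  n <- 600
  F <- matrix(100 + rnorm(2 * n, 0, 0.5), 2, n)
  # one large transient on cell 1 at frame 300
  bump <- 40 * exp(-(0:30) / 7)
  F[1, 300:330] <- F[1, 300:330] + bump
  ses <- make_toy_session(F, n_laps = 4)
  pp <- preprocess_session(ses)
  tr <- pp$transients[[1]]
  big <- tr[tr$offset - tr$onset > 2, ]
  expect_equal(nrow(big), 1)
  expect_lte(abs(big$onset - 300), 3)
  # slow drift is tracked by the baseline: dff stays near zero
  drift <- matrix(100 + seq(0, 10, length.out = n), 1, n, byrow = TRUE)
  sesd <- make_toy_session(rbind(drift, drift), n_laps = 4)
  ppd <- preprocess_session(sesd)
  expect_lt(max(abs(ppd$dff)), 0.05)
})

test_that("tuning curves localize a planted field and filter by speed", {
  set.seed(22)
  n <- 1200
  frames_per_lap <- 300
  position <- rep(seq(0, 229.99, length.out = frames_per_lap), 4)
  dff <- matrix(exp(-(position - 120)^2 / (2 * 8^2)), 1, n)
  ses <- make_toy_session(matrix(100, 1, n), n_laps = 4)
  tc <- tuning_curve(dff, ses, "near")
  peak_cm <- tc$bin_start_cm[which.max(tc$curves[1, ])]
  expect_lt(abs(peak_cm + 2.5 - 120), 5)
  # uniform dff gives a flat curve
  flat <- tuning_curve(matrix(1, 1, n), ses, "near")
  occupied <- flat$occupancy > 0
  expect_true(all(abs(flat$curves[1, occupied] - 1) < 1e-12))
  # appending stationary frames leaves the curve unchanged
  ses2 <- ses
  ses2$speed[1:100] <- 0
  tc2 <- tuning_curve(dff, ses2, "near")
  dff3 <- dff; dff3[1, 1:100] <- 99
  tc3 <- tuning_curve(dff3, ses2, "near")
  expect_equal(tc2$curves, tc3$curves)
  expect_error(tuning_curve(dff, ses, "far", variant = "stretched"),
               "no qualifying")
})

test_that("place-field criteria enforce width bounds and shuffles calibrate", {
  set.seed(23)
  # planted 30-cm field riding on sparse background transients (so the
  # shuffle null has realistic out-of-field activity)
  n <- 3000; frames_per_lap <- 250
  position <- rep(seq(0, 229.99, length.out = frames_per_lap), 12)
  F <- matrix(100, 2, n)
  infield <- position >= 100 & position < 130
  bg <- stats::filter(rbinom(n, 1, 0.04), exp(-(0:20) / 7), sides = 1)
  bg[is.na(bg)] <- 0
  F[1, ] <- 100 + 80 * infield + 50 * as.numeric(bg) + rnorm(n, 0, 0.8)
  F[2, ] <- 100 + rnorm(n, 0, 0.8)  # noise-only cell
  ses <- make_toy_session(F, n_laps = 12)
  pp <- preprocess_session(ses)
  res <- detect_place_fields(1, pp, ses, n_shuffles = 200, seed = 1)
  expect_true(res$significant)
  expect_gte(nrow(res$fields), 1)
  expect_true(any(res$fields$start_cm >= 85 & res$fields$end_cm <= 145))
  expect_true(all(res$fields$width_cm >= 15 & res$fields$width_cm <= 120))
  # a 10-cm field is rejected by the 15-cm minimum
  narrow <- osmlab:::putative_fields(
    c(rep(0.01, 20), rep(5, 2), rep(0.01, 24)), bin_cm = 5)
  expect_null(narrow)
  expect_error(detect_place_fields(1, pp, ses, n_shuffles = 50), "100")
})

test_that("noise-only cells pass the shuffle null at the nominal rate", {
  set.seed(24)
  n <- 2000; n_cells <- 40
  F <- matrix(100 + rnorm(n_cells * n, 0, 1), n_cells, n)
  ses <- make_toy_session(F, n_laps = 8)
  pp <- preprocess_session(ses)
  fp <- 0
  for (ci in seq_len(n_cells)) {
    r <- detect_place_fields(ci, pp, ses, n_shuffles = 100, seed = ci)
    if (r$significant) fp <- fp + 1
  }
  # binomial slack around the 5% level for 40 cells
  expect_lte(fp / n_cells, 0.05 + 2 * sqrt(0.05 * 0.95 / n_cells))
})

test_that("spatial dispersion entropy matches closed forms", {
  expect_equal(spatial_dispersion(c(0, 3, 0, 0)), 0)
  expect_equal(spatial_dispersion(rep(1, 46)), log2(46))
  expect_equal(round(spatial_dispersion(rep(1, 46)), 3), 5.524)
  expect_equal(spatial_dispersion(c(1, 1)), 1)
  expect_error(spatial_dispersion(rep(0, 5)), "all-zero")
  expect_error(spatial_dispersion(c(-1, 2)), "nonnegative")
})

test_that("splitter scores and categories follow the planted geometry", {
  x <- exp(-(seq(2.5, 227.5, by = 5) - 120)^2 / 200)
  s1 <- splitter_score(x, x)
  expect_equal(s1$r, 1)
  expect_equal(s1$D, 0)
  expect_equal(s1$category, "place")
  s2 <- splitter_score(2 * x, x)
  expect_equal(s2$D, 0.5)
  expect_equal(s2$category, "splitter")
  s3 <- splitter_score(x, 0 * x)
  expect_equal(s3$D, 1)
  # equal-amplitude peaks at different locations: remapping splitter
  y <- exp(-(seq(2.5, 227.5, by = 5) - 40)^2 / 200)
  s4 <- splitter_score(x, y)
  expect_lt(s4$D, 0.5)
  expect_lt(s4$r, 0.2)
  expect_equal(s4$category, "remapping_splitter")
  s5 <- splitter_score(0 * x, 0 * x)
  expect_true(s5$excluded)
  # the partition is exhaustive and mutually exclusive on random curves
  set.seed(25)
  for (k in 1:50) {
    cn <- runif(46); cf <- runif(46)
    s <- splitter_score(cn, cf)
    expect_true(s$category %in% c("place", "splitter", "remapping_splitter"))
  }
})

test_that("field-shift pairs stay on the identity line before the stretch", {
  bins_n <- seq(0, 225, by = 5)
  bins_s <- seq(0, 325, by = 5)
  mk <- function(center, bins) exp(-(bins + 2.5 - center)^2 / (2 * 64))
  curves_n <- rbind(mk(40, bins_n), mk(120, bins_n), 0 * bins_n)
  curves_s <- rbind(mk(40, bins_s), mk(165, bins_s), 0 * bins_s)
  tcn <- structure(list(curves = curves_n, bin_start_cm = bins_n,
                        bin_cm = 5, trial_type = "near"),
                   class = "tuning_curves")
  tcs <- structure(list(curves = curves_s, bin_start_cm = bins_s,
                        bin_cm = 5, trial_type = "near"),
                   class = "tuning_curves")
  fs <- field_shift_analysis(tcn, tcs)
  expect_equal(fs$n_excluded, 1)
  # the early cell is on the identity line; the later one shifted into the gap
  expect_equal(fs$pairs$stretched_peak_cm[fs$pairs$normal_peak_cm < 100][1],
               fs$pairs$normal_peak_cm[fs$pairs$normal_peak_cm < 100][1],
               tolerance = 5)
  expect_length(fs$stretch_histograms$first_gap, 1)
})
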