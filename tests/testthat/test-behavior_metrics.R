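# licking strategies, CPD decomposition and task performance

toy_lick_session <- function(lick_pos_by_trial, types, frames_per_trial = 100) {
  n_trials <- length(types)
  n <- n_trials * frames_per_trial
  position <- rep(seq(0, 229.99, length.out = frames_per_trial), n_trials)
  starts <- seq(1, n, by = frames_per_trial)
  trials <- data.frame(trial = seq_len(n_trials), type = types,
                       start = starts, end = starts + frames_per_trial - 1)
  licks <- integer(0)
  for (i in seq_len(n_trials)) {
    for (p in lick_pos_by_trial[[i]]) {
      fr <- trials$start[i]:trials$end[i]
      licks <- c(licks, fr[which(position[fr] >= p)[1]])
    }
  }
  calcium_session(matrix(0, 1, n), position,
                  rep(25, n), licks, trials)
}

test_that("lick densities bin correctly and split halves by duration", {
  ses <- toy_lick_session(list(140, 140, 187, 187),
                          c("near", "near", "far", "far"))
  lp <- lick_density(ses, bin_cm = 5)
  b140 <- floor(140 / 5) + 1
  expect_equal(lp$density[b140, "near", "start"], 1)
  expect_equal(sum(lp$density[, "near", "start"]), 1)
  # far trials fall in the second half of this 4-trial session
  expect_equal(sum(lp$density[, "far", "start"]), 0)
  expect_gt(sum(lp$density[, "far", "end"]), 0)
  empty <- toy_lick_session(list(numeric(0), numeric(0)), c("near", "far"))
  expect_true(lick_density(empty)$no_licks)
})

test_that("strategy bases have the stated supports and unit mass", {
  basis <- strategy_basis()
  nb <- length(basis$bin_start_cm)
  expect_equal(colSums(basis$X), rep(1, 4), ignore_attr = TRUE)
  centers <- basis$bin_start_cm + 2.5
  near_rows <- seq_len(nb); far_rows <- nb + seq_len(nb)
  # expert near support: lead-in plus R1 only, [110, 150)
  sup <- centers[basis$X[near_rows, "expert"] > 0]
  expect_true(all(sup >= 110 & sup < 150))
  # expert far support: lead-in plus R2
  supf <- centers[basis$X[far_rows, "expert"] > 0]
  expect_true(all(supf >= 160 & supf < 200))
  # lick-stop: nothing after R1 offset on near trials
  expect_true(all(centers[basis$X[near_rows, "lick_stop"] > 0] < 150))
  # but mass through R2 on far trials
  expect_gt(sum(basis$X[far_rows, "lick_stop"] *
                  (centers >= 150 & centers < 200)), 0)
  # random is uniform
  expect_equal(var(basis$X[, "random"]), 0)
})

test_that("CPD attains its closed-form limits", {
  basis <- strategy_basis()
  nb <- length(basis$bin_start_cm)
  mk_profile <- function(y) {
    dens <- array(rep(matrix(y, ncol = 2), 2), c(nb, 2, 2),
                  dimnames = list(NULL, c("near", "far"),
                                  c("start", "end")))
    structure(list(density = dens, bin_start_cm = basis$bin_start_cm,
                   bin_cm = 5, no_licks = FALSE), class = "lick_profile")
  }
  # profile exactly equal to the expert regressor: CPD_expert = 1 and the
  # redundant-fit regressors contribute 0
  y <- basis$X[, "expert"]
  res <- cpd(mk_profile(y), basis)
  expect_equal(unname(res$cpd["expert", "start"]), 1)
  expect_lt(max(res$cpd[c("random", "both_rewards"), ]), 1e-9)
  expect_equal(unname(res$dominant["start"]), "expert")
  # a duplicated regressor zeroes both copies
  basis2 <- basis
  basis2$X <- cbind(basis$X, expert2 = basis$X[, "expert"])
  res2 <- cpd(mk_profile(y), basis2)
  expect_lt(max(res2$cpd[c("expert", "expert2"), ]), 1e-9)
})

test_that("CPD is invariant to regressor scaling", {
  set.seed(31)
  basis <- strategy_basis()
  nb <- length(basis$bin_start_cm)
  y <- 0.5 * basis$X[, "lick_stop"] + 0.2 * basis$X[, "random"] +
    rnorm(2 * nb, 0, 0.001)
  dens <- array(rep(matrix(y, ncol = 2), 2), c(nb, 2, 2),
                dimnames = list(NULL, c("near", "far"), c("start", "end")))
  prof <- structure(list(density = dens, bin_start_cm = basis$bin_start_cm,
                         bin_cm = 5, no_licks = FALSE),
                    class = "lick_profile")
  r1 <- cpd(prof, basis)
  basis_scaled <- basis
  basis_scaled$X <- sweep(basis$X, 2, c(10, 0.1, 3, 7), "*")
  r2 <- cpd(prof, basis_scaled)
  expect_equal(r1$cpd, r2$cpd, tolerance = 1e-8)
  expect_equal(unname(r1$dominant["end"]), "lick_stop")
})

test_that("a planted lick-stop/expert mixture is attributed to lick-stop", {
  set.seed(32)
  basis <- strategy_basis()
  nb <- length(basis$bin_start_cm)
  y <- 0.7 * basis$X[, "lick_stop"] + 0.3 * basis$X[, "expert"] +
    abs(rnorm(2 * nb, 0, 5e-4))
  dens <- array(rep(matrix(y, ncol = 2), 2), c(nb, 2, 2),
                dimnames = list(NULL, c("near", "far"), c("start", "end")))
  prof <- structure(list(density = dens, bin_start_cm = basis$bin_start_cm,
                         bin_cm = 5, no_licks = FALSE),
                    class = "lick_profile")
  expect_equal(unname(cpd(prof, basis)$dominant["start"]), "lick_stop")
})

test_that("trial accuracy requires licking only at the correct zone", {
  ses <- toy_lick_session(list(140,          # near, correct
                               c(140, 187),  # near, licked both -> wrong
                               187,          # far, correct
                               140),         # far, licked near only -> wrong
                          c("near", "near", "far", "far"))
  perf <- performance(ses)
  expect_equal(perf$trial_correct, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(perf$accuracy, 0.5)
  expect_true(is.na(perf$expert))
  expect_true(performance(ses, history = c(0.8, 0.9, 0.8))$expert)
  expect_false(performance(ses, history = c(0.8, 0.9))$expert)
})
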