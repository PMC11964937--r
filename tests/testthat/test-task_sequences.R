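# printed task sequences, schedules and the n-gram ambiguity analysis

test_that("standard trials reproduce the canonical printed sequences", {
  near_rnn <- make_trial("near", "rnn")
  far_rnn <- make_trial("far", "rnn")
  expect_equal(near_rnn$symbols,
               c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 1, 1, 1, 4, 6, 1, 1, 1, 5, 5,
                 1, 1, 0))
  expect_equal(far_rnn$symbols,
               c(1, 1, 1, 1, 1, 1, 3, 3, 3, 3, 1, 1, 1, 4, 4, 1, 1, 1, 5, 6,
                 1, 1, 0))
  expect_length(near_rnn$symbols, 23)

  near_c <- make_trial("near", "cscg_visual_first")
  far_c <- make_trial("far", "cscg_visual_first")
  expect_equal(near_c$symbols,
               c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 1, 1, 1, 4, 6, 1, 1, 1, 5, 5,
                 1, 1, 7, 0, 0, 0))
  expect_equal(far_c$symbols,
               c(1, 1, 1, 1, 1, 1, 3, 3, 3, 3, 1, 1, 1, 4, 4, 1, 1, 1, 5, 6,
                 1, 1, 7, 0, 0, 0))
  expect_equal(tail(near_c$symbols, 4), c(7, 0, 0, 0))

  # water-first permutes the rewarded zone; conjunctive swaps the far code
  expect_equal(make_trial("near", "cscg_water_first")$symbols[14:15], c(6, 4))
  expect_equal(make_trial("far", "cscg_water_first")$symbols[19:20], c(6, 5))
  expect_equal(make_trial("far", "cscg_conjunctive")$symbols[19:20], c(5, 8))
  expect_equal(make_trial("near", "cscg_conjunctive")$symbols,
               near_c$symbols)
})

test_that("sequence structure invariants hold", {
  near <- make_trial("near", "rnn")
  far <- make_trial("far", "rnn")
  # exactly 6 differing positions: 4 indicator + 2nd symbol of each zone
  expect_equal(sum(near$symbols != far$symbols), 6)
  expect_equal(which(near$symbols != far$symbols), c(7:10, 15, 20))
  # 7 distinct rnn symbols; 8 for the visual-first cscg dialect
  expect_length(union(near$symbols, far$symbols), 7)
  expect_length(union(make_trial("near", "cscg_visual_first")$symbols,
                      make_trial("far", "cscg_visual_first")$symbols), 8)
  # exactly 3 consecutive greys separate the two reward-zone blocks
  expect_equal(near$symbols[16:18], c(1, 1, 1))
  expect_equal(near$symbols[c(15, 19)] == 1, c(FALSE, FALSE))
  # positions strictly increasing by 10 cm
  expect_equal(diff(near$positions_cm), rep(10, 22))
})

test_that("stretched trials follow the extended-track geometry", {
  st <- make_trial("near", "rnn", "stretched")
  expect_length(st$symbols, 33)
  # 8 greys in each stretched gap
  expect_equal(st$symbols[11:18], rep(1, 8))
  expect_equal(st$symbols[21:28], rep(1, 8))
  # near reward block sits at [180, 200), the standard far reward position
  lay <- track_layout("stretched")
  r1 <- lay$segments$start_cm[lay$segments$region == "r1"]
  expect_equal(range(r1), c(180, 190))
  expect_equal(st$symbols[19:20], c(4, 6))
  expect_equal(lay$track_length_cm, 330)
  expect_error(make_trial("near", "cscg_visual_first", "stretched"),
               "stretched")
  expect_error(make_trial("near", "rnn", "bogus"), "unknown variant")
})

test_that("novel indicator pairs replace only the indicator block", {
  nb <- make_trial("near", "rnn", "novel_pair_B")
  base <- make_trial("near", "rnn")
  expect_equal(nb$symbols[-(7:10)], base$symbols[-(7:10)])
  expect_false(any(nb$symbols[7:10] %in% 0:6))
  fc <- make_trial("far", "rnn", "novel_pair_C")
  expect_false(any(fc$symbols[7:10] == nb$symbols[7]))
})

test_that("limited-Poisson schedules respect run caps and balance", {
  s <- sample_session(200, lambda = 0.7, max_repeats = 3, seed = 1)
  expect_lte(max(rle(s$trial_types)$lengths), 3)
  # max_repeats = 1 forces strict alternation
  s1 <- sample_session(10, max_repeats = 1, seed = 7)
  expect_true(all(rle(s1$trial_types)$lengths == 1))
  # long-run type balance
  big <- sample_session(10000, seed = 1)
  expect_lt(abs(mean(big$trial_types == "near") - 0.5), 0.02)
  # deterministic given seed
  expect_identical(sample_session(50, seed = 3)$trial_types,
                   sample_session(50, seed = 3)$trial_types)
  expect_error(sample_session(0), "n_trials")
})

test_that("stretched insertions appear every five or six regular trials", {
  s <- sample_session(40, seed = 2, insert_stretched = TRUE)
  idx <- which(s$variants == "stretched")
  expect_gt(length(idx), 3)
  gaps <- diff(c(0, idx)) - 1
  expect_true(all(gaps %in% c(5, 6)))
})

test_that("context ambiguity finds the reward-determined threshold", {
  near <- make_trial("near", "rnn")
  far <- make_trial("far", "rnn")
  ca <- context_ambiguity(list(near, far), L_max = 10)
  expect_equal(ca$max_ambiguous_L, 4)
  amb4 <- ca$maps[[4]][ca$maps[[4]]$ambiguous, ]
  expect_setequal(amb4$context, c("1,1,1,4", "1,1,1,5"))
  expect_setequal(amb4$next_symbols, c("4,6", "5,6"))
  # no determined context is ambiguous at L = 5 or beyond
  for (L in 5:10) expect_false(any(ca$maps[[L]]$ambiguous))
  # each within-trial position contributes one entry at L = 1
  expect_equal(sum(sapply(strsplit(ca$maps[[1]]$next_symbols, ","), length) *
                     0 + 1) > 0, TRUE)
  # a deterministic single sequence is unambiguous
  toy <- structure(list(symbols = rep(1L, 6), trial_type = "near",
                        dialect = "rnn", variant = "standard",
                        positions_cm = 10 * (0:5)),
                   class = "trial_sequence")
  expect_equal(context_ambiguity(list(toy), 3)$max_ambiguous_L, 0)
  expect_error(context_ambiguity(list(), 4), "empty")
  expect_error(context_ambiguity(list(near, make_trial("near",
                                                       "cscg_visual_first"))),
               "share one alphabet")
})
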