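# spiking soft-WTA network dynamics and plasticity

test_that("stimulus encoding drives only the dedicated disjoint group", {
  p <- spiking_net_params()
  expect_equal(p$n_inputs, 96)
  for (s in 0:7) {
    sp <- encode_stimulus(s, p, n_ms = 50, seed = 1)
    active <- which(rowSums(sp) > 0)
    expect_true(all(active %in% (s * 12 + 1:12)))
  }
  # the 8 groups tile all 96 inputs
  groups <- unlist(lapply(0:7, function(s) s * 12 + 1:12))
  expect_setequal(groups, 1:96)
  expect_error(encode_stimulus(8, p), "outside")
})

test_that("softmax probabilities sum to 1 and are shift invariant", {
  p <- spiking_net_params(K = 30)
  st <- init_spiking_net(p, seed = 2)
  set.seed(3)
  out <- hebbian_step(st, 1, n_ms = 20, plastic = FALSE)
  expect_true(all(abs(colSums(out$record$f_history) - 1) < 1e-9))
  # zero weights and traces: uniform softmax
  st0 <- init_spiking_net(p, seed = 2)
  st0$W[] <- 0; st0$V[] <- 0
  o0 <- hebbian_step(st0, 0, n_ms = 1, plastic = FALSE,
                     input_spikes = matrix(0L, p$n_inputs, 1))
  expect_true(all(abs(o0$record$f_history - 1 / 30) < 1e-12))
})

test_that("the refractory period is never violated over a session", {
  st <- init_spiking_net(spiking_net_params(), seed = 4)
  sched <- sample_session(4, seed = 5, dialect = "cscg_visual_first")
  run <- run_session(st, sched, ms_per_symbol = 30, seed = 6,
                     record_detail = TRUE)
  for (k in seq_len(nrow(run$raster))) {
    times <- which(run$raster[k, ] == 1)
    if (length(times) > 1) expect_gte(min(diff(times)), 10 + 1)
  }
  # weights stay excitatory
  expect_gte(min(run$state$W), 0)
  expect_gte(min(run$state$V), 0)
})

test_that("traces follow the closed-form exponential filter", {
  p <- spiking_net_params(K = 10)
  st <- init_spiking_net(p, seed = 1)
  n_ms <- 60
  spikes <- matrix(0L, p$n_inputs, n_ms)
  spikes[5, 10] <- 1L  # single input spike at t = 10
  out <- hebbian_step(st, 0, n_ms = n_ms, plastic = FALSE,
                      input_spikes = spikes)
  xh <- out$record$x_trace_history[5, ]
  expect_true(all(xh[1:9] == 0))
  for (t in 10:n_ms)
    expect_lt(abs(xh[t] - exp(-(t - 10) / 20)), 1e-9)
})

test_that("the plasticity rule follows its stated update and gating", {
  p <- spiking_net_params(K = 2, n_stimuli = 2, group_size = 2)
  st <- init_spiking_net(p, seed = 1)
  # neuron 1 strongly driven -> softmax ~ (1, 0); neuron 2 never spikes
  st$W <- matrix(c(20, 0, 0, 0, 0, 0, 0, 0), 2, 4)
  st$V[] <- 0
  st$x_trace <- c(1, 1, 0, 0) / exp(-1 / 20)  # decays to exactly 1 at update
  st$y_trace <- rep(0, 2)
  W_before <- st$W
  set.seed(7)
  out <- hebbian_step(st, 0, n_ms = 1, plastic = TRUE,
                      input_spikes = matrix(0L, 4, 1))
  expect_equal(sum(out$record$raster), 1)
  expect_equal(unname(out$record$raster[1, 1]), 1L)
  # spiked row: dw = alpha * (exp(-w) * x_trace - offset)
  expect_equal(out$state$W[1, 2], 0.1 * (exp(0) * 1 - 0.1),
               tolerance = 1e-12)
  # w = 20 with trace 1: tiny decrement
  expect_equal(out$state$W[1, 1], 20 + 0.1 * (exp(-20) * 1 - 0.1),
               tolerance = 1e-12)
  # zero trace: pure decay floored at 0
  expect_equal(out$state$W[1, 3], 0)
  # non-spiking row untouched
  expect_equal(out$state$W[2, ], W_before[2, ])
})

test_that("sessions are deterministic given the seed and frozen at alpha 0", {
  p <- spiking_net_params(K = 40)
  sched <- sample_session(3, seed = 8, dialect = "cscg_visual_first")
  st <- init_spiking_net(p, seed = 9)
  r1 <- run_session(st, sched, ms_per_symbol = 20, seed = 10)
  r2 <- run_session(st, sched, ms_per_symbol = 20, seed = 10)
  expect_identical(r1$counts, r2$counts)
  p0 <- spiking_net_params(K = 40, alpha = 0)
  st0 <- init_spiking_net(p0, seed = 9)
  r0 <- run_session(st0, sched, ms_per_symbol = 20, seed = 10)
  expect_identical(r0$state$W, st0$W)
  expect_identical(r0$state$V, st0$V)
  expect_error(run_session(st, list()), "empty")
})

test_that("representation PVs average planted spike counts by position", {
  # hand-built run object: one neuron firing only at position 3 on near
  counts <- matrix(0, 4, 6)  # 4 neurons, 2 trials x 3 positions
  counts[2, 3] <- 4  # near trial 1, position 3
  counts[2, 6] <- 2  # near trial 2, position 3
  run <- structure(list(counts = counts,
                        trial_types = c("near", "near"),
                        trial_lengths = c(3L, 3L)),
                   class = "hebbian_run")
  pv <- representation_pv(run, "near")
  expect_equal(pv$mat[3, 2], 3)
  expect_equal(sum(pv$mat), 3)
  expect_error(representation_pv(run, "far"), "no complete trial")
})

test_that("a 2-stimulus world develops stimulus-specific assemblies", {
  p <- spiking_net_params(n_stimuli = 2, group_size = 12)
  hits <- 0
  for (seed in 1:5) {
    st <- init_spiking_net(p, seed = seed)
    toy <- list(rep(c(0L, 1L), 30))
    run <- run_session(st, rep(toy, 10), ms_per_symbol = 100,
                       seed = seed + 20)
    # mean activity vectors per stimulus over the last half of training
    steps <- seq_len(ncol(run$counts))
    late <- steps > length(steps) / 2
    sym <- rep(c(0L, 1L), 300)
    a <- rowMeans(run$counts[, late & sym == 0, drop = FALSE])
    b <- rowMeans(run$counts[, late & sym == 1, drop = FALSE])
    top_a <- order(a, decreasing = TRUE)[1:5]
    top_b <- order(b, decreasing = TRUE)[1:5]
    if (length(intersect(top_a, top_b)) == 0) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
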