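# gradient nets: encodings, analytic gradients vs finite differences,
# penalty math, accuracy oracles

fd_check <- function(loss_fn, grads_fn, params, keys, eps = 1e-5,
                     tol = 1e-4, n_probe = 4) {
  gr <- grads_fn(params)
  for (k in keys) {
    set.seed(nchar(k) + 17)
    probes <- sample(length(params[[k]]), min(n_probe, length(params[[k]])))
    for (i in probes) {
      pp <- params; pp[[k]][i] <- pp[[k]][i] + eps
      pm <- params; pm[[k]][i] <- pm[[k]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_lt(abs(num - gr[[k]][i]), tol * max(1, abs(num)))
    }
  }
}

test_that("one-hot encoding round trips all 7 symbols", {
  X <- osmlab:::one_hot(0:6, 7)
  expect_equal(osmlab:::one_hot_decode(X), 0:6)
  expect_equal(colSums(X), rep(1, 7))
  expect_error(osmlab:::one_hot(7, 7), "outside")
})

test_that("net specs validate family-specific fields", {
  expect_error(net_spec("lstm", activation = "relu"), "rate_rnn only")
  expect_error(net_spec("rate_rnn", regularizer = "dropout"), "lstm only")
  expect_error(net_spec("transformer", context_length = 0), "context_length")
  expect_error(net_spec("transformer", embed = 30, n_heads = 4), "divisible")
  s <- net_spec("rate_rnn")
  expect_equal(s$activation, "exp_softmax")
  expect_equal(s$hidden, 500)
})

test_that("correlation penalty matches its closed-form cases", {
  set.seed(4)
  h <- matrix(rnorm(23 * 6), 23, 6)
  expect_equal(correlation_penalty(h, h), 1)
  # orthogonal mean-centered streams
  a <- cbind(1, -1, 1, -1, 0, 0)[rep(1, 10), ]
  b <- cbind(1, 1, -1, -1, 0, 0)[rep(1, 10), ]
  expect_lt(correlation_penalty(a, b), 1e-12)
  # planted r = 0.5 at all positions -> penalty 0.25
  set.seed(5)
  x <- rnorm(200); y <- rnorm(200)
  y <- 0.5 * scale(x)[, 1] + sqrt(0.75) * scale(residuals(lm(y ~ x)))[, 1]
  A <- matrix(x, 3, 200, byrow = TRUE)
  B <- matrix(y, 3, 200, byrow = TRUE)
  expect_equal(correlation_penalty(A, B), 0.25, tolerance = 1e-6)
  expect_error(correlation_penalty(h, h[1:5, ]), "aligned")
})

test_that("correlation penalty gradient passes a finite-difference check", {
  set.seed(6)
  A <- matrix(rnorm(3 * 4), 3, 4)  # 3 units x 4 positions
  B <- matrix(rnorm(3 * 4), 3, 4)
  cp <- osmlab:::corr_penalty_grads(A, B)
  eps <- 1e-6
  for (i in seq_along(A)) {
    Ap <- A; Ap[i] <- Ap[i] + eps
    Am <- A; Am[i] <- Am[i] - eps
    num <- (osmlab:::corr_penalty_grads(Ap, B)$penalty -
            osmlab:::corr_penalty_grads(Am, B)$penalty) / (2 * eps)
    expect_lt(abs(num - cp$dA[i]), 1e-5)
  }
  for (i in seq_along(B)) {
    Bp <- B; Bp[i] <- Bp[i] + eps
    Bm <- B; Bm[i] <- Bm[i] - eps
    num <- (osmlab:::corr_penalty_grads(A, Bp)$penalty -
            osmlab:::corr_penalty_grads(A, Bm)$penalty) / (2 * eps)
    expect_lt(abs(num - cp$dB[i]), 1e-5)
  }
})

test_that("rate RNN BPTT gradients match finite differences", {
  set.seed(7)
  X <- osmlab:::one_hot(sample(0:6, 12, replace = TRUE), 7)
  for (act in c("exp_softmax", "poly_softmax", "relu", "sigmoid")) {
    spec <- net_spec("rate_rnn", hidden = 5, init_sd = 0.3, out_sd = 0.3)
    params <- osmlab:::rnn_init(spec, seed = 8)
    fd_check(function(p) osmlab:::rnn_loss_grads(p, X, act)$loss,
             function(p) osmlab:::rnn_loss_grads(p, X, act)$grads,
             params, c("Wx", "Wh", "b", "Wo", "bo"), tol = 2e-4)
  }
})

test_that("LSTM BPTT gradients match finite differences", {
  set.seed(9)
  X <- osmlab:::one_hot(sample(0:6, 10, replace = TRUE), 7)
  spec <- net_spec("lstm", hidden = 4, init_sd = 0.3, out_sd = 0.3)
  params <- osmlab:::lstm_init(spec, seed = 10)
  cfg <- train_config()
  fd_check(function(p) osmlab:::lstm_loss_grads(p, X, spec, cfg)$loss,
           function(p) osmlab:::lstm_loss_grads(p, X, spec, cfg)$grads,
           params, c("Wx", "Wh", "b", "Wo", "bo"), tol = 2e-4)
})

test_that("transformer gradients match finite differences", {
  spec <- net_spec("transformer", n_layers = 2, n_heads = 2, embed = 8,
                   context_length = 8)
  params <- osmlab:::tf_init(spec, seed = 11)
  set.seed(12)
  toks <- sample(0:6, 8, replace = TRUE)
  keys <- c("tok", "pos", "qkv_1", "proj_2", "fc1_1", "fc2_2", "ln1g_1",
            "ln2b_2", "lnfg", "head")
  fd_check(function(p) osmlab:::tf_loss_grads(p, toks, spec)$loss,
           function(p) osmlab:::tf_loss_grads(p, toks, spec)$grads,
           params, keys, tol = 5e-4)
})

test_that("prediction accuracy has the right trivial baselines", {
  near <- make_trial("near", "rnn")
  far <- make_trial("far", "rnn")
  # an untrained tiny net is a valid predictor object for the accuracy op
  spec <- net_spec("rate_rnn", hidden = 8)
  net <- structure(list(params = osmlab:::rnn_init(spec, 1), spec = spec,
                        trained = TRUE), class = "trained_net")
  acc <- next_symbol_accuracy(net, list(near, far))
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  expect_error(next_symbol_accuracy(net, list(near), positions = integer(0)),
               "empty filter")
  # the reward-determining positions are the two second-zone-symbol slots
  expect_equal(reward_determined_positions(), c(14, 19))
  # a perfect-memory oracle on deterministic positions scores 1: emulate by
  # scoring the true sequence against itself via a net that memorized it
  sched <- sample_session(16, seed = 13)
  cfg <- train_config(epochs = 150, seed = 13)
  tiny <- train_net(net_spec("rate_rnn", hidden = 40), cfg, sched)
  expect_gt(next_symbol_accuracy(tiny, tiny$trials[tiny$test_idx]), 0.5)
})

test_that("training decreases the loss and is seed-reproducible", {
  sched <- sample_session(12, seed = 14)
  cfg <- train_config(epochs = 40, seed = 15)
  for (spec in list(net_spec("rate_rnn", hidden = 16),
                    net_spec("lstm", hidden = 12),
                    net_spec("transformer", n_layers = 1, n_heads = 2,
                             embed = 8, context_length = 12))) {
    net <- train_net(spec, cfg, sched)
    expect_lt(tail(net$loss_curve, 1), net$loss_curve[1])
    net2 <- train_net(spec, cfg, sched)
    expect_equal(net$loss_curve, net2$loss_curve, tolerance = 1e-12)
    # train and test trials are disjoint
    expect_length(intersect(net$train_idx, net$test_idx), 0)
    pv <- hidden_pv(net, make_trial("near", "rnn"))
    expect_equal(dim(pv$mat), c(23, if (spec$family == "transformer")
      spec$embed else spec$hidden))
  }
})

test_that("hidden PVs of an input-driven untrained net ignore trial type", {
  spec <- net_spec("rate_rnn", hidden = 10, activation = "relu")
  params <- osmlab:::rnn_init(spec, seed = 16)
  params$Wh[] <- 0  # purely feedforward
  net <- structure(list(params = params, spec = spec, trained = TRUE),
                   class = "trained_net")
  pvn <- hidden_pv(net, make_trial("near", "rnn"))
  pvf <- hidden_pv(net, make_trial("far", "rnn"))
  shared <- which(make_trial("near", "rnn")$symbols ==
                  make_trial("far", "rnn")$symbols)
  expect_equal(pvn$mat[shared, ], pvf$mat[shared, ])
  expect_warning(hidden_pv(structure(list(params = params, spec = spec,
                                          trained = FALSE),
                                     class = "trained_net"),
                           make_trial("near", "rnn")), "not been trained")
})
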