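#' Specification of a gradient-trained next-symbol predictor
#'
#' Three families are supported, all trained to predict the next sensory
#' symbol of the task with a cross-entropy objective over the 7-symbol
#' one-hot encoding: `rate_rnn` (a vanilla recurrent layer whose activation
#' is one of exponential softmax, polynomial softmax with 8th-power
#' normalization, ReLU, or sigmoid; the softmax families implement a soft
#' winner-take-all), `lstm` (a single LSTM layer, optionally with L1 hidden
#' regularization, readout dropout, or a penalty on the near/far hidden-state
#' correlation), and `transformer` (a causal decoder with learned positional
#' embeddings, trained on random fixed-length chunks; `context_length` is
#' its block size). Input and recurrent weights start at N(0, 0.001^2), the
#' readout at N(0, 0.1^2).
#'
#' @param family `"rate_rnn"`, `"lstm"`, or `"transformer"`.
#' @param hidden hidden units (rate_rnn default 500, lstm default 800).
#' @param activation rate_rnn only: `"exp_softmax"`, `"poly_softmax"`,
#'   `"relu"`, `"sigmoid"`.
#' @param regularizer lstm only: `"none"`, `"l1_hidden"`, `"dropout"`,
#'   `"correlation_penalty"`.
#' @param n_layers,n_heads,embed transformer geometry (defaults 4, 4, 256).
#' @param context_length transformer block size, 1-100 (default 23).
#' @param vocab alphabet size (default 7, the rnn-dialect symbols 0-6).
#' @param init_sd,out_sd initialization standard deviations.
#' @return a list of class `net_spec`.
#' @export
net_spec <- function(family = c("rate_rnn", "lstm", "transformer"),
                     hidden = NULL, activation = NULL, regularizer = NULL,
                     n_layers = 4, n_heads = 4, embed = 256,
                     context_length = 23, vocab = 7,
                     init_sd = 0.001, out_sd = 0.1) {
  family <- match.arg(family)
  if (family != "rate_rnn" && !is.null(activation))
    stop("activation applies to rate_rnn only")
  if (family != "lstm" && !is.null(regularizer))
    stop("regularizer applies to lstm only")
  if (family == "rate_rnn") {
    activation <- if (is.null(activation)) "exp_softmax" else
      match.arg(activation, c("exp_softmax", "poly_softmax", "relu", "sigmoid"))
    if (is.null(hidden)) hidden <- 500
  }
  if (family == "lstm") {
    regularizer <- if (is.null(regularizer)) "none" else
      match.arg(regularizer,
                c("none", "l1_hidden", "dropout", "correlation_penalty"))
    if (is.null(hidden)) hidden <- 800
  }
  if (family == "transformer") {
    if (context_length < 1 || context_length > 100)
      stop("context_length must be in 1..100")
    if (embed %% n_heads != 0) stop("embed must be divisible by n_heads")
  }
  structure(list(family = family, hidden = hidden, activation = activation,
                 regularizer = regularizer, n_layers = n_layers,
                 n_heads = n_heads, embed = embed,
                 context_length = context_length, vocab = vocab,
                 init_sd = init_sd, out_sd = out_sd),
            class = "net_spec")
}

#' Training configuration for gradient nets
#'
#' Defaults follow the mid-range of each family: Adam throughout, learning
#' rate 0.01 for rate RNNs, 4e-4 for LSTMs, 3e-4 for transformers. The
#' session is split half/half into disjoint train and test trials.
#'
#' @param lr learning rate (NULL = family default).
#' @param epochs training epochs/iterations (NULL = family default: 400
#'   rate_rnn, 250 lstm, 600 transformer).
#' @param lambda weight of the lstm correlation penalty (default 1) or of
#'   L1 hidden regularization (scaled by 0.001 internally).
#' @param dropout readout dropout rate for the lstm dropout variant.
#' @param batch_chunks transformer chunks per iteration (default 8).
#' @param seed seed for initialization, splitting and chunk sampling.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr = NULL, epochs = NULL, lambda = 1,
                         dropout = 0.2, batch_chunks = 8, seed = 1L) {
  structure(list(lr = lr, epochs = epochs, lambda = lambda,
                 dropout = dropout, batch_chunks = batch_chunks, seed = seed),
            class = "train_config")
}

# ---- one-hot encoding -------------------------------------------------------

one_hot <- function(symbols, vocab = 7) {
  if (any(symbols < 0 | symbols >= vocab)) stop("symbol outside 0..vocab-1")
  X <- matrix(0, vocab, length(symbols))
  X[cbind(symbols + 1L, seq_along(symbols))] <- 1
  X
}

one_hot_decode <- function(X) max.col(t(X)) - 1L

softmax_cols <- function(O) {
  O <- sweep(O, 2, apply(O, 2, max), "-")
  E <- exp(O)
  sweep(E, 2, colSums(E), "/")
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (k in names(grads)) {
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * grads[[k]]
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- opt$m[[k]] / (1 - beta1^opt$t)
    vhat <- opt$v[[k]] / (1 - beta2^opt$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(opt = opt, params = params)
}

# ---- rate RNN ---------------------------------------------------------------

rnn_init <- function(spec, seed) {
  local_rng(seed)
  H <- spec$hidden; V <- spec$vocab
  # ReLU units start with a small positive bias: with the tiny weight
  # initialization a zero bias leaves the layer dead (h = 0 exactly) and
  # the recurrent pathway cannot bootstrap
  b0 <- if (identical(spec$activation, "relu")) 0.1 else 0
  list(Wx = matrix(rnorm(H * V, 0, spec$init_sd), H, V),
       Wh = matrix(rnorm(H * H, 0, spec$init_sd), H, H),
       b = rep(b0, H),
       Wo = matrix(rnorm(V * H, 0, spec$out_sd), V, H),
       bo = rep(0, V))
}

rnn_activation <- function(u, activation) {
  switch(activation,
    relu = pmax(u, 0),
    sigmoid = 1 / (1 + exp(-u)),
    exp_softmax = { e <- exp(u - max(u)); e / sum(e) },
    poly_softmax = {
      m <- max(abs(u))
      if (m == 0) return(rep(1 / length(u), length(u)))
      v <- (u / m)^8
      v / sum(v)
    })
}

# gradient through the activation: dh (grad wrt h) -> grad wrt u
rnn_activation_back <- function(dh, h, u, activation) {
  switch(activation,
    relu = dh * (u > 0),
    sigmoid = dh * h * (1 - h),
    exp_softmax = h * (dh - sum(dh * h)),
    poly_softmax = {
      m <- max(abs(u))
      if (m == 0) return(rep(0, length(u)))
      v <- u / m
      (8 * v^7 / (m * sum(v^8))) * (dh - sum(dh * h))
    })
}

rnn_forward <- function(params, X, activation) {
  Tn <- ncol(X); H <- length(params$b)
  Hs <- matrix(0, H, Tn); Us <- matrix(0, H, Tn)
  U0 <- params$Wx %*% X
  h <- rep(0, H)
  for (t in seq_len(Tn)) {
    u <- U0[, t] + params$Wh %*% h + params$b
    h <- rnn_activation(u, activation)
    Us[, t] <- u; Hs[, t] <- h
  }
  list(H = Hs, U = Us, O = params$Wo %*% Hs + params$bo)
}

# cross-entropy BPTT over one sequence; targets are X shifted by one
rnn_loss_grads <- function(params, X, activation) {
  fw <- rnn_forward(params, X, activation)
  Tn <- ncol(X)
  P <- softmax_cols(fw$O[, 1:(Tn - 1), drop = FALSE])
  Y <- X[, 2:Tn, drop = FALSE]
  loss <- -mean(colSums(Y * log(pmax(P, 1e-300))))
  dO <- cbind((P - Y) / (Tn - 1), rep(0, nrow(X)))
  dH <- crossprod(params$Wo, dO)
  H <- length(params$b)
  dU <- matrix(0, H, Tn)
  du_next <- rep(0, H)
  for (t in Tn:1) {
    dh <- dH[, t] + crossprod(params$Wh, du_next)
    du_next <- rnn_activation_back(dh, fw$H[, t], fw$U[, t], activation)
    dU[, t] <- du_next
  }
  grads <- list(
    Wx = dU %*% t(X),
    Wh = dU[, 2:Tn, drop = FALSE] %*% t(fw$H[, 1:(Tn - 1), drop = FALSE]),
    b = rowSums(dU),
    Wo = dO %*% t(fw$H),
    bo = rowSums(dO))
  list(loss = loss, grads = grads)
}

# ---- LSTM -------------------------------------------------------------------

lstm_init <- function(spec, seed) {
  local_rng(seed)
  H <- spec$hidden; V <- spec$vocab
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(Wx = matrix(rnorm(4 * H * V, 0, spec$init_sd), 4 * H, V),
       Wh = matrix(rnorm(4 * H * H, 0, spec$init_sd), 4 * H, H),
       b = b,
       Wo = matrix(rnorm(V * H, 0, spec$out_sd), V, H),
       bo = rep(0, V))
}

lstm_forward <- function(params, X) {
  Tn <- ncol(X); H <- nrow(params$Wh) / 4
  i1 <- 1:H; f1 <- (H + 1):(2 * H); o1 <- (2 * H + 1):(3 * H)
  g1 <- (3 * H + 1):(4 * H)
  Hs <- matrix(0, H, Tn); Cs <- matrix(0, H, Tn)
  Gi <- matrix(0, H, Tn); Gf <- Gi; Go <- Gi; Gg <- Gi
  Z0 <- params$Wx %*% X
  h <- rep(0, H); cc <- rep(0, H)
  for (t in seq_len(Tn)) {
    z <- Z0[, t] + params$Wh %*% h + params$b
    gi <- 1 / (1 + exp(-z[i1])); gf <- 1 / (1 + exp(-z[f1]))
    go <- 1 / (1 + exp(-z[o1])); gg <- tanh(z[g1])
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    Gi[, t] <- gi; Gf[, t] <- gf; Go[, t] <- go; Gg[, t] <- gg
    Cs[, t] <- cc; Hs[, t] <- h
  }
  list(H = Hs, C = Cs, Gi = Gi, Gf = Gf, Go = Go, Gg = Gg,
       O = params$Wo %*% Hs + params$bo)
}

# BPTT given gradient on outputs (dO, may be NULL) plus any direct gradient
# on hidden states (dH_ext, may be NULL)
lstm_backward <- function(params, X, fw, dO = NULL, dH_ext = NULL) {
  Tn <- ncol(X); H <- nrow(fw$H)
  if (is.null(dO)) dO <- matrix(0, nrow(params$Wo), Tn)
  dH <- crossprod(params$Wo, dO)
  if (!is.null(dH_ext)) dH <- dH + dH_ext
  dZ <- matrix(0, 4 * H, Tn)
  dh_next <- rep(0, H); dc_next <- rep(0, H)
  for (t in Tn:1) {
    dh <- dH[, t] + dh_next
    cc <- fw$C[, t]; tc <- tanh(cc)
    go <- fw$Go[, t]; gi <- fw$Gi[, t]; gf <- fw$Gf[, t]; gg <- fw$Gg[, t]
    dc <- dh * go * (1 - tc^2) + dc_next
    c_prev <- if (t > 1) fw$C[, t - 1] else rep(0, H)
    dgi <- dc * gg * gi * (1 - gi)
    dgf <- dc * c_prev * gf * (1 - gf)
    dgo <- dh * tc * go * (1 - go)
    dgg <- dc * gi * (1 - gg^2)
    dz <- c(dgi, dgf, dgo, dgg)
    dZ[, t] <- dz
    dh_next <- as.vector(crossprod(params$Wh, dz))
    dc_next <- dc * gf
  }
  Hprev <- cbind(rep(0, H), fw$H[, -Tn, drop = FALSE])
  list(Wx = dZ %*% t(X), Wh = dZ %*% t(Hprev), b = rowSums(dZ),
       Wo = dO %*% t(fw$H), bo = rowSums(dO))
}

lstm_loss_grads <- function(params, X, spec, config, dropout_mask = NULL) {
  fw <- lstm_forward(params, X)
  Tn <- ncol(X)
  Hout <- fw$H
  if (!is.null(dropout_mask)) Hout <- Hout * dropout_mask
  O <- params$Wo %*% Hout + params$bo
  P <- softmax_cols(O[, 1:(Tn - 1), drop = FALSE])
  Y <- X[, 2:Tn, drop = FALSE]
  loss <- -mean(colSums(Y * log(pmax(P, 1e-300))))
  dO <- cbind((P - Y) / (Tn - 1), rep(0, nrow(X)))
  dH_ext <- NULL
  if (!is.null(dropout_mask)) {
    # route the readout gradient through the mask, not the recurrence
    dH_ext <- (crossprod(params$Wo, dO)) * dropout_mask -
      crossprod(params$Wo, dO)
  }
  if (identical(spec$regularizer, "l1_hidden")) {
    l1w <- 0.001 * config$lambda
    loss <- loss + l1w * mean(abs(fw$H))
    dl1 <- l1w * sign(fw$H) / length(fw$H)
    dH_ext <- if (is.null(dH_ext)) dl1 else dH_ext + dl1
  }
  grads <- lstm_backward(params, X, fw, dO, dH_ext)
  if (!is.null(dropout_mask)) grads$Wo <- dO %*% t(Hout)
  list(loss = loss, grads = grads)
}

# ---- correlation penalty ----------------------------------------------------

#' Correlation penalty between aligned hidden-state streams
#'
#' Mean over positions of the squared Pearson correlation between the paired
#' hidden vectors of two equal-length sequences (one near, one far trial).
#' Identical streams score 1, mean-centered orthogonal streams 0; a
#' zero-variance vector contributes 0 at its position. Used as an auxiliary
#' differentiable loss that encourages trial-type decorrelation in LSTMs.
#'
#' @param hidden_near,hidden_far matrices positions x units (a
#'   `position_pv` is also accepted).
#' @return scalar penalty in `[0, 1]`.
#' @export
correlation_penalty <- function(hidden_near, hidden_far) {
  a <- pv_matrix(hidden_near); b <- pv_matrix(hidden_far)
  if (!all(dim(a) == dim(b))) stop("hidden sequences must be aligned")
  mean(vapply(seq_len(nrow(a)), function(i)
    as.numeric(safe_pearson(a[i, ], b[i, ]))^2, 0))
}

# gradients of mean-over-positions squared Pearson wrt both streams
# (units x positions orientation used internally)
corr_penalty_grads <- function(A, B) {
  Tn <- ncol(A)
  dA <- A * 0; dB <- B * 0
  pen <- 0
  for (t in seq_len(Tn)) {
    a <- A[, t]; b <- B[, t]
    ac <- a - mean(a); bc <- b - mean(b)
    na <- sqrt(sum(ac^2)); nb <- sqrt(sum(bc^2))
    if (na == 0 || nb == 0) next
    r <- sum(ac * bc) / (na * nb)
    pen <- pen + r^2
    dr_da <- bc / (na * nb) - r * ac / na^2
    dr_db <- ac / (na * nb) - r * bc / nb^2
    ga <- 2 * r * dr_da / Tn
    gb <- 2 * r * dr_db / Tn
    dA[, t] <- ga - mean(ga)
    dB[, t] <- gb - mean(gb)
  }
  list(penalty = pen / Tn, dA = dA, dB = dB)
}

# ---- transformer ------------------------------------------------------------

tf_init <- function(spec, seed) {
  local_rng(seed)
  E <- spec$embed; V <- spec$vocab; Tb <- spec$context_length
  p <- list(tok = matrix(rnorm(V * E, 0, 0.02), V, E),
            pos = matrix(rnorm(Tb * E, 0, 0.02), Tb, E))
  for (l in seq_len(spec$n_layers)) {
    p[[paste0("ln1g_", l)]] <- rep(1, E)
    p[[paste0("ln1b_", l)]] <- rep(0, E)
    p[[paste0("qkv_", l)]] <- matrix(rnorm(E * 3 * E, 0, 0.02), E, 3 * E)
    p[[paste0("qkvb_", l)]] <- rep(0, 3 * E)
    p[[paste0("proj_", l)]] <- matrix(rnorm(E * E, 0, 0.02), E, E)
    p[[paste0("projb_", l)]] <- rep(0, E)
    p[[paste0("ln2g_", l)]] <- rep(1, E)
    p[[paste0("ln2b_", l)]] <- rep(0, E)
    p[[paste0("fc1_", l)]] <- matrix(rnorm(E * 4 * E, 0, 0.02), E, 4 * E)
    p[[paste0("fc1b_", l)]] <- rep(0, 4 * E)
    p[[paste0("fc2_", l)]] <- matrix(rnorm(4 * E * E, 0, 0.02), 4 * E, E)
    p[[paste0("fc2b_", l)]] <- rep(0, E)
  }
  p$lnfg <- rep(1, E); p$lnfb <- rep(0, E)
  p$head <- matrix(rnorm(E * V, 0, 0.02), E, V)
  p$headb <- rep(0, V)
  p
}

ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  va <- rowMeans(Xc^2)
  inv <- 1 / sqrt(va + eps)
  Xn <- Xc * inv
  list(Y = sweep(Xn, 2, g, "*") + matrix(b, nrow(X), length(b), byrow = TRUE),
       Xn = Xn, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  Xn <- cache$Xn; inv <- cache$inv
  dg <- colSums(dY * Xn); db <- colSums(dY)
  dXn <- sweep(dY, 2, g, "*")
  n <- ncol(Xn)
  dX <- inv * (dXn - rowMeans(dXn) - Xn * rowMeans(dXn * Xn))
  list(dX = dX, dg = dg, db = db)
}

gelu <- function(x) x * pnorm(x)
gelu_back <- function(dy, x) dy * (pnorm(x) + x * dnorm(x))

# forward on one token sequence (rows = positions); returns caches for BPTT
tf_forward <- function(params, tokens, spec) {
  Tn <- length(tokens); E <- spec$embed
  if (Tn > spec$context_length) stop("sequence longer than context_length")
  X <- params$tok[tokens + 1L, , drop = FALSE] +
       params$pos[seq_len(Tn), , drop = FALSE]
  d <- E / spec$n_heads
  mask <- outer(seq_len(Tn), seq_len(Tn), ">=")  # causal: key <= query
  layers <- list()
  for (l in seq_len(spec$n_layers)) {
    ln1 <- ln_forward(X, params[[paste0("ln1g_", l)]],
                      params[[paste0("ln1b_", l)]])
    QKV <- ln1$Y %*% params[[paste0("qkv_", l)]] +
      matrix(params[[paste0("qkvb_", l)]], Tn, 3 * E, byrow = TRUE)
    heads <- vector("list", spec$n_heads)
    O <- matrix(0, Tn, E)
    for (h in seq_len(spec$n_heads)) {
      cols <- (h - 1) * d + seq_len(d)
      Q <- QKV[, cols, drop = FALSE]
      K <- QKV[, E + cols, drop = FALSE]
      Vv <- QKV[, 2 * E + cols, drop = FALSE]
      S <- Q %*% t(K) / sqrt(d)
      S[!mask] <- -Inf
      P <- exp(S - apply(S, 1, max))
      P <- P / rowSums(P)
      O[, cols] <- P %*% Vv
      heads[[h]] <- list(Q = Q, K = K, V = Vv, P = P)
    }
    att <- O %*% params[[paste0("proj_", l)]] +
      matrix(params[[paste0("projb_", l)]], Tn, E, byrow = TRUE)
    A <- X + att
    ln2 <- ln_forward(A, params[[paste0("ln2g_", l)]],
                      params[[paste0("ln2b_", l)]])
    U <- ln2$Y %*% params[[paste0("fc1_", l)]] +
      matrix(params[[paste0("fc1b_", l)]], Tn, 4 * E, byrow = TRUE)
    G <- gelu(U)
    M <- G %*% params[[paste0("fc2_", l)]] +
      matrix(params[[paste0("fc2b_", l)]], Tn, E, byrow = TRUE)
    Xout <- A + M
    layers[[l]] <- list(Xin = X, ln1 = ln1, QKV = QKV, heads = heads, O = O,
                        A = A, ln2 = ln2, U = U, G = G)
    X <- Xout
  }
  lnf <- ln_forward(X, params$lnfg, params$lnfb)
  logits <- lnf$Y %*% params$head +
    matrix(params$headb, Tn, spec$vocab, byrow = TRUE)
  list(prelogit = lnf$Y, logits = logits, lnf = lnf, Xfinal = X,
       layers = layers, tokens = tokens, mask = mask)
}

tf_backward <- function(params, fw, spec, dlogits) {
  Tn <- length(fw$tokens); E <- spec$embed; d <- E / spec$n_heads
  g <- list()
  g$head <- t(fw$prelogit) %*% dlogits
  g$headb <- colSums(dlogits)
  dPre <- dlogits %*% t(params$head)
  lb <- ln_backward(dPre, fw$lnf, params$lnfg)
  g$lnfg <- lb$dg; g$lnfb <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(spec$n_layers))) {
    L <- fw$layers[[l]]
    # mlp branch
    dM <- dX
    g[[paste0("fc2_", l)]] <- t(L$G) %*% dM
    g[[paste0("fc2b_", l)]] <- colSums(dM)
    dG <- dM %*% t(params[[paste0("fc2_", l)]])
    dU <- gelu_back(dG, L$U)
    g[[paste0("fc1_", l)]] <- t(L$ln2$Y) %*% dU
    g[[paste0("fc1b_", l)]] <- colSums(dU)
    dLn2 <- dU %*% t(params[[paste0("fc1_", l)]])
    lb2 <- ln_backward(dLn2, L$ln2, params[[paste0("ln2g_", l)]])
    g[[paste0("ln2g_", l)]] <- lb2$dg
    g[[paste0("ln2b_", l)]] <- lb2$db
    dA <- dX + lb2$dX
    # attention branch
    datt <- dA
    g[[paste0("proj_", l)]] <- t(L$O) %*% datt
    g[[paste0("projb_", l)]] <- colSums(datt)
    dO <- datt %*% t(params[[paste0("proj_", l)]])
    dQKV <- matrix(0, Tn, 3 * E)
    for (h in seq_len(spec$n_heads)) {
      cols <- (h - 1) * d + seq_len(d)
      hd <- L$heads[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dP <- dOh %*% t(hd$V)
      dV <- t(hd$P) %*% dOh
      dS <- hd$P * (dP - rowSums(dP * hd$P))
      dS[!fw$mask] <- 0
      dQ <- dS %*% hd$K / sqrt(d)
      dK <- t(dS) %*% hd$Q / sqrt(d)
      dQKV[, cols] <- dQ
      dQKV[, E + cols] <- dK
      dQKV[, 2 * E + cols] <- dV
    }
    g[[paste0("qkv_", l)]] <- t(L$ln1$Y) %*% dQKV
    g[[paste0("qkvb_", l)]] <- colSums(dQKV)
    dLn1 <- dQKV %*% t(params[[paste0("qkv_", l)]])
    lb1 <- ln_backward(dLn1, L$ln1, params[[paste0("ln1g_", l)]])
    g[[paste0("ln1g_", l)]] <- lb1$dg
    g[[paste0("ln1b_", l)]] <- lb1$db
    dX <- dA + lb1$dX
  }
  g$tok <- matrix(0, spec$vocab, E)
  for (t in seq_len(Tn))
    g$tok[fw$tokens[t] + 1L, ] <- g$tok[fw$tokens[t] + 1L, ] + dX[t, ]
  g$pos <- matrix(0, spec$context_length, E)
  g$pos[seq_len(Tn), ] <- dX
  g
}

tf_loss_grads <- function(params, tokens, spec) {
  fw <- tf_forward(params, tokens, spec)
  Tn <- length(tokens)
  P <- softmax_cols(t(fw$logits[1:(Tn - 1), , drop = FALSE]))
  Y <- one_hot(tokens[2:Tn], spec$vocab)
  loss <- -mean(colSums(Y * log(pmax(P, 1e-300))))
  dlog <- rbind(t(P - Y) / (Tn - 1), rep(0, spec$vocab))
  list(loss = loss, grads = tf_backward(params, fw, spec, dlog))
}

# ---- training driver --------------------------------------------------------

schedule_symbols <- function(trials) {
  lapply(trials, function(tr)
    if (inherits(tr, "trial_sequence")) tr$symbols else as.integer(tr))
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (k in names(b)) a[[k]] <- a[[k]] + b[[k]]
  a
}

#' Train a next-symbol predictor on a task session
#'
#' Splits the session's trials into disjoint train/test halves, trains with
#' Adam on the cross-entropy next-symbol objective (plus the configured
#' regularizer for LSTMs: the correlation-penalty variant additionally
#' backpropagates `lambda` times the squared near/far hidden-state
#' correlation computed on one canonical trial of each type per epoch), and
#' records the loss curve. Rate RNNs and LSTMs do full backpropagation
#' through time over the concatenated training trials; the transformer
#' trains on randomly sampled `context_length`-element chunks of the
#' concatenated stream.
#'
#' @param spec a [net_spec()].
#' @param config a [train_config()].
#' @param session a `session_schedule` in the rnn dialect (or list of
#'   `trial_sequence`).
#' @return an object of class `trained_net`: list with `params`, `spec`,
#'   `config`, `loss_curve`, `train_idx`, `test_idx`, `trials`, `trained`.
#' @export
train_net <- function(spec, config = train_config(), session) {
  trials <- if (inherits(session, "session_schedule")) session$trials
            else session
  syms <- schedule_symbols(trials)
  if (any(unlist(syms) >= spec$vocab))
    stop("session symbols not one-hot encodable in ", spec$vocab, " dims")
  local_rng(config$seed)
  n <- length(trials)
  train_idx <- sort(sample.int(n, floor(n / 2)))
  test_idx <- setdiff(seq_len(n), train_idx)

  lr <- config$lr
  epochs <- config$epochs
  if (is.null(lr)) lr <- switch(spec$family, rate_rnn = 0.01, lstm = 4e-4,
                                transformer = 3e-4)
  if (is.null(epochs)) epochs <- switch(spec$family, rate_rnn = 400,
                                        lstm = 250, transformer = 600)

  Xtrain <- one_hot(unlist(syms[train_idx]), spec$vocab)
  loss_curve <- numeric(epochs)

  if (spec$family == "rate_rnn") {
    params <- rnn_init(spec, config$seed)
    opt <- adam_new(params)
    for (e in seq_len(epochs)) {
      lg <- rnn_loss_grads(params, Xtrain, spec$activation)
      loss_curve[e] <- lg$loss
      st <- adam_step(opt, params, lg$grads, lr)
      opt <- st$opt; params <- st$params
    }
  } else if (spec$family == "lstm") {
    params <- lstm_init(spec, config$seed)
    opt <- adam_new(params)
    near <- one_hot(make_trial("near", "rnn")$symbols, spec$vocab)
    far <- one_hot(make_trial("far", "rnn")$symbols, spec$vocab)
    for (e in seq_len(epochs)) {
      mask <- NULL
      if (identical(spec$regularizer, "dropout"))
        mask <- matrix(rbinom(spec$hidden * ncol(Xtrain), 1,
                              1 - config$dropout) / (1 - config$dropout),
                       spec$hidden, ncol(Xtrain))
      lg <- lstm_loss_grads(params, Xtrain, spec, config, mask)
      grads <- lg$grads
      loss <- lg$loss
      if (identical(spec$regularizer, "correlation_penalty")) {
        fwn <- lstm_forward(params, near)
        fwf <- lstm_forward(params, far)
        cp <- corr_penalty_grads(fwn$H, fwf$H)
        loss <- loss + config$lambda * cp$penalty
        gn <- lstm_backward(params, near, fwn, NULL, config$lambda * cp$dA)
        gf <- lstm_backward(params, far, fwf, NULL, config$lambda * cp$dB)
        grads <- sum_grads(sum_grads(grads, gn), gf)
      }
      loss_curve[e] <- loss
      st <- adam_step(opt, params, grads, lr)
      opt <- st$opt; params <- st$params
    }
  } else {
    params <- tf_init(spec, config$seed)
    opt <- adam_new(params)
    stream <- unlist(syms[train_idx])
    Tb <- spec$context_length
    for (e in seq_len(epochs)) {
      grads <- NULL; loss <- 0
      for (k in seq_len(config$batch_chunks)) {
        start <- sample.int(length(stream) - Tb, 1)
        lg <- tf_loss_grads(params, stream[start:(start + Tb - 1)], spec)
        loss <- loss + lg$loss / config$batch_chunks
        for (nm in names(lg$grads)) lg$grads[[nm]] <-
          lg$grads[[nm]] / config$batch_chunks
        grads <- sum_grads(grads, lg$grads)
      }
      loss_curve[e] <- loss
      st <- adam_step(opt, params, grads, lr)
      opt <- st$opt; params <- st$params
    }
  }
  structure(list(params = params, spec = spec, config = config,
                 loss_curve = loss_curve, train_idx = train_idx,
                 test_idx = test_idx, trials = trials, trained = TRUE),
            class = "trained_net")
}

#' @export
print.trained_net <- function(x, ...) {
  cat(sprintf("<trained_net> %s%s, final loss %.4f\n", x$spec$family,
              if (!is.null(x$spec$activation))
                paste0("/", x$spec$activation)
              else if (!is.null(x$spec$regularizer))
                paste0("/", x$spec$regularizer) else "",
              tail(x$loss_curve, 1)))
  invisible(x)
}

# hidden representation over one trial; transformer uses a sliding window of
# its block size and reads the pre-logit layer at the window's last position
net_hidden <- function(net, symbols) {
  spec <- net$spec
  X <- one_hot(symbols, spec$vocab)
  if (spec$family == "rate_rnn") {
    rnn_forward(net$params, X, spec$activation)$H
  } else if (spec$family == "lstm") {
    lstm_forward(net$params, X)$H
  } else {
    Tb <- spec$context_length
    out <- matrix(0, spec$embed, length(symbols))
    for (t in seq_along(symbols)) {
      lo <- max(1, t - Tb + 1)
      fw <- tf_forward(net$params, symbols[lo:t], spec)
      out[, t] <- fw$prelogit[t - lo + 1, ]
    }
    out
  }
}

#' Hidden-state population vector for one trial
#'
#' Runs the trained network over a trial and returns its hidden states as a
#' positions x units population vector: the recurrent state for rate RNNs,
#' the hidden (or cell) state for LSTMs, and the pre-logit layer for
#' transformers.
#'
#' @param net a `trained_net`.
#' @param trial a `trial_sequence` or integer symbol vector.
#' @param state for lstm, `"hidden"` (default) or `"cell"`.
#' @return a `position_pv` (positions x hidden units).
#' @export
hidden_pv <- function(net, trial, state = c("hidden", "cell")) {
  state <- match.arg(state)
  if (!isTRUE(net$trained)) warning("network has not been trained")
  sym <- if (inherits(trial, "trial_sequence")) trial$symbols
         else as.integer(trial)
  H <- if (net$spec$family == "lstm" && state == "cell")
    lstm_forward(net$params, one_hot(sym, net$spec$vocab))$C
  else net_hidden(net, sym)
  position_pv(t(H), positions_cm = 10 * (seq_along(sym) - 1L),
              trial_type = if (inherits(trial, "trial_sequence"))
                trial$trial_type else NA_character_,
              source = paste0("net_", net$spec$family))
}

# next-symbol prediction (argmax) over one trial
net_predict <- function(net, symbols) {
  spec <- net$spec
  X <- one_hot(symbols, spec$vocab)
  if (spec$family == "rate_rnn") {
    O <- rnn_forward(net$params, X, spec$activation)$O
    max.col(t(O)) - 1L
  } else if (spec$family == "lstm") {
    O <- lstm_forward(net$params, X)$O
    max.col(t(O)) - 1L
  } else {
    Tb <- spec$context_length
    vapply(seq_along(symbols), function(t) {
      lo <- max(1, t - Tb + 1)
      fw <- tf_forward(net$params, symbols[lo:t], spec)
      which.max(fw$logits[t - lo + 1, ]) - 1L
    }, 0L)
  }
}

#' Positions whose next symbol is decided by the trial type
#'
#' Compares the canonical near and far sequences and returns the (1-based)
#' positions whose next symbol both differs across trial types and falls in
#' a reward zone - the positions a predictor must disambiguate to report the
#' reward location. The indicator onset (randomly sampled) is excluded.
#'
#' @param dialect task dialect (default `"rnn"`).
#' @return integer vector of positions (prediction evaluated for position+1).
#' @export
reward_determined_positions <- function(dialect = "rnn") {
  near <- make_trial("near", dialect)$symbols
  far <- make_trial("far", dialect)$symbols
  lay <- track_layout("standard")
  rz <- lay$segments$segment[lay$segments$region %in% c("r1", "r2")]
  p <- which(near != far)
  p <- (p - 1L)[(p - 1L) >= 1]            # positions preceding a difference
  p <- p[(p + 1L) %in% rz]
  sort(unique(p))
}

#' Next-symbol prediction accuracy
#'
#' Fraction of positions at which the argmax prediction matches the true
#' next symbol, over the given trials, optionally restricted to a position
#' filter (e.g. [reward_determined_positions()]).
#'
#' @param net a `trained_net`.
#' @param trials list of `trial_sequence` (held-out trials).
#' @param positions optional 1-based positions at which to score (the
#'   prediction of the symbol at position+1); NULL = all within-trial
#'   positions.
#' @return accuracy in `[0, 1]`.
#' @export
next_symbol_accuracy <- function(net, trials, positions = NULL) {
  if (!is.null(positions) && length(positions) == 0) stop("empty filter")
  hits <- 0; tot <- 0
  for (tr in trials) {
    sym <- if (inherits(tr, "trial_sequence")) tr$symbols else as.integer(tr)
    pred <- net_predict(net, sym)
    ps <- seq_len(length(sym) - 1L)
    if (!is.null(positions)) ps <- intersect(ps, positions)
    hits <- hits + sum(pred[ps] == sym[ps + 1L])
    tot <- tot + length(ps)
  }
  if (tot == 0) stop("no scoreable positions")
  hits / tot
}
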