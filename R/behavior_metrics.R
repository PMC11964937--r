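#' Lick density by position, trial type and session half
#'
#' Counts licks per position bin, normalized by the number of trials, split
#' by trial type and by session half (the session is divided into two parts
#' of equal duration; a trial belongs to the half containing its start
#' frame).
#'
#' @param session a `calcium_session` (only `licks`, `position`, `trials`
#'   are used).
#' @param bin_cm position bin (default 5 cm).
#' @return an object of class `lick_profile`: list with `density` (array
#'   bins x type x half), `bin_start_cm`, `n_trials` (type x half), and
#'   `no_licks` flag.
#' @export
lick_density <- function(session, bin_cm = 5) {
  nb <- ceiling(session$track_length_cm / bin_cm)
  types <- c("near", "far")
  halves <- c("start", "end")
  dens <- array(0, c(nb, 2, 2),
                dimnames = list(NULL, types, halves))
  ntr <- matrix(0L, 2, 2, dimnames = list(types, halves))
  mid <- ceiling(ncol_or_frames(session) / 2)
  tr <- session$trials
  half_of <- ifelse(tr$start <= mid, "start", "end")
  for (i in seq_len(nrow(tr))) {
    ty <- tr$type[i]
    if (!ty %in% types) next
    hf <- half_of[i]
    ntr[ty, hf] <- ntr[ty, hf] + 1L
    lk <- session$licks[session$licks >= tr$start[i] &
                        session$licks <= tr$end[i]]
    if (!length(lk)) next
    pos <- session$position[lk]
    bi <- pmin(floor(pos / bin_cm) + 1L, nb)
    for (b in bi) dens[b, ty, hf] <- dens[b, ty, hf] + 1
  }
  for (ty in types) for (hf in halves)
    if (ntr[ty, hf] > 0) dens[, ty, hf] <- dens[, ty, hf] / ntr[ty, hf]
  structure(list(density = dens, bin_start_cm = bin_cm * (seq_len(nb) - 1L),
                 bin_cm = bin_cm, n_trials = ntr,
                 no_licks = length(session$licks) == 0),
            class = "lick_profile")
}

ncol_or_frames <- function(session)
  if (!is.null(session$F)) ncol(session$F) else length(session$position)

#' Licking-strategy basis functions
#'
#' Four regressors over (position bin x trial type), each normalized to unit
#' mass, describing the canonical licking strategies: `random` (uniform over
#' the track on both trial types), `both_rewards` (licking at both reward
#' zones and their anticipatory lead-ins on both types), `lick_stop`
#' (licking from the first reward zone onward but stopping once the reward
#' is collected: only up to R1 on near trials, from R1 through R2 on far
#' trials), and `expert` (only the correct zone and its lead-in). Lead-ins
#' extend `leadin_cm` before each zone.
#'
#' @param bin_cm position bin (default 5 cm).
#' @param leadin_cm anticipatory lead-in before each reward zone (default
#'   20 cm).
#' @param track_length_cm track length (default 230).
#' @return an object of class `strategy_basis`: list with `X` (matrix
#'   `2*nbins` x 4; rows = near bins then far bins), `bin_start_cm`,
#'   `strategies`.
#' @export
strategy_basis <- function(bin_cm = 5, leadin_cm = 20, track_length_cm = 230) {
  nb <- ceiling(track_length_cm / bin_cm)
  centers <- bin_cm * (seq_len(nb) - 1L) + bin_cm / 2
  rz <- reward_zone_cm("standard")
  z1 <- centers >= (rz$r1[1] - leadin_cm) & centers < rz$r1[2]
  z2 <- centers >= (rz$r2[1] - leadin_cm) & centers < rz$r2[2]
  both_zones <- as.numeric(z1 | z2)
  stack <- function(near, far) c(near, far)
  X <- cbind(
    random = stack(rep(1, nb), rep(1, nb)),
    both_rewards = stack(both_zones, both_zones),
    lick_stop = stack(as.numeric(z1),
                      as.numeric(centers >= (rz$r1[1] - leadin_cm) &
                                 centers < rz$r2[2])),
    expert = stack(as.numeric(z1), as.numeric(z2)))
  X <- sweep(X, 2, colSums(X), "/")
  structure(list(X = X, bin_start_cm = bin_cm * (seq_len(nb) - 1L),
                 bin_cm = bin_cm, strategies = colnames(X)),
            class = "strategy_basis")
}

# nested-OLS coefficient of partial determination for one observation
# vector. No intercept: the uniform "random" strategy regressor spans the
# constant, and adding an intercept would make it unidentifiable (its CPD
# would be 0 by collinearity, so random licking could never dominate).
cpd_fit <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sse_full <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  cpd <- setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    fit_j <- stats::lm.fit(X[, -j, drop = FALSE], y)
    sse_j <- sum(fit_j$residuals^2)
    cpd[j] <- if (sse_j > 0) (sse_j - sse_full) / sse_j else 0
  }
  rank_deficient <- fit$rank < ncol(X)
  list(cpd = pmax(cpd, 0), sse_full = sse_full,
       explained_variance = if (sst > 0) 1 - sse_full / sst else 0,
       rank_deficient = rank_deficient)
}

#' Coefficients of partial determination for licking strategies
#'
#' Regresses the observed lick densities (concatenated over position bins
#' and trial types, per session half) on the four strategy regressors (no
#' intercept: the uniform random-licking regressor spans the constant),
#' then removes each regressor in turn:
#' `CPD_i = (SSE_without_i - SSE_full) / SSE_without_i`, the unique variance
#' contribution of strategy i. The dominant strategy of each half is the
#' regressor with the largest CPD.
#'
#' @param profile a `lick_profile` from [lick_density()].
#' @param basis a `strategy_basis` on the same bins.
#' @return an object of class `cpd_result`: list with `cpd` (strategies x
#'   halves), `dominant` (named character per half), `explained_variance`,
#'   `sse_full`, `collinear` flag.
#' @export
cpd <- function(profile, basis) {
  stopifnot(inherits(profile, "lick_profile"), inherits(basis, "strategy_basis"))
  nb <- dim(profile$density)[1]
  if (2 * nb != nrow(basis$X)) stop("profile and basis bins differ")
  halves <- dimnames(profile$density)[[3]]
  cpds <- matrix(NA_real_, ncol(basis$X), length(halves),
                 dimnames = list(colnames(basis$X), halves))
  ev <- setNames(numeric(length(halves)), halves)
  sse <- ev; coll <- FALSE
  for (h in halves) {
    y <- c(profile$density[, "near", h], profile$density[, "far", h])
    if (length(y) < 4) stop("need at least 4 observations per fit")
    f <- cpd_fit(y, basis$X)
    cpds[, h] <- f$cpd
    ev[h] <- f$explained_variance
    sse[h] <- f$sse_full
    coll <- coll || f$rank_deficient
  }
  dominant <- apply(cpds, 2, function(v) rownames(cpds)[which.max(v)])
  structure(list(cpd = cpds, dominant = dominant, explained_variance = ev,
                 sse_full = sse, collinear = coll),
            class = "cpd_result")
}

#' @export
print.cpd_result <- function(x, ...) {
  cat("<cpd_result>\n")
  print(round(x$cpd, 3))
  cat("dominant:", paste(names(x$dominant), x$dominant, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Task-performance metrics
#'
#' Binarized per-trial accuracy: a trial is correct when the animal licked
#' within the correct reward zone (including the anticipatory lead-in) and
#' not within the incorrect one. Also reports the fraction of licks falling
#' in correct zones and the expert criterion (mean accuracy >= 0.75 over
#' three consecutive sessions) when a vector of session accuracies is
#' supplied via `history`.
#'
#' @param session a `calcium_session`.
#' @param leadin_cm anticipatory lead-in (default 20 cm).
#' @param history optional numeric vector of previous session accuracies to
#'   evaluate the 3-consecutive-sessions expert criterion (the current
#'   session is appended).
#' @return list with `trial_correct`, `accuracy`, `correct_lick_fraction`,
#'   `expert` (flag or NA when no history).
#' @export
performance <- function(session, leadin_cm = 20, history = NULL) {
  rz <- reward_zone_cm("standard")
  z1 <- c(rz$r1[1] - leadin_cm, rz$r1[2])
  z2 <- c(rz$r2[1] - leadin_cm, rz$r2[2])
  tr <- session$trials
  correct <- logical(nrow(tr))
  lick_ok <- 0; lick_tot <- 0
  for (i in seq_len(nrow(tr))) {
    lk <- session$licks[session$licks >= tr$start[i] &
                        session$licks <= tr$end[i]]
    pos <- session$position[lk]
    in1 <- pos >= z1[1] & pos < z1[2]
    in2 <- pos >= z2[1] & pos < z2[2]
    good <- if (tr$type[i] == "near") in1 else in2
    bad <- if (tr$type[i] == "near") in2 else in1
    correct[i] <- any(good) && !any(bad)
    lick_ok <- lick_ok + sum(good)
    lick_tot <- lick_tot + length(lk)
  }
  acc <- mean(correct)
  accs <- c(history, acc)
  expert <- if (length(accs) >= 3)
    any(vapply(3:length(accs), function(k) all(accs[(k - 2):k] >= 0.75), TRUE))
  else NA
  list(trial_correct = correct, accuracy = acc,
       correct_lick_fraction = if (lick_tot > 0) lick_ok / lick_tot else NA,
       expert = expert)
}
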