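# internal helpers shared across modules

# Deterministic seeding. Functions with a `seed` argument call this once at
# entry; passing NULL leaves the caller's RNG stream untouched.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647L))
  invisible(NULL)
}

# Pearson r with the degenerate-0 convention: a zero-variance (or all-zero)
# vector on either side yields r = 0 with attribute degenerate = TRUE so that
# correlation matrices stay total. Used everywhere a PV column/row may be
# silent.
safe_pearson <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(x, y)
}

# angle (degrees) between two nonnegative vectors; 0 if either is zero
vector_angle_deg <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(structure(0, degenerate = TRUE))
  cosv <- sum(x * y) / (nx * ny)
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

row_normalize <- function(m, pseudo = 0) {
  m <- m + pseudo
  sweep(m, 1, pmax(rowSums(m), .Machine$double.xmin), "/")
}
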