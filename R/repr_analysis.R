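#' Position-binned population vector
#'
#' A population vector (PV) is the mean activity of every recorded unit at
#' one position bin: rows are positions along the track, columns are units
#' (cells, network units, or model states). The same container is used for
#' calcium data (5-cm bins), model clone occupancies, and network hidden
#' states (one symbol per bin), so all sources flow through the same
#' comparison machinery.
#'
#' @param mat numeric matrix, positions x units, finite entries.
#' @param positions_cm position of each row (bin start, cm), increasing.
#' @param trial_type `"near"`, `"far"`, or `NA`.
#' @param source free-text provenance tag.
#' @return an object of class `position_pv`.
#' @export
position_pv <- function(mat, positions_cm = 10 * (seq_len(nrow(mat)) - 1L),
                        trial_type = NA_character_, source = "unknown") {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("PV entries must be finite")
  if (is.unsorted(positions_cm)) stop("positions must be ordered")
  structure(list(mat = mat, positions_cm = positions_cm,
                 trial_type = trial_type, source = source),
            class = "position_pv")
}

#' @export
print.position_pv <- function(x, ...) {
  cat(sprintf("<position_pv> %d positions x %d units (%s, %s)\n",
              nrow(x$mat), ncol(x$mat), x$trial_type, x$source))
  invisible(x)
}

pv_matrix <- function(pv) if (inherits(pv, "position_pv")) pv$mat else as.matrix(pv)

#' Near-by-far population-vector cross-correlation matrix
#'
#' Pearson correlation coefficient between the population vectors of every
#' (near-position, far-position) pair. Zero-variance population vectors
#' (e.g. silent bins) correlate as 0 by convention and are flagged.
#'
#' @param pv_near,pv_far `position_pv` objects (or matrices) with identical
#'   unit count and order.
#' @return a `cross_corr_matrix`: numeric matrix near-positions x
#'   far-positions with attributes `positions_near`, `positions_far`, and
#'   `degenerate` (logical matrix marking convention-zero entries).
#' @export
pv_cross_correlation <- function(pv_near, pv_far) {
  a <- pv_matrix(pv_near); b <- pv_matrix(pv_far)
  if (ncol(a) != ncol(b)) stop("unit count mismatch between PVs")
  n <- nrow(a); m <- nrow(b)
  sda <- apply(a, 1, stats::sd); sdb <- apply(b, 1, stats::sd)
  oka <- is.finite(sda) & sda > 0; okb <- is.finite(sdb) & sdb > 0
  cc <- matrix(0, n, m)
  if (any(oka) && any(okb))
    cc[oka, okb] <- stats::cor(t(a[oka, , drop = FALSE]),
                               t(b[okb, , drop = FALSE]))
  deg <- outer(!oka, rep(TRUE, m), "&") | outer(rep(TRUE, n), !okb, "&")
  structure(cc,
            positions_near = if (inherits(pv_near, "position_pv"))
              pv_near$positions_cm else seq_len(n),
            positions_far = if (inherits(pv_far, "position_pv"))
              pv_far$positions_cm else seq_len(m),
            degenerate = deg,
            class = c("cross_corr_matrix", "matrix", "array"))
}

#' Named track regions for a set of position bins
#'
#' Maps position bins onto the canonical track regions (initial grey,
#' indicator, pre-R1, R1, pre-R2, R2, end grey, teleport) by their cm
#' coordinates, and lists the grey regions whose pairwise ("off-diagonal")
#' correlations quantify within-track disambiguation.
#'
#' @param positions_cm bin start positions in cm (10-cm model bins or 5-cm
#'   neural bins).
#' @param variant `"standard"` or `"stretched"` track geometry.
#' @return an object of class `region_spec`: list with `regions` (named list
#'   of row indices), `grey` (names of the grey regions), `positions_cm`.
#' @export
region_spec <- function(positions_cm, variant = "standard") {
  lay <- track_layout(variant)
  segs <- lay$segments
  # region of the 10-cm segment containing each bin start
  seg_of <- pmin(floor(positions_cm / 10) + 1L, nrow(segs))
  reg <- segs$region[seg_of]
  regions <- split(seq_along(positions_cm), reg)
  regions <- regions[intersect(unique(segs$region), names(regions))]
  structure(list(regions = regions,
                 grey = intersect(c("initial", "pre_r1", "pre_r2", "end"),
                                  names(regions)),
                 positions_cm = positions_cm, variant = variant),
            class = "region_spec")
}

#' Region-averaged correlations and population-vector angles
#'
#' Averages a near-by-far cross-correlation matrix over named track regions:
#' for each region its square block on the matrix (near positions x far
#' positions of the same region; `average = "diagonal"` restricts to
#' corresponding-position pairs instead), plus the mean over the full
#' cross-blocks of all ordered pairs of *distinct* grey regions (the
#' "off-diagonal" grey correlation). When the underlying PVs
#' are supplied, also returns the per-position angle (degrees) between the
#' paired near/far population vectors: orthogonal nonnegative PVs meet at
#' 90 degrees, identical ones at 0.
#'
#' @param ccm a `cross_corr_matrix`.
#' @param regions a `region_spec` matching the matrix bins.
#' @param pv_near,pv_far optional `position_pv` objects for angle analysis.
#' @param average `"block"` (default) or `"diagonal"`.
#' @return list with `region_means` (named numeric, including
#'   `off_diagonal`), and `angles_deg` (per shared position, or NULL).
#' @export
region_correlations <- function(ccm, regions, pv_near = NULL, pv_far = NULL,
                                average = c("block", "diagonal")) {
  average <- match.arg(average)
  stopifnot(inherits(regions, "region_spec"))
  idx <- regions$regions
  if (any(vapply(idx, length, 1L) == 0)) stop("empty region")
  if (max(unlist(idx)) > nrow(ccm) || max(unlist(idx)) > ncol(ccm))
    stop("regions outside matrix bounds")
  means <- if (average == "block")
    vapply(idx, function(i) mean(ccm[i, i, drop = FALSE]), 0)
  else vapply(idx, function(i) mean(ccm[cbind(i, i)]), 0)
  grey <- regions$grey
  off <- c()
  for (a in grey) for (b in grey) if (a != b)
    off <- c(off, mean(ccm[idx[[a]], idx[[b]], drop = FALSE]))
  means <- c(means,
             off_diagonal = if (length(off)) mean(off) else NA_real_)
  angles <- NULL
  if (!is.null(pv_near) && !is.null(pv_far)) {
    a <- pv_matrix(pv_near); b <- pv_matrix(pv_far)
    k <- min(nrow(a), nrow(b))
    angles <- vapply(seq_len(k),
                     function(i) as.numeric(vector_angle_deg(a[i, ], b[i, ])), 0)
  }
  list(region_means = means, angles_deg = angles)
}

#' Decorrelation trajectory across training checkpoints
#'
#' Tracks per-region mean near/far correlations over a series of checkpoints
#' and finds, for each region, the first time the series falls below a
#' threshold (default 0.3), with linear interpolation between checkpoints.
#' Times are reported on a normalized 0..1 axis (checkpoint index divided by
#' training duration) when `normalize` is set; regions that never cross are
#' flagged `NA` with `crossed = FALSE`.
#'
#' @param ccms list of `cross_corr_matrix`, one per checkpoint (>= 2).
#' @param regions a `region_spec` matching the matrices.
#' @param threshold correlation threshold (default 0.3).
#' @param normalize divide crossing times by total duration (default TRUE).
#' @param average region averaging mode, see [region_correlations()].
#' @return an object of class `decorr_trajectory`: list with `series`
#'   (checkpoints x regions matrix, including `off_diagonal`), `times`
#'   (checkpoint axis), `crossing` (named vector, NA = never crossed),
#'   `crossed` (named logical), `threshold`.
#' @export
decorrelation_trajectory <- function(ccms, regions, threshold = 0.3,
                                     normalize = TRUE, average = "block") {
  if (length(ccms) < 2) stop("need at least 2 checkpoints")
  series <- t(vapply(ccms, function(m)
    region_correlations(m, regions, average = average)$region_means,
    region_correlations(ccms[[1]], regions, average = average)$region_means))
  k <- nrow(series)
  times <- seq(0, 1, length.out = k)
  if (!normalize) times <- seq_len(k) - 1
  crossing <- setNames(rep(NA_real_, ncol(series)), colnames(series))
  for (r in colnames(series)) {
    v <- series[, r]
    below <- which(v < threshold)
    if (length(below) == 0) next
    i <- below[1]
    if (i == 1) { crossing[r] <- times[1]; next }
    frac <- (v[i - 1] - threshold) / (v[i - 1] - v[i])
    crossing[r] <- times[i - 1] + frac * (times[i] - times[i - 1])
  }
  structure(list(series = series, times = times, crossing = crossing,
                 crossed = !is.na(crossing), threshold = threshold),
            class = "decorr_trajectory")
}

#' Order of decorrelation across the key regions
#'
#' Ranks the threshold-crossing times of the off-diagonal grey pairs, the
#' pre-R2 region, and the pre-R1 region. The hippocampal (and cloned-HMM)
#' signature is off-diagonal <= pre-R2 <= pre-R1 (ties allowed); the match
#' flag is false, with a reason, when any of the three never crosses.
#'
#' @param trajectory a `decorr_trajectory` containing regions
#'   `off_diagonal`, `pre_r2`, `pre_r1`.
#' @return list with `times` (named), `order` (region names sorted by
#'   crossing time), `match` (logical), `reason`.
#' @export
decorrelation_order <- function(trajectory) {
  need <- c("off_diagonal", "pre_r2", "pre_r1")
  if (!all(need %in% names(trajectory$crossing)))
    stop("trajectory must contain off_diagonal, pre_r2 and pre_r1")
  tms <- trajectory$crossing[need]
  if (anyNA(tms)) {
    miss <- need[is.na(tms)]
    return(list(times = tms, order = NULL, match = FALSE,
                reason = paste("never crossed:", paste(miss, collapse = ", "))))
  }
  list(times = tms, order = need[order(tms)],
       match = tms["off_diagonal"] <= tms["pre_r2"] &&
               tms["pre_r2"] <= tms["pre_r1"],
       reason = "ok")
}
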