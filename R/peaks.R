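#' Detect and measure peaks in a chromatogram
#'
#' Finds local maxima, draws a local linear baseline between the flanking
#' minima of each peak, and measures retention time, baseline-corrected
#' height, area and widths at 50% and 5% of height. Detection and bound
#' finding run on a lightly smoothed copy of the trace (5-point running
#' mean) so baseline noise does not fragment peaks; all measurements are
#' taken on the raw baseline-corrected signal.
#'
#' Conventions (each a single constant, see the package vignette):
#' * retention time and height come from a 3-point parabolic refinement of
#'   the apex sample;
#' * integration bounds are where the corrected signal falls to 1% of the
#'   apex height or a local minimum, whichever comes first (EMG tails are
#'   not truncated early);
#' * widths are linear interpolations between the bracketing samples at 50%
#'   and 5% of corrected height; areas are trapezoidal, in response x min.
#'
#' @param chrom A [chromatogram()].
#' @param min_height Minimum baseline-corrected apex height (response
#'   units) for a maximum to count as a peak. Must be > 0.
#' @param expected Optional named list of retention windows
#'   `c(lower, upper)` in minutes, one per analyte. When given, each window
#'   must contain at least one detected peak (else a missing-analyte error)
#'   and contributes exactly one row - the highest apex in the window -
#'   labelled with the window's name.
#'
#' @return A `data.frame` of class `"peak_measurements"`, one row per peak,
#'   ordered by retention time, with columns `analyte_id`,
#'   `retention_time`, `height`, `area`, `width_at_half`, `width_at_5pct`,
#'   `front_at_5pct`.
#' @examples
#' ch <- generate_chromatogram(peak_spec("X", 10, area = 5, sigma = 0.1))
#' detect_peaks(ch, min_height = 1)
#' @export
detect_peaks <- function(chrom, min_height, expected = NULL) {
  if (!inherits(chrom, "chromatogram")) chrom <- chromatogram(chrom$time, chrom$signal)
  check_scalar(min_height, "min_height", positive = TRUE)
  t <- chrom$time
  s <- chrom$signal
  n <- length(s)
  if (n < 5) stopf("chromatogram too short for peak detection")

  sm <- smooth_trace(s, 5L)
  # noise scale of the raw trace (robust; ~0 for noiseless signals);
  # drives the hysteresis of the peak-bound walk
  tol <- 3 * stats::mad(diff(s)) / sqrt(2)
  # candidate apexes: interior local maxima of the smoothed trace
  cand <- which(sm[-c(1L, n)] >= sm[-c(n - 1L, n)] & sm[-c(1L, n)] > sm[-(1:2)]) + 1L
  rows <- list()
  used_apex <- integer(0)
  for (i in cand) {
    m <- measure_peak(t, s, sm, i, min_height, tol)
    if (is.null(m)) next
    if (m$apex_index %in% used_apex) next
    used_apex <- c(used_apex, m$apex_index)
    rows[[length(rows) + 1L]] <- m
  }
  out <- peaks_to_df(rows)

  if (!is.null(expected)) {
    if (is.null(names(expected)) || any(!nzchar(names(expected))))
      stopf("`expected` windows must be named by analyte")
    sel <- lapply(names(expected), function(id) {
      w <- expected[[id]]
      hit <- out[out$retention_time >= w[1] & out$retention_time <= w[2], , drop = FALSE]
      if (nrow(hit) == 0L)
        stopf("missing analyte: no peak above min_height in window [%g, %g] for '%s'",
              w[1], w[2], id)
      hit <- hit[which.max(hit$height), , drop = FALSE]
      hit$analyte_id <- id
      hit
    })
    out <- do.call(rbind, sel)
  }
  out <- out[order(out$retention_time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_measurements", "data.frame")
  out
}

smooth_trace <- function(s, k) {
  if (length(s) <= k) return(s)
  sm <- as.numeric(stats::filter(s, rep(1 / k, k), sides = 2))
  na <- is.na(sm)
  sm[na] <- s[na]
  sm
}

peaks_to_df <- function(rows) {
  cols <- c("analyte_id", "retention_time", "height", "area",
            "width_at_half", "width_at_5pct", "front_at_5pct")
  if (length(rows) == 0L) {
    out <- data.frame(analyte_id = character(0), retention_time = numeric(0),
                      height = numeric(0), area = numeric(0),
                      width_at_half = numeric(0), width_at_5pct = numeric(0),
                      front_at_5pct = numeric(0))
    return(out)
  }
  do.call(rbind, lapply(rows, function(m)
    data.frame(analyte_id = m$analyte_id, retention_time = m$retention_time,
               height = m$height, area = m$area,
               width_at_half = m$width_at_half,
               width_at_5pct = m$width_at_5pct,
               front_at_5pct = m$front_at_5pct)))[, cols]
}

# Walk from apex i in direction dir, tracking the running minimum of the
# smoothed trace; stop once the trace rises `tol` above it. With tol = 0
# this is the nearest local minimum; with noise it skips spurious upticks.
walk_min <- function(sm, i, dir, tol) {
  n <- length(sm)
  j <- i
  minv <- sm[i]
  minj <- i
  while (j + dir >= 1L && j + dir <= n) {
    j <- j + dir
    if (sm[j] < minv) {
      minv <- sm[j]
      minj <- j
    } else if (sm[j] > minv + tol) break
  }
  minj
}

# Measure one candidate peak at smoothed-apex index i.
# Returns NULL if the baseline-corrected height is below min_height.
measure_peak <- function(t, s, sm, i, min_height, tol = 0) {
  n <- length(s)
  # baseline anchors: flanking minima of the smoothed trace
  lo <- walk_min(sm, i, -1L, tol)
  hi <- walk_min(sm, i, +1L, tol)
  if (hi - lo < 3L) return(NULL)

  # local linear baseline between the anchors, on the smoothed trace
  base <- sm[lo] + (sm[hi] - sm[lo]) * (t[lo:hi] - t[lo]) / (t[hi] - t[lo])
  cs <- s[lo:hi] - base
  m <- length(cs)
  i0 <- which.max(cs)
  if (i0 == 1L || i0 == m) return(NULL)

  # 3-point parabolic apex refinement (raw corrected signal)
  y1 <- cs[i0 - 1L]; y2 <- cs[i0]; y3 <- cs[i0 + 1L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  dt_loc <- (t[lo + i0] - t[lo + i0 - 2L]) / 2
  rt <- t[lo + i0 - 1L] + delta * dt_loc
  height <- y2 - 0.25 * (y1 - y3) * delta
  if (!is.finite(height) || height <= min_height) return(NULL)

  # integration bounds: corrected signal at 1% of apex, or the anchor minima
  left_ids <- which(cs[seq_len(i0 - 1L)] <= 0.01 * height)
  j_lo <- if (length(left_ids)) max(left_ids) else 1L
  right_ids <- which(cs[(i0 + 1L):m] <= 0.01 * height)
  j_hi <- if (length(right_ids)) i0 + min(right_ids) else m

  area <- pracma::trapz(t[(lo + j_lo - 1L):(lo + j_hi - 1L)], cs[j_lo:j_hi])

  l50 <- cross_left(t, lo, cs, i0, 0.50 * height)
  r50 <- cross_right(t, lo, cs, i0, 0.50 * height)
  l05 <- cross_left(t, lo, cs, i0, 0.05 * height)
  r05 <- cross_right(t, lo, cs, i0, 0.05 * height)
  if (any(is.na(c(l50, r50, l05, r05)))) return(NULL)

  list(analyte_id = NA_character_, retention_time = rt, height = height,
       area = area, width_at_half = r50 - l50, width_at_5pct = r05 - l05,
       front_at_5pct = rt - l05, apex_index = lo + i0 - 1L)
}

# linear interpolation of the crossing of `level` on the leading edge
cross_left <- function(t, lo, cs, i0, level) {
  below <- which(cs[seq_len(i0 - 1L)] <= level)
  if (!length(below)) return(NA_real_)
  j <- max(below)
  frac <- (level - cs[j]) / (cs[j + 1L] - cs[j])
  t[lo + j - 1L] + frac * (t[lo + j] - t[lo + j - 1L])
}

# ... and on the trailing edge
cross_right <- function(t, lo, cs, i0, level) {
  m <- length(cs)
  below <- which(cs[(i0 + 1L):m] <= level)
  if (!length(below)) return(NA_real_)
  j <- i0 + min(below)          # first sample at/below level after apex
  frac <- (cs[j - 1L] - level) / (cs[j - 1L] - cs[j])
  t[lo + j - 2L] + frac * (t[lo + j - 1L] - t[lo + j - 2L])
}
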