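# Zero-phase low-pass filtering of kinematic and pressure signals.
#
# Convention follows common motion-analysis practice: a 2nd-order Butterworth
# applied forward and backward (signal::filtfilt), giving an effective
# 4th-order zero-phase response. Edges are stabilized by odd-reflection
# padding before the forward-backward pass, so constants and slow signals
# pass through essentially unchanged at the boundaries.

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a uniformly sampled signal with a 2nd-order Butterworth low-pass
#' applied forward and backward (zero phase, effective 4th order). `NA`
#' segments are preserved: each contiguous run of finite samples is filtered
#' on its own; runs shorter than 12 samples are returned unfiltered.
#'
#' @param x numeric vector (or matrix, filtered column-wise).
#' @param cutoff_hz cutoff frequency in Hz; must be below the Nyquist rate.
#' @param rate_hz sampling rate in Hz.
#' @param order filter order of one pass (default 2).
#' @return filtered signal, same length/shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff_hz, rate_hz, order = 2) {
  if (is.matrix(x))
    return(apply(x, 2, lowpass_filter, cutoff_hz = cutoff_hz,
                 rate_hz = rate_hz, order = order))
  if (cutoff_hz >= rate_hz / 2)
    stop("cutoff must be below the Nyquist frequency (rate/2)")
  if (cutoff_hz <= 0 || rate_hz <= 0)
    stop("cutoff and rate must be positive")
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  out <- x
  runs <- finite_runs(x)
  for (r in runs) {
    seg <- x[r]
    n <- length(seg)
    if (n < 12) next
    # several filter time constants of odd-reflection padding, so the
    # forward-backward zero-state transients decay inside the pad
    pad <- min(n - 1, ceiling(6 * rate_hz / cutoff_hz))
    xp <- c(2 * seg[1] - seg[(pad + 1):2],
            seg,
            2 * seg[n] - seg[(n - 1):(n - pad)])
    yp <- signal::filtfilt(bf, xp)
    out[r] <- yp[(pad + 1):(pad + n)]
  }
  out
}

# indices of maximal runs of finite values, as a list of integer vectors
finite_runs <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lapply(which(r$values), function(i) starts[i]:ends[i])
}

#' Fill short gaps in a signal by linear interpolation
#'
#' Interior `NA` runs of length at most `max_gap` samples are replaced by
#' linear interpolation between the neighbouring finite samples; longer runs
#' and leading/trailing `NA`s are left missing. This is the gap policy
#' applied to marker coordinates before filtering, to avoid filter ringing
#' across tracking holes.
#'
#' @param x numeric vector.
#' @param max_gap maximum gap length (samples) to bridge; default 5.
#' @return `x` with short gaps interpolated.
#' @export
fill_gaps <- function(x, max_gap = 5) {
  na <- is.na(x)
  if (!any(na) || all(na)) return(x)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    if (s == 1 || e == length(x)) next          # edge gaps stay missing
    if (r$lengths[i] > max_gap) next
    x0 <- x[s - 1]; x1 <- x[e + 1]
    x[s:e] <- x0 + (x1 - x0) * seq_len(e - s + 1) / (e - s + 2)
  }
  x
}

#' Low-pass filter every marker coordinate of a trajectory set
#'
#' Applies [fill_gaps()] then [lowpass_filter()] to each marker's X, Y and Z
#' series independently (coordinates are filtered before any distance or
#' pose computation).
#'
#' @param x a `trajectory_set`.
#' @param cutoff_hz cutoff in Hz (study default 40).
#' @param max_gap gap-fill limit in frames, see [fill_gaps()].
#' @return a filtered `trajectory_set`.
#' @export
filter_trajectories <- function(x, cutoff_hz = 40, max_gap = 5) {
  out <- x
  for (i in seq_along(x$markers))
    for (k in 1:3)
      out$coords[, i, k] <- lowpass_filter(fill_gaps(x$coords[, i, k], max_gap),
                                           cutoff_hz, x$frame_rate_hz)
  out
}
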