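#' Process a raw intra-oral pressure trace
#'
#' Low-pass filters the pressure (zero-phase Butterworth, study cutoff
#' 300 Hz at 1000 Hz sampling) and re-references it to the mean over a
#' pre-strike baseline window, so that ambient pressure reads 0 Pa and
#' sub-ambient intra-oral pressure is negative.
#'
#' @param pressure data.frame with `time_s` and `pressure_pa` (e.g. from
#'   [read_pressure()]).
#' @param cutoff_hz filter cutoff in Hz (default 300); must be below the
#'   Nyquist rate.
#' @param baseline_s length-2 numeric: start and end time (s) of the
#'   pre-strike ambient window.
#' @return a `pressure_trace` data.frame (`time_s`, `pressure_pa`) with
#'   attribute `sample_rate_hz`.
#' @export
process_pressure <- function(pressure, cutoff_hz = 300, baseline_s) {
  t <- pressure$time_s
  p <- pressure$pressure_pa
  dt <- median(diff(t))
  rate <- 1 / dt
  pf <- lowpass_filter(p, cutoff_hz, rate)
  win <- t >= baseline_s[1] & t <= baseline_s[2]
  if (!any(win))
    stop("baseline window contains no pressure samples")
  pf <- pf - mean(pf[win])
  structure(data.frame(time_s = t, pressure_pa = pf),
            sample_rate_hz = rate, baseline_s = baseline_s,
            class = c("pressure_trace", "data.frame"))
}

#' Resample pressure onto the video frame times
#'
#' Linearly interpolates the (already filtered, re-zeroed) pressure trace
#' onto the video frame times; filtering happens at the native pressure
#' rate *before* this downsampling. Frames outside the pressure record are
#' `NA`. Study synchronization tests showed no offset between pressure and
#' video, so `offset_s` defaults to 0; a positive offset shifts the
#' pressure clock forward relative to video.
#'
#' @param pressure a `pressure_trace` (or data.frame with `time_s`,
#'   `pressure_pa`).
#' @param frame_times_s numeric vector of video frame times (s).
#' @param offset_s pressure-to-video clock offset (s), default 0.
#' @return numeric vector: pressure (Pa) at each frame time.
#' @export
synchronize <- function(pressure, frame_times_s, offset_s = 0) {
  t <- pressure$time_s - offset_s
  if (max(t) < min(frame_times_s) || min(t) > max(frame_times_s))
    stop("pressure and video records do not overlap")
  approx(t, pressure$pressure_pa, xout = frame_times_s, rule = 1)$y
}

#' Instantaneous mouth-expansion power
#'
#' Power at each frame is the product of the sign-flipped instantaneous
#' pressure (Pa) and the rate of mouth-volume change (m^3/s):
#' `power = (-pressure) * dVdt`, so sub-ambient pressure during expansion
#' gives positive power. The signed product is kept at all frames (ambient
#' or supra-ambient pressure during expansion yields negative power rather
#' than being zeroed).
#'
#' @param pressure_pa pressure at frame times (Pa, re-zeroed to ambient).
#' @param dVdt_m3s rate of total mouth-volume change (m^3/s), same length.
#' @return list with `power_w` (series), `max_power_w` and `peak_frame`.
#' @export
instantaneous_power <- function(pressure_pa, dVdt_m3s) {
  if (length(pressure_pa) != length(dVdt_m3s))
    stop("pressure and dV/dt series differ in length")
  pw <- (-pressure_pa) * dVdt_m3s
  if (all(!is.finite(pw)))
    return(list(power_w = pw, max_power_w = NA_real_, peak_frame = NA_integer_))
  pk <- which.max(pw)
  list(power_w = pw, max_power_w = pw[pk], peak_frame = pk)
}

#' Peak-power window mask
#'
#' Frames where expansion power is within `(1 - fraction)` of its maximum,
#' i.e. `power >= fraction * max(power)` (study definition: within 25% of
#' maximum, `fraction = 0.75`). The mask may be non-contiguous; the maximal
#' contiguous block containing the peak frame is returned as well.
#'
#' @param power_w power series (W); its maximum must be positive.
#' @param fraction threshold fraction of maximum (default 0.75).
#' @return list with logical `mask`, logical `block` (contiguous block
#'   containing the peak), `max_power_w`, `peak_frame`.
#' @export
peak_power_mask <- function(power_w, fraction = 0.75) {
  if (all(!is.finite(power_w)) || max(power_w, na.rm = TRUE) <= 0)
    stop("power series has no positive maximum")
  mx <- max(power_w, na.rm = TRUE)
  pk <- which.max(power_w)
  mask <- !is.na(power_w) & power_w >= fraction * mx
  block <- rep(FALSE, length(power_w))
  i <- pk
  while (i >= 1 && isTRUE(mask[i])) { block[i] <- TRUE; i <- i - 1 }
  i <- pk + 1
  while (i <= length(power_w) && isTRUE(mask[i])) { block[i] <- TRUE; i <- i + 1 }
  list(mask = mask, block = block, max_power_w = mx, peak_frame = pk)
}

#' Normalize peak power by muscle/body mass or mouth volume
#'
#' Divides a power value by each supplied divisor: muscle or body masses in
#' kg give W/kg; the maximum change in mouth volume in cm^3 gives W/cm^3.
#' Masses from unilateral dissection should be doubled by the caller
#' (bilateral convention) before being passed in.
#'
#' @param max_power_w peak power (W).
#' @param divisors named numeric vector (all > 0), e.g.
#'   `c(hypaxial_kg = 0.03, cranial_kg = 0.006, body_kg = 0.8, dvol_cm3 = 25)`.
#' @return named numeric vector of normalized powers, names suffixed
#'   `_Wkg` or `_Wcm3` based on the divisor's `_kg`/`_cm3` suffix.
#' @export
normalize_power <- function(max_power_w, divisors) {
  if (any(divisors <= 0) || anyNA(divisors))
    stop("all divisors must be positive")
  out <- max_power_w / divisors
  nm <- names(divisors)
  nm <- ifelse(grepl("_kg$", nm), sub("_kg$", "_Wkg", nm),
        ifelse(grepl("_cm3$", nm), sub("_cm3$", "_Wcm3", nm),
               paste0(nm, "_per_unit")))
  setNames(out, nm)
}

#' Per-individual mean and standard error tables
#'
#' Groups per-strike summary scalars by individual and reports mean and
#' s.e.m. (`sd/sqrt(n)`; 0 with a flag when n = 1) for each variable.
#'
#' @param strikes data.frame of per-strike scalars, one row per strike.
#' @param individual factor/character vector of individual IDs (length =
#'   rows of `strikes`).
#' @return data.frame with columns `individual`, `variable`, `mean`, `sem`,
#'   `n`.
#' @export
summarize_individuals <- function(strikes, individual) {
  stopifnot(nrow(strikes) == length(individual))
  num <- names(strikes)[vapply(strikes, is.numeric, TRUE)]
  rows <- list()
  for (id in unique(individual)) {
    sel <- individual == id
    n <- sum(sel)
    if (n == 0) { warning(sprintf("individual '%s' has no strikes", id)); next }
    for (v in num) {
      x <- strikes[[v]][sel]
      x <- x[is.finite(x)]
      if (length(x) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        individual = id, variable = v, mean = mean(x),
        sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
        n = length(x))
    }
  }
  do.call(rbind, rows)
}
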