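#' Axial muscle region defined by an intramuscular marker chain
#'
#' A muscle region is an ordered chain of intramuscular markers. Adjacent
#' marker pairs define subregions; the first-to-last pair defines the whole
#' region (straight-line distance by default).
#'
#' @param name muscle name (e.g. `"hypaxial"`).
#' @param markers ordered character vector of marker names (>= 2).
#' @param mass_kg optional bilateral muscle mass for power normalization.
#' @return an object of class `muscle_region`.
#' @export
muscle_region <- function(name, markers, mass_kg = NULL) {
  if (length(markers) < 2)
    stop("a muscle region needs at least 2 markers")
  if (!is.null(mass_kg) && mass_kg <= 0)
    stop("mass_kg must be positive")
  structure(list(name = name, markers = markers, mass_kg = mass_kg),
            class = "muscle_region")
}

#' Per-frame distance between two markers
#'
#' Fluoromicrometry's primitive: the Euclidean distance between two
#' radio-opaque intramuscular markers at every frame, computed on
#' low-pass-filtered coordinates. Missing samples propagate as `NA`.
#'
#' @param a,b `frames x 3` coordinate matrices (e.g. [marker_xyz()] of a
#'   filtered trajectory set).
#' @return numeric length series.
#' @export
pairwise_length <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(rowSums((a - b)^2))
}

#' Subregion and whole-region length series of a marker chain
#'
#' @param trajectories a (filtered) `trajectory_set`.
#' @param region a [muscle_region()].
#' @param whole `"straight"` (default) measures the whole region as the
#'   straight-line distance between the first and last marker; `"chain"`
#'   sums the subregion lengths.
#' @return a `frames x (n_sub + 1)` matrix; columns named
#'   `<name>_sub1..subK` and `<name>_whole`.
#' @export
region_lengths <- function(trajectories, region, whole = c("straight", "chain")) {
  whole <- match.arg(whole)
  mk <- region$markers
  xyz <- lapply(mk, function(m) marker_xyz(trajectories, m))
  nsub <- length(mk) - 1
  L <- sapply(seq_len(nsub), function(i) pairwise_length(xyz[[i]], xyz[[i + 1]]))
  L <- matrix(L, ncol = nsub)
  wholeL <- if (whole == "straight") pairwise_length(xyz[[1]], xyz[[length(mk)]])
            else rowSums(L)
  out <- cbind(L, wholeL)
  colnames(out) <- c(paste0(region$name, "_sub", seq_len(nsub)),
                     paste0(region$name, "_whole"))
  out
}

#' Mean initial length across strikes
#'
#' The reference length L_i is the mean, across strikes from one
#' individual, of the baseline-window mean length of each strike.
#'
#' @param lengths list of numeric length series, one per strike.
#' @param baseline_frames list (same length) of baseline frame-index
#'   vectors, or a single vector reused for every strike.
#' @return L_i (scalar).
#' @export
mean_initial_length <- function(lengths, baseline_frames) {
  if (!is.list(lengths)) lengths <- list(lengths)
  if (!is.list(baseline_frames))
    baseline_frames <- rep(list(baseline_frames), length(lengths))
  vals <- mapply(function(L, w) mean(L[w], na.rm = TRUE),
                 lengths, baseline_frames)
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0)
    stop("no strike had a valid baseline window")
  mean(vals)
}

#' Strain and strain rate from a length series
#'
#' Strain is the percent change in length relative to the mean initial
#' length, `100 * (L_i - L) / L_i`, positive when the muscle shortens.
#' Strain rate (shortening velocity) is `-(dL/dt) / L_i` in initial lengths
#' per second, positive when shortening; the derivative uses central
#' differences (one-sided at the ends) on the already-filtered lengths.
#'
#' @param length numeric length series.
#' @param L_i mean initial length (> 0).
#' @param frame_rate_hz sampling rate of the series.
#' @param name optional muscle/subregion label.
#' @return a `strain_trace`: data.frame with `frame`, `time_s`, `length`,
#'   `strain_pct`, `rate_Li_per_s`.
#' @export
strain_and_rate <- function(length, L_i, frame_rate_hz, name = NULL) {
  if (!is.finite(L_i) || L_i <= 0)
    stop("L_i must be a positive length")
  n <- length(length)
  dL <- central_diff(length, 1 / frame_rate_hz)
  out <- data.frame(frame = seq_len(n),
                    time_s = (seq_len(n) - 1) / frame_rate_hz,
                    length = length,
                    strain_pct = 100 * (L_i - length) / L_i,
                    rate_Li_per_s = -dL / L_i)
  structure(out, muscle = name, L_i = L_i, frame_rate_hz = frame_rate_hz,
            class = c("strain_trace", "data.frame"))
}

#' @export
print.strain_trace <- function(x, ...) {
  ok <- is.finite(x$strain_pct)
  cat(sprintf("<strain_trace> %s: %d frames, L_i = %.4g\n",
              attr(x, "muscle") %||% "?", nrow(x), attr(x, "L_i")))
  if (any(ok))
    cat(sprintf("  peak strain %.2f%% (positive = shortening), peak rate %.3f L_i/s\n",
                max(x$strain_pct[ok]), max(x$rate_Li_per_s[is.finite(x$rate_Li_per_s)])))
  invisible(x)
}

# central differences with one-sided ends; NA-aware (NA in -> NA out locally)
central_diff <- function(x, dt) {
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n >= 2) {
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
  }
  if (n >= 3)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Cranial muscle fiber set anchored on animated bones
#'
#' Cranial muscle lengths are measured between bone-attached virtual
#' landmarks at the origin and insertion of three fibers; whole-muscle
#' length is the per-frame mean of the three fiber lengths. For muscles
#' with substantial tendons this is muscle-tendon-unit length, not fiber
#' length.
#'
#' @param muscle muscle name.
#' @param origins,insertions length-3 character vectors naming the origin
#'   and insertion landmarks of the three fibers.
#' @param mtu logical: lengths represent the muscle-tendon unit (default
#'   FALSE = whole muscle ~ fiber length).
#' @return an object of class `fiber_set`.
#' @export
fiber_set <- function(muscle, origins, insertions, mtu = FALSE) {
  if (length(origins) != 3 || length(insertions) != 3)
    stop("a fiber set has exactly three origin-insertion pairs")
  structure(list(muscle = muscle, origins = origins, insertions = insertions,
                 mtu = mtu),
            class = "fiber_set")
}

#' Whole-muscle length from three fibers
#'
#' @param fibers a [fiber_set()].
#' @param landmarks a `trajectory_set` containing the animated origin and
#'   insertion landmarks (e.g. from [animate_landmarks()], possibly merged
#'   across bones).
#' @return numeric series: mean of the three fiber lengths per frame (NA
#'   when any landmark is missing).
#' @export
fiber_muscle_length <- function(fibers, landmarks) {
  Ls <- sapply(1:3, function(i)
    pairwise_length(marker_xyz(landmarks, fibers$origins[i]),
                    marker_xyz(landmarks, fibers$insertions[i])))
  rowMeans(matrix(Ls, ncol = 3))
}

#' Extremum of a trace during a frame mask
#'
#' Restricts a series to masked frames (typically the peak-power window)
#' and returns its extremum, e.g. maximum strain or maximum shortening
#' velocity during peak expansion power.
#'
#' @param x numeric series.
#' @param mask logical mask over frames (non-empty).
#' @param what `"max"` (default), `"min"`, or `"absmax"` (value of largest
#'   magnitude, sign preserved).
#' @return scalar extremum.
#' @export
peak_during_window <- function(x, mask, what = c("max", "min", "absmax")) {
  what <- match.arg(what)
  if (!any(mask, na.rm = TRUE))
    stop("mask selects no frames")
  v <- x[which(mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  switch(what,
         max = max(v),
         min = min(v),
         absmax = v[which.max(abs(v))])
}
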