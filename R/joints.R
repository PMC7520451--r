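#' Anatomical coordinate system attached to a bone
#'
#' An ACS is an origin plus a right-handed orthonormal axis triad, defined
#' in the reference (CT) space of the bone (or body plane) it is attached
#' to. Axis convention: +x runs rostro-caudally pointing rostral, +z runs
#' transversely pointing to the animal's right, and +y = z cross x points
#' dorsal. Under the right-hand rule this makes dorsal rotation (cranial
#' elevation, girdle protraction) a positive z-axis rotation and ventral
#' rotation (depression, retraction) negative, and rightward translation
#' positive z.
#'
#' @param bone name of the bone (or body plane) the ACS is attached to.
#' @param origin length-3 reference-space coordinate of the joint center.
#' @param axes 3x3 matrix whose columns are the x, y, z axis directions in
#'   reference space (default identity). Must be right-handed orthonormal.
#' @return an object of class `anatomical_cs`.
#' @export
anatomical_cs <- function(bone, origin, axes = diag(3)) {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3, all(dim(axes) == c(3, 3)))
  if (max(abs(t(axes) %*% axes - diag(3))) > 1e-8)
    stop("ACS axes must be orthonormal")
  if (det(axes) < 0)
    stop("ACS axes must be right-handed (det = +1)")
  structure(list(bone = bone, origin = origin, axes = axes),
            class = "anatomical_cs")
}

#' Joint coordinate system from a duplicated ACS pair
#'
#' A JCS measures the motion of a distal bone relative to a proximal one: an
#' anatomical coordinate system is duplicated, one copy attached to each
#' bone, and the relative transform between the two copies is decomposed in
#' a z-y-x rotation order. The two copies coincide at the reference (setup)
#' pose.
#'
#' @param name joint name.
#' @param proximal,distal [anatomical_cs()] objects for the proximal body
#'   (e.g. the body plane) and the mobile distal bone.
#' @return an object of class `joint_cs`.
#' @export
joint_cs <- function(name, proximal, distal) {
  stopifnot(inherits(proximal, "anatomical_cs"),
            inherits(distal, "anatomical_cs"))
  structure(list(name = name, proximal = proximal, distal = distal,
                 order = "zyx"),
            class = "joint_cs")
}

#' Decompose relative bone motion in a joint coordinate system
#'
#' For each frame, expresses the pose of the distal ACS in the frame of the
#' proximal ACS and decomposes the relative rotation as intrinsic z, then y,
#' then x rotations (degrees), plus translations along the proximal ACS
#' axes. An identity relative pose gives all-zero channels. Frames where
#' the middle rotation is within 1e-3 rad of +/-90 deg are flagged
#' `gimbal` (values still returned).
#'
#' @param pose_distal,pose_proximal `pose_sequence` objects sharing frames.
#' @param joint a [joint_cs()].
#' @return a `kinematic_trace`: data.frame with columns `frame`, `time_s`,
#'   `rz_deg`, `ry_deg`, `rx_deg`, `tz`, `ty`, `tx`, `gimbal`, with
#'   attributes `joint` and `frame_rate_hz`.
#' @export
jcs_decompose <- function(pose_distal, pose_proximal, joint) {
  nfr <- length(pose_distal$missing)
  if (length(pose_proximal$missing) != nfr)
    stop("pose sequences do not share frames")
  Ap <- joint$proximal$axes; op <- joint$proximal$origin
  Ad <- joint$distal$axes;   od <- joint$distal$origin
  out <- data.frame(frame = seq_len(nfr),
                    time_s = (seq_len(nfr) - 1) / pose_distal$frame_rate_hz,
                    rz_deg = NA_real_, ry_deg = NA_real_, rx_deg = NA_real_,
                    tz = NA_real_, ty = NA_real_, tx = NA_real_,
                    gimbal = FALSE)
  for (f in seq_len(nfr)) {
    if (pose_distal$missing[f] || pose_proximal$missing[f]) next
    Rp <- pose_proximal$R[, , f]; tp <- pose_proximal$t[f, ]
    Rd <- pose_distal$R[, , f];   td <- pose_distal$t[f, ]
    # world pose of each ACS copy
    axes_p <- Rp %*% Ap
    axes_d <- Rd %*% Ad
    orig_p <- as.vector(Rp %*% op) + tp
    orig_d <- as.vector(Rd %*% od) + td
    Rrel <- t(axes_p) %*% axes_d
    trel <- as.vector(t(axes_p) %*% (orig_d - orig_p))
    eul <- euler_zyx_decompose(Rrel)
    out$rz_deg[f] <- eul$rz; out$ry_deg[f] <- eul$ry; out$rx_deg[f] <- eul$rx
    out$gimbal[f] <- eul$gimbal
    out$tx[f] <- trel[1]; out$ty[f] <- trel[2]; out$tz[f] <- trel[3]
  }
  structure(out, joint = joint$name,
            frame_rate_hz = pose_distal$frame_rate_hz,
            class = c("kinematic_trace", "data.frame"))
}

#' @export
print.kinematic_trace <- function(x, ...) {
  ok <- is.finite(x$rz_deg)
  cat(sprintf("<kinematic_trace> joint '%s': %d frames @ %g Hz\n",
              attr(x, "joint"), nrow(x), attr(x, "frame_rate_hz")))
  if (any(ok))
    cat(sprintf("  rz range [%.2f, %.2f] deg; %d gimbal-flagged frames\n",
                min(x$rz_deg[ok]), max(x$rz_deg[ok]), sum(x$gimbal)))
  invisible(x)
}

#' Gape trace: distance between the jaw tips
#'
#' Per-frame Euclidean distance between two landmark trajectories, e.g. the
#' rostral tips of the neurocranium (upper jaw) and lower jaw.
#'
#' @param upper_tip,lower_tip `frames x 3` matrices (e.g. from
#'   [marker_xyz()]) sharing frames.
#' @return numeric vector of distances (NA where either landmark is
#'   missing).
#' @export
gape_trace <- function(upper_tip, lower_tip) {
  stopifnot(nrow(upper_tip) == nrow(lower_tip))
  g <- sqrt(rowSums((upper_tip - lower_tip)^2))
  if (all(!is.finite(g)))
    stop("gape trace has no finite frames")
  g
}

#' Find the frame of peak gape
#'
#' Index of the global maximum of the (already filtered) gape trace; ties
#' break to the earliest frame. Peak gape is the t = 0 reference all other
#' traces are timed against.
#'
#' @param gape numeric gape series.
#' @param frame_rate_hz frame rate, for the returned time.
#' @return list with `frame` (1-based index) and `time_s` (frame 1 = 0 s).
#' @export
find_peak_gape <- function(gape, frame_rate_hz = NULL) {
  if (all(!is.finite(gape)))
    stop("gape trace has no finite values")
  f <- which.max(gape)           # which.max takes the first maximum
  list(frame = f,
       time_s = if (is.null(frame_rate_hz)) NA_real_
                else (f - 1) / frame_rate_hz)
}

#' Re-zero trace channels to a pre-strike baseline
#'
#' Subtracts the baseline-window mean from each rotation/translation channel
#' so traces read relative to their initial, pre-strike values. Applying it
#' twice with the same window is a no-op.
#'
#' @param trace a `kinematic_trace` (or any data.frame with numeric channel
#'   columns).
#' @param baseline_frames integer vector of frame indices forming the
#'   baseline window (must be non-empty and contain finite data).
#' @param channels columns to re-zero; defaults to the six JCS channels.
#' @return the re-zeroed trace.
#' @export
rezero_trace <- function(trace, baseline_frames,
                         channels = c("rz_deg", "ry_deg", "rx_deg",
                                      "tz", "ty", "tx")) {
  if (length(baseline_frames) == 0)
    stop("baseline window is empty")
  channels <- intersect(channels, names(trace))
  for (ch in channels) {
    b <- mean(trace[[ch]][baseline_frames], na.rm = TRUE)
    if (!is.finite(b))
      stop(sprintf("baseline window has no finite data for channel '%s'", ch))
    trace[[ch]] <- trace[[ch]] - b
  }
  trace
}

#' Baseline window frames relative to peak gape
#'
#' The default pre-strike baseline is a window of `width_s` seconds ending
#' `end_before_s` seconds before the time of peak gape.
#'
#' @param peak_frame frame index of peak gape.
#' @param frame_rate_hz frame rate in Hz.
#' @param width_s window width in seconds (default 0.1).
#' @param end_before_s gap between window end and peak gape (default 0.2).
#' @return integer vector of frame indices (>= 1, non-empty).
#' @export
baseline_window_frames <- function(peak_frame, frame_rate_hz,
                                   width_s = 0.1, end_before_s = 0.2) {
  end <- floor(peak_frame - end_before_s * frame_rate_hz)
  start <- ceiling(end - width_s * frame_rate_hz)
  idx <- seq(max(1, start), max(1, end))
  if (length(idx) == 0)
    stop("baseline window precedes the recording")
  idx
}

#' Export a kinematic trace as CSV
#'
#' Columns: `frame,time_s,rz_deg,ry_deg,rx_deg,tz,ty,tx,gimbal_flag`.
#'
#' @param trace a `kinematic_trace`.
#' @param path output CSV path.
#' @export
write_kinematic_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  names(df)[names(df) == "gimbal"] <- "gimbal_flag"
  write.csv(df[, c("frame", "time_s", "rz_deg", "ry_deg", "rx_deg",
                   "tz", "ty", "tx", "gimbal_flag")],
            path, row.names = FALSE)
  invisible(path)
}
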