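#' Reference geometry of a marked bone
#'
#' A `bone_definition` carries the reference (CT-space) coordinates of a
#' bone's implanted markers, plus any virtual landmarks (fiber attachment
#' sites, jaw tips, joint points, endocast points) defined in the same
#' reference frame. At least 3 non-collinear markers are required to fit a
#' rigid transform.
#'
#' @param name bone name.
#' @param markers `n x 3` numeric matrix of reference marker coordinates with
#'   rownames = marker names.
#' @param landmarks optional `m x 3` matrix of virtual landmark reference
#'   coordinates with rownames = landmark names.
#' @param collinear_tol smallest allowed second principal-axis spread of the
#'   marker cloud, as a fraction of the largest spread (default 1e-6).
#' @return an object of class `bone_definition`.
#' @export
bone_definition <- function(name, markers, landmarks = NULL,
                            collinear_tol = 1e-6) {
  markers <- as.matrix(markers)
  stopifnot(ncol(markers) == 3)
  if (is.null(rownames(markers)))
    stop("marker reference coordinates need rownames (marker names)")
  if (nrow(markers) < 3)
    stop(sprintf("bone '%s' has %d markers; at least 3 are required",
                 name, nrow(markers)))
  sv <- svd(scale(markers, scale = FALSE))$d
  if (sv[2] < collinear_tol * sv[1])
    stop(sprintf("markers of bone '%s' are collinear", name))
  if (!is.null(landmarks)) {
    landmarks <- as.matrix(landmarks)
    stopifnot(ncol(landmarks) == 3)
    if (is.null(rownames(landmarks)))
      stop("landmarks need rownames")
  }
  structure(list(name = name, markers = markers, landmarks = landmarks),
            class = "bone_definition")
}

#' @export
print.bone_definition <- function(x, ...) {
  cat(sprintf("<bone_definition> %s: %d markers, %d landmarks\n",
              x$name, nrow(x$markers),
              if (is.null(x$landmarks)) 0L else nrow(x$landmarks)))
  invisible(x)
}

#' Read per-bone reference geometry from CSV
#'
#' Reads a `bone,marker,x,y,z` table (CT-space coordinates). Rows whose
#' marker name starts with `lm_` are treated as virtual landmarks rather
#' than fitted markers.
#'
#' @param path CSV path.
#' @return named list of [bone_definition()] objects.
#' @export
read_bone_definitions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bone", "marker", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("reference geometry CSV must have columns bone,marker,x,y,z")
  out <- list()
  for (b in unique(df$bone)) {
    d <- df[df$bone == b, ]
    is_lm <- startsWith(d$marker, "lm_")
    mk <- as.matrix(d[!is_lm, c("x", "y", "z")])
    rownames(mk) <- d$marker[!is_lm]
    lm <- NULL
    if (any(is_lm)) {
      lm <- as.matrix(d[is_lm, c("x", "y", "z")])
      rownames(lm) <- d$marker[is_lm]
    }
    out[[b]] <- bone_definition(b, mk, lm)
  }
  out
}

#' Write per-bone reference geometry to CSV
#' @param bones named list of [bone_definition()] objects.
#' @param path output CSV path.
#' @export
write_bone_definitions <- function(bones, path) {
  rows <- list()
  for (b in bones) {
    rows[[length(rows) + 1]] <- data.frame(
      bone = b$name, marker = rownames(b$markers),
      x = b$markers[, 1], y = b$markers[, 2], z = b$markers[, 3])
    if (!is.null(b$landmarks))
      rows[[length(rows) + 1]] <- data.frame(
        bone = b$name, marker = rownames(b$landmarks),
        x = b$landmarks[, 1], y = b$landmarks[, 2], z = b$landmarks[, 3])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Least-squares rigid transform between two point sets
#'
#' Fits the rotation `R` and translation `t` minimizing
#' `sum || R %*% ref_i + t - obs_i ||^2` (orthogonal Procrustes via the
#' cross-covariance SVD, with determinant correction so that no reflection
#' is ever returned).
#'
#' @param reference `n x 3` matrix of reference coordinates (n >= 3,
#'   non-collinear).
#' @param observed `n x 3` matrix of observed coordinates, row-matched to
#'   `reference`. Rows with any `NA` in either matrix are dropped.
#' @return list with `R` (3x3, `det(R) = +1`), `t` (length-3), `residual`
#'   (RMS distance of the fit) and `n_used`.
#' @export
fit_rigid_transform <- function(reference, observed) {
  reference <- as.matrix(reference); observed <- as.matrix(observed)
  stopifnot(ncol(reference) == 3, ncol(observed) == 3,
            nrow(reference) == nrow(observed))
  ok <- stats::complete.cases(reference) & stats::complete.cases(observed)
  if (sum(ok) < 3)
    stop("fewer than 3 usable marker correspondences")
  A <- reference[ok, , drop = FALSE]
  B <- observed[ok, , drop = FALSE]
  sv <- svd(scale(A, scale = FALSE))$d
  if (sv[2] < 1e-9 * sv[1])
    stop("degenerate geometry: reference markers are collinear")
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cb - as.vector(R %*% ca)
  fit <- sweep(A %*% t(R), 2, tr, "+")
  residual <- sqrt(mean(rowSums((fit - B)^2)))
  list(R = R, t = tr, residual = residual, n_used = sum(ok))
}

#' Fit a bone's per-frame rigid transforms from its markers
#'
#' For every frame, estimates the rigid transform carrying the bone's
#' reference marker coordinates onto the tracked marker positions with
#' [fit_rigid_transform()]. Frames with fewer than 3 usable markers are
#' flagged missing.
#'
#' @param trajectories a `trajectory_set` containing the bone's markers.
#' @param bone a [bone_definition()].
#' @return a `pose_sequence`: list with `bone`, 3x3xframes rotation array
#'   `R`, `frames x 3` translation matrix `t`, per-frame RMS `residual`,
#'   logical `missing`, and `frame_rate_hz`.
#' @export
fit_pose_sequence <- function(trajectories, bone) {
  mk <- rownames(bone$markers)
  miss <- setdiff(mk, trajectories$markers)
  if (length(miss) > 0)
    stop(sprintf("markers of bone '%s' absent from trajectories: %s",
                 bone$name, paste(miss, collapse = ", ")))
  nfr <- n_frames(trajectories)
  R <- array(NA_real_, c(3, 3, nfr))
  tr <- matrix(NA_real_, nfr, 3)
  res <- rep(NA_real_, nfr)
  missing <- rep(TRUE, nfr)
  obs_all <- trajectories$coords[, mk, , drop = FALSE]
  for (f in seq_len(nfr)) {
    obs <- matrix(obs_all[f, , ], ncol = 3)
    ok <- stats::complete.cases(obs)
    if (sum(ok) < 3) next
    fit <- fit_rigid_transform(bone$markers, obs)
    R[, , f] <- fit$R
    tr[f, ] <- fit$t
    res[f] <- fit$residual
    missing[f] <- FALSE
  }
  structure(list(bone = bone$name, R = R, t = tr, residual = res,
                 missing = missing,
                 frame_rate_hz = trajectories$frame_rate_hz),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %s: %d frames @ %g Hz (%d missing), mean RMS residual %.4g\n",
              x$bone, length(x$missing), x$frame_rate_hz, sum(x$missing),
              mean(x$residual, na.rm = TRUE)))
  invisible(x)
}

#' Low-pass filter a pose sequence
#'
#' Filters the rigid-body motion rather than raw matrix entries: rotations
#' are converted to unit quaternions (sign-continuous across frames), the
#' four quaternion components and three translation components are low-pass
#' filtered, and quaternions are renormalized — preserving orthogonality of
#' the rotations.
#'
#' @param pose a `pose_sequence`.
#' @param cutoff_hz cutoff in Hz (study default 40).
#' @return a filtered `pose_sequence`.
#' @export
filter_poses <- function(pose, cutoff_hz = 40) {
  nfr <- length(pose$missing)
  Q <- matrix(NA_real_, nfr, 4)
  for (f in seq_len(nfr)) {
    if (pose$missing[f]) next
    q <- rot_to_quat(pose$R[, , f])
    if (f > 1 && !any(is.na(Q[f - 1, ])) && sum(q * Q[f - 1, ]) < 0) q <- -q
    Q[f, ] <- q
  }
  Qf <- apply(Q, 2, function(v)
    lowpass_filter(fill_gaps(v), cutoff_hz, pose$frame_rate_hz))
  Tf <- apply(pose$t, 2, function(v)
    lowpass_filter(fill_gaps(v), cutoff_hz, pose$frame_rate_hz))
  out <- pose
  for (f in seq_len(nfr)) {
    if (any(is.na(Qf[f, ]))) {
      out$R[, , f] <- NA_real_
      out$t[f, ] <- NA_real_
      out$missing[f] <- TRUE
      next
    }
    out$R[, , f] <- quat_to_rot(Qf[f, ])
    out$t[f, ] <- Tf[f, ]
    out$missing[f] <- FALSE
  }
  out
}

#' Animate bone-attached virtual landmarks
#'
#' Maps named reference-space landmarks through a bone's per-frame rigid
#' transforms: `world = R %*% reference + t`. Missing pose frames give
#' missing landmark samples.
#'
#' @param pose a `pose_sequence` for the bone.
#' @param bone the matching [bone_definition()] carrying the landmarks.
#' @param names landmark names to animate (default: all).
#' @return a [trajectory_set()] of the animated landmarks.
#' @export
animate_landmarks <- function(pose, bone, names = NULL) {
  if (is.null(bone$landmarks))
    stop(sprintf("bone '%s' has no landmarks", bone$name))
  names <- names %||% rownames(bone$landmarks)
  unknown <- setdiff(names, rownames(bone$landmarks))
  if (length(unknown) > 0)
    stop(sprintf("unknown landmark(s) on bone '%s': %s",
                 bone$name, paste(unknown, collapse = ", ")))
  ref <- bone$landmarks[names, , drop = FALSE]
  nfr <- length(pose$missing)
  arr <- array(NA_real_, c(nfr, length(names), 3))
  for (f in seq_len(nfr)) {
    if (pose$missing[f]) next
    arr[f, , ] <- sweep(ref %*% t(pose$R[, , f]), 2, pose$t[f, ], "+")
  }
  trajectory_set(arr, names, pose$frame_rate_hz)
}

#' Marker-tracking precision from intra-bone marker pairs
#'
#' Precision is the mean over pairs of the standard deviation (over frames)
#' of the distance between two markers on the same rigid bone: for a truly
#' rigid bone any variation in that distance is tracking noise.
#'
#' @param trajectories a `trajectory_set` (unfiltered coordinates).
#' @param pairs list of length-2 character vectors of marker names; each
#'   pair must lie on one rigid bone.
#' @return mean standard deviation, in the trajectory units (convert to mm
#'   externally if desired); attribute `"per_pair"` carries the per-pair
#'   values.
#' @export
tracking_precision <- function(trajectories, pairs) {
  sds <- numeric(0)
  labs <- character(0)
  for (p in pairs) {
    d <- sqrt(rowSums((marker_xyz(trajectories, p[1]) -
                         marker_xyz(trajectories, p[2]))^2))
    d <- d[is.finite(d)]
    if (length(d) < 2) {
      warning(sprintf("pair %s-%s has <2 co-visible frames; skipped",
                      p[1], p[2]))
      next
    }
    sds <- c(sds, sd(d))
    labs <- c(labs, paste(p[1], p[2], sep = "-"))
  }
  if (length(sds) == 0)
    stop("no marker pair had co-visible frames")
  structure(mean(sds), per_pair = setNames(sds, labs))
}
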