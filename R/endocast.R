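#' Definition of the dynamic mouth-cavity endocast
#'
#' The endocast is a per-frame alpha shape fitted to virtual landmarks on
#' the medial surfaces of the (left-side) cranial skeleton, the midsagittal
#' plane, and the caudal closure plane between the cleithra. Its unilateral
#' volume is doubled (assuming bilateral symmetry) to estimate total mouth
#' cavity volume.
#'
#' @param landmarks character vector of landmark/marker names (>= 4).
#' @param alpha alpha radius (circumradius threshold) in coordinate units;
#'   study value 2.
#' @param bilateral_factor multiplier from unilateral to total volume
#'   (default 2).
#' @return an object of class `endocast_definition`.
#' @export
endocast_definition <- function(landmarks, alpha = 2, bilateral_factor = 2) {
  if (length(landmarks) < 4)
    stop("an endocast needs at least 4 landmarks")
  if (alpha <= 0) stop("alpha must be positive")
  if (bilateral_factor <= 0) stop("bilateral_factor must be positive")
  structure(list(landmarks = landmarks, alpha = alpha,
                 bilateral_factor = bilateral_factor),
            class = "endocast_definition")
}

#' Alpha-shape volume of a 3D point cloud
#'
#' Computes the Delaunay tetrahedralization of the points, keeps the
#' tetrahedra whose circumsphere radius is at most `alpha` (the "alpha
#' radius" convention), and returns the summed volume of the kept
#' tetrahedra together with the boundary mesh (faces belonging to exactly
#' one kept tetrahedron, oriented outward). Tetrahedra with volume below
#' `1e-12` times the cloud's bounding-box volume are dropped as degenerate
#' before the circumradius test.
#'
#' @param points `n x 3` numeric matrix (n >= 4). Rows with `NA` are an
#'   error; filter upstream.
#' @param alpha alpha radius in the same length units as `points`. `Inf`
#'   gives the convex hull volume.
#' @return list with `volume`, `vertices` (the input points), `faces`
#'   (`m x 3` 1-based boundary triangles), and `n_tets` kept.
#' @export
alpha_shape_volume <- function(points, alpha) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (anyNA(points)) stop("points contain NA")
  if (nrow(points) < 4) {
    warning("fewer than 4 points: zero volume")
    return(list(volume = 0, vertices = points,
                faces = matrix(integer(0), 0, 3), n_tets = 0L))
  }
  if (alpha <= 0) stop("alpha must be positive")
  d <- .delaunay3d_cpp(points)
  bbox <- apply(points, 2, function(v) diff(range(v)))
  vol_floor <- 1e-12 * max(prod(bbox), 1e-300)
  ok <- d$volume > vol_floor
  if (!any(ok)) {
    warning("degenerate (coplanar?) point cloud: zero volume")
    return(list(volume = 0, vertices = points,
                faces = matrix(integer(0), 0, 3), n_tets = 0L))
  }
  keep <- ok & (d$circumradius <= alpha)
  if (!any(keep)) {
    warning("alpha too small: no tetrahedron kept, zero volume")
    return(list(volume = 0, vertices = points,
                faces = matrix(integer(0), 0, 3), n_tets = 0L))
  }
  tets <- d$tets[keep, , drop = FALSE]
  vol <- sum(d$volume[keep])
  faces <- boundary_faces(tets, points)
  list(volume = vol, vertices = points, faces = faces,
       n_tets = sum(keep))
}

# faces belonging to exactly one tet, oriented so normals point away from
# the owning tet's opposite vertex (vectorized: faces keyed by a numeric
# encoding of the sorted vertex triple)
boundary_faces <- function(tets, points) {
  tri <- rbind(tets[, c(2, 3, 4), drop = FALSE],
               tets[, c(1, 4, 3), drop = FALSE],
               tets[, c(1, 2, 4), drop = FALSE],
               tets[, c(1, 3, 2), drop = FALSE])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  lo <- pmin(tri[, 1], tri[, 2], tri[, 3])
  hi <- pmax(tri[, 1], tri[, 2], tri[, 3])
  mid <- tri[, 1] + tri[, 2] + tri[, 3] - lo - hi
  N <- as.double(nrow(points) + 1)
  key <- (lo * N + mid) * N + hi
  idx <- match(key, key)
  cnt <- tabulate(idx, nbins = length(key))
  sel <- which(cnt[idx] == 1L)
  if (length(sel) == 0) return(matrix(integer(0), 0, 3))
  tri <- tri[sel, , drop = FALSE]
  opp <- opp[sel]
  A <- points[tri[, 1], , drop = FALSE]
  e1 <- points[tri[, 2], , drop = FALSE] - A
  e2 <- points[tri[, 3], , drop = FALSE] - A
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  inward <- rowSums(nrm * (points[opp, , drop = FALSE] - A)) > 0
  flip <- tri[inward, 3]
  tri[inward, 3] <- tri[inward, 2]
  tri[inward, 2] <- flip
  tri
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dynamic endocast volume trace
#'
#' Fits the alpha shape to the endocast landmark cloud at every frame,
#' doubles the unilateral volume by the bilateral factor, and differentiates
#' the total volume by central differences (one-sided at the ends). Frames
#' where any landmark is missing, or where the alpha shape is degenerate,
#' yield `NA` and a log note.
#'
#' @param landmarks a `trajectory_set` containing the endocast landmarks
#'   (animated from bones, or tracked directly).
#' @param defn an [endocast_definition()].
#' @param mesh_dir optional directory: when given, the per-frame boundary
#'   mesh is written as `endocast_%04d.obj` for visual inspection.
#' @return a `volume_trace`: data.frame with `frame`, `time_s`,
#'   `vol_unilateral_cm3`, `vol_total_cm3`, `dVdt_cm3_s`, `dVdt_m3_s`.
#' @export
endocast_trace <- function(landmarks, defn, mesh_dir = NULL) {
  miss <- setdiff(defn$landmarks, landmarks$markers)
  if (length(miss) > 0)
    stop(sprintf("endocast landmarks absent from trajectories: %s",
                 paste(miss, collapse = ", ")))
  nfr <- n_frames(landmarks)
  uni <- rep(NA_real_, nfr)
  cloud <- landmarks$coords[, defn$landmarks, , drop = FALSE]
  for (f in seq_len(nfr)) {
    pts <- matrix(cloud[f, , ], ncol = 3)
    if (anyNA(pts)) next
    as <- withCallingHandlers(
      alpha_shape_volume(pts, defn$alpha),
      warning = function(w) {
        message(sprintf("endocast frame %d: %s", f, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    uni[f] <- as$volume
    if (!is.null(mesh_dir))
      write_endocast_obj(as$vertices, as$faces,
                         file.path(mesh_dir, sprintf("endocast_%04d.obj", f)))
  }
  tot <- uni * defn$bilateral_factor
  dV <- central_diff(tot, 1 / landmarks$frame_rate_hz)
  out <- data.frame(frame = seq_len(nfr),
                    time_s = (seq_len(nfr) - 1) / landmarks$frame_rate_hz,
                    vol_unilateral_cm3 = uni,
                    vol_total_cm3 = tot,
                    dVdt_cm3_s = dV,
                    dVdt_m3_s = dV * 1e-6)
  structure(out, alpha = defn$alpha,
            bilateral_factor = defn$bilateral_factor,
            frame_rate_hz = landmarks$frame_rate_hz,
            class = c("volume_trace", "data.frame"))
}

#' @export
print.volume_trace <- function(x, ...) {
  ok <- is.finite(x$vol_total_cm3)
  cat(sprintf("<volume_trace> %d frames (alpha = %g, x%g bilateral)\n",
              nrow(x), attr(x, "alpha"), attr(x, "bilateral_factor")))
  if (any(ok))
    cat(sprintf("  total volume %.2f-%.2f cm^3, max dV/dt %.1f cm^3/s\n",
                min(x$vol_total_cm3[ok]), max(x$vol_total_cm3[ok]),
                max(x$dVdt_cm3_s[is.finite(x$dVdt_cm3_s)])))
  invisible(x)
}
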