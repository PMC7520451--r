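#' Per-frame 3D marker trajectories
#'
#' A `trajectory_set` holds the tracked 3D coordinates of named markers at a
#' fixed frame rate: a `frames x markers x 3` array plus metadata. Missing
#' samples (markers not visible in a frame) are `NA`. Coordinates are in the
#' scene's length units, centimetres by default.
#'
#' @param coords numeric array `frames x markers x 3`, or a list of
#'   `frames x 3` matrices (one per marker).
#' @param markers character vector of marker names (defaults to the array's
#'   dimnames).
#' @param frame_rate_hz video frame rate in Hz (> 0).
#' @param units length unit label, default `"cm"`.
#' @return an object of class `trajectory_set`.
#' @export
trajectory_set <- function(coords, markers = NULL, frame_rate_hz, units = "cm") {
  if (is.list(coords)) {
    markers <- markers %||% names(coords)
    nfr <- nrow(coords[[1]])
    arr <- array(NA_real_, dim = c(nfr, length(coords), 3))
    for (i in seq_along(coords)) arr[, i, ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  markers <- markers %||% dimnames(coords)[[2]]
  if (is.null(markers))
    stop("marker names are required")
  if (length(markers) != dim(coords)[2])
    stop("length of 'markers' does not match the coordinate array")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be > 0")
  dimnames(coords) <- list(NULL, markers, c("X", "Y", "Z"))
  structure(list(coords = coords, markers = markers,
                 frame_rate_hz = frame_rate_hz, units = units),
            class = "trajectory_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d frames x %d markers @ %g Hz [%s]\n",
              n_frames(x), length(x$markers), x$frame_rate_hz, x$units))
  nm <- sum(is.na(x$coords)) / 3
  if (nm > 0) cat(sprintf("  missing samples: %g marker-frames\n", nm))
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param x a `trajectory_set`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' Frame times of a trajectory set
#' @param x a `trajectory_set`.
#' @return numeric vector of times in seconds, frame 1 at t = 0.
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1) / x$frame_rate_hz

#' Extract one marker's trajectory
#' @param x a `trajectory_set`.
#' @param marker marker name.
#' @return a `frames x 3` numeric matrix.
#' @export
marker_xyz <- function(x, marker) {
  if (!marker %in% x$markers)
    stop(sprintf("unknown marker '%s'", marker))
  m <- x$coords[, marker, , drop = FALSE]
  dim(m) <- c(dim(x$coords)[1], 3)
  colnames(m) <- c("X", "Y", "Z")
  m
}

#' Read marker trajectories from a 3D-points CSV
#'
#' Reads the marker-tracking CSV dialect with one `<name>_X,<name>_Y,<name>_Z`
#' column triple per marker and one row per frame. Empty cells become `NA`
#' (missing samples).
#'
#' @param path CSV file path.
#' @param frame_rate_hz video frame rate in Hz.
#' @param units length unit label, default `"cm"`.
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(path, frame_rate_hz, units = "cm") {
  df <- read.csv(path, check.names = FALSE)
  cn <- names(df)
  suf <- sub(".*_([XYZ])$", "\\1", cn)
  base <- sub("_[XYZ]$", "", cn)
  bad <- !grepl("_[XYZ]$", cn)
  if (any(bad))
    stop(sprintf("column '%s' does not match the <marker>_X/_Y/_Z pattern",
                 cn[which(bad)[1]]))
  markers <- unique(base)
  for (m in markers) {
    have <- sort(suf[base == m])
    if (!identical(have, c("X", "Y", "Z")))
      stop(sprintf("marker '%s' is missing one of its X/Y/Z columns", m))
  }
  nfr <- nrow(df)
  arr <- array(NA_real_, dim = c(nfr, length(markers), 3))
  for (i in seq_along(markers)) {
    for (k in 1:3) {
      col <- paste0(markers[i], "_", c("X", "Y", "Z")[k])
      v <- df[[col]]
      if (is.character(v)) {
        v[v == ""] <- NA
        vn <- suppressWarnings(as.numeric(v))
        if (any(!is.na(v) & is.na(vn)))
          stop(sprintf("non-numeric value in column '%s' at row %d",
                       col, which(!is.na(v) & is.na(vn))[1]))
        v <- vn
      }
      arr[, i, k] <- v
    }
  }
  trajectory_set(arr, markers, frame_rate_hz, units)
}

#' Write marker trajectories to a 3D-points CSV
#'
#' Inverse of [read_trajectories()]; `NA` samples are written as empty cells.
#'
#' @param x a `trajectory_set`.
#' @param path output CSV path.
#' @export
write_trajectories <- function(x, path) {
  out <- list()
  for (m in x$markers) {
    xyz <- marker_xyz(x, m)
    out[[paste0(m, "_X")]] <- xyz[, 1]
    out[[paste0(m, "_Y")]] <- xyz[, 2]
    out[[paste0(m, "_Z")]] <- xyz[, 3]
  }
  df <- as.data.frame(out, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an intra-oral pressure trace
#'
#' Reads a two-column CSV (`time_s,value`) and converts millivolts to
#' pascals with the probe calibration. Sampling must be uniform: a deviation
#' of more than 1% from `rate_hz` raises a warning.
#'
#' @param path CSV file path.
#' @param calibration_pa_per_mv probe calibration (Pa per mV). Ignored when
#'   `units = "Pa"`.
#' @param units `"mV"` (default, converted) or `"Pa"` (passed through).
#' @param rate_hz expected sample rate; `NULL` skips the uniformity check.
#' @return data.frame with columns `time_s` and `pressure_pa`.
#' @export
read_pressure <- function(path, calibration_pa_per_mv = 1,
                          units = c("mV", "Pa"), rate_hz = NULL) {
  units <- match.arg(units)
  df <- read.csv(path)
  if (ncol(df) < 2)
    stop("pressure CSV must have two columns: time_s,value")
  t <- as.numeric(df[[1]])
  v <- as.numeric(df[[2]])
  if (any(diff(t) <= 0))
    stop("pressure time column is not strictly increasing")
  if (!is.null(rate_hz)) {
    dt <- diff(t)
    if (any(abs(dt - 1 / rate_hz) > 0.01 / rate_hz))
      warning(sprintf("pressure sampling deviates >1%% from %g Hz", rate_hz))
  }
  p <- if (units == "mV") v * calibration_pa_per_mv else v
  data.frame(time_s = t, pressure_pa = p)
}

#' Write a mesh as a Wavefront OBJ file
#'
#' Writes `v` records for the vertices and `f` records (1-based indices) for
#' the triangular faces, e.g. one frame of the endocast boundary mesh.
#'
#' @param vertices `n x 3` numeric matrix.
#' @param faces `m x 3` integer matrix of 1-based vertex indices (may have
#'   zero rows).
#' @param path output file path.
#' @export
write_endocast_obj <- function(vertices, faces, path) {
  if (is.null(vertices) || nrow(vertices) == 0) {
    warning("empty mesh: writing header-only OBJ")
    writeLines("# empty alpha-shape mesh", path)
    return(invisible(path))
  }
  stopifnot(ncol(vertices) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  if (!is.null(faces) && nrow(faces) > 0) {
    if (any(faces < 1)) stop("OBJ face indices must be 1-based")
    writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  }
  invisible(path)
}

#' Read vertices and faces back from a Wavefront OBJ file
#'
#' Minimal reader for round-trip checks of [write_endocast_obj()].
#'
#' @param path OBJ file path.
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  parse3 <- function(lines, mode) {
    if (length(lines) == 0)
      return(matrix(if (mode == "num") numeric(0) else integer(0), 0, 3))
    m <- do.call(rbind, lapply(strsplit(trimws(sub("^[vf] ", "", lines)),
                                        "\\s+"), function(s) s[1:3]))
    if (mode == "num") matrix(as.numeric(m), ncol = 3)
    else matrix(as.integer(sub("/.*", "", m)), ncol = 3)
  }
  list(vertices = parse3(vl, "num"), faces = parse3(fl, "int"))
}

#' Export a pose sequence as row-major homogeneous transforms
#'
#' Writes one row per frame with 16 values: the 4x4 homogeneous rigid
#' transform in row-major order (missing frames are empty cells).
#'
#' @param pose a `pose_sequence`.
#' @param path output CSV path.
#' @export
write_pose_csv <- function(pose, path) {
  nfr <- length(pose$missing)
  M <- matrix(NA_real_, nfr, 16)
  for (f in seq_len(nfr)) {
    if (pose$missing[f]) next
    H <- diag(4)
    H[1:3, 1:3] <- pose$R[, , f]
    H[1:3, 4] <- pose$t[f, ]
    M[f, ] <- as.vector(t(H))
  }
  colnames(M) <- paste0("m", rep(1:4, each = 4), rep(1:4, 4))
  write.csv(as.data.frame(M), path, row.names = FALSE, na = "")
  invisible(path)
}
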