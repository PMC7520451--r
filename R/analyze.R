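#' Merge trajectory sets sharing a frame grid
#'
#' Column-binds the markers of several `trajectory_set`s (e.g. tracked
#' markers plus bone-animated landmarks) into one set.
#'
#' @param ... `trajectory_set`s with equal frame counts and rates.
#' @return a combined `trajectory_set`.
#' @export
merge_trajectories <- function(...) {
  sets <- list(...)
  nfr <- n_frames(sets[[1]])
  fr <- sets[[1]]$frame_rate_hz
  for (s in sets)
    if (n_frames(s) != nfr || s$frame_rate_hz != fr)
      stop("trajectory sets do not share a frame grid")
  markers <- unlist(lapply(sets, function(s) s$markers))
  if (anyDuplicated(markers))
    stop("duplicate marker names across sets")
  arr <- array(NA_real_, c(nfr, length(markers), 3))
  i <- 0
  for (s in sets) {
    arr[, i + seq_along(s$markers), ] <- s$coords
    i <- i + length(s$markers)
  }
  trajectory_set(arr, markers, fr, sets[[1]]$units)
}

#' Run the full strike-analysis pipeline
#'
#' From marker trajectories, bone reference geometry, a study configuration
#' and a raw pressure trace to a complete per-strike result:
#' \enumerate{
#'   \item fit per-frame rigid transforms for every bone and for the body
#'     plane, then low-pass filter the pose sequences (quaternion +
#'     translation);
#'   \item low-pass filter marker coordinates (for muscle-length and
#'     endocast computations);
#'   \item animate bone-attached virtual landmarks; compute the gape trace
#'     and the time of peak gape (the t = 0 reference) and the pre-strike
#'     baseline window;
#'   \item decompose relative bone motion in each configured joint
#'     coordinate system (z-y-x order) and re-zero to the baseline;
#'   \item measure subregion/whole-region lengths of each muscle marker
#'     chain and the three-fiber lengths of each cranial muscle; convert to
#'     strain and strain rate via the baseline mean initial length;
#'   \item fit the dynamic endocast (alpha shape) per frame, double it
#'     (bilateral symmetry), differentiate to dV/dt;
#'   \item filter + re-zero the pressure, resample it onto frame times, and
#'     form instantaneous expansion power, its peak, the peak-power window
#'     (within 25% of maximum), and mass-/volume-normalized peak powers.
#' }
#'
#' @param x a `strike_bundle`, or a `trajectory_set` (then supply `bones`,
#'   `config`, `pressure`).
#' @param bones named list of [bone_definition()]s (one entry per config
#'   bone, including the body plane).
#' @param config a [study_config()].
#' @param pressure data.frame `time_s,value` (mV by default; converted with
#'   the config calibration).
#' @param filter_kinematics logical; `FALSE` skips marker/pose filtering
#'   (useful to isolate the geometric chain on noiseless data).
#' @param filter_pressure logical; `FALSE` skips the pressure filter.
#' @param mesh_dir optional directory for per-frame endocast OBJ meshes.
#' @return a `strike_result` (list; see Details) with a `summary` element
#'   of per-strike scalars.
#' @export
analyze_strike <- function(x, bones = NULL, config = NULL, pressure = NULL,
                           filter_kinematics = TRUE, filter_pressure = TRUE,
                           mesh_dir = NULL) {
  if (inherits(x, "strike_bundle")) {
    bones <- x$bones; config <- x$config; pressure <- x$pressure
    trajectories <- x$trajectories
  } else {
    trajectories <- x
  }
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(config, "study_config"))
  fr <- trajectories$frame_rate_hz
  cut_kin <- config$filters$cutoff_kinematics_hz

  # poses from raw markers, then filtered as rigid motions
  poses <- list()
  for (b in names(config$bones)) {
    if (!b %in% names(bones))
      stop(sprintf("no bone definition for '%s'", b))
    p <- fit_pose_sequence(trajectories, bones[[b]])
    poses[[b]] <- if (filter_kinematics) filter_poses(p, cut_kin) else p
  }

  # marker coordinates filtered for length/volume work
  traj_f <- if (filter_kinematics)
    filter_trajectories(trajectories, cut_kin) else trajectories

  # animated landmarks from all bones that have any
  lm_sets <- list()
  for (b in names(poses))
    if (!is.null(bones[[b]]$landmarks))
      lm_sets[[b]] <- animate_landmarks(poses[[b]], bones[[b]])
  landmarks <- if (length(lm_sets) > 0) do.call(merge_trajectories, lm_sets)
               else NULL
  scene <- if (is.null(landmarks)) traj_f
           else merge_trajectories(traj_f, landmarks)

  # gape, peak gape, baseline window
  gape <- peak <- baseline <- NULL
  if (!is.null(config$gape)) {
    gape <- gape_trace(marker_xyz(scene, config$gape$upper),
                       marker_xyz(scene, config$gape$lower))
    peak <- find_peak_gape(gape, fr)
    baseline <- baseline_window_frames(
      peak$frame, fr,
      config$baseline_window_s$width_s,
      config$baseline_window_s$end_before_s)
  } else {
    baseline <- seq_len(max(1, round(0.1 * fr)))
    peak <- list(frame = NA_integer_, time_s = NA_real_)
  }

  # joint coordinate systems
  kinematics <- list()
  for (j in names(config$jcs_defs)) {
    jd <- config$jcs_defs[[j]]
    axes <- if (is.null(jd$axes)) diag(3) else matrix(unlist(jd$axes), 3, 3)
    jcs <- joint_cs(j,
                    anatomical_cs(jd$proximal, unlist(jd$origin), axes),
                    anatomical_cs(jd$distal, unlist(jd$origin), axes))
    tr <- jcs_decompose(poses[[jd$distal]], poses[[jd$proximal]], jcs)
    kinematics[[j]] <- rezero_trace(tr, baseline)
  }

  # muscles: chains (fluoromicrometry) and fiber sets (animated bones)
  muscles <- list()
  for (m in names(config$muscles$chains)) {
    reg <- muscle_region(m, config$muscles$chains[[m]],
                         config$masses[[m]] %||% NULL)
    L <- region_lengths(scene, reg)
    muscles[[m]] <- lapply(colnames(L), function(col) {
      Li <- mean_initial_length(list(L[, col]), baseline)
      strain_and_rate(L[, col], Li, fr, name = col)
    })
    names(muscles[[m]]) <- colnames(L)
  }
  fibers <- list()
  for (m in names(config$muscles$fibers)) {
    fs <- fiber_set(m, config$muscles$fibers[[m]]$origins,
                    config$muscles$fibers[[m]]$insertions)
    L <- fiber_muscle_length(fs, scene)
    Li <- mean_initial_length(list(L), baseline)
    fibers[[m]] <- strain_and_rate(L, Li, fr, name = m)
  }

  # dynamic endocast
  volume <- NULL
  if (!is.null(config$endocast)) {
    defn <- endocast_definition(config$endocast$landmarks,
                                config$endocast$alpha,
                                config$endocast$bilateral_factor %||% 2)
    volume <- endocast_trace(scene, defn, mesh_dir = mesh_dir)
  }

  # pressure and expansion power
  ft <- frame_times(trajectories)
  power <- mask <- NULL
  pressure_pa_frames <- NULL
  if (!is.null(pressure) && !is.null(volume)) {
    praw <- data.frame(
      time_s = pressure$time_s,
      pressure_pa = pressure[[2]] * config$pressure_calibration_pa_per_mv)
    baseline_t <- range(ft[baseline])
    ptr <- if (filter_pressure)
      process_pressure(praw, config$filters$cutoff_pressure_hz, baseline_t)
    else {
      p0 <- praw
      p0$pressure_pa <- p0$pressure_pa -
        mean(p0$pressure_pa[p0$time_s >= baseline_t[1] &
                            p0$time_s <= baseline_t[2]])
      p0
    }
    pressure_pa_frames <- synchronize(ptr, ft)
    power <- instantaneous_power(pressure_pa_frames, volume$dVdt_m3_s)
    mask <- peak_power_mask(power$power_w)
  }

  res <- structure(list(
    poses = poses, landmarks = landmarks, gape = gape,
    peak_gape = peak, baseline_frames = baseline,
    kinematics = kinematics, muscles = muscles, fibers = fibers,
    volume = volume, pressure_pa = pressure_pa_frames,
    power = power, mask = mask,
    frame_rate_hz = fr, time_s = ft, config = config),
    class = "strike_result")
  res$summary <- summarize_strike(res)
  res
}

#' Per-strike summary scalars
#'
#' Collects the scalars reported per strike: peak sub-ambient pressure,
#' maximum total mouth volume, maximum rate of volume change, maximum
#' expansion power, mass- and volume-normalized peak power, peak z-axis
#' rotation of each joint during the peak-power window, and peak strain and
#' shortening velocity of each muscle during the peak-power window.
#'
#' @param res a `strike_result`.
#' @return named list of scalars.
#' @export
summarize_strike <- function(res) {
  s <- list(t_peak_gape_s = res$peak_gape$time_s)
  msk <- if (!is.null(res$mask)) res$mask$mask
         else rep(TRUE, length(res$time_s))
  if (!is.null(res$pressure_pa))
    s$peak_subambient_pressure_pa <- min(res$pressure_pa, na.rm = TRUE)
  if (!is.null(res$volume)) {
    v <- res$volume
    s$max_volume_cm3 <- max(v$vol_total_cm3, na.rm = TRUE)
    s$max_dVdt_cm3_s <- max(v$dVdt_cm3_s, na.rm = TRUE)
    s$delta_volume_cm3 <- s$max_volume_cm3 -
      mean(v$vol_total_cm3[res$baseline_frames], na.rm = TRUE)
  }
  if (!is.null(res$power)) {
    s$max_power_w <- res$power$max_power_w
    s$t_peak_power_s <- res$time_s[res$power$peak_frame]
    div <- c()
    mass <- res$config$masses
    if (!is.null(mass$hypaxial)) div <- c(div, hypaxial_kg = mass$hypaxial)
    if (!is.null(mass$cranial_total)) div <- c(div, cranial_kg = mass$cranial_total)
    if (!is.null(mass$body)) div <- c(div, body_kg = mass$body)
    if (!is.null(s$delta_volume_cm3) && s$delta_volume_cm3 > 0)
      div <- c(div, dvol_cm3 = s$delta_volume_cm3)
    if (length(div) > 0)
      s <- c(s, as.list(normalize_power(s$max_power_w, div)))
  }
  for (j in names(res$kinematics)) {
    rz <- res$kinematics[[j]]$rz_deg
    s[[paste0("peak_rz_", j, "_deg")]] <-
      peak_during_window(rz, msk, "absmax")
  }
  for (m in names(res$muscles)) {
    whole <- res$muscles[[m]][[paste0(m, "_whole")]]
    s[[paste0("peak_strain_", m, "_pct")]] <-
      peak_during_window(whole$strain_pct, msk, "max")
    s[[paste0("peak_rate_", m, "_Li_s")]] <-
      peak_during_window(whole$rate_Li_per_s, msk, "max")
  }
  for (m in names(res$fibers)) {
    s[[paste0("peak_strain_", m, "_fiber_pct")]] <-
      peak_during_window(res$fibers[[m]]$strain_pct, msk, "max")
  }
  s
}

#' @export
print.strike_result <- function(x, ...) {
  cat(sprintf("<strike_result> %d frames @ %g Hz; peak gape at t = %.3f s\n",
              length(x$time_s), x$frame_rate_hz, x$peak_gape$time_s))
  s <- x$summary
  if (!is.null(s$max_power_w))
    cat(sprintf("  peak power %.3f W at t = %.3f s; peak pressure %.0f Pa; max volume %.1f cm^3\n",
                s$max_power_w, s$t_peak_power_s,
                s$peak_subambient_pressure_pa, s$max_volume_cm3))
  for (j in names(x$kinematics))
    cat(sprintf("  %s: peak rz %.2f deg during peak power\n",
                j, s[[paste0("peak_rz_", j, "_deg")]]))
  invisible(x)
}

#' @export
summary.strike_result <- function(object, ...) {
  df <- data.frame(variable = names(object$summary),
                   value = unlist(object$summary), row.names = NULL)
  df
}

#' Write strike-result CSV exports
#'
#' Writes the per-joint kinematic traces, per-muscle strain traces, the
#' volume trace, the synchronized power trace, and a one-row summary CSV
#' into a directory.
#'
#' @param res a `strike_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_strike_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in names(res$kinematics))
    write_kinematic_csv(res$kinematics[[j]],
                        file.path(dir, sprintf("kinematics_%s.csv", j)))
  for (m in names(res$muscles)) {
    whole <- res$muscles[[m]][[paste0(m, "_whole")]]
    write.csv(as.data.frame(whole),
              file.path(dir, sprintf("strain_%s.csv", m)), row.names = FALSE)
  }
  if (!is.null(res$volume))
    write.csv(as.data.frame(res$volume), file.path(dir, "volume.csv"),
              row.names = FALSE)
  if (!is.null(res$power)) {
    pw <- data.frame(frame = seq_along(res$time_s), time_s = res$time_s,
                     pressure_Pa = res$pressure_pa,
                     vol_m3 = res$volume$vol_total_cm3 * 1e-6,
                     dVdt_m3s = res$volume$dVdt_m3_s,
                     power_W = res$power$power_w,
                     in_peak_mask = res$mask$mask)
    write.csv(pw, file.path(dir, "power.csv"), row.names = FALSE)
  }
  su <- res$summary
  write.csv(as.data.frame(su[!vapply(su, is.null, TRUE)]),
            file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}
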