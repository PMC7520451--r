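# Synthetic suction strike with analytically known ground truth.
#
# The generator builds a simplified catfish-like scene in cm units: a static
# body plane (6 trunk markers), a neurocranium that elevates dorsally about
# the craniovertebral joint, a cleithrum that retracts caudoventrally about
# the cleithrum/post-temporal joint, a lower jaw that depresses to open the
# gape, intramuscular marker chains whose subregion lengths follow
# prescribed strain pulses, an endocast landmark cloud (half-ellipsoid
# shell + midsagittal wall) whose total volume follows an analytic V(t),
# and a pressure trace constructed so that peak expansion power equals a
# prescribed target exactly. Gaussian tracking noise (default 0.08 mm, the
# precision scale of marker-based X-ray tracking) is added to every marker
# coordinate.

#' Smooth raised-cosine pulse
#'
#' `0.5 * (1 - cos(2*pi*(t - t0)/dur))` inside `[t0, t0 + dur]`, 0 outside:
#' a C1 pulse rising from 0 to 1 (at `t0 + dur/2`) and back.
#'
#' @param t time vector (s).
#' @param t0 pulse onset (s).
#' @param dur pulse duration (s).
#' @return pulse values in `[0, 1]`.
#' @export
cosine_pulse <- function(t, t0, dur) {
  ifelse(t >= t0 & t <= t0 + dur,
         0.5 * (1 - cos(2 * pi * (t - t0) / dur)), 0)
}

# analytic time derivative of cosine_pulse
cosine_pulse_deriv <- function(t, t0, dur) {
  ifelse(t >= t0 & t <= t0 + dur,
         (pi / dur) * sin(2 * pi * (t - t0) / dur), 0)
}

#' Ground-truth parameters of a synthetic strike
#'
#' Default magnitudes mirror the scales reported for channel catfish
#' suction feeding: pectoral girdle retraction of several degrees (6-11),
#' small cranial elevation (< 5 deg), hypaxial subregion strains of a few
#' percent (4-8%), near-isometric epaxial muscles, tens of cm^3 of mouth
#' volume, kilopascal-scale sub-ambient pressure, and strike duration under
#' a second.
#'
#' @param duration_s recording length (s).
#' @param frame_rate_hz video frame rate.
#' @param pressure_rate_hz pressure sample rate.
#' @param t_peak_gape_s prescribed time of peak gape.
#' @param elevation_deg neurocranium elevation pulse amplitude (deg,
#'   positive = dorsal).
#' @param retraction_deg cleithrum retraction pulse amplitude (deg,
#'   magnitude; applied as negative z-rotation).
#' @param jaw_depression_deg lower-jaw depression amplitude (deg).
#' @param hypaxial_strain_pct peak strain of each hypaxial subregion
#'   (percent, positive = shortening; one value per subregion).
#' @param epaxial_strain_pct peak strain of each epaxial subregion.
#' @param expansion_frac fractional mouth-volume increase at peak.
#' @param target_peak_power_w prescribed peak expansion power (W).
#' @param noise_sd_mm isotropic marker noise s.d. (mm); 0 disables noise.
#' @param pressure_noise_frac pressure noise s.d. as a fraction of the
#'   pulse amplitude (added before filtering).
#' @param ambient_pa constant ambient offset added to the raw pressure.
#' @return an object of class `synthetic_truth` (a parameter list).
#' @export
synthetic_truth <- function(duration_s = 0.8,
                            frame_rate_hz = 300,
                            pressure_rate_hz = 1000,
                            t_peak_gape_s = 0.45,
                            elevation_deg = 5,
                            retraction_deg = 8,
                            jaw_depression_deg = 18,
                            hypaxial_strain_pct = c(4, 8, 6, 3),
                            epaxial_strain_pct = c(0, 0, 0),
                            expansion_frac = 0.8,
                            target_peak_power_w = 5,
                            noise_sd_mm = 0.08,
                            pressure_noise_frac = 0.01,
                            ambient_pa = 250) {
  stopifnot(duration_s > 0, frame_rate_hz > 0, pressure_rate_hz > 0,
            noise_sd_mm >= 0)
  if (any(abs(hypaxial_strain_pct) >= 100) || any(abs(epaxial_strain_pct) >= 100))
    stop("strains must be below 100%")
  if (expansion_frac <= -1)
    stop("expansion_frac would give negative volume")
  pulse_dur <- 0.30
  structure(list(
    duration_s = duration_s, frame_rate_hz = frame_rate_hz,
    pressure_rate_hz = pressure_rate_hz, t_peak_gape_s = t_peak_gape_s,
    elevation_deg = elevation_deg, retraction_deg = retraction_deg,
    jaw_depression_deg = jaw_depression_deg,
    hypaxial_strain_pct = hypaxial_strain_pct,
    epaxial_strain_pct = epaxial_strain_pct,
    expansion_frac = expansion_frac,
    target_peak_power_w = target_peak_power_w,
    noise_sd_mm = noise_sd_mm,
    pressure_noise_frac = pressure_noise_frac,
    ambient_pa = ambient_pa,
    # pulse timing (s): jaw and elevation peak at t_peak_gape; retraction
    # and strain peak slightly later; volume expansion peaks just before,
    # so peak dV/dt (and peak power) precedes peak gape as in vivo
    windows = list(
      jaw = c(t_peak_gape_s - pulse_dur / 2, pulse_dur),
      elevation = c(t_peak_gape_s - pulse_dur / 2, pulse_dur),
      retraction = c(t_peak_gape_s - pulse_dur / 2 + 0.02, pulse_dur),
      strain = c(t_peak_gape_s - pulse_dur / 2 + 0.02, pulse_dur),
      volume = c(t_peak_gape_s - 0.14, 0.26))),
    class = "synthetic_truth")
}

#' Build the synthetic skeleton
#'
#' Bone definitions for the synthetic scene: a 6-marker body plane, a
#' 5-marker neurocranium (with snout-tip, craniovertebral-joint and
#' sternohyoideus-insertion landmarks), a 4-marker lower jaw (jaw-tip
#' landmark), and a 4-marker cleithrum (joint and sternohyoideus-origin
#' landmarks). Also returns the endocast geometry (half-ellipsoid landmark
#' cloud, left side) and the rest positions of the axial marker chains.
#' All coordinates in cm; +x rostral, +y dorsal, +z to the animal's right.
#'
#' @param n_shell number of points on the lateral endocast shell.
#' @param noise_sd_cm marker noise s.d. (cm), only used to verify marker
#'   spreads comfortably exceed the noise scale.
#' @return list with `bones` (named list of [bone_definition()]),
#'   `endocast` (list: `center`, `semiaxes`, `points` n x 3 rest cloud,
#'   `names`), `chains` (rest geometry of hypaxial/epaxial chains), and
#'   `joints` (reference-space JCS origins).
#' @export
make_skeleton <- function(n_shell = 200, noise_sd_cm = 0.008) {
  neuro_mk <- rbind(
    neuro_m1 = c(2.2, 1.0, -1.2),
    neuro_m2 = c(4.0, 2.4, 0.8),
    neuro_m3 = c(6.0, 0.6, -0.9),
    neuro_m4 = c(7.6, 1.8, 1.1),
    neuro_m5 = c(3.2, 0.2, 1.3))
  neuro_lm <- rbind(
    lm_snout_tip = c(9.0, 1.2, 0.0),
    lm_cv_joint = c(1.5, 1.5, 0.0),
    lm_sh_ins_1 = c(5.2, -0.8, -0.3),
    lm_sh_ins_2 = c(5.4, -0.9, 0.0),
    lm_sh_ins_3 = c(5.2, -0.8, 0.3))
  jaw_mk <- rbind(
    jaw_m1 = c(6.2, -0.3, -0.6),
    jaw_m2 = c(7.5, 0.2, 0.5),
    jaw_m3 = c(8.3, -0.4, -0.2),
    jaw_m4 = c(6.8, 0.5, 0.4))
  jaw_lm <- rbind(
    lm_jaw_tip = c(9.0, 0.2, 0.0),
    lm_jaw_joint = c(6.0, 0.2, 0.0))
  clei_mk <- rbind(
    clei_m1 = c(0.5, -2.5, -0.5),
    clei_m2 = c(1.5, -1.0, -0.8),
    clei_m3 = c(0.8, -0.2, 0.6),
    clei_m4 = c(2.0, -2.0, 0.7))
  clei_lm <- rbind(
    lm_clpt_joint = c(1.8, 0.3, 0.0),
    lm_sh_ori_1 = c(1.2, -1.6, -0.3),
    lm_sh_ori_2 = c(1.4, -1.7, 0.0),
    lm_sh_ori_3 = c(1.2, -1.6, 0.3))
  body_mk <- rbind(
    body_m1 = c(-3.0, 2.0, -1.0),
    body_m2 = c(-5.0, 1.2, 1.0),
    body_m3 = c(-7.0, 2.3, -0.8),
    body_m4 = c(-9.0, 1.5, 0.9),
    body_m5 = c(-4.0, 0.8, 0.3),
    body_m6 = c(-8.0, 0.7, -1.1))
  for (mk in list(neuro_mk, jaw_mk, clei_mk, body_mk)) {
    spread <- min(svd(scale(mk, scale = FALSE))$d[1:2])
    if (spread < 10 * noise_sd_cm)
      stop("marker spread too small relative to tracking noise")
  }
  bones <- list(
    neurocranium = bone_definition("neurocranium", neuro_mk, neuro_lm),
    lowerjaw = bone_definition("lowerjaw", jaw_mk, jaw_lm),
    cleithrum = bone_definition("cleithrum", clei_mk, clei_lm),
    bodyplane = bone_definition("bodyplane", body_mk))

  # endocast: left (z <= 0) half-ellipsoid shell + midsagittal wall +
  # half-depth inner shell, so no interior Delaunay tetrahedron has a
  # circumradius near the alpha radius
  center <- c(4.5, 0.3, 0)
  semi <- c(a = 3.2, b = 1.4, c = 1.6)
  shell <- fibonacci_hemisphere(n_shell)
  inner <- 0.55 * fibonacci_hemisphere(round(n_shell / 4))
  wall <- midsagittal_wall()
  unit_pts <- rbind(shell, inner, wall)
  pts <- sweep(unit_pts %*% diag(semi), 2, center, "+")
  rownames(pts) <- sprintf("endo_%03d", seq_len(nrow(pts)))
  chains <- list(
    hypaxial = list(p0 = c(0.2, -2.3, -0.4),
                    u = normalize3(c(-1, -0.03, 0.05)),
                    L0 = c(2.2, 2.0, 2.4, 2.1),
                    markers = paste0("hyp_m", 1:5)),
    epaxial = list(p0 = c(0.0, 2.2, 0.3),
                   u = normalize3(c(-1, 0.02, -0.03)),
                   L0 = c(2.3, 2.2, 2.5),
                   markers = paste0("epx_m", 1:4)))
  joints <- list(neuro_body = c(1.5, 1.5, 0), cleithrum_body = c(1.8, 0.3, 0))
  list(bones = bones,
       endocast = list(center = center, semiaxes = semi, points = pts,
                       names = rownames(pts)),
       chains = chains, joints = joints)
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# roughly uniform points on the z <= 0 unit hemisphere (Fibonacci spiral)
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- -i / n                       # z in (-1, 0)
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# polar grid over the unit disk in the z = 0 midsagittal plane
midsagittal_wall <- function() {
  pts <- rbind(c(0, 0, 0))
  for (r in c(0.35, 0.65, 0.92)) {
    k <- round(14 * r) + 4
    th <- seq(0, 2 * pi, length.out = k + 1)[-1]
    pts <- rbind(pts, cbind(r * cos(th), r * sin(th), 0))
  }
  pts
}

# pose rotating by `deg` about the world z-axis through point `o`
rotation_about_z <- function(deg, o) {
  R <- rot_z(deg)
  list(R = R, t = o - as.vector(R %*% o))
}

#' Pressure trace consistent with a target peak power
#'
#' Inverts the expansion-power product: given the analytic rate of volume
#' change, builds `p(t) = -P* . max(dVdt, 0) / max(dVdt)^2` so that the
#' instantaneous power `(-p) * dVdt` equals `P* . (dVdt+/max)^2`, which
#' peaks at exactly the target power where dV/dt is maximal, and is zero
#' while the mouth is not expanding (no supra-ambient phase).
#'
#' @param dVdt_m3s analytic rate of total volume change (m^3/s) on the
#'   pressure time grid.
#' @param target_peak_power_w prescribed peak power (W); 0 gives p == 0.
#' @return pressure series (Pa, <= 0).
#' @export
power_consistent_pressure <- function(dVdt_m3s, target_peak_power_w) {
  mx <- max(dVdt_m3s)
  if (mx <= 0)
    stop("dV/dt is never positive; cannot place an expansion power pulse")
  if (target_peak_power_w == 0) return(rep(0, length(dVdt_m3s)))
  -target_peak_power_w * pmax(dVdt_m3s, 0) / mx^2
}

#' Generate a complete synthetic strike bundle
#'
#' Composes bone poses from the prescribed joint-angle pulses, places
#' muscle-chain markers so each subregion length follows
#' `L0 * (1 - strain(t)/100)`, scales the endocast cloud so total volume
#' follows the analytic V(t), samples the power-consistent pressure at the
#' pressure rate, and adds seeded Gaussian noise to every marker
#' coordinate. With `noise_sd_mm = 0` the bundle is exactly consistent
#' with the returned truth.
#'
#' @param truth a [synthetic_truth()].
#' @param skeleton a [make_skeleton()] result.
#' @param seed RNG seed; the same seed reproduces the bundle bit for bit.
#' @return a `strike_bundle`: list with `trajectories` ([trajectory_set()]
#'   of all markers incl. the endocast cloud), `bones`, `config`
#'   ([study_config()]), `pressure` (data.frame `time_s,value` in mV), and
#'   `truth` (parameters plus noiseless reference series).
#' @export
simulate_strike <- function(truth = synthetic_truth(),
                            skeleton = make_skeleton(),
                            seed = 1) {
  set.seed(seed)
  fr <- truth$frame_rate_hz
  t <- seq(0, truth$duration_s, by = 1 / fr)
  nfr <- length(t)
  w <- truth$windows

  elev <- truth$elevation_deg * cosine_pulse(t, w$elevation[1], w$elevation[2])
  retr <- -truth$retraction_deg * cosine_pulse(t, w$retraction[1], w$retraction[2])
  jawd <- -truth$jaw_depression_deg * cosine_pulse(t, w$jaw[1], w$jaw[2])
  strain_pulse <- cosine_pulse(t, w$strain[1], w$strain[2])

  bones <- skeleton$bones
  poses <- list(
    bodyplane = lapply(t, function(.) list(R = diag(3), t = c(0, 0, 0))),
    neurocranium = lapply(elev, rotation_about_z, o = skeleton$joints$neuro_body),
    cleithrum = lapply(retr, rotation_about_z, o = skeleton$joints$cleithrum_body),
    lowerjaw = lapply(jawd, rotation_about_z,
                      o = bones$lowerjaw$landmarks["lm_jaw_joint", ]))

  world_point <- function(bone, p, f) {
    ps <- poses[[bone]][[f]]
    as.vector(ps$R %*% p) + ps$t
  }

  markers <- character(0)
  clean <- list()
  for (b in names(bones)) {
    ref <- bones[[b]]$markers
    for (m in rownames(ref)) {
      clean[[m]] <- t(vapply(seq_len(nfr),
                             function(f) world_point(b, ref[m, ], f),
                             numeric(3)))
      markers <- c(markers, m)
    }
  }

  # axial chains: straight lines with prescribed subregion lengths
  for (ch_name in names(skeleton$chains)) {
    ch <- skeleton$chains[[ch_name]]
    s_pct <- if (ch_name == "hypaxial") truth$hypaxial_strain_pct
             else truth$epaxial_strain_pct
    stopifnot(length(s_pct) == length(ch$L0))
    for (k in seq_along(ch$markers)) {
      cum <- if (k == 1) rep(0, nfr)
             else Reduce(`+`, lapply(seq_len(k - 1), function(j)
               ch$L0[j] * (1 - s_pct[j] * strain_pulse / 100)))
      clean[[ch$markers[k]]] <- cbind(ch$p0[1] + ch$u[1] * cum,
                                      ch$p0[2] + ch$u[2] * cum,
                                      ch$p0[3] + ch$u[3] * cum)
      markers <- c(markers, ch$markers[k])
    }
  }

  # sternohyoideus intramuscular pair rides on the fiber-1 attachment
  # landmarks, so fluoromicrometry and the bone-animated fiber path measure
  # the same length (the cross-validation the method relies on)
  sh_ori <- t(vapply(seq_len(nfr), function(f)
    world_point("cleithrum", bones$cleithrum$landmarks["lm_sh_ori_1", ], f),
    numeric(3)))
  sh_ins <- t(vapply(seq_len(nfr), function(f)
    world_point("neurocranium", bones$neurocranium$landmarks["lm_sh_ins_1", ], f),
    numeric(3)))
  clean[["sh_m1"]] <- sh_ori
  clean[["sh_m2"]] <- sh_ins
  markers <- c(markers, "sh_m1", "sh_m2")

  # endocast cloud: scale y and z about the center so volume tracks f(t)
  fvol <- 1 + truth$expansion_frac * cosine_pulse(t, w$volume[1], w$volume[2])
  svol <- sqrt(fvol)
  ec <- skeleton$endocast
  rel <- sweep(ec$points, 2, ec$center)
  for (i in seq_len(nrow(ec$points))) {
    nm <- ec$names[i]
    clean[[nm]] <- cbind(ec$center[1] + rel[i, 1],
                         ec$center[2] + rel[i, 2] * svol,
                         ec$center[3] + rel[i, 3] * svol)
    markers <- c(markers, nm)
  }

  arr <- array(NA_real_, c(nfr, length(markers), 3))
  sd_cm <- truth$noise_sd_mm / 10
  for (i in seq_along(markers)) {
    m <- clean[[markers[i]]]
    if (sd_cm > 0) m <- m + matrix(stats::rnorm(length(m), 0, sd_cm), nrow(m))
    arr[, i, ] <- m
  }
  trajectories <- trajectory_set(arr, markers, fr)

  # analytic volume and the power-consistent pressure at 1000 Hz
  V0_total <- 2 * (2 / 3) * pi * prod(ec$semiaxes)   # cm^3, doubled half-ellipsoid
  tp <- seq(0, truth$duration_s, by = 1 / truth$pressure_rate_hz)
  fvol_p <- 1 + truth$expansion_frac * cosine_pulse(tp, w$volume[1], w$volume[2])
  dVdt_p <- V0_total * truth$expansion_frac *
    cosine_pulse_deriv(tp, w$volume[1], w$volume[2]) * 1e-6   # m^3/s
  p_pa <- power_consistent_pressure(dVdt_p, truth$target_peak_power_w)
  amp <- max(abs(p_pa))
  p_raw <- p_pa + truth$ambient_pa
  if (truth$pressure_noise_frac > 0 && amp > 0)
    p_raw <- p_raw + stats::rnorm(length(p_raw), 0,
                                  truth$pressure_noise_frac * amp)
  cal <- 1000   # Pa per mV
  pressure <- data.frame(time_s = tp, value = p_raw / cal)

  config <- study_config(
    bones = lapply(bones, function(b) rownames(b$markers)),
    body_plane_markers = rownames(bones$bodyplane$markers),
    muscles = list(
      chains = list(hypaxial = skeleton$chains$hypaxial$markers,
                    epaxial = skeleton$chains$epaxial$markers,
                    sternohyoideus = c("sh_m1", "sh_m2")),
      fibers = list(sternohyoideus = list(
        origins = c("lm_sh_ori_1", "lm_sh_ori_2", "lm_sh_ori_3"),
        insertions = c("lm_sh_ins_1", "lm_sh_ins_2", "lm_sh_ins_3")))),
    jcs_defs = list(
      neurocranium = list(proximal = "bodyplane", distal = "neurocranium",
                          origin = skeleton$joints$neuro_body),
      cleithrum = list(proximal = "bodyplane", distal = "cleithrum",
                       origin = skeleton$joints$cleithrum_body)),
    endocast = list(landmarks = ec$names, alpha = 2, bilateral_factor = 2),
    masses = list(hypaxial = 0.030, cranial_total = 0.006, body = 0.85),
    frame_rate_hz = fr,
    pressure_rate_hz = truth$pressure_rate_hz,
    gape = list(upper = "lm_snout_tip", lower = "lm_jaw_tip"))

  # noiseless reference series (generator truth)
  gape_true <- vapply(seq_len(nfr), function(f)
    sqrt(sum((world_point("neurocranium",
                          bones$neurocranium$landmarks["lm_snout_tip", ], f) -
              world_point("lowerjaw",
                          bones$lowerjaw$landmarks["lm_jaw_tip", ], f))^2)),
    numeric(1))
  dVdt_frames <- V0_total * truth$expansion_frac *
    cosine_pulse_deriv(t, w$volume[1], w$volume[2]) * 1e-6
  p_frames <- power_consistent_pressure(
    if (max(dVdt_frames) > 0) dVdt_frames else dVdt_p,
    truth$target_peak_power_w)
  truth_out <- truth
  truth_out$series <- list(
    time_s = t, elevation_deg = elev, retraction_deg = retr,
    jaw_depression_deg = jawd, strain_pulse = strain_pulse,
    gape = gape_true,
    t_peak_gape_s = t[which.max(gape_true)],
    vol_total_cm3 = V0_total * fvol,
    V0_total_cm3 = V0_total,
    dVdt_m3s = dVdt_frames,
    pressure_pa = p_frames,
    power_w = -p_frames * dVdt_frames,
    sh_L0_cm = sqrt(sum((bones$cleithrum$landmarks["lm_sh_ori_1", ] -
                         bones$neurocranium$landmarks["lm_sh_ins_1", ])^2)),
    chain_L0 = lapply(skeleton$chains, function(ch) ch$L0))

  structure(list(trajectories = trajectories, bones = bones,
                 config = config, pressure = pressure, truth = truth_out,
                 seed = seed),
            class = "strike_bundle")
}

#' @export
print.strike_bundle <- function(x, ...) {
  cat(sprintf("<strike_bundle> seed %d: %d frames @ %g Hz, %d markers, %d pressure samples\n",
              x$seed, n_frames(x$trajectories), x$trajectories$frame_rate_hz,
              length(x$trajectories$markers), nrow(x$pressure)))
  cat(sprintf("  truth: elevation %g deg, retraction %g deg, peak power %g W, noise %g mm\n",
              x$truth$elevation_deg, x$truth$retraction_deg,
              x$truth$target_peak_power_w, x$truth$noise_sd_mm))
  invisible(x)
}

#' Write a strike bundle to a directory
#'
#' Emits the interchange files a real study would provide: marker
#' trajectories CSV, reference geometry CSV, raw pressure CSV, the study
#' configuration YAML, and a JSON table of the ground truth.
#'
#' @param bundle a `strike_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_strike_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectories(bundle$trajectories, file.path(dir, "trajectories.csv"))
  write_bone_definitions(bundle$bones, file.path(dir, "reference_geometry.csv"))
  write.csv(bundle$pressure, file.path(dir, "pressure.csv"), row.names = FALSE)
  cfg <- bundle$config
  write_study_config(cfg, file.path(dir, "config.yaml"))
  tr <- unclass(bundle$truth)
  tr$windows <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a strike bundle back from a directory
#'
#' Counterpart of [write_strike_bundle()]; the truth table is reloaded if
#' present.
#'
#' @param dir directory written by [write_strike_bundle()].
#' @return a `strike_bundle` (without the `truth` element if absent).
#' @export
read_strike_bundle <- function(dir) {
  cfg <- read_study_config(file.path(dir, "config.yaml"))
  trj <- read_trajectories(file.path(dir, "trajectories.csv"),
                           cfg$frame_rate_hz, cfg$units)
  bones <- read_bone_definitions(file.path(dir, "reference_geometry.csv"))
  pr <- read.csv(file.path(dir, "pressure.csv"))
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  structure(list(trajectories = trj, bones = bones, config = cfg,
                 pressure = pr, truth = truth, seed = NA_integer_),
            class = "strike_bundle")
}
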