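#' Study configuration
#'
#' A declarative description of one study setup: which bones and markers
#' exist, which markers form the body plane, the muscle marker chains and
#' fiber landmark triples, the joint coordinate system definitions, the
#' endocast landmark set and alpha, filter cutoffs, frame rates, muscle and
#' body masses, and the pressure calibration. Every numeric default can be
#' overridden; the defaults are the study constants (40 Hz kinematic and
#' 300 Hz pressure cutoffs, alpha = 2, 300 frames/s video, 1000 Hz
#' pressure).
#'
#' @param bones named list: for each bone, a character vector of its marker
#'   names.
#' @param body_plane_markers >= 3 marker names defining the body plane
#'   (6 epaxial markers in the study).
#' @param muscles list with elements `chains` (named list of ordered marker
#'   vectors) and `fibers` (named list of lists with `origins`,
#'   `insertions`).
#' @param jcs_defs named list: each joint has `proximal`, `distal` (bone
#'   names), `origin` (length-3, reference space) and optionally `axes`.
#' @param endocast list with `landmarks`, `alpha`, `bilateral_factor`.
#' @param filters list with `cutoff_kinematics_hz` (40) and
#'   `cutoff_pressure_hz` (300).
#' @param masses named list of masses in kg (> 0), e.g. `hypaxial`,
#'   `cranial_total`, `body`.
#' @param pressure_calibration_pa_per_mv Pa per mV (default 1000).
#' @param frame_rate_hz video frame rate (default 300).
#' @param pressure_rate_hz pressure sample rate (default 1000).
#' @param baseline_window_s list with `width_s` (0.1) and `end_before_s`
#'   (0.2) relative to peak gape.
#' @param gape optional list with `upper` and `lower`: the landmark names
#'   of the upper (neurocranium) and lower jaw tips used for the gape
#'   trace.
#' @param units coordinate length unit label (default `"cm"`).
#' @return an object of class `study_config`.
#' @export
study_config <- function(bones, body_plane_markers,
                         muscles = list(chains = list(), fibers = list()),
                         jcs_defs = list(),
                         endocast = NULL,
                         filters = list(cutoff_kinematics_hz = 40,
                                        cutoff_pressure_hz = 300),
                         masses = list(),
                         pressure_calibration_pa_per_mv = 1000,
                         frame_rate_hz = 300,
                         pressure_rate_hz = 1000,
                         baseline_window_s = list(width_s = 0.1,
                                                  end_before_s = 0.2),
                         gape = NULL,
                         units = "cm") {
  if (length(body_plane_markers) < 3)
    stop("the body plane needs at least 3 markers")
  if (frame_rate_hz <= 0 || pressure_rate_hz <= 0)
    stop("frame rates must be positive")
  for (m in names(masses))
    if (masses[[m]] <= 0) stop(sprintf("mass '%s' must be positive", m))
  if (!is.null(endocast) && (is.null(endocast$alpha) || endocast$alpha <= 0))
    stop("endocast alpha must be positive")
  cfg <- structure(list(bones = bones,
                        body_plane_markers = body_plane_markers,
                        muscles = muscles, jcs_defs = jcs_defs,
                        endocast = endocast, filters = filters,
                        masses = masses,
                        pressure_calibration_pa_per_mv = pressure_calibration_pa_per_mv,
                        frame_rate_hz = frame_rate_hz,
                        pressure_rate_hz = pressure_rate_hz,
                        baseline_window_s = baseline_window_s,
                        gape = gape, units = units),
                   class = "study_config")
  validate_config_names(cfg)
  cfg
}

# every marker referenced by a muscle chain or JCS must live somewhere
validate_config_names <- function(cfg) {
  known <- unique(c(unlist(cfg$bones), cfg$body_plane_markers))
  for (nm in names(cfg$muscles$chains)) {
    ch <- cfg$muscles$chains[[nm]]
    # chain markers are tracked directly; only warn if they clash with bones
    if (length(ch) < 2)
      stop(sprintf("muscle chain '%s' needs at least 2 markers", nm))
  }
  for (j in names(cfg$jcs_defs)) {
    jd <- cfg$jcs_defs[[j]]
    for (b in c(jd$proximal, jd$distal))
      if (!b %in% c(names(cfg$bones), "bodyplane"))
        stop(sprintf("JCS '%s' references unknown bone '%s'", j, b))
  }
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d bones, %d muscle chains, %d fiber sets, %d joints [%s]\n",
              length(x$bones), length(x$muscles$chains),
              length(x$muscles$fibers), length(x$jcs_defs), x$units))
  cat(sprintf("  video %g Hz (filter %g Hz); pressure %g Hz (filter %g Hz); alpha %s\n",
              x$frame_rate_hz, x$filters$cutoff_kinematics_hz,
              x$pressure_rate_hz, x$filters$cutoff_pressure_hz,
              if (is.null(x$endocast)) "-" else format(x$endocast$alpha)))
  invisible(x)
}

#' Read a study configuration from YAML
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}

#' Write a study configuration to YAML
#' @param cfg a [study_config()].
#' @param path output path.
#' @export
write_study_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
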