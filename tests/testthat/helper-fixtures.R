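# Shared fixtures, computed once per test run. The full-pipeline analyses
# are the expensive part of the suite, so the noiseless and noisy synthetic
# strikes (and their analyses) are memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

noiseless_bundle <- function() memo("b0",
  simulate_strike(synthetic_truth(noise_sd_mm = 0, pressure_noise_frac = 0),
                  seed = 101))

# filtering off isolates the geometric chain: pose fit, JCS, lengths,
# endocast and power arithmetic are then exact on noiseless data
noiseless_result <- function() memo("r0",
  analyze_strike(noiseless_bundle(), filter_kinematics = FALSE,
                 filter_pressure = FALSE))

noisy_bundle <- function() memo("bN", simulate_strike(synthetic_truth(), seed = 7))

# pose + joint kinematics only (no endocast/pressure): cheap noisy recovery
noisy_jcs <- function() memo("jcsN", {
  b <- noisy_bundle()
  jcs_from_bundle(b, filter = TRUE)
})

jcs_from_bundle <- function(b, filter = TRUE) {
  cut <- b$config$filters$cutoff_kinematics_hz
  poses <- lapply(b$bones[c("neurocranium", "cleithrum", "bodyplane")],
                  function(bd) {
                    p <- fit_pose_sequence(b$trajectories, bd)
                    if (filter) filter_poses(p, cut) else p
                  })
  out <- list()
  for (j in names(b$config$jcs_defs)) {
    jd <- b$config$jcs_defs[[j]]
    jcs <- joint_cs(j, anatomical_cs(jd$proximal, jd$origin),
                    anatomical_cs(jd$distal, jd$origin))
    out[[j]] <- jcs_decompose(poses[[jd$distal]], poses[[jd$proximal]], jcs)
  }
  out
}

# random proper rotation
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
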