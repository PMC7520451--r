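test_that("rigid fit recovers exact transforms and never reflects", {
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(1, 1, 1.5),
               c(2, 2, 0.5), c(0.5, 0.2, 2))
  rownames(ref) <- paste0("m", 1:6)
  fit <- fit_rigid_transform(ref, ref)
  expect_equal(fit$R, diag(3), tolerance = 1e-12)
  expect_equal(fit$t, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-12)

  R90 <- euler_zyx_compose(90, 0, 0)
  obs <- sweep(ref %*% t(R90), 2, c(1, 2, 3), "+")
  fit <- fit_rigid_transform(ref, obs)
  expect_equal(fit$R, R90, tolerance = 1e-9)
  expect_equal(fit$t, c(1, 2, 3), tolerance = 1e-9)

  set.seed(11)
  for (i in 1:200) {
    Rt <- random_rotation()
    # near-planar configurations are the classic reflection trap
    pts <- cbind(matrix(rnorm(8), 4), rnorm(4, sd = 1e-4))
    rownames(pts) <- paste0("m", 1:4)
    obs <- sweep(pts %*% t(Rt), 2, rnorm(3), "+") +
      matrix(rnorm(12, sd = 0.01), 4)
    fit <- fit_rigid_transform(pts, obs)
    expect_gt(det(fit$R), 0.999999)
  }
  expect_error(fit_rigid_transform(ref[1:2, ], obs = ref[1:2, ]), "fewer than 3")
  line <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  rownames(line) <- paste0("m", 1:4)
  expect_error(fit_rigid_transform(line, line), "collinear")
})

test_that("fit residuals under Gaussian noise match the degrees-of-freedom law", {
  # E[sum of squared residuals] = sigma^2 * (3n - 6) for noise on the
  # observed points only (6 rigid dof absorbed); Monte-Carlo over 2000 draws
  set.seed(21)
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(1, 1, 1.5),
               c(2, 2, 0.5), c(0.5, 0.2, 2))
  rownames(ref) <- paste0("m", 1:6)
  n <- nrow(ref)
  sigma <- 0.008   # 0.08 mm in cm
  ss <- replicate(2000, {
    obs <- ref + matrix(rnorm(3 * n, sd = sigma), n)
    n * fit_rigid_transform(ref, obs)$residual^2
  })
  expect_equal(mean(ss), sigma^2 * (3 * n - 6), tolerance = 0.05)
})

test_that("pose sequences round-trip noiseless synthetic motion", {
  b <- noiseless_bundle()
  truth <- b$truth
  pose <- fit_pose_sequence(b$trajectories, b$bones$neurocranium)
  expect_false(any(pose$missing))
  expect_true(all(abs(pose$residual) < 1e-9))
  # every frame's fitted rotation matches the generating elevation
  for (f in c(1, 100, 136, 200)) {
    Rtrue <- euler_zyx_compose(truth$series$elevation_deg[f], 0, 0)
    expect_lt(max(abs(pose$R[, , f] - Rtrue)), 1e-8)
  }
  expect_true(all(abs(apply(pose$R, 3, det) - 1) < 1e-6))
})

test_that("frames with fewer than 3 usable markers are flagged missing", {
  b <- noiseless_bundle()
  tr <- b$trajectories
  mk <- rownames(b$bones$neurocranium$markers)
  tr$coords[10, mk[1:3], ] <- NA
  pose <- fit_pose_sequence(tr, b$bones$neurocranium)
  expect_true(pose$missing[10])
  expect_false(pose$missing[11])
  lms <- animate_landmarks(pose, b$bones$neurocranium, "lm_snout_tip")
  expect_true(all(is.na(lms$coords[10, 1, ])))
})

test_that("landmark animation is exact and rigidly consistent", {
  b <- noiseless_bundle()
  pose <- fit_pose_sequence(b$trajectories, b$bones$neurocranium)
  lms <- animate_landmarks(pose, b$bones$neurocranium)
  # identity pose at frame 1 (pre-strike): landmark equals its reference
  expect_equal(lms$coords[1, "lm_snout_tip", ],
               b$bones$neurocranium$landmarks["lm_snout_tip", ],
               ignore_attr = TRUE, tolerance = 1e-9)
  # rigidity: inter-landmark distance constant over all frames
  d <- pairwise_length(marker_xyz(lms, "lm_snout_tip"),
                       marker_xyz(lms, "lm_cv_joint"))
  expect_lt(diff(range(d)), 1e-9)
  expect_error(animate_landmarks(pose, b$bones$neurocranium, "nope"),
               "unknown landmark")

  # pure translation: landmark shifts by the same vector
  ref <- b$bones$neurocranium$markers
  nfr <- 5
  arr <- array(NA_real_, c(nfr, nrow(ref), 3))
  for (f in 1:nfr) arr[f, , ] <- sweep(ref, 2, c(f - 1, 0, 0), "+")
  ts <- trajectory_set(arr, rownames(ref), 300)
  pose2 <- fit_pose_sequence(ts, b$bones$neurocranium)
  lm2 <- animate_landmarks(pose2, b$bones$neurocranium, "lm_snout_tip")
  expect_equal(lm2$coords[3, 1, ] - lm2$coords[1, 1, ], c(2, 0, 0),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("tracking precision reproduces its definition and noise expectation", {
  b <- noiseless_bundle()
  pairs <- list(c("neuro_m1", "neuro_m2"), c("clei_m1", "clei_m2"))
  expect_equal(as.numeric(tracking_precision(b$trajectories, pairs)), 0,
               tolerance = 1e-9)

  # two pairs -> mean of the per-pair sds
  set.seed(3)
  arr <- array(rnorm(400 * 4 * 3, sd = 0.01), c(400, 4, 3))
  arr[, 2, 1] <- arr[, 2, 1] + 2      # pair 1: 2 apart
  arr[, 4, 2] <- arr[, 4, 2] + 3      # pair 2: 3 apart
  ts <- trajectory_set(arr, c("a1", "a2", "b1", "b2"), 300)
  tp <- tracking_precision(ts, list(c("a1", "a2"), c("b1", "b2")))
  pp <- attr(tp, "per_pair")
  expect_equal(as.numeric(tp), mean(pp))

  # isotropic sigma on both markers of a static pair: distance sd is
  # sigma * sqrt(2) for separation >> sigma (Monte-Carlo cross-check)
  sigma <- 0.008
  set.seed(4)
  mc <- sd(sqrt(rowSums((matrix(rnorm(3e4, sd = sigma), ncol = 3) -
                           cbind(2 + rnorm(1e4, sd = sigma),
                                 rnorm(1e4, sd = sigma),
                                 rnorm(1e4, sd = sigma)))^2)))
  arr2 <- array(rnorm(500 * 2 * 3, sd = sigma), c(500, 2, 3))
  arr2[, 2, 1] <- arr2[, 2, 1] + 2
  ts2 <- trajectory_set(arr2, c("p", "q"), 300)
  tp2 <- as.numeric(tracking_precision(ts2, list(c("p", "q"))))
  expect_equal(tp2, mc, tolerance = 0.10)

  ts$coords[, 3, ] <- NA
  expect_warning(tracking_precision(ts, list(c("a1", "a2"), c("b1", "b2"))),
                 "skipped")
  expect_error(suppressWarnings(tracking_precision(ts, list(c("b1", "b2")))),
               "no marker pair")
})

test_that("synthetic noise yields the expected tracking precision", {
  b <- noisy_bundle()
  pairs <- list(c("neuro_m1", "neuro_m2"), c("neuro_m3", "neuro_m4"),
                c("clei_m1", "clei_m2"), c("jaw_m1", "jaw_m2"),
                c("body_m1", "body_m2"), c("body_m3", "body_m4"))
  tp_mm <- as.numeric(tracking_precision(b$trajectories, pairs)) * 10
  expect_equal(tp_mm, 0.08 * sqrt(2), tolerance = 0.10)
})
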