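test_that("intrinsic zyx Euler angles round-trip 1e4 random rotations", {
  set.seed(42)
  worst <- 0
  for (i in 1:10000) {
    rz <- runif(1, -180, 180)
    ry <- runif(1, -80, 80)
    rx <- runif(1, -180, 180)
    R <- euler_zyx_compose(rz, ry, rx)
    e <- euler_zyx_decompose(R)
    R2 <- euler_zyx_compose(e$rz, e$ry, e$rx)
    worst <- max(worst, max(abs(R2 - R)))
  }
  expect_lt(worst, 1e-9)
})

test_that("JCS decomposition matches constructed relative poses", {
  b <- noiseless_bundle()
  origin <- c(1.5, 1.5, 0)
  mkpose <- function(Rlist, tlist, n) {
    structure(list(bone = "x",
                   R = array(unlist(Rlist), c(3, 3, n)),
                   t = do.call(rbind, tlist),
                   residual = rep(0, n), missing = rep(FALSE, n),
                   frame_rate_hz = 300), class = "pose_sequence")
  }
  jcs <- joint_cs("j", anatomical_cs("prox", origin),
                  anatomical_cs("dist", origin))
  idn <- list(R = diag(3), t = c(0, 0, 0))

  # identical poses -> all six channels zero
  pp <- mkpose(list(diag(3), diag(3)), list(c(0, 0, 0), c(0, 0, 0)), 2)
  tr <- jcs_decompose(pp, pp, jcs)
  expect_equal(unlist(tr[1, c("rz_deg", "ry_deg", "rx_deg", "tz", "ty", "tx")]),
               rep(0, 6), ignore_attr = TRUE, tolerance = 1e-12)

  # distal = Rz(30) about the ACS -> rz = 30, others 0
  R30 <- euler_zyx_compose(30, 0, 0)
  d30 <- list(R = R30, t = origin - as.vector(R30 %*% origin))
  pd <- mkpose(list(d30$R), list(d30$t), 1)
  pp1 <- mkpose(list(diag(3)), list(c(0, 0, 0)), 1)
  tr <- jcs_decompose(pd, pp1, jcs)
  expect_equal(tr$rz_deg[1], 30, tolerance = 1e-9)
  expect_equal(tr$ry_deg[1], 0, tolerance = 1e-9)
  expect_equal(abs(tr$tz[1]) + abs(tr$ty[1]) + abs(tr$tx[1]), 0,
               tolerance = 1e-9)

  # compose-and-invert oracle: relative rotation built by brute-force
  # matrix composition is recovered angle for angle
  set.seed(7)
  for (i in 1:50) {
    ang <- c(runif(1, -170, 170), runif(1, -75, 75), runif(1, -170, 170))
    Rp <- random_rotation(); tp <- rnorm(3)
    Rrel <- euler_zyx_compose(ang[1], ang[2], ang[3])
    # distal world pose such that prox^-1 . dist = Rrel about the ACS
    Rd <- Rp %*% Rrel
    td <- as.vector(Rp %*% origin) + tp - as.vector(Rd %*% origin)
    trx <- jcs_decompose(mkpose(list(Rd), list(td), 1),
                         mkpose(list(Rp), list(tp), 1), jcs)
    expect_equal(c(trx$rz_deg, trx$ry_deg, trx$rx_deg), ang, tolerance = 1e-8)
    expect_equal(c(trx$tx, trx$ty, trx$tz), rep(0, 3), tolerance = 1e-8)
  }

  # gimbal flag at ry ~ 90
  R90 <- euler_zyx_compose(10, 90, 0)
  trg <- jcs_decompose(mkpose(list(R90), list(c(0, 0, 0) - as.vector(R90 %*% origin) + origin), 1),
                       pp1, jcs)
  expect_true(trg$gimbal[1])
})

test_that("sign conventions match the anatomical reading", {
  # dorsal (elevation) rotation of the neurocranium -> rz > 0;
  # caudoventral (retraction) rotation of the cleithrum -> rz < 0
  b <- noiseless_bundle()
  tr <- jcs_from_bundle(b, filter = FALSE)
  i_peak <- which.max(b$truth$series$elevation_deg)
  expect_gt(tr$neurocranium$rz_deg[i_peak], 0)
  expect_equal(max(tr$neurocranium$rz_deg), b$truth$elevation_deg,
               tolerance = 1e-6)
  expect_lt(min(tr$cleithrum$rz_deg), 0)
  expect_equal(min(tr$cleithrum$rz_deg), -b$truth$retraction_deg,
               tolerance = 1e-6)
})

test_that("kinematic traces are invariant to a global rigid transform", {
  b <- noiseless_bundle()
  tr1 <- jcs_from_bundle(b, filter = FALSE)
  Rg <- euler_zyx_compose(25, -40, 65)
  tg <- c(10, -4, 7)
  b2 <- b
  for (i in seq_along(b2$trajectories$markers))
    b2$trajectories$coords[, i, ] <-
      sweep(b2$trajectories$coords[, i, ] %*% t(Rg), 2, tg, "+")
  tr2 <- jcs_from_bundle(b2, filter = FALSE)
  for (j in names(tr1))
    for (ch in c("rz_deg", "ry_deg", "rx_deg", "tz", "ty", "tx"))
      expect_equal(tr2[[j]][[ch]], tr1[[j]][[ch]], tolerance = 1e-8)
})

test_that("gape trace and peak-gape timing behave as defined", {
  expect_equal(gape_trace(cbind(0, 0, 0), cbind(3, 4, 0)), 5)
  expect_equal(gape_trace(cbind(1, 1, 1), cbind(1, 1, 1)), 0)
  a <- matrix(rnorm(30), 10); bm <- matrix(rnorm(30), 10)
  shift <- matrix(rep(c(5, -2, 1), each = 10), 10)
  expect_equal(gape_trace(a + shift, bm + shift), gape_trace(a, bm),
               tolerance = 1e-12)
  expect_error(gape_trace(matrix(NA_real_, 2, 3), matrix(NA_real_, 2, 3)),
               "finite")

  g <- c(1, 2, 5, 3, 1)
  expect_equal(find_peak_gape(g)$frame, 3)
  expect_equal(find_peak_gape(rep(2, 5))$frame, 1)   # tie -> earliest
  expect_equal(find_peak_gape(g, 300)$time_s, 2 / 300)

  b <- noiseless_bundle()
  r0 <- noiseless_result()
  expect_lt(abs(r0$peak_gape$time_s - b$truth$series$t_peak_gape_s),
            1 / b$config$frame_rate_hz + 1e-12)
})

test_that("re-zeroing subtracts the baseline mean and is idempotent", {
  tr <- data.frame(rz_deg = c(rep(2, 10), seq(2, 9, length.out = 10)),
                   ry_deg = 0, rx_deg = 0, tz = 1, ty = 1, tx = 1)
  z1 <- rezero_trace(tr, 1:10)
  expect_equal(z1$rz_deg[1:10], rep(0, 10))
  expect_equal(max(z1$rz_deg), 7)
  expect_equal(rezero_trace(z1, 1:10), z1)
  expect_error(rezero_trace(tr, integer(0)), "empty")
  expect_equal(rezero_trace(data.frame(rz_deg = rep(7, 5)), 1:3)$rz_deg,
               rep(0, 5))
})
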