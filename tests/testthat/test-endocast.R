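# clouds with analytically known convex-hull volume: random interior points
# inside an affinely transformed simplex whose vertices are included
hull_known_cloud <- function(n_interior = 40) {
  A <- matrix(rnorm(9), 3)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
  verts <- rbind(c(0, 0, 0), diag(3)) %*% t(A)
  w <- matrix(stats::rexp(4 * n_interior), ncol = 4)
  w <- w / rowSums(w)
  list(points = rbind(verts, w %*% verts), volume = abs(det(A)) / 6)
}

test_that("alpha-shape volume matches closed forms", {
  # regular tetrahedron, edge 1: V = 1/(6 sqrt 2), circumradius sqrt(3/8)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  as <- alpha_shape_volume(tet, alpha = 10)
  expect_equal(as$volume, 1 / (6 * sqrt(2)), tolerance = 1e-9)
  expect_equal(nrow(as$faces), 4)
  expect_true(all(as$faces >= 1))
  # alpha below the circumradius keeps nothing
  expect_warning(z <- alpha_shape_volume(tet, alpha = 0.9 * sqrt(3 / 8)),
                 "no tetrahedron")
  expect_equal(z$volume, 0)

  # dense unit-cube cloud (corners + faces + interior): hull volume is 1
  set.seed(31)
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  faces <- matrix(runif(900), ncol = 3)
  faces[cbind(seq_len(300), sample(1:3, 300, TRUE))] <-
    sample(0:1, 300, TRUE)
  cloud <- rbind(g, faces, matrix(runif(300), ncol = 3))
  expect_equal(alpha_shape_volume(cloud, alpha = 50)$volume, 1,
               tolerance = 0.02)

  # two clusters 10 apart with alpha = 1: volumes add, no bridging
  set.seed(32)
  c1 <- matrix(runif(150), ncol = 3)
  c2 <- c1 + 10
  both <- alpha_shape_volume(rbind(c1, c2), alpha = 1)$volume
  sep <- alpha_shape_volume(c1, alpha = 1)$volume +
    alpha_shape_volume(c2, alpha = 1)$volume
  expect_equal(both, sep, tolerance = 1e-9)
})

test_that("degenerate clouds give zero volume with a warning", {
  flat <- cbind(matrix(runif(40), ncol = 2), 0)
  expect_warning(z <- alpha_shape_volume(flat, 2), "degenerate|coplanar")
  expect_equal(z$volume, 0)
  expect_warning(z2 <- alpha_shape_volume(flat[1:3, ], 2), "fewer than 4")
  expect_equal(z2$volume, 0)
})

test_that("volume is monotone in alpha and converges to the convex hull", {
  set.seed(33)
  alphas <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, Inf)
  for (i in 1:50) {
    cl <- hull_known_cloud()
    vols <- vapply(alphas, function(a)
      suppressWarnings(alpha_shape_volume(cl$points, a)$volume), numeric(1))
    expect_true(all(diff(vols) >= -1e-12))
    expect_equal(vols[length(vols)], cl$volume, tolerance = 1e-9)
  }
})

test_that("volume is rigid-invariant and scales as s^3", {
  set.seed(34)
  pts <- matrix(rnorm(450), ncol = 3)
  v0 <- alpha_shape_volume(pts, 1.2)$volume
  R <- random_rotation()
  v1 <- alpha_shape_volume(sweep(pts %*% t(R), 2, c(7, -3, 2), "+"), 1.2)$volume
  expect_equal(v1, v0, tolerance = 1e-9)
  s <- 3.7
  v2 <- alpha_shape_volume(pts * s, 1.2 * s)$volume
  expect_equal(v2, v0 * s^3, tolerance = 1e-9)
})

test_that("boundary mesh is closed and encloses the alpha volume", {
  set.seed(35)
  pts <- matrix(rnorm(300), ncol = 3)
  as <- alpha_shape_volume(pts, Inf)
  # divergence theorem on the boundary mesh reproduces the volume
  v <- 0
  for (i in seq_len(nrow(as$faces))) {
    tri <- as$vertices[as$faces[i, ], ]
    v <- v + det(tri) / 6
  }
  expect_equal(abs(v), as$volume, tolerance = 1e-9)
})

test_that("the endocast trace tracks an analytic half-ellipsoid within 3%", {
  b <- noiseless_bundle()
  r0 <- noiseless_result()
  truth <- b$truth
  vt <- r0$volume
  expect_true(all(is.finite(vt$vol_total_cm3)))
  # doubling identity holds exactly at every frame
  expect_equal(vt$vol_total_cm3, 2 * vt$vol_unilateral_cm3, tolerance = 1e-12)
  # total volume within 3% of 2 * (2/3 pi a b c) * f(t) at rest and peak
  rel <- vt$vol_total_cm3 / truth$series$vol_total_cm3
  expect_true(all(abs(rel - 1) < 0.03))
  # static cloud pre-strike: constant volume, dV/dt ~ 0
  pre <- 2:30
  expect_lt(diff(range(vt$vol_total_cm3[pre])), 1e-6)
  expect_lt(max(abs(vt$dVdt_cm3_s[pre])), 1e-3)
})

test_that("dV/dt recovers a linear volume ramp", {
  # scale a fixed cloud so total volume rises linearly: V(t) = V0 + k t
  set.seed(36)
  sk <- make_skeleton()
  rel <- sweep(sk$endocast$points, 2, sk$endocast$center)
  fr <- 300
  t <- seq(0, 0.3, by = 1 / fr)
  V0_frac <- 1; k_frac <- 1.5        # V = V0 (1 + 1.5 t)
  arr <- array(NA_real_, c(length(t), nrow(rel), 3))
  s <- sqrt(V0_frac + k_frac * t)
  for (f in seq_along(t))
    arr[f, , ] <- sweep(cbind(rel[, 1], rel[, 2] * s[f], rel[, 3] * s[f]),
                        2, sk$endocast$center, "+")
  ts <- trajectory_set(arr, sk$endocast$names, fr)
  vt <- endocast_trace(ts, endocast_definition(sk$endocast$names, 2, 2))
  V0_est <- vt$vol_total_cm3[1]
  core <- 10:(length(t) - 10)
  expect_equal(median(vt$dVdt_cm3_s[core]), V0_est * k_frac, tolerance = 0.01)
  expect_true(all(abs(vt$dVdt_cm3_s[core] - V0_est * k_frac) /
                    (V0_est * k_frac) < 0.05))
})
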