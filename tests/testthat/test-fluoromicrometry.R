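test_that("pairwise lengths are exact and rigid-motion invariant", {
  a <- matrix(rep(c(0, 0, 0), each = 5), 5)
  b <- matrix(rep(c(2, 0, 0), each = 5), 5)
  expect_equal(pairwise_length(a, b), rep(2, 5))
  conv <- cbind(seq(2, 1.8, length.out = 5), 0, 0)
  expect_equal(pairwise_length(a[, , drop = FALSE], conv),
               seq(2, 1.8, length.out = 5))
  set.seed(9)
  R <- random_rotation(); tg <- rnorm(3)
  p <- matrix(rnorm(30), 10); q <- matrix(rnorm(30), 10)
  expect_equal(pairwise_length(sweep(p %*% t(R), 2, tg, "+"),
                               sweep(q %*% t(R), 2, tg, "+")),
               pairwise_length(p, q), tolerance = 1e-9)
})

test_that("mean initial length follows its window definition", {
  expect_equal(mean_initial_length(list(rep(2, 20)), 1:10), 2)
  expect_equal(mean_initial_length(list(c(rep(1.9, 10), rep(1, 10)),
                                        c(rep(2.1, 10), rep(3, 10))),
                                   1:10), 2)
  # invariant to post-baseline shortening
  expect_equal(mean_initial_length(list(c(rep(2, 10), rep(0.5, 10))), 1:10), 2)
  expect_error(mean_initial_length(list(rep(NA_real_, 5)), 1:5), "baseline")
})

test_that("strain and strain rate identities hold", {
  fr <- 300
  L <- rep(2, 50)
  st <- strain_and_rate(L, 2, fr)
  expect_equal(st$strain_pct, rep(0, 50))
  expect_equal(st$rate_Li_per_s, rep(0, 50))

  # drop to 0.92 L_i -> +8% strain (the scale of axial shortening in vivo)
  L2 <- c(rep(2, 10), seq(2, 1.84, length.out = 30), rep(1.84, 10))
  st2 <- strain_and_rate(L2, 2, fr)
  expect_equal(max(st2$strain_pct), 8, tolerance = 1e-9)

  # sinusoidal length: peak rate matches the analytic derivative within 1%
  t <- seq(0, 1, by = 1 / fr)
  L3 <- 2 * (1 - 0.05 * sin(2 * pi * 2 * t))
  st3 <- strain_and_rate(L3, 2, fr)
  expect_equal(max(st3$rate_Li_per_s), 0.05 * 2 * pi * 2, tolerance = 0.01)

  expect_error(strain_and_rate(L, 0, fr), "positive")
})

test_that("shortening is always positive strain and positive rate", {
  set.seed(14)
  for (i in 1:50) {
    Li <- runif(1, 1, 5)
    drop <- runif(1, 0.01, 0.3)
    L <- Li * (1 - drop * sort(runif(40)))   # monotone shortening
    st <- strain_and_rate(L, Li, 300)
    expect_true(all(st$strain_pct[-1] > 0))
    expect_true(all(st$rate_Li_per_s >= -1e-9))
  }
})

test_that("uniformly straining straight chains have equal sub- and whole-region strain", {
  b <- noiseless_bundle()
  fr <- 300
  t <- seq(0, 0.5, by = 1 / fr)
  pulse <- cosine_pulse(t, 0.1, 0.3)
  u <- c(1, 0, 0)
  L0 <- c(2, 3, 1.5)
  arr <- array(0, c(length(t), 4, 3))
  for (k in 2:4)
    arr[, k, ] <- outer(sum(L0[1:(k - 1)]) * (1 - 0.06 * pulse), u)
  ts <- trajectory_set(arr, paste0("c", 1:4), fr)
  reg <- muscle_region("m", paste0("c", 1:4))
  L <- region_lengths(ts, reg)
  strains <- apply(L, 2, function(col) {
    Li <- mean(col[1:20])
    100 * (Li - col) / Li
  })
  # all subregions and the whole region see the same 6% peak strain
  expect_equal(apply(strains, 2, max), rep(6, 4), ignore_attr = TRUE,
               tolerance = 1e-9)
  # straight chain: whole (straight) equals summed chain mode
  Lchain <- region_lengths(ts, reg, whole = "chain")
  expect_equal(L[, "m_whole"], Lchain[, "m_whole"], tolerance = 1e-9)
})

test_that("prescribed subregion strains are recovered from the synthetic strike", {
  r0 <- noiseless_result()
  truth <- noiseless_bundle()$truth
  for (k in seq_along(truth$hypaxial_strain_pct)) {
    st <- r0$muscles$hypaxial[[paste0("hypaxial_sub", k)]]
    expect_equal(max(st$strain_pct), truth$hypaxial_strain_pct[k],
                 tolerance = 1e-3)
  }
  # epaxial stays isometric
  expect_lt(max(abs(r0$muscles$epaxial$epaxial_whole$strain_pct)), 1e-6)
})

test_that("fiber-based muscle length averages three fibers and matches fluoromicrometry", {
  # three constant fibers of lengths 1, 2, 3 -> mean 2
  arr <- array(0, c(4, 6, 3))
  arr[, 2, 1] <- 1; arr[, 4, 1] <- 2; arr[, 6, 1] <- 3
  ts <- trajectory_set(arr, c("o1", "i1", "o2", "i2", "o3", "i3"), 300)
  fs <- fiber_set("m", c("o1", "o2", "o3"), c("i1", "i2", "i3"))
  expect_equal(fiber_muscle_length(fs, ts), rep(2, 4))
  expect_error(fiber_set("m", c("o1", "o2"), c("i1", "i2")), "three")

  # the synthetic sternohyoideus is measured two ways: intramuscular
  # markers (fluoromicrometry) and bone-animated fiber landmarks; the whole
  # muscle averages three fibers whose ends move with the same bones, so
  # the two length series must agree closely (exactly for fiber 1)
  r0 <- noiseless_result()
  flu <- r0$muscles$sternohyoideus$sternohyoideus_whole
  fib <- r0$fibers$sternohyoideus
  expect_equal(stats::cor(flu$length, fib$length), 1, tolerance = 1e-4)
  expect_lt(max(abs(flu$length - fib$length)) / mean(flu$length), 0.05)
  expect_equal(max(flu$strain_pct), max(fib$strain_pct), tolerance = 0.5)
})

test_that("windowed peaks respect the mask", {
  x <- c(1, 2, 3, 10, 3, 2, 8, 1)
  mask <- c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(peak_during_window(x, mask), 10)
  mask2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(peak_during_window(x, mask2), 3)     # global peak is outside
  expect_equal(peak_during_window(x, rep(TRUE, 8)), 10)
  expect_equal(peak_during_window(-x, mask, "absmax"), -10)
  expect_error(peak_during_window(x, rep(FALSE, 8)), "no frames")
})
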