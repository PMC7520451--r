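test_that("pressure processing filters and re-zeroes to ambient", {
  t <- seq(0, 1, by = 1e-3)
  p <- data.frame(time_s = t, pressure_pa = rep(101000, length(t)))
  out <- process_pressure(p, 300, baseline_s = c(0.05, 0.15))
  expect_lt(max(abs(out$pressure_pa)), 0.01)   # ~1e-7 of the input scale

  # smooth drop to -2 kPa survives re-zeroing
  p2 <- data.frame(time_s = t,
                   pressure_pa = 500 - 2000 * cosine_pulse(t, 0.4, 0.4) *
                     as.numeric(t >= 0.4))
  p2$pressure_pa[t >= 0.6] <- 500 - 2000
  out2 <- process_pressure(p2, 300, baseline_s = c(0.05, 0.15))
  expect_equal(out2$pressure_pa[length(t)], -2000, tolerance = 5)

  # 450 Hz noise on a -1 kPa pulse attenuated per the analytic response
  set.seed(41)
  noise <- sin(2 * pi * 450 * t)
  p3 <- data.frame(time_s = t,
                   pressure_pa = -1000 * cosine_pulse(t, 0.3, 0.4) + 100 * noise)
  out3 <- process_pressure(p3, 300, baseline_s = c(0.05, 0.15))
  resid <- out3$pressure_pa - process_pressure(
    data.frame(time_s = t, pressure_pa = -1000 * cosine_pulse(t, 0.3, 0.4)),
    300, baseline_s = c(0.05, 0.15))$pressure_pa
  h2 <- 1 / (1 + (450 / 300)^4)
  core <- 100:900
  expect_lt(max(abs(resid[core])), 100 * (h2 + 0.01))

  expect_error(process_pressure(p, 600, baseline_s = c(0, 0.1)), "Nyquist")
  expect_error(process_pressure(p, 300, baseline_s = c(5, 6)), "baseline")
})

test_that("synchronization interpolates pressure onto frame times", {
  t <- seq(0, 1, by = 1e-3)
  ptr <- data.frame(time_s = t, pressure_pa = 5 * t)
  ft <- seq(0, 1, by = 1 / 250)     # frame times coincide with samples
  expect_equal(synchronize(ptr, ft), 5 * ft, tolerance = 1e-12)
  ft2 <- seq(0.0005, 0.9995, by = 1 / 300)
  expect_equal(synchronize(ptr, ft2), 5 * ft2, tolerance = 1e-9)
  # offset: +10 ms shifts the pressure clock; frames whose shifted time
  # falls outside the record become missing
  sh <- synchronize(ptr, ft2, offset_s = 0.01)
  ok <- ft2 + 0.01 <= max(t)
  expect_equal(sh[ok], 5 * (ft2[ok] + 0.01), tolerance = 1e-9)
  expect_true(all(is.na(sh[!ok])))
  expect_error(synchronize(ptr, ft2 + 100), "overlap")
  # frames outside the record are missing
  out <- synchronize(ptr, c(-0.5, 0.5, 2))
  expect_true(is.na(out[1]) && is.na(out[3]) && !is.na(out[2]))
})

test_that("instantaneous power is the sign-flipped pressure-flow product", {
  expect_equal(instantaneous_power(-1000, 1e-4)$power_w, 0.1)
  pw <- instantaneous_power(c(0, -500, 0), c(1, 1, 1) * 1e-4)
  expect_equal(pw$power_w, c(0, 0.05, 0))
  expect_equal(pw$peak_frame, 2L)
  expect_error(instantaneous_power(1:3, 1:2), "length")

  # sign identity: power > 0 iff expansion under sub-ambient pressure or
  # compression under supra-ambient pressure
  set.seed(42)
  p <- rnorm(200); dv <- rnorm(200)
  pw2 <- instantaneous_power(p, dv)$power_w
  expect_equal(pw2 > 0, (p < 0 & dv > 0) | (p > 0 & dv < 0))

  # unit discipline: cm^3/s converted to m^3/s equals SI throughout
  dv_cm3 <- runif(50, -500, 1500)
  expect_equal(instantaneous_power(p[1:50], dv_cm3 * 1e-6)$power_w,
               instantaneous_power(p[1:50], dv_cm3)$power_w * 1e-6,
               tolerance = 1e-12)
})

test_that("sinusoidal volume with constant pressure hits the closed-form peak power", {
  # V(t) = V0 + A sin(w t), p = -P0: analytic peak power = P0 A w
  fr <- 300
  t <- seq(0, 1, by = 1 / fr)
  A <- 20; omega <- 2 * pi * 5; P0 <- 5000
  V_cm3 <- 100 + A * sin(omega * t)
  dVdt <- suctionpower:::central_diff(V_cm3, 1 / fr) * 1e-6
  pw <- instantaneous_power(rep(-P0, length(t)), dVdt)
  analytic <- P0 * A * 1e-6 * omega
  expect_equal(pw$max_power_w, analytic, tolerance = 0.01)
})

test_that("the peak-power mask selects frames within 25% of maximum", {
  tri <- c(seq(0, 10, length.out = 11), seq(9, 0, length.out = 10))
  m <- peak_power_mask(tri)
  expect_equal(which(m$mask), which(tri >= 7.5))
  expect_equal(m$max_power_w, 10)

  # two pulses: both contribute frames, the block covers only the taller
  two <- c(0, 4, 10, 4, 0, 0, 4, 8, 4, 0)
  m2 <- peak_power_mask(two)
  expect_equal(which(m2$mask), c(3, 8))
  expect_equal(which(m2$block), 3)

  m3 <- peak_power_mask(tri, fraction = 1)
  expect_equal(which(m3$mask), which.max(tri))

  expect_error(peak_power_mask(rep(0, 5)), "positive")
  expect_error(peak_power_mask(c(-3, -1)), "positive")
})

test_that("power normalization divides by mass and volume", {
  out <- normalize_power(10, c(hypaxial_kg = 0.05))
  expect_equal(as.numeric(out), 200)
  expect_equal(names(out), "hypaxial_Wkg")
  out2 <- normalize_power(10, c(dvol_cm3 = 100))
  expect_equal(as.numeric(out2), 0.1)
  expect_equal(names(out2), "dvol_Wcm3")
  both <- normalize_power(10, c(hypaxial_kg = 0.05, dvol_cm3 = 100))
  expect_equal(unname(both), c(200, 0.1))   # order-independent division
  expect_error(normalize_power(10, c(a_kg = -1)), "positive")
})

test_that("per-individual summaries report mean and s.e.m.", {
  strikes <- data.frame(peak_strain = c(4, 8, 5, 7))
  ind <- c("Cat1", "Cat1", "Cat2", "Cat2")
  s <- summarize_individuals(strikes, ind)
  c1 <- s[s$individual == "Cat1", ]
  expect_equal(c1$mean, 6)
  expect_equal(c1$sem, 2)       # sd(c(4,8))/sqrt(2) = 2
  expect_equal(c1$n, 2)
  one <- summarize_individuals(data.frame(v = 3), "only")
  expect_equal(one$sem, 0)
  expect_equal(one$n, 1)
})
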