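test_that("elliptical slice geometry matches closed forms", {
  # circle: Ramanujan is exact
  g <- slice_geometry(100, 100)
  expect_equal(g$area, 2500 * pi, tolerance = 1e-12)
  expect_equal(g$circumference, 100 * pi, tolerance = 1e-12)

  # true ellipse: exact area, perimeter within 0.01 mm of the elliptic
  # integral
  g2 <- slice_geometry(120, 80)
  expect_equal(g2$area, pi * 60 * 40, tolerance = 1e-12)
  expect_lt(abs(g2$circumference - ellipse_perimeter_exact(60, 40)), 0.01)
  expect_equal(round(g2$circumference, 2), 317.31)

  expect_error(slice_geometry(-1, 50), "non-positive")
  expect_error(slice_geometry(numeric(0), numeric(0)), "empty")
})

test_that("Ramanujan perimeter stays within 0.01 mm of the integral oracle
           over leg-like axis ratios", {
  for (ratio in c(0.6, 0.75, 0.9, 1, 1.2, 1.5)) {
    a <- 60
    b <- a * ratio
    approx <- slice_geometry(2 * a, 2 * b)$circumference
    expect_lt(abs(approx - ellipse_perimeter_exact(a, b)), 0.01)
  }
})

test_that("circumference profile preserves order and rejects degenerate input", {
  prof <- leg_profile(heights = (1:30 - 0.5) * 4.7,
                      front_width = rep(100, 30), side_width = rep(100, 30))
  geom <- circumference_profile(prof)
  expect_equal(nrow(geom), 30)
  expect_true(all(abs(geom$circumference - 100 * pi) < 1e-9))
  expect_equal(geom$height, prof$heights)

  expect_error(leg_profile(numeric(0), numeric(0), numeric(0)), "at least 2")
  expect_error(leg_profile(c(1, 2, 4), rep(1, 3), rep(1, 3)), "constant")
})

test_that("segment volume matches the analytic cylinder and is additive", {
  # circular cylinder, width 100 mm, 100 slices of 4.7 mm
  prof <- leg_profile(heights = (1:100 - 0.5) * 4.7,
                      front_width = rep(100, 100),
                      side_width = rep(100, 100))
  expect_equal(segment_volume(prof, 1, 101), 2500 * pi * 470 / 1000,
               tolerance = 1e-12)
  # a single slice
  expect_equal(segment_volume(prof, 5, 6), 2500 * pi * 4.7 / 1000,
               tolerance = 1e-12)

  # half-open ranges are exactly additive on an irregular profile
  set.seed(11)
  w <- 100 + runif(100, -20, 20)
  prof2 <- leg_profile((1:100 - 0.5) * 4.7, w, 0.9 * w)
  expect_equal(
    segment_volume(prof2, 3, 40) + segment_volume(prof2, 40, 90),
    segment_volume(prof2, 3, 90), tolerance = 1e-13)

  # quadratic scaling in width
  prof3 <- leg_profile((1:100 - 0.5) * 4.7, 2 * w, 1.8 * w)
  expect_equal(segment_volume(prof3, 3, 90),
               4 * segment_volume(prof2, 3, 90), tolerance = 1e-12)

  expect_error(segment_volume(prof, 10, 10), "from_index < to_index")
  expect_error(segment_volume(prof, 50, 200), "from_index < to_index")
})

test_that("landmarks detected on the generator shape match its control points", {
  # ankle min at 120 mm, calf max at 330 mm, knee min at 500 mm, top 800 mm
  prof <- default_profile()
  meas <- measure_leg(prof)
  lm_ <- meas$landmarks
  t <- prof$slice_thickness
  expect_lt(abs(lm_$height_B - 120), t + 1e-9)
  expect_lt(abs(lm_$height_C - 330), t + 1e-9)
  expect_lt(abs(lm_$height_knee - 500), t + 1e-9)
  expect_equal(lm_$index_D, lm_$index_knee - 1L)
  # F: nearest slice to the midpoint of knee height and profile top
  expect_lt(abs(lm_$height_F - (lm_$height_knee + max(prof$heights)) / 2),
            t / 2 + 1e-9)
  expect_true(lm_$index_B < lm_$index_C)
  expect_true(lm_$index_C < lm_$index_D)
  expect_true(lm_$index_D < lm_$index_F)

  # leg_BD equals an independent brute-force re-summation between B and D
  geom <- circumference_profile(prof)
  idx <- seq(lm_$index_B, lm_$index_D - 1L)
  expect_equal(meas$leg_BD, sum(geom$area[idx]) * t / 1000,
               tolerance = 1e-12)
  expect_lt(meas$leg_BD, meas$limb_BF)
})

test_that("landmark detection errors are specific", {
  n <- 60
  h <- (1:n - 0.5) * 4.7
  # monotonically increasing circumference: no ankle minimum exists
  expect_error(detect_landmarks(seq(200, 500, length.out = n), h),
               "no ankle minimum")
  expect_error(detect_landmarks(rep(300, 10), h[1:10]), "at least 20")
})

test_that("equal ankle minima resolve to the lowest index", {
  n <- 80
  h <- (1:n - 0.5) * 4.7
  circ <- numeric(n)
  circ[1:10] <- seq(260, 280, length.out = 10)       # foot bulge
  circ[11:30] <- 220                                  # flat ankle trough
  circ[31:50] <- seq(220, 370, length.out = 20)       # calf rise
  circ[51:60] <- seq(370, 340, length.out = 10)       # fall to knee
  circ[61:80] <- seq(340, 520, length.out = 20)       # thigh
  lm_ <- detect_landmarks(circ, h)
  # the trough is flat from slice 11; 3-slice smoothing reaches the floor at
  # slice 12, every later slice ties and must lose to the lowest index
  expect_equal(lm_$index_B, 12L)
})

test_that("halving the slice thickness changes the integrated volume by < 0.5%", {
  # Riemann-sum convergence on the analytically defined generator shape:
  # same physical column [0, 799 mm], twice the slice resolution
  p1 <- default_profile(4.7)
  p2 <- default_profile(2.35)
  v1 <- segment_volume(p1, 1, length(p1$heights) + 1L)
  v2 <- segment_volume(p2, 1, length(p2$heights) + 1L)
  expect_lt(abs(v2 - v1) / v1, 0.005)
})

test_that("landmarks are stable under 0.5 mm width noise", {
  prof <- default_profile()
  base_vol <- measure_leg(prof)
  base <- base_vol$landmarks
  set.seed(202)
  for (i in 1:5) {
    noisy <- leg_profile(
      prof$heights,
      prof$front_width + rnorm(length(prof$heights), 0, 0.5),
      prof$side_width + rnorm(length(prof$heights), 0, 0.5),
      prof$slice_thickness)
    lm_ <- measure_leg(noisy)$landmarks
    # B and F sit in well-curved regions and barely move; the calf maximum
    # and the knee minimum lie on stretches that are flat to a fraction of
    # the noise SD over several slices, so their location is intrinsically
    # softer — allow one extra slice there
    expect_lte(abs(lm_$index_B - base$index_B), 2L)
    expect_lte(abs(lm_$index_C - base$index_C), 3L)
    expect_lte(abs(lm_$index_D - base$index_D), 3L)
    expect_lte(abs(lm_$index_F - base$index_F), 2L)
  }
})
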