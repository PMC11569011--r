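test_that("trunk inclination recovers tilt from the gravity projection", {
  expect_equal(trunk_inclination(-1, 0, 0), 0)
  expect_equal(trunk_inclination(0, 0, 1), 90)
  g45 <- trunk_gravity(45)
  expect_equal(trunk_inclination(g45["ax"], g45["ay"], g45["az"]), 45,
               tolerance = 1e-12)
  # round trip over the physical range, noise-free, to 1e-9 degrees
  alpha <- seq(0, 80, by = 0.5)
  g <- vapply(alpha, trunk_gravity, numeric(3))
  expect_lt(max(abs(trunk_inclination(g[1, ], g[2, ], g[3, ]) - alpha)), 1e-9)
  expect_error(trunk_inclination(0, 0, 0), "zero-magnitude")
  expect_true(is.na(trunk_inclination(0, 0, 0, zero = "na")))
})

test_that("leg inclination is signed and antisymmetric", {
  expect_equal(leg_inclination(-1, 0, 0), 0)
  g10 <- leg_gravity(10)
  expect_equal(unname(leg_inclination(g10["ax"], g10["ay"], g10["az"])), 10,
               tolerance = 1e-12)
  gm10 <- leg_gravity(-10)
  expect_equal(unname(leg_inclination(gm10["ax"], gm10["ay"], gm10["az"])),
               -10, tolerance = 1e-12)
  alpha <- seq(-60, 60, by = 1)
  g <- vapply(alpha, leg_gravity, numeric(3))
  phi <- leg_inclination(g[1, ], g[2, ], g[3, ])
  expect_lt(max(abs(phi - alpha)), 1e-9)
  expect_lt(max(abs(phi + rev(phi))), 1e-9)  # mirror symmetry
})

test_that("the perpendicular spine model is the printed affine map", {
  expect_equal(ca_perpendicular(0, 0), 0.3856)
  expect_equal(ca_perpendicular(10, 10), 10.3856)
  expect_equal(ca_perpendicular(20, 0), 0.3856 + 0.4542 * 20)
  # coefficients sum to one: equal inputs add only the intercept
  x <- seq(-20, 60, by = 2.5)
  expect_equal(ca_perpendicular(x, x) - x, rep(0.3856, length(x)))
  # monotone increasing in each argument
  expect_true(all(diff(ca_perpendicular(x, 5)) > 0))
  expect_true(all(diff(ca_perpendicular(5, x)) > 0))
})

test_that("knee angle follows the interior-angle relation", {
  expect_equal(knee_angle(0, 0), 180)
  expect_equal(knee_angle(30, 0), 150)
  expect_equal(knee_angle(10, -10), 180)
  # the oracle confirms 180 means collinear segments
  o <- leg_oracle(10, -10, 0.45, 0.45)
  expect_equal(o$theta, 180, tolerance = 1e-9)
})

test_that("leg angle matches hand geometry on worked postures", {
  a <- anthropometry(0.45, 0.45)
  straight <- leg_angle(0, 0, a)
  expect_equal(straight$phi_leg, 0)
  expect_equal(straight$h, 0.90)
  tilted <- leg_angle(10, -10, a)
  expect_equal(tilted$phi_leg, 10, tolerance = 1e-9)
  expect_equal(tilted$h, 0.90, tolerance = 1e-12)
  bent <- leg_angle(30, 0, a)
  expect_equal(bent$theta, 150)
  expect_equal(bent$h, 0.8693, tolerance = 1e-4)
  expect_equal(bent$phi_leg, 15, tolerance = 1e-6)
  expect_equal(bent$z_u, 0.45 * cos(30 * pi / 180), tolerance = 1e-12)
})

test_that("leg angle agrees with the brute-force forward-kinematics oracle", {
  set.seed(11)
  n <- 600
  u <- runif(n, 0.3, 0.6); l <- runif(n, 0.3, 0.6)
  phi_th <- runif(n, -60, 60); phi_sh <- runif(n, -60, 60)
  keep <- knee_angle(phi_th, phi_sh) > 90 & knee_angle(phi_th, phi_sh) <= 180
  for (i in which(keep)) {
    got <- leg_angle(phi_th[i], phi_sh[i], anthropometry(u[i], l[i]))
    want <- leg_oracle(phi_th[i], phi_sh[i], u[i], l[i])
    expect_lt(abs(got$phi_leg - want$phi_leg), 1e-9)
    expect_lt(abs(got$h - want$h), 1e-12)
    expect_lt(abs(got$theta - want$theta), 1e-7)
  }
})

test_that("collinear thigh and shank reduce to the common tilt", {
  for (tilt in seq(-50, 50, by = 5)) {
    for (dims in list(c(0.40, 0.40), c(0.35, 0.5))) {
      got <- leg_angle(tilt, -tilt, anthropometry(dims[1], dims[2]))
      expect_lt(abs(got$phi_leg - tilt), 1e-9)
      expect_equal(got$h, sum(dims), tolerance = 1e-12)
    }
  }
})

test_that("physically invalid knee angles are masked, not propagated", {
  a <- anthropometry(0.45, 0.45)
  res <- leg_angle(c(0, 100, -100), c(0, 90, -95), a)  # theta -10, 375
  expect_equal(res$valid, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(res$phi_leg[!res$valid])))
  # hyperextension just past 180 stays valid (straight-leg jitter)
  eps <- leg_angle(0.1, -0.2, a)
  expect_true(eps$valid)
})

test_that("malleolus composition is an exact sum with a strict cutoff", {
  expect_equal(ca_malleolus(20, 10), 30)
  expect_equal(ca_malleolus(15, -5), 10)
  expect_equal(ca_malleolus(0.3856, 0), 0.3856)
  set.seed(3)
  per <- runif(200, -10, 60); leg <- runif(200, -20, 20)
  expect_identical(ca_malleolus(per, leg) - per - leg, rep(0, 200))
  expect_false(classify_camptocormia(30.0))
  expect_true(classify_camptocormia(30.1))
  expect_false(any(classify_camptocormia(rep(0, 50))))
  expect_error(classify_camptocormia(10, threshold = -1), ">= 0")
})

test_that("inclination-to-CA chain masks low-confidence samples", {
  rec <- make_constant_recording(n = 256, trunk_deg = 20, th_deg = 5,
                                 sh_deg = -5)
  ch <- rec$channels
  ch[10, c("C7_ax", "C7_ay", "C7_az")] <- 0.1 * ch[10, c("C7_ax", "C7_ay", "C7_az")]
  rec <- accel_recording(ch)
  incl <- compute_inclinations(rec)
  expect_false(incl$valid$phi_c7[10])
  s <- compute_camptocormia(incl, anthropometry(0.45, 0.45))
  expect_false(s$valid[10])
  ok <- s$valid
  expect_equal(s$ca_mal[ok], s$ca_per[ok] + s$phi_leg[ok])
  expect_equal(unique(round(s$ca_per[ok], 6)), round(ca_perpendicular(20, 20), 6))
})

test_that("per-sensor axis flips recover upside-down mountings", {
  rec <- make_constant_recording(n = 16, trunk_deg = 20)
  flipped <- rec$channels
  for (a in c("ax", "ay", "az"))
    flipped[[paste0("C7_", a)]] <- -flipped[[paste0("C7_", a)]]
  incl <- compute_inclinations(accel_recording(flipped),
                               flip = c(C7 = -1))
  expect_equal(incl$angles$phi_c7, rep(20, 16), tolerance = 1e-9)
})
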