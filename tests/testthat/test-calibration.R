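make_inclination_set <- function(angles, rate = 128) {
  n <- nrow(angles)
  structure(list(time_s = (seq_len(n) - 1) / rate,
                 angles = angles,
                 valid = as.data.frame(lapply(angles, function(x) rep(TRUE, n))),
                 sample_rate = rate),
            class = "inclination_set")
}

test_that("zero calibration averages the upright window and re-zeroes channels", {
  n <- 128 * 70
  angles <- data.frame(phi_c7 = rep(3, n), phi_l5 = rep(5, n),
                       phi_th = rep(1, n), phi_sh = rep(-1, n))
  incl <- make_inclination_set(angles)
  cal <- zero_calibrate(incl)
  expect_equal(unname(cal$zero_refs["phi_l5"]), 5)
  out <- apply_calibration(incl, cal)
  expect_equal(out$angles$phi_l5, rep(0, n))
  expect_equal(out$angles$phi_c7, rep(0, n))
})

test_that("zero calibration recovers a noisy reference within 3 sigma over root n", {
  set.seed(21)
  n <- 128 * 60
  sigma <- 0.8
  angles <- data.frame(phi_c7 = 3 + rnorm(n, 0, sigma),
                       phi_l5 = 5 + rnorm(n, 0, sigma),
                       phi_th = rnorm(n, 0, sigma),
                       phi_sh = rnorm(n, 0, sigma))
  cal <- zero_calibrate(make_inclination_set(angles), c(0, 59.5))
  expect_lt(abs(cal$zero_refs[["phi_c7"]] - 3), 3 * sigma / sqrt(n))
  expect_lt(abs(cal$zero_refs[["phi_th"]] - 0), 3 * sigma / sqrt(n))
})

test_that("zero calibration rejects bad windows", {
  angles <- data.frame(phi_c7 = rep(1, 128 * 30), phi_l5 = rep(1, 128 * 30),
                       phi_th = rep(0, 128 * 30), phi_sh = rep(0, 128 * 30))
  incl <- make_inclination_set(angles)
  expect_error(zero_calibrate(incl, c(0, 60)), "not covered")
  expect_error(zero_calibrate(incl, c(0, 3)), "at least 5 s")
  incl$valid$phi_c7[1:(128 * 20)] <- FALSE
  expect_error(zero_calibrate(incl, c(0, 25)), "low-confidence")
})

test_that("patient-specific calibration shifts CA by photo minus measured", {
  cal <- patient_specific_calibrate(28, 38, 30, 40)
  expect_equal(cal$offset_per, 2)
  expect_equal(cal$offset_mal, 2)
  expect_equal(patient_specific_calibrate(28, 38, 28, 38)$offset_per, 0)
  n <- 100
  s <- structure(list(time_s = (0:(n - 1)) / 128,
                      ca_per = rep(28, n), phi_leg = rep(10, n),
                      ca_mal = rep(38, n), theta = rep(180, n),
                      valid = rep(TRUE, n), sample_rate = 128,
                      calibration = list(applied = character(0))),
                 class = "camptocormia_series")
  out <- apply_calibration(s, cal)
  expect_equal(out$ca_per, rep(30, n))
  expect_equal(out$ca_mal, rep(40, n))
  # corrected CA over the calibration window equals the photo angle exactly
  expect_equal(mean(out$ca_per), 30, tolerance = 1e-9)
  # applying the same method twice is refused
  expect_error(apply_calibration(out, cal), "already applied")
})

test_that("offset_leg is the mean L5-vs-IC gap and recovers constructions", {
  t <- (0:999) / 100
  ic <- angle_series(t, rep(12, 1000), label = "phi_leg_ref_ic")
  l5 <- angle_series(t, rep(12, 1000) + 7, label = "phi_leg_ref_l5")
  expect_equal(estimate_offset_leg(l5, ic, c(0, 10)), 7)
  # coincident reference points: zero offset
  expect_equal(estimate_offset_leg(ic, ic, c(0, 10)), 0)
  # constant bias b comes back exactly
  b <- -2.25
  l5b <- angle_series(t, ic$angle + b)
  expect_equal(estimate_offset_leg(l5b, ic, c(2, 8)), b)
  expect_error(estimate_offset_leg(l5, ic, c(20, 30)), "no valid samples")
})

test_that("offset_leg from synthetic marker geometry reproduces the built-in gap", {
  truth <- generate_truth(short_script(), rate = 64)
  mk <- project_markers(truth, anthropometry(0.45, 0.45),
                        body_dimensions(l5_gap_deg = 7))
  ref <- compute_reference_angles(mk)
  l5 <- angle_series(ref$time_s, ref$phi_leg_ref_l5)
  ic <- angle_series(ref$time_s, ref$phi_leg_ref_ic)
  # forward-lean block (leg tilted 5 deg anterior), static frames
  expect_lt(abs(estimate_offset_leg(l5, ic, c(14, 19)) - 7), 1e-9)
})

test_that("calibration guards contradictory offset configurations", {
  expect_error(calibration_state(offset_leg = 7, offset_mal = 2),
               "double-corrects")
  expect_error(calibration_state(offset_per = NaN), "finite")
})

test_that("shifting both series leaves RMSE unchanged (translation invariance)", {
  t <- (0:499) / 128
  seg <- activity_segments("walking", 0, 4)
  a <- angle_series(t, sin(t) * 10)
  b <- angle_series(t, sin(t) * 10 + rnorm(500, 0, 0.5))
  r1 <- rmse_by_activity(a, b, seg, sample_wise = TRUE)
  a2 <- angle_series(t, a$angle + 2); b2 <- angle_series(t, b$angle + 2)
  r2 <- rmse_by_activity(a2, b2, seg, sample_wise = TRUE)
  expect_equal(r1$overall$rmse, r2$overall$rmse, tolerance = 1e-12)
})
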