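test_that("truth generation inverts the spine model and leg geometry", {
  # trunk at exactly the model intercept: zero trunk inclinations
  s <- posture_script(list(
    posture_block("standing_upright", 5, trunk = traj_constant(0.3856))),
    transition_s = 0)
  tr <- generate_truth(s, rate = 32)
  expect_lt(max(abs(tr$phi_l5)), 1e-12)
  expect_lt(max(abs(tr$phi_c7)), 1e-12)
  # straight-leg block: thigh and shank antisymmetric
  s2 <- posture_script(list(
    posture_block("standing_forward_lean", 5, trunk = traj_constant(20),
                  leg = traj_constant(10))), transition_s = 0)
  tr2 <- generate_truth(s2, rate = 32)
  expect_equal(tr2$phi_th, rep(10, nrow(tr2)))
  expect_equal(tr2$phi_sh, rep(-10, nrow(tr2)))
  expect_equal(tr2$phi_leg_true, rep(10, nrow(tr2)), tolerance = 1e-9)
  # the generated inclinations satisfy the spine model exactly
  expect_lt(max(abs(ca_perpendicular(tr2$phi_l5, tr2$phi_c7) -
                    tr2$ca_per_true)), 1e-9)
  expect_equal(tr2$ca_mal_true, tr2$ca_per_true + tr2$phi_leg_true)
})

test_that("sinusoidal trunk blocks reach the prescribed extremes", {
  s <- posture_script(list(
    posture_block("parkinsonian_gait", 40,
                  trunk = traj_sine(20, 10, 0.1))), transition_s = 0)
  tr <- generate_truth(s, rate = 64)
  expect_equal(max(tr$ca_per_true), 30, tolerance = 1e-3)
  expect_equal(min(tr$ca_per_true), 10, tolerance = 1e-3)
  expect_equal(mean(tr$ca_per_true), 20, tolerance = 1e-3)
})

test_that("infeasible scripts fail naming the offending block", {
  s <- posture_script(list(
    posture_block("standing_upright", 5, trunk = traj_constant(2)),
    posture_block("standing_forward_lean", 5, trunk = traj_constant(85))),
    transition_s = 1)
  expect_error(generate_truth(s, rate = 32),
               "beyond 80 deg in block 'standing_forward_lean'")
  s2 <- posture_script(list(
    posture_block("walking", 5, leg = traj_constant(65))), transition_s = 0)
  expect_error(generate_truth(s2, rate = 32), "beyond 60 deg")
})

test_that("a configurable spine ratio still satisfies the spine model", {
  s <- short_script()
  for (rho in c(0.5, 1, 2)) {
    tr <- generate_truth(s, rate = 16, spine_ratio = rho)
    expect_lt(max(abs(ca_perpendicular(tr$phi_l5, tr$phi_c7) -
                      tr$ca_per_true)), 1e-9)
    expect_equal(tr$phi_c7, rho * tr$phi_l5, tolerance = 1e-12)
  }
})

test_that("accelerometer projection realizes the axis conventions", {
  s <- posture_script(list(
    posture_block("standing_upright", 2, trunk = traj_constant(0.3856))),
    transition_s = 0)
  rec <- project_accelerometers(generate_truth(s, rate = 32))
  expect_equal(rec$channels$C7_ax, rep(-1, 64), tolerance = 1e-12)
  expect_equal(rec$channels$C7_ay, rep(0, 64))
  expect_equal(rec$channels$C7_az, rep(0, 64), tolerance = 1e-12)
  s45 <- posture_script(list(
    posture_block("standing_forward_lean", 2,
                  trunk = traj_constant(0.3856 + 45))), transition_s = 0)
  rec45 <- project_accelerometers(generate_truth(s45, rate = 32))
  expect_equal(rec45$channels$L5_ax, rep(-sqrt(2) / 2, 64), tolerance = 1e-9)
  expect_equal(rec45$channels$L5_az, rep(sqrt(2) / 2, 64), tolerance = 1e-9)
})

test_that("noise-free projection round-trips through the kinematics module", {
  truth <- generate_truth(short_script(), rate = 32)
  incl <- compute_inclinations(project_accelerometers(truth))
  expect_lt(max(abs(incl$angles$phi_c7 - truth$phi_c7)), 1e-9)
  expect_lt(max(abs(incl$angles$phi_l5 - truth$phi_l5)), 1e-9)
  expect_lt(max(abs(incl$angles$phi_th - truth$phi_th)), 1e-9)
  expect_lt(max(abs(incl$angles$phi_sh - truth$phi_sh)), 1e-9)
})

test_that("marker projection is consistent with the truth angles", {
  truth <- generate_truth(short_script(), rate = 32)
  mk <- project_markers(truth, anthropometry(0.45, 0.45))
  ref <- compute_reference_angles(mk)
  expect_lt(max(abs(ref$phi_per_ref - truth$ca_per_true)), 1e-6)
  expect_lt(max(abs(ref$phi_leg_ref_ic - abs(truth$phi_leg_true))), 1e-6)
  # upright posture: all reference angles essentially zero
  s0 <- posture_script(list(
    posture_block("standing_upright", 2, trunk = traj_constant(0))),
    transition_s = 0)
  ref0 <- compute_reference_angles(
    project_markers(generate_truth(s0, rate = 32), anthropometry(0.45, 0.45)))
  expect_lt(max(abs(ref0$phi_per_ref)), 1e-9)
  expect_lt(max(abs(ref0$phi_leg_ref_l5)), 1e-9)
})

test_that("generator randomness is reproducible from the seed alone", {
  truth <- generate_truth(short_script(), rate = 32)
  nm <- noise_model(accel_sigma_g = 0.02, marker_sigma_m = 0.002, seed = 99)
  a1 <- project_accelerometers(truth, nm)
  a2 <- project_accelerometers(truth, nm)
  expect_identical(a1$channels, a2$channels)
  m1 <- project_markers(truth, anthropometry(0.45, 0.45), noise = nm)
  m2 <- project_markers(truth, anthropometry(0.45, 0.45), noise = nm)
  expect_identical(m1$coords, m2$coords)
  a3 <- project_accelerometers(truth, noise_model(accel_sigma_g = 0.02,
                                                  seed = 100))
  expect_false(identical(a1$channels$C7_ax, a3$channels$C7_ax))
})

test_that("motion-artifact bursts push samples outside the confidence band", {
  truth <- generate_truth(short_script(), rate = 128)
  nm <- noise_model(burst_amplitude_g = 2, burst_rate_hz = 1, seed = 17)
  rec <- project_accelerometers(truth, nm)
  expect_gt(sum(as.matrix(flag_low_confidence(rec))), 0)
})
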