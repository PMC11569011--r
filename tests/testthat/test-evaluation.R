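test_that("window averaging reduces to the mean of unmasked samples", {
  t <- (0:127) / 128
  const <- window_average(angle_series(t, rep(7.5, 128)), 1.0)
  expect_equal(nrow(const), 1)
  expect_equal(const$angle, 7.5)
  ramp <- window_average(angle_series(t, 0:127), 1.0)
  expect_equal(ramp$angle, 63.5)
  half <- window_average(angle_series(t, 0:127, valid = c(rep(FALSE, 64),
                                                          rep(TRUE, 64))), 1.0)
  expect_equal(half$angle, mean(64:127))
  allmask <- window_average(angle_series(t, 0:127, valid = FALSE), 1.0)
  expect_false(allmask$valid)
  expect_error(window_average(angle_series(t, 0:127), 1 / 400),
               "sample period")
})

test_that("partial trailing windows need half a window of unmasked samples", {
  t <- (0:191) / 128  # 1.5 s
  keep <- window_average(angle_series(t, rep(1, 192)), 1.0)
  expect_equal(nrow(keep), 2)   # 64-sample tail = exactly half, kept
  t2 <- (0:159) / 128           # 1.25 s: 32-sample tail dropped
  drop <- window_average(angle_series(t2, rep(1, 160)), 1.0)
  expect_equal(nrow(drop), 1)
})

test_that("per-activity RMSE pools squared errors and marks empty labels", {
  t <- (0:(128 * 4 - 1)) / 128
  seg <- activity_segments(c("standing_upright", "walking", "other"),
                           c(0, 2, 3.5), c(2, 3.5, 3.6))
  est <- angle_series(t, rep(10, length(t)))
  r0 <- rmse_by_activity(est, est, seg)
  expect_true(all(r0$by_activity$rmse[r0$by_activity$n > 0] == 0))
  # constant difference d gives RMSE |d|
  rd <- rmse_by_activity(angle_series(t, est$angle + 3), est, seg)
  expect_equal(rd$overall$rmse, 3, tolerance = 1e-12)
  # hand-computed two-sample case: differences 3 and 4 -> sqrt(12.5)
  t2 <- c(0, 1 / 128)
  seg2 <- activity_segments("walking", 0, 1)
  r2 <- rmse_by_activity(angle_series(t2, c(3, 4)), angle_series(t2, c(0, 0)),
                         seg2, sample_wise = TRUE)
  expect_equal(r2$overall$rmse, sqrt(12.5), tolerance = 1e-12)
  # empty label reported with n = 0 and undefined RMSE
  seg3 <- activity_segments(c("walking", "parkinsonian_gait"),
                            c(0, 100), c(1, 101))
  r3 <- rmse_by_activity(angle_series(t2, c(3, 4)), angle_series(t2, c(0, 0)),
                         seg3, sample_wise = TRUE)
  pg <- r3$by_activity[r3$by_activity$label == "parkinsonian_gait", ]
  expect_equal(pg$n, 0L)
  expect_true(is.na(pg$rmse))
})

test_that("overall RMSE squared is the count-weighted mean of activity RMSE squares", {
  set.seed(5)
  t <- (0:(128 * 8 - 1)) / 128
  seg <- activity_segments(
    c("standing_upright", "standing_forward_lean", "walking"),
    c(0, 3, 5.5), c(3, 5.5, 8))
  est <- angle_series(t, 20 + rnorm(length(t)))
  ref <- angle_series(t, 20 + rnorm(length(t)))
  for (sw in c(TRUE, FALSE)) {
    r <- rmse_by_activity(est, ref, seg, sample_wise = sw)
    ba <- r$by_activity[r$by_activity$n > 0, ]
    expect_equal(r$overall$rmse^2,
                 sum(ba$n * ba$rmse^2) / sum(ba$n), tolerance = 1e-9)
    expect_equal(r$overall$n, sum(ba$n))
  }
})

test_that("misaligned series are rejected with overlap diagnostics", {
  t <- (0:99) / 128
  a <- angle_series(t, rep(0, 100))
  b <- angle_series(t + 5, rep(0, 100))
  expect_error(rmse_by_activity(a, b, activity_segments("other", 0, 1)),
               "not aligned")
})

test_that("MAD histogram bins by rounded reference angle and conserves counts", {
  t <- (0:999) / 128
  est <- angle_series(t, rep(21.2, 1000))
  ref <- angle_series(t, rep(20.2, 1000))
  h <- mad_histogram(est, ref)
  expect_equal(h$ref_deg, 20L)
  expect_equal(h$mad, 1.0)
  expect_equal(h$n, 1000L)
  # exact per-bin means on a constructed two-bin fixture
  ref2 <- angle_series(t, c(rep(10.4, 600), rep(11.6, 400)))
  est2 <- angle_series(t, ref2$angle + c(rep(0.5, 600), rep(-2, 400)))
  h2 <- mad_histogram(est2, ref2)
  expect_equal(h2$ref_deg, c(10L, 12L))
  expect_equal(h2$mad, c(0.5, 2))
  expect_equal(sum(h2$n), 1000L)
  # identical series: all bins zero
  h0 <- mad_histogram(ref2, ref2)
  expect_true(all(h0$mad == 0))
  # rounding is half away from zero
  hh <- mad_histogram(angle_series(0, 0), angle_series(0, 0.5))
  expect_equal(hh$ref_deg, 1L)
  hn <- mad_histogram(angle_series(0, 0), angle_series(0, -0.5))
  expect_equal(hn$ref_deg, -1L)
})

test_that("evaluation reports serialize to TSV and text", {
  t <- (0:255) / 128
  seg <- activity_segments("walking", 0, 2)
  r <- rmse_by_activity(angle_series(t, rep(1, 256)),
                        angle_series(t, rep(0, 256)), seg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_evaluation_report(r, tsv, txt)
  back <- utils::read.delim(tsv)
  expect_equal(back$rmse[back$label == "all"], 1, tolerance = 1e-12)
  expect_true(any(grepl("RMSE", readLines(txt))))
})
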