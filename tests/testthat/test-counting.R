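test_that("the quartic through five points reproduces them exactly", {
  set.seed(11)
  freqs <- default_band_freqs()
  for (i in 1:30) {
    amps <- runif(5, 0, 80)
    sp <- structure(list(freqs = (0:63) * 20 / 64,
                         amps = replace(numeric(64), 3:7, amps),
                         fs = 20, N = 64L), class = "gyro_spectrum")
    fit <- estimate_walking_frequency(sp)
    co <- fit$coefficients  # a, b, c, d, e (descending powers)
    at <- function(f) co[["a"]] * f^4 + co[["b"]] * f^3 + co[["c"]] * f^2 +
      co[["d"]] * f + co[["e"]]
    for (j in 1:5) {
      expect_equal(at(freqs[j]), amps[j], tolerance = 1e-6)
      # and the whole polynomial equals the Lagrange form everywhere
      expect_equal(at(0.7 + 0.2 * j), lagrange_eval(freqs, amps, 0.7 + 0.2 * j),
                   tolerance = 1e-6)
    }
  }
})

test_that("derivative-root maximisation agrees with dense grid search", {
  set.seed(12)
  freqs <- default_band_freqs()
  worst <- 0
  for (i in 1:200) {
    amps <- runif(5, 0, 50)
    sp <- structure(list(freqs = (0:63) * 20 / 64,
                         amps = replace(numeric(64), 3:7, amps),
                         fs = 20, N = 64L), class = "gyro_spectrum")
    fit <- estimate_walking_frequency(sp)
    oracle <- grid_argmax(freqs, amps, min(freqs), max(freqs))
    worst <- max(worst, abs(fit$f_hat - oracle))
  }
  expect_lte(worst, 2e-4)
})

test_that("a parabolic spectrum is maximised at its vertex", {
  fit <- estimate_walking_frequency(parabola_spectrum(peak = 1.25, height = 4))
  expect_equal(fit$f_hat, 1.25, tolerance = 1e-3)
  expect_false(fit$degenerate)
  fit2 <- estimate_walking_frequency(parabola_spectrum(peak = 1.5, height = 60))
  expect_equal(fit2$f_hat, 1.5, tolerance = 1e-6)
})

test_that("a single-spike spectrum stays within one bin of the walking peak", {
  amps <- numeric(64); amps[5] <- 50  # middle walking-band bin
  sp <- structure(list(freqs = (0:63) * 20 / 64, amps = amps, fs = 20,
                       N = 64L), class = "gyro_spectrum")
  fit <- estimate_walking_frequency(sp)
  expect_lte(abs(fit$f_hat - 0.9375), 0.3125 + 1e-9)
  expect_equal(fit$f_hat,
               grid_argmax(default_band_freqs(), amps[3:7], 0.625, 1.875),
               tolerance = 2e-4)
})

test_that("a flat five-bin spectrum falls back to the central frequency", {
  amps <- numeric(64); amps[3:7] <- 7
  sp <- structure(list(freqs = (0:63) * 20 / 64, amps = amps, fs = 20,
                       N = 64L), class = "gyro_spectrum")
  fit <- estimate_walking_frequency(sp)
  expect_true(fit$degenerate)
  expect_equal(fit$f_hat, 1.25)
})

test_that("frequency smoothing follows the weighted-average recursion", {
  expect_equal(smooth_frequency(1.0, 2.0, alpha = 0.8), 1.2)
  expect_equal(smooth_frequency(NA_real_, 1.5), 1.5)  # initialisation
  f <- NA_real_
  for (i in 1:20) f <- smooth_frequency(f, 1.37, alpha = 0.8)
  expect_equal(f, 1.37)  # constant input is a fixed point
})

test_that("walking windows accumulate duration and steps incrementally", {
  sp <- parabola_spectrum(peak = 1.5, height = 60)  # f_hat = 1.5 exactly
  st <- step_state()
  for (i in 1:50) st <- update_step_count(st, list(is_walking = TRUE), sp)
  expect_equal(st$walking_time, 60)
  expect_equal(st$steps, 90, tolerance = 1e-9)
  expect_equal(st$f_smooth, 1.5)
})

test_that("non-walking windows leave the state untouched", {
  st <- step_state()
  for (i in 1:10) st <- update_step_count(st, list(is_walking = FALSE))
  expect_equal(st$steps, 0)
  expect_equal(st$walking_time, 0)
  expect_true(is.na(st$f_smooth))
})

test_that("the cadence persists across gaps unless reset_on_gap triggers", {
  sp <- parabola_spectrum(peak = 1.4)
  st <- update_step_count(step_state(), list(is_walking = TRUE), sp)
  for (i in 1:5) st <- update_step_count(st, list(is_walking = FALSE))
  expect_equal(st$f_smooth, 1.4)  # default: never reset
  st2 <- update_step_count(step_state(counting_config(reset_on_gap = 3)),
                           list(is_walking = TRUE), sp)
  for (i in 1:3) st2 <- update_step_count(st2, list(is_walking = FALSE))
  expect_true(is.na(st2$f_smooth))
})

test_that("step count is non-decreasing along any trace", {
  res <- generate_trace(scripted_scenarios()$intermittent_walk, seed = 21)
  ct <- count_trace(res$trace)
  expect_true(all(diff(ct$log$steps) >= 0))
  expect_true(all(diff(ct$log$walking_time) >= 0))
})

test_that("appending still time changes the count only by edge effects", {
  walk <- activity_script(walk_bout(60, 1.25))
  both <- activity_script(walk_bout(60, 1.25), still_bout(30))
  c1 <- gyrostep(generate_trace(walk, seed = 31)$trace)$state$steps
  c2 <- gyrostep(generate_trace(both, seed = 31)$trace)$state$steps
  # at most two windows' worth of steps (2 slides at ~2 Hz)
  expect_lt(abs(c2 - c1), 2 * 1.2 * 2)
})

test_that("a zeros trace counts zero steps", {
  tr <- gyro_trace(wx = numeric(400), wy = numeric(400), wz = numeric(400),
                   fs = 20)
  ct <- count_trace(tr)
  expect_equal(ct$state$steps, 0)
  expect_equal(ct$state$walking_time, 0)
})

test_that("steps on a 120 s constant-cadence walk land within 5% of truth", {
  res <- generate_trace(activity_script(walk_bout(120, 1.25)), seed = 41)
  fit <- gyrostep(res$trace)
  expect_equal(res$true_steps, 150)
  expect_lt(abs(fit$steps - 150) / 150, 0.05)
})

test_that("cadence estimates agree with the grid-search oracle per window", {
  # the pipeline's guarantee is faithfulness to the quartic maximiser, not
  # unbiasedness: check f_hat against the independent oracle on noisy walks
  res <- generate_trace(activity_script(
    walk_bout(30, 1.0, noise_sd = walk_noise_for_snr(10))), seed = 51)
  ws <- iter_windows(res$trace)
  freqs <- default_band_freqs()
  for (w in ws[c(1, 8, 15)]) {
    sp <- compute_spectrum(w$samples[, select_sensitive_axis(w)], 20)
    fit <- estimate_walking_frequency(sp)
    expect_equal(fit$f_hat, grid_argmax(freqs, sp$amps[3:7], 0.625, 1.875),
                 tolerance = 2e-4)
  }
})

test_that("intermittent walking at two cadences lands within 7% of truth", {
  res <- generate_trace(scripted_scenarios()$intermittent_walk, seed = 61)
  fit <- gyrostep(res$trace)
  expect_equal(res$true_steps, 156)
  expect_lt(abs(fit$steps - 156) / 156, 0.07)
})
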