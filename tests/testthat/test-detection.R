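test_that("sensitive-axis selection matches the absolute-sum oracle", {
  set.seed(101)
  for (i in 1:50) {
    m <- matrix(rnorm(64 * 3), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
    oracle <- c("x", "y", "z")[which.max(c(sum(abs(m[, 1])), sum(abs(m[, 2])),
                                           sum(abs(m[, 3])))) ]
    expect_identical(select_sensitive_axis(m), oracle)
  }
})

test_that("axis dominance, sign flips and ties behave as specified", {
  base <- sin(2 * pi * 1.25 * (0:63) / 20)
  m <- cbind(x = base, y = 2 * base, z = base)
  expect_identical(select_sensitive_axis(m), "y")
  # invariant to flipping the sign of any axis
  expect_identical(select_sensitive_axis(m %*% diag(c(-1, 1, 1))), "y")
  expect_identical(select_sensitive_axis(m %*% diag(c(1, -1, 1))), "y")
  # all-zero window: deterministic tie-break to x
  expect_identical(select_sensitive_axis(matrix(0, 64, 3)), "x")
})

test_that("spectrum of a constant signal is DC-only with amplitude N*|c|", {
  sp <- compute_spectrum(rep(-0.5, 64), 20)
  expect_equal(sp$amps[1], 32)
  expect_lt(max(sp$amps[-1]), 1e-10)
  expect_equal(sp$freqs, (0:63) * 20 / 64)
})

test_that("an on-bin sinusoid concentrates in its bin and mirror at N/2*A", {
  A <- 1.7
  x <- A * sin(2 * pi * 0.9375 * (0:63) / 20)  # bin 3 at fs = 20, N = 64
  sp <- compute_spectrum(x, 20)
  expect_equal(sp$freqs[4], 0.9375)
  expect_equal(sp$amps[4], 32 * A, tolerance = 1e-9)
  expect_equal(sp$amps[62], 32 * A, tolerance = 1e-9)
  expect_lt(max(sp$amps[-c(4, 62)]), 1e-9)
})

test_that("the FFT path agrees with a naive DFT to 1e-9 relative", {
  set.seed(202)
  for (N in c(8, 16, 32, 64)) {
    x <- rnorm(N)
    sp <- compute_spectrum(x, 20)
    oracle <- naive_dft_amps(x)
    expect_equal(sp$amps, oracle, tolerance = 1e-9)
  }
})

test_that("spectrum magnitudes are Nyquist-symmetric and satisfy Parseval", {
  set.seed(303)
  x <- rnorm(64)
  sp <- compute_spectrum(x, 20)
  expect_equal(sp$amps[2:64], rev(sp$amps[2:64]), tolerance = 1e-9)
  expect_equal(sum(x^2), sum(sp$amps^2) / 64, tolerance = 1e-9)
})

test_that("non-power-of-2 lengths are refused", {
  expect_error(compute_spectrum(rnorm(60), 20), "power of 2")
})

test_that("band means: uniform spectrum, single-bin spectrum, bin count", {
  cfg <- detection_config()
  sp <- structure(list(freqs = (0:63) * 20 / 64, amps = rep(1, 64),
                       fs = 20, N = 64L), class = "gyro_spectrum")
  bm <- band_mean_amplitudes(sp, cfg)
  expect_equal(unname(bm), c(1, 1))
  # all 50 at 0-based bin 3 -> averaged over the five walking-band bins
  amps <- numeric(64); amps[4] <- 50
  sp2 <- structure(list(freqs = sp$freqs, amps = amps, fs = 20, N = 64L),
                   class = "gyro_spectrum")
  bm2 <- band_mean_amplitudes(sp2, cfg)
  expect_equal(unname(bm2), c(10, 0))
  # exactly five bins in the walking band, one in the sub-walking band
  expect_equal(sum(sp$freqs[1:33] >= 0.6 & sp$freqs[1:33] <= 2), 5)
})

test_that("include_dc folds bin 0 into the sub-walking average", {
  amps <- numeric(64); amps[1] <- 64  # pure DC
  sp <- structure(list(freqs = (0:63) * 20 / 64, amps = amps, fs = 20,
                       N = 64L), class = "gyro_spectrum")
  expect_equal(band_mean_amplitudes(sp, detection_config())[["omega_0"]], 0)
  expect_equal(band_mean_amplitudes(
    sp, detection_config(include_dc = TRUE))[["omega_0"]], 32)
})

test_that("empty bands under a custom config raise a config error", {
  sp <- compute_spectrum(rnorm(64), 20)
  expect_error(band_mean_amplitudes(sp, detection_config(band_walk = c(1.9, 1.95))),
               "band_walk")
})

test_that("the decision rule requires both conditions strictly", {
  cfg <- detection_config()
  expect_true(detect_walking(15, 5, cfg))
  expect_false(detect_walking(15, 20, cfg))   # band dominance fails
  expect_false(detect_walking(8, 2, cfg))     # threshold fails
  expect_false(detect_walking(10, 2, cfg))    # ties are non-walking
  expect_false(detect_walking(15, 15, cfg))
})

test_that("band dominance is scale-invariant and the decision is monotone", {
  set.seed(404)
  cfg <- detection_config()
  for (i in 1:25) {
    x <- rnorm(64, sd = runif(1, 0.1, 5))
    sp <- compute_spectrum(x, 20)
    bm <- band_mean_amplitudes(sp, cfg)
    for (c_scale in c(0.01, 0.5, 3, 100)) {
      bms <- band_mean_amplitudes(compute_spectrum(c_scale * x, 20), cfg)
      expect_equal(sign(bms[["omega_c"]] - bms[["omega_0"]]),
                   sign(bm[["omega_c"]] - bm[["omega_0"]]))
    }
    if (detect_walking(bm[["omega_c"]], bm[["omega_0"]], cfg)) {
      bup <- band_mean_amplitudes(compute_spectrum(10 * x, 20), cfg)
      expect_true(detect_walking(bup[["omega_c"]], bup[["omega_0"]], cfg))
    }
  }
})

test_that("a sustained synthetic walk is detected in every window", {
  res <- generate_trace(activity_script(walk_bout(60, 1.25, noise_sd = 0)),
                        seed = 1)
  det <- detect_trace(res$trace)
  expect_true(all(det$records$is_walking))
  # cross-check one window against the band-mean oracle
  w <- iter_windows(res$trace)[[5]]
  sp <- compute_spectrum(w$samples[, select_sensitive_axis(w)], 20)
  bm <- band_mean_amplitudes(sp)
  expect_gt(bm[["omega_c"]], 10)
  expect_gt(bm[["omega_c"]], bm[["omega_0"]])
})

test_that("an all-zero trace yields no walking windows and one segment", {
  tr <- gyro_trace(wx = numeric(1200), wy = numeric(1200),
                   wz = numeric(1200), fs = 20)
  det <- detect_trace(tr)
  expect_false(any(det$records$is_walking))
  expect_equal(nrow(det$segments), 1)
  expect_identical(det$segments$label, "non_walking")
})

test_that("walk then still yields two merged runs with a near-30 s boundary", {
  res <- generate_trace(activity_script(walk_bout(30, 1.25), still_bout(30)),
                        seed = 4)
  det <- detect_trace(res$trace)
  expect_equal(det$segments$label, c("walking", "non_walking"))
  boundary <- det$segments$end[1]
  # detection trails the true boundary by at most two slides (strong
  # walking energy keeps part-walk windows classified as walking)
  expect_lt(abs(boundary - 30), 2 * 1.2 + 1e-9)
})

test_that("placement-switch bursts are never classified as walking", {
  for (s in c(1, 7, 13)) {
    res <- generate_trace(activity_script(still_bout(10), switch_bout(6),
                                          still_bout(10)), seed = s)
    det <- detect_trace(res$trace)
    expect_false(any(det$records$is_walking))
  }
})
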