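# Noise calibration, Butterworth band-pass, vest sampling.

test_that("add_noise calibrates the requested SNR", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  clean <- rbind(sin(2 * pi * 7 * t), 0.3 * sin(2 * pi * 11 * t + 1))
  noisy <- add_noise(clean, 20, rng_seed = 21)
  snr <- measure_snr(clean, noisy$potentials)
  expect_gt(snr, 19.9)
  expect_lt(snr, 20.1)
  # per-electrode calibration
  for (e in 1:2) {
    se <- measure_snr(clean[e, , drop = FALSE],
                      noisy$potentials[e, , drop = FALSE])
    expect_lt(abs(se - 20), 0.3)
  }
  # determinism and NULL passthrough
  n2 <- add_noise(clean, 20, rng_seed = 21)
  expect_identical(noisy$potentials, n2$potentials)
  expect_identical(add_noise(clean, NULL)$potentials, clean)
  clean0 <- clean; clean0[1, ] <- 0
  expect_error(add_noise(clean0, 20), "all-zero")
})

test_that("noise calibration holds across repetitions (stochastic)", {
  fs <- 500
  t <- (0:(5 * fs - 1)) / fs
  clean <- matrix(sin(2 * pi * 9 * t), 1)
  snrs <- vapply(1:20, function(r)
    measure_snr(clean, add_noise(clean, 15, rng_seed = 100 + r)$potentials),
    numeric(1))
  expect_lt(max(abs(snrs - 15)), 0.3)
  expect_lt(abs(mean(snrs) - 15), 0.1)
})

test_that("Butterworth band edges sit at -3 dB (single pass)", {
  flt <- butter_bandpass(4, 3, 30, 500)
  resp_db <- 20 * log10(filter_response(flt, c(3, 30)))
  expect_lt(max(abs(resp_db + 3)), 0.2)
  expect_lt(filter_response(flt, 0), 1e-9)        # DC rejected
  expect_error(butter_bandpass(4, 3, 260, 500), "Nyquist")
})

test_that("measured pass-band gain matches the analog prototype oracle", {
  # oracle: analog Butterworth band-pass magnitude at the pre-warped
  # frequency, |H| = 1/sqrt(1 + ((w^2 - w0^2)/(bw w))^(2n))
  fs <- 500
  flt <- butter_bandpass(4, 3, 30, fs)
  analog_mag <- function(f_hz) {
    warp <- function(f) 2 * fs * tan(pi * f / fs)
    w <- warp(f_hz); w1 <- warp(3); w2 <- warp(30)
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    1 / sqrt(1 + ((w^2 - w0^2) / (bw * w))^(2 * 4))
  }
  t <- (0:(20 * fs - 1)) / fs
  for (f in c(8, 15, 24)) {
    x <- sin(2 * pi * f * t)
    y <- filter_apply(flt, x)
    amp <- max(abs(y[(5 * fs):(15 * fs)]))   # steady-state interior
    expect_lt(abs(amp - analog_mag(f)) / analog_mag(f), 0.01)
  }
})

test_that("constant offset is annihilated and filtering is linear", {
  flt <- butter_bandpass(4, 3, 30, 500)
  dc <- rep(4.2, 3000)
  y <- filtfilt_apply(flt, dc)
  expect_lt(max(abs(y[500:2500])), 1e-6 * 4.2)
  set.seed(1)
  a <- rnorm(2000); b <- rnorm(2000)
  lhs <- filtfilt_apply(flt, 2 * a - 3 * b)
  rhs <- 2 * filtfilt_apply(flt, a) - 3 * filtfilt_apply(flt, b)
  # linear by construction; the bound reflects round-off accumulation in
  # the IIR recursion (poles near the unit circle), not a design limit
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-7)
})

test_that("bandpass_filter preserves shape and records provenance", {
  set.seed(2)
  x <- matrix(rnorm(4 * 1000), 4)
  bsp <- afdriverloc:::new_bsp_recording(x, 500)
  out <- bandpass_filter(bsp)
  expect_equal(dim(out$potentials), dim(x))
  expect_equal(out$filter$order, 4)
  expect_equal(out$fs, 500)
})

test_that("sample_vest selects 64 channels in canonical order", {
  torso <- small_torso()
  E <- nrow(torso$electrode_coords)
  x <- matrix(seq_len(E * 3), E)   # trace value identifies the electrode
  vest <- sample_vest(afdriverloc:::new_bsp_recording(x, 500),
                      torso$electrode_table)
  expect_equal(nrow(vest$potentials), 64L)
  expect_equal(vest$channels$panel[1:24], rep("front", 24))
  expect_equal(vest$channels$panel[25:48], rep("back", 24))
  expect_equal(vest$channels$panel[49:64],
               rep(c("side_left", "side_right"), each = 8))
  # identity: channel k equals the mapped electrode's trace exactly
  for (k in c(1, 30, 64))
    expect_identical(vest$potentials[k, ], x[vest$channels$index[k], ])
  # broken tables are rejected
  bad <- torso$electrode_table
  bad$in_vest[which(bad$in_vest)[1]] <- FALSE
  expect_error(sample_vest(x, bad), "64")
  dup <- torso$electrode_table
  dup$index[which(dup$in_vest)[2]] <- dup$index[which(dup$in_vest)[1]]
  expect_error(sample_vest(x, dup), "duplicate")
})
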