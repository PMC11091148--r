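test_that("synthetic ECG has the implied sample count and is seeded", {
  spec <- synthetic_ecg_spec(fs = 500, duration = 20, heart_rate = 60,
                             seed = 1)
  x <- generate_synthetic_ecg(spec)
  expect_s3_class(x, "signal1d")
  expect_length(x, 10000L)
  expect_equal(sig_fs(x), 500)

  spec72 <- synthetic_ecg_spec(fs = 500, duration = 20, heart_rate = 72,
                               seed = 1)
  expect_identical(as.numeric(generate_synthetic_ecg(spec72)),
                   as.numeric(generate_synthetic_ecg(spec72)))
})

test_that("noiseless ECG is exactly periodic at the beat period", {
  spec <- synthetic_ecg_spec(fs = 500, duration = 5, heart_rate = 60,
                             baseline_noise_sd = 0, seed = NULL)
  x <- as.numeric(generate_synthetic_ecg(spec))
  interior <- 300:1800  # away from record edges; period = 1 s = 500 samples
  expect_lt(max(abs(x[interior] - x[interior + 500L])), 1e-9)
})

test_that("ECG spec validation rejects degenerate parameters", {
  expect_error(synthetic_ecg_spec(fs = 500, duration = 0.0011),
               "integer")
  expect_error(synthetic_ecg_spec(heart_rate = 0), "heart_rate")
  wp <- default_wave_params(); wp$width[2] <- 0
  expect_error(synthetic_ecg_spec(wave_params = wp), "width")
})

test_that("synthetic audio is zero-mean, seeded, and independent of the ECG", {
  a1 <- generate_synthetic_audio(10000, fs = 500, seed = 7)
  a2 <- generate_synthetic_audio(10000, fs = 500, seed = 7)
  expect_identical(as.numeric(a1), as.numeric(a2))
  expect_length(a1, 10000L)
  expect_lt(abs(mean(as.numeric(a1))) / sd(as.numeric(a1)), 1e-6)
  expect_error(generate_synthetic_audio(1), "n must be >= 2")

  ecg <- generate_synthetic_ecg(synthetic_ecg_spec(seed = 1))
  expect_lt(abs(cor(as.numeric(ecg), as.numeric(a1))), 0.1)
})

test_that("AWGN injection hits the target SNR and preserves metadata", {
  x <- generate_synthetic_ecg(synthetic_ecg_spec(fs = 500, duration = 200,
                                                 seed = 3))  # n = 1e5
  for (snr in c(10, 0)) {
    y <- add_awgn(x, snr_db = snr, seed = 11)
    expect_length(y, length(x))
    expect_equal(sig_fs(y), sig_fs(x))
    noise <- as.numeric(y) - as.numeric(x)
    realized <- 10 * log10(mean(as.numeric(x)^2) / mean(noise^2))
    expect_lt(abs(realized - snr), 0.2)
  }
  # 0 dB: noise power within 5% of signal power
  noise0 <- as.numeric(add_awgn(x, 0, seed = 11)) - as.numeric(x)
  expect_lt(abs(mean(noise0^2) / mean(as.numeric(x)^2) - 1), 0.05)
  # zero-noise limit and degenerate input
  expect_identical(add_awgn(x, Inf), x)
  expect_error(add_awgn(signal1d(c(0, 0, 0), 500), 10), "zero power")
})

test_that("notch filter removes the powerline tone and passes DC and 5 Hz", {
  fs <- 500
  t <- (0:4999) / fs
  mains <- signal1d(sin(2 * pi * 50 * t), fs)
  out <- as.numeric(notch_filter(mains, f0 = 50, q_factor = 30))
  steady <- 2500:5000  # past the transient
  expect_lt(sqrt(mean(out[steady]^2)), 0.05 * sqrt(mean(sin(2 * pi * 50 * t[steady])^2)))

  dc <- signal1d(rep(1, 2000), fs)
  out_dc <- as.numeric(notch_filter(dc, 50, 30))
  expect_lt(max(abs(out_dc[1000:2000] - 1)), 0.01)

  slow <- signal1d(sin(2 * pi * 5 * t), fs)
  out_slow <- as.numeric(notch_filter(slow, 50, 30))
  rms_ratio <- sqrt(mean(out_slow[steady]^2)) / sqrt(mean(sin(2 * pi * 5 * t[steady])^2))
  expect_lt(abs(rms_ratio - 1), 0.05)

  expect_error(notch_filter(mains, f0 = 300), "fs/2")
  expect_error(notch_filter(mains, f0 = 0), "fs/2")
})

test_that("match_lengths truncates to the shorter signal without editing values", {
  a <- signal1d(1:10000, 500); b <- signal1d(1:8000, 500)
  m <- match_lengths(a, b)
  expect_length(m$a, 8000L)
  expect_length(m$b, 8000L)
  expect_identical(as.numeric(m$a), as.numeric(a)[1:8000])

  m2 <- match_lengths(a, a)
  expect_identical(m2$a, a)

  m3 <- match_lengths(signal1d(c(1, 2, 3, 4, 5), 1), signal1d(c(9, 8, 7), 1))
  expect_identical(as.numeric(m3$a), c(1, 2, 3))
  expect_identical(as.numeric(m3$b), c(9, 8, 7))
})

test_that("signal1d validates its invariants", {
  expect_error(signal1d(1, 500), "at least 2")
  expect_error(signal1d(c(1, NA), 500), "finite")
  expect_error(signal1d(c(1, 2), -1), "positive")
  tb <- tibble::as_tibble(signal1d(c(1, 2, 3), fs = 2))
  expect_equal(tb$time, c(0, 0.5, 1))
})
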