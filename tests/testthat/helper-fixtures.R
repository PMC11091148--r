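# fixture builders shared across the suite; everything is generated in code

white_pair <- function(n, seed, fs = 500) {
  withr::with_seed(seed, {
    list(s1 = signal1d(rnorm(n), fs), s2 = signal1d(rnorm(n), fs))
  })
}

ecg_audio_pair <- function(n = 10000L, fs = 500, ecg_seed = 1L,
                           audio_seed = 7L) {
  list(
    ecg = generate_synthetic_ecg(synthetic_ecg_spec(
      fs = fs, duration = n / fs, heart_rate = 72, seed = ecg_seed)),
    audio = generate_synthetic_audio(n, fs = fs, seed = audio_seed)
  )
}

# empirical cross-correlation of the explicitly filtered outputs (brute-force
# oracle for the closed-form prediction)
empirical_output_xcorr <- function(x1, x2, w1, w2, lags) {
  a <- as.numeric(x1) - mean(as.numeric(x1))
  b <- as.numeric(x2) - mean(as.numeric(x2))
  filt <- function(x, w) {
    out <- stats::convolve(x, rev(w), type = "open")
    out[seq_along(x)]
  }
  y1 <- a + filt(b, w1)
  y2 <- b + filt(a, w2)
  vapply(lags, function(l) xcorr_lag(y1, y2, l), numeric(1))
}

# minimal WFDB writers (format 16 and 212) used to exercise the reader;
# binary files are created at test time, never stored in the repo
write_wfdb16 <- function(dir, record, channels, fs, gains, baselines,
                         descs) {
  n_sig <- length(channels)
  n <- length(channels[[1L]])
  adc <- vapply(seq_len(n_sig), function(i) {
    as.integer(round(channels[[i]] * gains[i] + baselines[i]))
  }, integer(n))
  hea <- file.path(dir, paste0(record, ".hea"))
  dat <- paste0(record, ".dat")
  writeLines(c(
    sprintf("%s %d %g %d", record, n_sig, fs, n),
    sprintf("%s 16 %g(%d)/mV 16 0 0 0 0 %s", dat, gains, baselines, descs)
  ), hea)
  con <- file(file.path(dir, dat), "wb")
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  close(con)
  hea
}

write_wfdb212 <- function(dir, record, channel, fs, gain, baseline, desc) {
  n <- length(channel)
  stopifnot(n %% 2L == 0L)
  adc <- as.integer(round(channel * gain + baseline))
  stopifnot(all(adc >= -2048L & adc <= 2047L))
  u <- ifelse(adc < 0L, adc + 4096L, adc)
  s1 <- u[seq(1L, n, 2L)]; s2 <- u[seq(2L, n, 2L)]
  b1 <- s1 %% 256L
  b2 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
  b3 <- s2 %% 256L
  hea <- file.path(dir, paste0(record, ".hea"))
  dat <- paste0(record, ".dat")
  writeLines(c(
    sprintf("%s 1 %g %d", record, fs, n),
    sprintf("%s 212 %g(%d)/mV 12 0 0 0 0 %s", dat, gain, baseline, desc)
  ), hea)
  con <- file(file.path(dir, dat), "wb")
  writeBin(as.raw(rbind(b1, b2, b3)), con)
  close(con)
  hea
}

# exhaustive per-threshold recount used as the ROC oracle
naive_rates <- function(genuine, imposter, thresholds) {
  data.frame(
    threshold = thresholds,
    tpr = vapply(thresholds, function(t) sum(genuine >= t) / length(genuine),
                 numeric(1)),
    fpr = vapply(thresholds, function(t) sum(imposter >= t) / length(imposter),
                 numeric(1))
  )
}
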