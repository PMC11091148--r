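#' Add white Gaussian noise at a target SNR
#'
#' Contaminates a signal with additive white Gaussian noise whose power is
#' set from the signal's mean-square power: `P_noise = P_x / 10^(snr_db/10)`.
#' `snr_db = Inf` returns the input unchanged (zero-noise limit).
#'
#' @param x A [signal1d()] with nonzero power.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer seed for the noise realisation.
#' @return A `signal1d` of the same length and sampling rate.
#' @examples
#' ecg <- generate_synthetic_ecg(synthetic_ecg_spec(duration = 2))
#' noisy <- add_awgn(ecg, snr_db = 10, seed = 42)
#' @export
add_awgn <- function(x, snr_db, seed = 1L) {
  px <- mean(as_samples(x)^2)
  if (px <= 0) {
    stop("add_awgn: input has zero power (degenerate input)", call. = FALSE)
  }
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  pn <- px / 10^(snr_db / 10)
  noise <- with_seed(seed, stats::rnorm(length(x), sd = sqrt(pn)))
  resignal(as_samples(x) + noise, x,
           label = sprintf("%s + awgn(%g dB)", sig_label(x), snr_db))
}

#' Second-order IIR notch filter
#'
#' Removes a narrowband interferer (typically 50/60 Hz power-line pickup)
#' with a biquad notch of centre frequency `f0` and quality factor
#' `q_factor = f0 / bandwidth`. Gain is unity (within 1 dB) at DC and at the
#' Nyquist frequency.
#'
#' @param x A [signal1d()].
#' @param f0 Notch centre frequency in Hz, in (0, fs/2).
#' @param q_factor Quality factor (> 0); higher is narrower. Default 30.
#' @return The filtered `signal1d`.
#' @export
notch_filter <- function(x, f0 = 50, q_factor = 30) {
  fs <- sig_fs(x)
  if (!is.finite(f0) || f0 <= 0 || f0 >= fs / 2) {
    stop("notch_filter: f0 must lie in (0, fs/2) = (0, ", fs / 2, ")",
         call. = FALSE)
  }
  if (q_factor <= 0) stop("notch_filter: q_factor must be positive",
                          call. = FALSE)
  # standard audio-EQ biquad notch
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q_factor)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  y <- as.numeric(signal::filter(b / a[1], a / a[1], as_samples(x)))
  resignal(y, x, label = sprintf("%s | notch(%g Hz, Q=%g)",
                                 sig_label(x), f0, q_factor))
}
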