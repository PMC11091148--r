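#' Specification for a synthetic PQRST ECG
#'
#' Describes a quasi-periodic single-lead ECG built as a sum of Gaussian
#' bumps, one per P/Q/R/S/T wave per beat, on the regular beat grid implied
#' by the heart rate, plus Gaussian baseline noise. The model is intentionally
#' simple: it is seedable and exercises separation and matching, but makes no
#' claim of physiological fidelity (no respiration, HRV, or arrhythmia).
#'
#' Default amplitudes/widths are textbook lead-II proportions (R normalised
#' to 1 mV-equivalent); default acquisition settings mirror a common
#' single-lead protocol of 20 s at 500 Hz.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds; `fs * duration` must be an
#'   integer number of samples >= 2.
#' @param heart_rate Beats per minute (> 0).
#' @param wave_params Data frame with columns `wave`, `amplitude` (relative
#'   to R), `width` (s, Gaussian sd), `center` (s, offset of the wave apex
#'   from the beat origin). Defaults cover P, Q, R, S, T.
#' @param baseline_noise_sd Baseline wander / myographic noise sd, relative
#'   to the R amplitude.
#' @param seed Integer seed making the record reproducible.
#' @return An object of class `ecg_spec` (a validated list).
#' @seealso [generate_synthetic_ecg()]
#' @export
synthetic_ecg_spec <- function(fs = 500, duration = 20, heart_rate = 72,
                               wave_params = default_wave_params(),
                               baseline_noise_sd = 0.05, seed = 1L) {
  n <- fs * duration
  if (!is.finite(n) || abs(n - round(n)) > 1e-9 || round(n) < 2) {
    stop("synthetic_ecg_spec: fs * duration must be an integer >= 2",
         call. = FALSE)
  }
  if (heart_rate <= 0) {
    stop("synthetic_ecg_spec: heart_rate must be positive", call. = FALSE)
  }
  req <- c("wave", "amplitude", "width", "center")
  if (!is.data.frame(wave_params) || !all(req %in% names(wave_params))) {
    stop("synthetic_ecg_spec: wave_params needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(wave_params$width <= 0)) {
    stop("synthetic_ecg_spec: wave widths must be positive", call. = FALSE)
  }
  if (baseline_noise_sd < 0) {
    stop("synthetic_ecg_spec: baseline_noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(fs = fs, duration = duration, heart_rate = heart_rate,
                 wave_params = wave_params,
                 baseline_noise_sd = baseline_noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ecg_spec")
}

#' @rdname synthetic_ecg_spec
#' @export
default_wave_params <- function() {
  data.frame(
    wave      = c("P",    "Q",     "R",    "S",     "T"),
    amplitude = c(0.15,  -0.15,    1.00,  -0.25,    0.35),
    width     = c(0.025,  0.010,   0.012,  0.012,   0.045),
    center    = c(0.15,   0.23,    0.25,   0.27,    0.45)
  )
}

#' Generate a synthetic quasi-periodic ECG record
#'
#' Places one Gaussian bump per wave per beat on the beat grid implied by
#' `heart_rate`, sums them, and adds seeded Gaussian baseline noise. With
#' `baseline_noise_sd = 0` the record is exactly periodic with period
#' `60 / heart_rate` seconds (away from the record edges).
#'
#' @param spec An [synthetic_ecg_spec()] object.
#' @return A [signal1d()] of `fs * duration` samples.
#' @examples
#' ecg <- generate_synthetic_ecg(synthetic_ecg_spec(fs = 500, duration = 5))
#' length(ecg)
#' @export
generate_synthetic_ecg <- function(spec) {
  if (!inherits(spec, "ecg_spec")) {
    stop("generate_synthetic_ecg: spec must come from synthetic_ecg_spec()",
         call. = FALSE)
  }
  n <- round(spec$fs * spec$duration)
  t <- (seq_len(n) - 1) / spec$fs
  period <- 60 / spec$heart_rate
  # beats whose support can reach into [0, duration]
  beats <- seq(-1L, ceiling(spec$duration / period) + 1L) * period
  x <- numeric(n)
  wp <- spec$wave_params
  for (b in beats) {
    for (i in seq_len(nrow(wp))) {
      mu <- b + wp$center[i]
      sd <- wp$width[i]
      # 8-sigma support keeps truncation error below 1e-12 of the amplitude
      lo <- mu - 8 * sd; hi <- mu + 8 * sd
      idx <- which(t >= lo & t <= hi)
      if (length(idx)) {
        x[idx] <- x[idx] + wp$amplitude[i] * exp(-0.5 * ((t[idx] - mu) / sd)^2)
      }
    }
  }
  if (spec$baseline_noise_sd > 0) {
    x <- x + with_seed(spec$seed, stats::rnorm(n, sd = spec$baseline_noise_sd))
  }
  signal1d(x, fs = spec$fs,
           label = sprintf("synthetic_ecg(hr=%g,seed=%s)", spec$heart_rate,
                           spec$seed %||% "NULL"))
}

#' Generate an audio-like auxiliary signal
#'
#' The auxiliary channel the template pipeline pairs with the ECG. It is a
#' sum of a few seeded random sinusoids (random frequencies in the speech
#' band scaled to `fs`, random phases) plus low-pass filtered Gaussian noise,
#' then exactly mean-centred. Sinusoids carry most of the power so the
#' signal is narrowband, as casual voice-like audio is; no claim of acoustic
#' realism is made.
#'
#' @param n Number of samples (>= 2).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param n_tones Number of sinusoidal components.
#' @param noise_frac Fraction of total power carried by the filtered-noise
#'   floor (in (0, 1)).
#' @return A zero-mean [signal1d()] of length `n`.
#' @export
generate_synthetic_audio <- function(n, fs = 500, seed = 1L, n_tones = 3L,
                                     noise_frac = 0.2) {
  if (!is.finite(n) || n < 2) {
    stop("generate_synthetic_audio: n must be >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  x <- with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    freqs <- stats::runif(n_tones, min = 0.01 * fs, max = 0.2 * fs)
    phases <- stats::runif(n_tones, 0, 2 * pi)
    amps <- stats::runif(n_tones, 0.5, 1)
    tones <- rowSums(vapply(seq_len(n_tones), function(i) {
      amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
    }, numeric(n)))
    noise <- as.numeric(stats::filter(stats::rnorm(n), rep(1 / 4, 4),
                                      sides = 1))
    noise[is.na(noise)] <- 0
    tones <- tones / stats::sd(tones)
    noise <- noise / max(stats::sd(noise), .Machine$double.eps)
    sqrt(1 - noise_frac) * tones + sqrt(noise_frac) * noise
  })
  x <- x - mean(x)
  signal1d(x, fs = fs, label = sprintf("synthetic_audio(seed=%s)",
                                       seed %||% "NULL"))
}

#' Simulate a synthetic subject population
#'
#' Builds `n_subjects` synthetic identities, each with its own heart rate and
#' per-wave morphology jitter, and `n_acquisitions` ECG records per subject
#' (independent baseline-noise realisations of the same morphology) plus one
#' auxiliary audio signal per subject. Used by the evaluation workflow and as
#' the test-fixture factory.
#'
#' @param n_subjects Number of identities (>= 1).
#' @param n_acquisitions ECG records per subject (>= 1).
#' @param n_samples Samples per record.
#' @param fs Sampling rate in Hz.
#' @param seed Master seed; every subject/acquisition seed is derived from it.
#' @param baseline_noise_sd Per-record baseline noise (relative to R).
#' @return A list of subjects; each has `subject_id`, `ecg` (list of
#'   `signal1d`), and `audio` (one `signal1d`).
#' @export
simulate_subjects <- function(n_subjects = 10L, n_acquisitions = 2L,
                              n_samples = 10000L, fs = 500,
                              seed = 1L, baseline_noise_sd = 0.05) {
  if (n_subjects < 1L) stop("simulate_subjects: n_subjects must be >= 1",
                            call. = FALSE)
  duration <- n_samples / fs
  subj_par <- with_seed(seed, {
    list(hr = stats::runif(n_subjects, 55, 95),
         amp_jit = matrix(stats::rnorm(n_subjects * 5L, 1, 0.12),
                          nrow = n_subjects),
         wid_jit = matrix(stats::rnorm(n_subjects * 5L, 1, 0.08),
                          nrow = n_subjects))
  })
  lapply(seq_len(n_subjects), function(s) {
    wp <- default_wave_params()
    wp$amplitude <- wp$amplitude * subj_par$amp_jit[s, ]
    wp$width <- wp$width * pmax(abs(subj_par$wid_jit[s, ]), 0.5)
    ecgs <- lapply(seq_len(n_acquisitions), function(a) {
      generate_synthetic_ecg(synthetic_ecg_spec(
        fs = fs, duration = duration, heart_rate = subj_par$hr[s],
        wave_params = wp, baseline_noise_sd = baseline_noise_sd,
        seed = seed + 1000L * s + a))
    })
    audio <- generate_synthetic_audio(n_samples, fs = fs,
                                      seed = seed + 1000L * s + 500L)
    list(subject_id = sprintf("S%03d", s), ecg = ecgs, audio = audio)
  })
}
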