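#' Run configuration for the enroll/verify/evaluate workflows
#'
#' Bundles every tunable of the pipeline: separation hyperparameters, probe
#' contamination level, optional notch pre-filter, which separation output
#' feeds the template, the decision threshold, the master seed, and the
#' template-store location.
#'
#' @param bss A [bss_config()].
#' @param snr_db SNR in dB of additive white Gaussian noise applied to probe
#'   ECGs during evaluation (`Inf` = clean).
#' @param notch `NULL`, or `c(f0, q_factor)` enabling the power-line notch
#'   pre-filter on every ECG.
#' @param output_choice `"y1"` or `"y2"`.
#' @param threshold Decision threshold in (0, 1).
#' @param seed Master integer seed; all derived randomness is seeded from it.
#' @param template_store Path of the JSON-lines template store.
#' @param verbose Emit progress/parameter messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(bss = bss_config(), snr_db = Inf, notch = NULL,
                       output_choice = c("y1", "y2"), threshold = 0.5,
                       seed = 1L, template_store = "templates.jsonl",
                       verbose = FALSE) {
  output_choice <- match.arg(output_choice)
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("run_config: threshold must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(inherits(bss, "bss_config"))
  if (!is.null(notch) && (length(notch) < 1L || notch[1L] <= 0)) {
    stop("run_config: notch must be NULL or c(f0, q_factor)", call. = FALSE)
  }
  structure(list(bss = bss, snr_db = snr_db, notch = notch,
                 output_choice = output_choice, threshold = threshold,
                 seed = as.integer(seed), template_store = template_store,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a flat key-value configuration file
#'
#' Parses `key = value` lines (one per line, `#` comments allowed) into a
#' [run_config()]. Recognised keys: `q`, `l1`, `l2`, `max_iter`, `conv_tol`,
#' `ridge`, `snr_db`, `notch_f0`, `notch_q`, `output_choice`, `threshold`,
#' `seed`, `template_store`. Unknown keys raise an error so typos do not
#' silently fall back to defaults.
#'
#' @param path Configuration file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_run_config: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- lapply(strsplit(lines, "\\s*=\\s*"), function(p) {
    list(key = p[1L], value = paste(p[-1L], collapse = "="))
  })
  vals <- stats::setNames(lapply(kv, `[[`, "value"),
                          vapply(kv, `[[`, "", "key"))
  known <- c("q", "l1", "l2", "max_iter", "conv_tol", "ridge", "snr_db",
             "notch_f0", "notch_q", "output_choice", "threshold", "seed",
             "template_store")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("read_run_config: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num <- function(key, default) {
    if (is.null(vals[[key]])) default else as.numeric(vals[[key]])
  }
  notch <- if (!is.null(vals$notch_f0)) {
    c(num("notch_f0", 50), num("notch_q", 30))
  } else NULL
  run_config(
    bss = bss_config(q = num("q", 4), l1 = num("l1", -25),
                     l2 = num("l2", 25), max_iter = num("max_iter", 100),
                     conv_tol = num("conv_tol", 1e-4),
                     ridge = num("ridge", 1e-8)),
    snr_db = num("snr_db", Inf), notch = notch,
    output_choice = vals$output_choice %||% "y1",
    threshold = num("threshold", 0.5), seed = num("seed", 1),
    template_store = vals$template_store %||% "templates.jsonl")
}

log_cfg <- function(config, stage) {
  if (!config$verbose) return(invisible(NULL))
  message(sprintf(
    "[%s] q=%d l1=%d l2=%d conv_tol=%g ridge=%g snr_db=%g threshold=%g seed=%d output=%s",
    stage, config$bss$q, config$bss$l1, config$bss$l2, config$bss$conv_tol,
    config$bss$ridge, config$snr_db, config$threshold, config$seed,
    config$output_choice))
}

load_ecg <- function(path, config, channel = 1L) {
  if (!file.exists(path) && !file.exists(paste0(path, ".hea"))) {
    stop("enroll/verify: input file not found: ", path, call. = FALSE)
  }
  x <- read_signal(path, channel = channel)
  if (!is.null(config$notch)) {
    x <- notch_filter(x, f0 = config$notch[1L],
                      q_factor = if (length(config$notch) > 1L)
                        config$notch[2L] else 30)
  }
  x
}

#' Enroll a subject into the template store
#'
#' Reads the ECG and audio signals, applies the configured preprocessing,
#' generates the cancellable template with a key derived from `key_seed`,
#' and appends the record to the template store. Deterministic: identical
#' inputs and seeds give byte-identical store records.
#'
#' @param config A [run_config()].
#' @param ecg_path,audio_path Input signal files (CSV or WFDB).
#' @param subject_id Identifier stored with the template.
#' @param key_seed Seed of the subject's secret key.
#' @return Invisibly, the stored `cancellable_template`.
#' @export
cmd_enroll <- function(config, ecg_path, audio_path, subject_id, key_seed) {
  log_cfg(config, "enroll")
  ecg <- load_ecg(ecg_path, config)
  audio <- load_ecg(audio_path, config)
  m <- match_lengths(ecg, audio)
  key <- generate_key(length(m$a), seed = key_seed)
  tp <- generate_template(m$a, m$b, key, config$bss,
                          output_choice = config$output_choice,
                          subject_id = subject_id)
  if (config$verbose) {
    message(sprintf("[enroll] %s: separation %s after %d iterations, cost ratio %.3g",
                    subject_id,
                    if (tp$provenance$converged) "converged" else "did not converge",
                    tp$provenance$iterations, tp$provenance$cost_ratio))
  }
  existing <- if (file.exists(config$template_store)) {
    read_template_store(config$template_store)
  } else list()
  write_template_store(c(existing, list(tp)), config$template_store)
  invisible(tp)
}

#' Verify a probe against a stored enrollment
#'
#' Regenerates the probe template with the enrolled subject's key (recorded
#' in the store's provenance), scores it against the stored template, and
#' applies the configured decision threshold.
#'
#' @param config A [run_config()].
#' @param ecg_path,audio_path Probe signal files.
#' @param subject_id Claimed identity; must exist in the store.
#' @return A list: `match`, `score`, `threshold`, `subject_id`.
#' @export
cmd_verify <- function(config, ecg_path, audio_path, subject_id) {
  log_cfg(config, "verify")
  store <- read_template_store(config$template_store)
  ids <- vapply(store, `[[`, "", "subject_id")
  hit <- which(ids == subject_id)
  if (!length(hit)) {
    stop("cmd_verify: no enrollment for subject ", dQuote(subject_id),
         " in ", config$template_store, call. = FALSE)
  }
  enrolled <- store[[hit[1L]]]
  ecg <- load_ecg(ecg_path, config)
  audio <- load_ecg(audio_path, config)
  m <- match_lengths(ecg, audio)
  key <- generate_key(length(m$a), seed = enrolled$provenance$key_seed)
  cfg <- do.call(bss_config, as.list(enrolled$provenance$config))
  probe <- generate_template(m$a, m$b, key, cfg,
                             output_choice = enrolled$provenance$output_choice,
                             subject_id = subject_id)
  res <- verify_template(probe, enrolled, threshold = config$threshold)
  if (config$verbose) {
    message(sprintf("[verify] %s: score %.4f vs threshold %.2f -> %s",
                    subject_id, res$score, res$threshold,
                    if (res$match) "match" else "no-match"))
  }
  c(res, list(subject_id = subject_id))
}

#' Evaluate authentication performance on a synthetic population
#'
#' Simulates `n_subjects` identities with `n_acquisitions` ECG records each,
#' enrolls acquisition 1 of every subject, and probes with the remaining
#' acquisitions (optionally contaminated with AWGN at `config$snr_db`).
#' Every probe is scored against every enrollment: same-subject pairs are
#' genuine, the rest imposter. Returns the score set, the ROC with EER and
#' AROC, and optionally writes the per-threshold CSV report.
#'
#' Two probe regimes are supported. With `probe_source = "fresh"` (default)
#' probes are independent re-acquisitions: each carries its own baseline-noise
#' realisation, as in repeat enrollment sessions. With
#' `probe_source = "replay"` the probe re-uses the enrollment acquisition
#' itself, the regime of a transmission-noise robustness test where the same
#' record reaches the verifier through a noisy channel; it is the natural
#' companion of a finite `snr_db`.
#'
#' @param config A [run_config()].
#' @param n_subjects Number of identities (>= 2, else no imposter pairs).
#' @param n_acquisitions Records per subject (>= 2, else no genuine pairs).
#' @param n_samples Samples per record.
#' @param fs Sampling rate in Hz.
#' @param baseline_noise_sd Acquisition-to-acquisition ECG variability.
#' @param probe_source `"fresh"` (independent probe acquisitions) or
#'   `"replay"` (probe = enrollment record, for channel-noise robustness).
#' @param report_path Optional CSV output for the ROC report.
#' @return A list with `scores` ([build_scores()] result), `roc`
#'   ([roc_curve()]), and `summary` (one-row tibble).
#' @export
cmd_evaluate <- function(config, n_subjects = 10L, n_acquisitions = 2L,
                         n_samples = 10000L, fs = 500,
                         baseline_noise_sd = 0.05,
                         probe_source = c("fresh", "replay"),
                         report_path = NULL) {
  log_cfg(config, "evaluate")
  probe_source <- match.arg(probe_source)
  if (n_subjects < 2L) {
    stop("cmd_evaluate: need n_subjects >= 2 to form imposter pairs",
         call. = FALSE)
  }
  if (n_acquisitions < 2L) {
    stop("cmd_evaluate: need n_acquisitions >= 2 to form genuine pairs",
         call. = FALSE)
  }
  pop <- simulate_subjects(n_subjects, n_acquisitions, n_samples, fs,
                           seed = config$seed,
                           baseline_noise_sd = baseline_noise_sd)
  enrolled <- list(); probes <- list()
  for (s in seq_along(pop)) {
    subj <- pop[[s]]
    key <- generate_key(n_samples, seed = config$seed + 7000L + s)
    enrolled[[s]] <- generate_template(subj$ecg[[1L]], subj$audio, key,
                                       config$bss,
                                       output_choice = config$output_choice,
                                       subject_id = subj$subject_id)
    for (a in seq_len(n_acquisitions - 1L) + 1L) {
      probe_ecg <- if (probe_source == "replay") subj$ecg[[1L]] else
        subj$ecg[[a]]
      if (is.finite(config$snr_db)) {
        probe_ecg <- add_awgn(probe_ecg, config$snr_db,
                              seed = config$seed + 9000L + 100L * s + a)
      }
      probes[[length(probes) + 1L]] <-
        generate_template(probe_ecg, subj$audio, key, config$bss,
                          output_choice = config$output_choice,
                          subject_id = subj$subject_id)
    }
  }
  scores <- build_scores(enrolled, probes)
  roc <- roc_curve(scores)
  if (!is.null(report_path)) write_roc_csv(roc, report_path)
  if (config$verbose) {
    message(sprintf(
      "[evaluate] %d genuine / %d imposter pairs: EER %.4f, AROC %.4f",
      roc$n_genuine, roc$n_imposter, roc$eer, roc$aroc))
  }
  list(scores = scores, roc = roc,
       summary = tibble::tibble(
         n_subjects = n_subjects, n_acquisitions = n_acquisitions,
         n_samples = n_samples, snr_db = config$snr_db,
         genuine_mean = mean(scores$genuine),
         imposter_mean = mean(scores$imposter),
         eer = roc$eer, aroc = roc$aroc))
}

#' Write a synthetic ECG/audio fixture pair to disk
#'
#' The `simulate` workflow: generates one synthetic subject's ECG and audio
#' at the configured seed and writes them as CSV signal files, so that the
#' enroll/verify commands can be exercised without real recordings.
#'
#' @param config A [run_config()].
#' @param ecg_path,audio_path Output CSV paths.
#' @param n_samples,fs,heart_rate Generation parameters.
#' @return Invisibly, a list with the two signals.
#' @export
cmd_simulate <- function(config, ecg_path, audio_path, n_samples = 10000L,
                         fs = 500, heart_rate = 72) {
  ecg <- generate_synthetic_ecg(synthetic_ecg_spec(
    fs = fs, duration = n_samples / fs, heart_rate = heart_rate,
    seed = config$seed))
  audio <- generate_synthetic_audio(n_samples, fs = fs,
                                    seed = config$seed + 500L)
  write_signal(ecg, ecg_path)
  write_signal(audio, audio_path)
  invisible(list(ecg = ecg, audio = audio))
}
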