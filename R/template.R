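#' Binarize a separation output
#'
#' Thresholds the signal at its median: samples strictly above the median
#' map to 1, the rest to 0. Median thresholding keeps the bit stream close
#' to balanced for continuous-valued inputs and is invariant to affine
#' rescaling of the signal.
#'
#' @param y A non-constant [signal1d()] or numeric vector.
#' @return An integer vector of 0/1 bits, same length as `y`.
#' @export
binarize <- function(y) {
  v <- as.numeric(y)
  if (length(unique(v)) < 2L) {
    stop("binarize: constant signal gives a zero-variance template ",
         "(degenerate input)", call. = FALSE)
  }
  as.integer(v > stats::median(v))
}

#' Generate a user-specific secret key
#'
#' Seeded i.i.d. uniform bits of a given length. Seeding makes enrollment
#' reproducible in tests and experiments; for production use the seed should
#' come from OS entropy and never be stored alongside templates.
#'
#' @param n Key length in bits (>= 1), equal to the template length.
#' @param seed Integer seed recorded as key provenance.
#' @param key_id Optional identifier; defaults to one derived from the seed.
#' @return An object of class `user_key` with fields `bits`, `key_id`,
#'   `seed`.
#' @export
generate_key <- function(n, seed, key_id = NULL) {
  if (!is.finite(n) || n < 1) {
    stop("generate_key: n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  bits <- with_seed(seed, sample(c(0L, 1L), n, replace = TRUE))
  structure(list(bits = bits,
                 key_id = key_id %||% sprintf("key-%d", as.integer(seed)),
                 seed = as.integer(seed)),
            class = "user_key")
}

#' XOR lightweight encryption
#'
#' Element-wise XOR of a bit vector with a user key of the same length. XOR
#' is an involution: applying the same key twice restores the input, which
#' is what makes templates revocable — a leaked template is discarded and a
#' fresh key produces a statistically unrelated one.
#'
#' @param bits Integer 0/1 vector.
#' @param key A [generate_key()] object or a raw 0/1 vector of equal length.
#' @return Integer 0/1 vector.
#' @export
xor_encrypt <- function(bits, key) {
  kb <- if (inherits(key, "user_key")) key$bits else as.integer(key)
  if (length(bits) != length(kb)) {
    stop("xor_encrypt: bit vector (", length(bits), ") and key (",
         length(kb), ") lengths differ", call. = FALSE)
  }
  if (!all(bits %in% c(0L, 1L)) || !all(kb %in% c(0L, 1L))) {
    stop("xor_encrypt: inputs must be 0/1 bit vectors", call. = FALSE)
  }
  as.integer(bitwXor(as.integer(bits), kb))
}

#' Generate a cancellable ECG template
#'
#' The full protection chain: truncate the ECG and auxiliary audio to a
#' common length, run the decorrelating separation, binarize the selected
#' output, and XOR the bits with the user key. The result never stores the
#' original ECG samples; revocation is a key change away.
#'
#' @param ecg ECG [signal1d()].
#' @param audio Auxiliary audio [signal1d()].
#' @param key A [generate_key()] key whose length equals the matched signal
#'   length.
#' @param cfg [bss_config()] for the separation stage.
#' @param output_choice Which separation output to binarize, `"y1"` (the
#'   output anchored on the ECG observation; default) or `"y2"`.
#' @param subject_id Identifier stored with the template.
#' @return An object of class `cancellable_template` with fields `bits`,
#'   `subject_id`, `key_id`, and `provenance` (output choice, separation
#'   convergence, cost ratio, config). Separation non-convergence is
#'   recorded in the provenance, not raised.
#' @export
generate_template <- function(ecg, audio, key, cfg = bss_config(),
                              output_choice = c("y1", "y2"),
                              subject_id = "anonymous") {
  output_choice <- match.arg(output_choice)
  m <- match_lengths(ecg, audio)
  kb <- if (inherits(key, "user_key")) key$bits else as.integer(key)
  if (length(kb) != length(m$a)) {
    stop("generate_template: key length (", length(kb),
         ") must equal matched signal length (", length(m$a), ")",
         call. = FALSE)
  }
  fit <- bss_separate(m$a, m$b, cfg)
  y <- if (output_choice == "y1") fit$y1 else fit$y2
  bits <- xor_encrypt(binarize(y), kb)
  structure(list(
    bits = bits,
    subject_id = subject_id,
    key_id = if (inherits(key, "user_key")) key$key_id else "raw-key",
    provenance = list(
      output_choice = output_choice,
      converged = fit$converged,
      iterations = fit$iterations,
      cost_ratio = utils::tail(fit$cost_trajectory, 1L) /
        max(fit$cost_trajectory[1L], .Machine$double.xmin),
      key_seed = if (inherits(key, "user_key")) key$seed else NA_integer_,
      config = unclass(cfg)
    )
  ), class = "cancellable_template")
}

#' @export
print.cancellable_template <- function(x, ...) {
  cat(sprintf(
    "<cancellable_template> subject %s, key %s\n  %d bits (balance %.3f), from %s, separation %s\n",
    x$subject_id, x$key_id, length(x$bits), mean(x$bits),
    x$provenance$output_choice,
    if (isTRUE(x$provenance$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Revoke and reissue a template
#'
#' Re-enrolls the subject with a fresh key (and optionally fresh audio).
#' The new template is statistically uncorrelated with the old one, so a
#' compromised template becomes useless while the subject keeps their
#' biometric.
#'
#' @param ecg,audio Enrollment signals.
#' @param old The compromised `cancellable_template`.
#' @param new_seed Seed for the replacement key; must differ from the old
#'   key's seed.
#' @param cfg [bss_config()] (defaults to the old template's configuration).
#' @return A fresh `cancellable_template`.
#' @export
revoke_template <- function(ecg, audio, old, new_seed, cfg = NULL) {
  stopifnot(inherits(old, "cancellable_template"))
  if (!is.na(old$provenance$key_seed) &&
      as.integer(new_seed) == old$provenance$key_seed) {
    stop("revoke_template: new_seed equals the revoked key's seed; ",
         "choose a different seed", call. = FALSE)
  }
  if (is.null(cfg)) cfg <- do.call(bss_config, old$provenance$config)
  m <- match_lengths(ecg, audio)
  key <- generate_key(length(m$a), seed = new_seed)
  new <- generate_template(m$a, m$b, key, cfg,
                           output_choice = old$provenance$output_choice,
                           subject_id = old$subject_id)
  if (identical(new$bits, old$bits)) {
    stop("revoke_template: reissued template equals the revoked one ",
         "(seed collision); choose a different seed", call. = FALSE)
  }
  new
}

# ---- template store (JSON lines, hex-packed bits) -------------------------

# bits -> hex, little-endian within each byte (bit i of a byte is the
# (i+1)-th template bit of that byte, i = 0..7); zero-padded tail.
bits_to_hex <- function(bits) {
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  m <- matrix(c(as.integer(bits), integer(pad)), nrow = 8L)
  bytes <- as.integer(2L^(0:7) %*% m)
  paste(sprintf("%02x", bytes), collapse = "")
}

hex_to_bits <- function(hex, n) {
  bytes <- strtoi(substring(hex, seq(1L, nchar(hex), 2L),
                            seq(2L, nchar(hex), 2L)), base = 16L)
  bits <- as.integer(vapply(bytes, function(b) bitwAnd(b %/% 2L^(0:7), 1L),
                            integer(8L)))
  bits[seq_len(n)]
}

#' Read and write a template store
#'
#' One enrollment record per line, serialized as JSON: subject id, key id,
#' the bit vector hex-packed (little-endian bit order within each byte),
#' its exact bit length, and the generation parameters. Byte-identical
#' round trips are guaranteed for identical inputs.
#'
#' @param templates List of `cancellable_template` objects.
#' @param path Store file path.
#' @return `write_template_store()` invisibly returns `path`;
#'   `read_template_store()` returns a list of `cancellable_template`s.
#' @export
write_template_store <- function(templates, path) {
  if (inherits(templates, "cancellable_template")) templates <- list(templates)
  lines <- vapply(templates, function(tp) {
    jsonlite::toJSON(list(
      subject_id = tp$subject_id,
      key_id = tp$key_id,
      n_bits = length(tp$bits),
      bits_hex = bits_to_hex(tp$bits),
      provenance = tp$provenance
    ), auto_unbox = TRUE, digits = NA)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_template_store
#' @export
read_template_store <- function(path) {
  if (!file.exists(path)) {
    stop("read_template_store: file not found: ", path, call. = FALSE)
  }
  lapply(readLines(path, warn = FALSE), function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    structure(list(
      bits = hex_to_bits(rec$bits_hex, rec$n_bits),
      subject_id = rec$subject_id,
      key_id = rec$key_id,
      provenance = rec$provenance
    ), class = "cancellable_template")
  })
}
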