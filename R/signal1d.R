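#' Construct a sampled 1-D signal
#'
#' The basic container used throughout the package: a finite real-valued
#' sample vector together with its sampling rate and a free-text provenance
#' label. ECG leads, auxiliary audio, mixture observations and separation
#' outputs are all `signal1d` objects.
#'
#' @param samples Numeric vector of at least two finite samples.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param label Free-text provenance tag.
#' @return An object of class `signal1d`: a numeric vector with attributes
#'   `fs` and `label`.
#' @examples
#' x <- signal1d(sin(2 * pi * 5 * seq(0, 1, by = 1 / 500)), fs = 500)
#' x
#' @export
signal1d <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("signal1d: need at least 2 samples, got ", length(samples),
         call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("signal1d: all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("signal1d: fs must be a positive finite scalar", call. = FALSE)
  }
  structure(samples, fs = as.numeric(fs), label = as.character(label)[1L],
            class = "signal1d")
}

#' @export
print.signal1d <- function(x, ...) {
  cat(sprintf("<signal1d> %d samples @ %g Hz (%.3f s)%s\n",
              length(x), sig_fs(x), length(x) / sig_fs(x),
              if (nzchar(sig_label(x))) paste0("  [", sig_label(x), "]") else ""))
  utils::str(as.numeric(utils::head(unclass(x), 8L)))
  invisible(x)
}

#' Sampling rate and label accessors
#' @param x A `signal1d`.
#' @return `sig_fs()` the sampling rate in Hz; `sig_label()` the provenance tag.
#' @export
sig_fs <- function(x) attr(x, "fs")

#' @rdname sig_fs
#' @export
sig_label <- function(x) attr(x, "label") %||% ""

`%||%` <- function(a, b) if (is.null(a)) b else a

as_samples <- function(x) as.numeric(unclass(x))

# rebuild a signal1d keeping metadata of a donor
resignal <- function(samples, donor, label = NULL) {
  signal1d(samples, fs = sig_fs(donor),
           label = label %||% sig_label(donor))
}

#' @importFrom tibble as_tibble tibble
#' @exportS3Method tibble::as_tibble
as_tibble.signal1d <- function(x, ...) {
  tibble::tibble(time = (seq_along(x) - 1) / sig_fs(x),
                 value = as_samples(x))
}

#' Truncate two signals to a common length
#'
#' Enrollment and probe pipelines require equal-length ECG and audio signals.
#' Both signals are truncated to the shorter of the two; samples are never
#' resampled or altered, only dropped from the tail.
#'
#' @param a,b `signal1d` objects (or plain numeric vectors of length >= 2).
#' @return A list with elements `a` and `b`, both of length
#'   `min(length(a), length(b))`.
#' @examples
#' m <- match_lengths(signal1d(rnorm(100), 500), signal1d(rnorm(80), 500))
#' lengths(m)
#' @export
match_lengths <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    stop("match_lengths: inputs must be non-empty", call. = FALSE)
  }
  n <- min(length(a), length(b))
  trunc1 <- function(x) {
    if (length(x) == n) return(x)
    if (inherits(x, "signal1d")) resignal(as_samples(x)[seq_len(n)], x)
    else x[seq_len(n)]
  }
  list(a = trunc1(a), b = trunc1(b))
}

# Run code under a private RNG stream without disturbing the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Causal FIR filtering with zero initial conditions: (w * x)[1:N].
fir_apply <- function(x, w) {
  x <- as.numeric(x)
  w <- as.numeric(w)
  if (length(w) == 0L || all(w == 0)) return(numeric(length(x)))
  out <- stats::convolve(x, rev(w), type = "open")
  out[seq_along(x)]
}
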