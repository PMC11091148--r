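#' Read and write 1-D signals
#'
#' CSV files hold one sample per line with `.` as the decimal separator and
#' an optional single header line `fs=<Hz>`; a write/read round trip
#' reproduces the samples to float precision and preserves the sampling
#' rate. WFDB (PhysioNet `.hea`/`.dat`) records are read-only: the header is
#' parsed and one named (or indexed) channel is extracted in physical units.
#' Signal formats 16 (16-bit little-endian) and 212 (packed 12-bit pairs)
#' are supported, which covers the ECG-ID and MIT-BIH encodings.
#'
#' @param path File path. For WFDB give the `.hea` file or the record name
#'   without extension.
#' @param format `"csv"` or `"wfdb"`; default guessed from the extension.
#' @param channel For WFDB: channel name or 1-based index. Default first.
#' @param fs Fallback sampling rate when a CSV has no `fs=` header.
#' @return [read_signal()] returns a [signal1d()]; [write_signal()] invisibly
#'   returns `path`.
#' @export
read_signal <- function(path, format = c("auto", "csv", "wfdb"),
                        channel = 1L, fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path) ||
                  file.exists(paste0(path, ".hea"))) "wfdb" else "csv"
  }
  if (format == "csv") read_signal_csv(path, fs = fs)
  else read_signal_wfdb(path, channel = channel)
}

#' @rdname read_signal
#' @param x A [signal1d()] to write (CSV only).
#' @export
write_signal <- function(x, path, format = "csv") {
  if (format != "csv") {
    stop("write_signal: only csv output is supported", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%.10g", sig_fs(x)), con)
  writeLines(formatC(as_samples(x), format = "g", digits = 17), con)
  invisible(path)
}

read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) {
    stop("read_signal: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  if (length(lines) && grepl("^\\s*fs\\s*=", lines[1L])) {
    fs <- as.numeric(sub("^\\s*fs\\s*=\\s*", "", lines[1L]))
    offset <- 1L
    lines <- lines[-1L]
  }
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  if (length(bad)) {
    stop(sprintf("read_signal: non-numeric value %s at row %d of %s",
                 dQuote(lines[bad[1L]]), bad[1L] + offset, path),
         call. = FALSE)
  }
  signal1d(vals, fs = fs %||% 1, label = basename(path))
}

# Minimal WFDB reader: header + formats 16 and 212, enough for single-lead
# extraction from standard ambulatory ECG records.
read_signal_wfdb <- function(path, channel = 1L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    stop("read_signal: WFDB header not found: ", hea, call. = FALSE)
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 3L) {
    stop("read_signal: malformed WFDB record line in ", hea, call. = FALSE)
  }
  n_sig <- as.integer(rec[2L])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*", "", rec[3L])) else 250
  n_samp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  sig_lines <- lines[seq_len(n_sig) + 1L]
  sigs <- lapply(seq_along(sig_lines), function(i) {
    f <- strsplit(trimws(sig_lines[i]), "\\s+")[[1L]]
    if (length(f) < 2L) {
      stop(sprintf("read_signal: malformed WFDB signal line %d in %s", i, hea),
           call. = FALSE)
    }
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_field))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else if (length(f) >= 5L) as.numeric(f[5L]) else 0
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else
      paste0("ch", i)
    list(file = f[1L], fmt = sub("x.*|:.*|\\+.*", "", f[2L]),
         gain = gain, baseline = baseline, desc = desc)
  })
  idx <- if (is.character(channel)) {
    m <- which(vapply(sigs, `[[`, "", "desc") == channel)
    if (!length(m)) {
      stop("read_signal: no WFDB channel named ", dQuote(channel),
           " in ", hea, call. = FALSE)
    }
    m[1L]
  } else as.integer(channel)
  if (idx < 1L || idx > n_sig) {
    stop("read_signal: channel index out of range", call. = FALSE)
  }
  dat <- file.path(dirname(hea), sigs[[idx]]$file)
  if (!file.exists(dat)) {
    stop("read_signal: WFDB signal file not found: ", dat, call. = FALSE)
  }
  fmt <- sigs[[idx]]$fmt
  raw_all <- readBin(dat, "raw", n = file.info(dat)$size)
  adc <- switch(fmt,
    "16" = {
      v <- readBin(raw_all, "integer", n = length(raw_all) %/% 2L,
                   size = 2L, signed = TRUE, endian = "little")
      matrix_head(v, n_sig, n_samp)[, idx]
    },
    "212" = {
      v <- decode_fmt212(raw_all)
      matrix_head(v, n_sig, n_samp)[, idx]
    },
    stop("read_signal: unsupported WFDB format ", dQuote(fmt), call. = FALSE)
  )
  phys <- (adc - sigs[[idx]]$baseline) / sigs[[idx]]$gain
  signal1d(phys, fs = fs,
           label = sprintf("%s:%s", basename(hea), sigs[[idx]]$desc))
}

# interleaved sample stream -> n x n_sig matrix (truncated to whole frames)
matrix_head <- function(v, n_sig, n_samp) {
  frames <- length(v) %/% n_sig
  if (!is.na(n_samp)) frames <- min(frames, n_samp)
  matrix(v[seq_len(frames * n_sig)], ncol = n_sig, byrow = TRUE)
}

# WFDB format 212: two 12-bit two's-complement samples per 3 bytes.
decode_fmt212 <- function(raw) {
  nb <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(nb)])
  b1 <- b[seq(1L, nb, 3L)]; b2 <- b[seq(2L, nb, 3L)]; b3 <- b[seq(3L, nb, 3L)]
  s1 <- b1 + bitwAnd(b2, 0x0FL) * 256L
  s2 <- b3 + bitwAnd(b2, 0xF0L) * 16L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}
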