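#' Normalized correlation matching score
#'
#' The similarity metric between a stored template and a query: covariance
#' divided by the product of standard deviations, in `[-1, 1]`. Binary
#' templates are mapped from `{0, 1}` to `{-1, +1}` before scoring so that
#' balanced independent templates score near zero.
#'
#' @param x,y Templates (`cancellable_template`), 0/1 bit vectors, or
#'   numeric signals of equal length >= 2 and nonzero variance.
#' @return Scalar correlation score.
#' @export
correlation_score <- function(x, y) {
  x <- score_vector(x); y <- score_vector(y)
  if (length(x) != length(y)) {
    stop("correlation_score: length mismatch (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("correlation_score: need at least 2 elements", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation_score: zero-variance input (degenerate)",
         call. = FALSE)
  }
  as.numeric(stats::cor(x, y))
}

score_vector <- function(x) {
  if (inherits(x, "cancellable_template")) x <- x$bits
  x <- as.numeric(x)
  if (all(x %in% c(0, 1))) 2 * x - 1 else x
}

#' Score all enrollment/probe pairs
#'
#' With two lists, scores every probe against every enrolled template
#' exactly once (bipartite protocol). With a single list (`probes = NULL`)
#' scores every unordered pair of distinct templates once. Pairs sharing a
#' subject id are genuine, all others imposter; both sets must be non-empty
#' for downstream EER/ROC computation.
#'
#' @param enrolled,probes Lists of `cancellable_template` objects carrying
#'   `subject_id`s.
#' @return An object of class `score_set`: a list with numeric vectors
#'   `genuine` and `imposter` and a tibble `pairs` (enrolled id, probe id,
#'   score, genuine flag).
#' @export
build_scores <- function(enrolled, probes = NULL) {
  if (inherits(enrolled, "cancellable_template")) enrolled <- list(enrolled)
  if (is.null(probes)) {
    if (length(enrolled) < 2L) {
      stop("build_scores: need at least two templates", call. = FALSE)
    }
    grid <- utils::combn(length(enrolled), 2L)
    grid <- data.frame(e = grid[1L, ], p = grid[2L, ])
    probes <- enrolled
  } else {
    if (inherits(probes, "cancellable_template")) probes <- list(probes)
    grid <- expand.grid(e = seq_along(enrolled), p = seq_along(probes))
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    e <- enrolled[[grid$e[i]]]; p <- probes[[grid$p[i]]]
    data.frame(enrolled_id = e$subject_id, probe_id = p$subject_id,
               score = correlation_score(e, p),
               genuine = identical(e$subject_id, p$subject_id))
  })
  pairs <- tibble::as_tibble(do.call(rbind, res))
  if (!any(pairs$genuine) || all(pairs$genuine)) {
    stop("build_scores: need at least one genuine and one imposter pair",
         call. = FALSE)
  }
  structure(list(genuine = pairs$score[pairs$genuine],
                 imposter = pairs$score[!pairs$genuine],
                 pairs = pairs),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf(
    "<score_set> %d genuine (mean %.3f), %d imposter (mean %.3f)\n",
    length(x$genuine), mean(x$genuine),
    length(x$imposter), mean(x$imposter)))
  invisible(x)
}

#' ROC curve, EER and AROC from genuine/imposter scores
#'
#' Sweeps the decision threshold over every distinct score plus the two
#' infinities. At threshold `t`, `TPR(t)` is the fraction of genuine scores
#' `>= t` and `FPR(t)` the fraction of imposter scores `>= t`. The area
#' under the curve (AROC) is computed by trapezoidal integration; the equal
#' error rate is taken where FAR (= FPR) crosses FRR (= 1 - TPR), with
#' linear interpolation between adjacent thresholds since the empirical
#' rates are step functions.
#'
#' @param scores A [build_scores()] result, or a list with numeric
#'   `genuine` and `imposter` elements.
#' @return An object of class `roc_curve`: tibble `points` (threshold, fpr,
#'   tpr, far, frr) plus scalars `eer`, `eer_threshold`, `aroc`.
#' @export
roc_curve <- function(scores) {
  g <- as.numeric(scores$genuine); im <- as.numeric(scores$imposter)
  if (!length(g) || !length(im)) {
    stop("roc_curve: need non-empty genuine and imposter score sets",
         call. = FALSE)
  }
  if (!all(is.finite(g)) || !all(is.finite(im))) {
    stop("roc_curve: scores must be finite", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(c(g, im))), Inf)
  tpr <- vapply(thr, function(t) mean(g >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(im >= t), numeric(1L))
  pts <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr,
                        far = fpr, frr = 1 - tpr)
  # sweep from high threshold (0,0) to low (1,1)
  pts <- pts[order(pts$threshold, decreasing = TRUE), ]
  aroc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1L) +
                                 utils::tail(pts$tpr, -1L)) / 2)
  d <- pts$far - pts$frr
  eer <- NA_real_; eer_thr <- NA_real_
  zero <- which(d == 0)
  if (length(zero)) {
    eer <- pts$far[zero[1L]]
    eer_thr <- pts$threshold[zero[1L]]
  } else {
    cross <- which(d[-1L] * d[-length(d)] < 0)[1L]
    if (!is.na(cross)) {
      # linear interpolation of both rates between the bracketing thresholds
      w <- d[cross] / (d[cross] - d[cross + 1L])
      eer <- pts$far[cross] + w * (pts$far[cross + 1L] - pts$far[cross])
      frr_i <- pts$frr[cross] + w * (pts$frr[cross + 1L] - pts$frr[cross])
      eer <- (eer + frr_i) / 2
      t0 <- pts$threshold[cross]; t1 <- pts$threshold[cross + 1L]
      eer_thr <- if (is.finite(t0) && is.finite(t1)) t0 + w * (t1 - t0) else
        if (is.finite(t1)) t1 else t0
    }
  }
  structure(list(points = pts, eer = eer, eer_threshold = eer_thr,
                 aroc = aroc,
                 n_genuine = length(g), n_imposter = length(im)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> %d genuine / %d imposter scores\n  EER = %.4f (threshold %.3f), AROC = %.4f\n",
    x$n_genuine, x$n_imposter, x$eer, x$eer_threshold, x$aroc))
  invisible(x)
}

#' @rdname tidy.bss_separation
#' @exportS3Method generics::tidy
tidy.roc_curve <- function(x, ...) x$points

#' @rdname tidy.bss_separation
#' @exportS3Method generics::glance
glance.roc_curve <- function(x, ...) {
  tibble::tibble(eer = x$eer, eer_threshold = x$eer_threshold,
                 aroc = x$aroc, n_genuine = x$n_genuine,
                 n_imposter = x$n_imposter)
}

#' @importFrom rlang .data
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (EER = %.3f, AROC = %.4f)",
                                  object$eer, object$aroc)) +
    ggplot2::theme_minimal()
}

#' Verify a probe template against an enrollment
#'
#' Declares a match when the correlation score is strictly greater than the
#' decision threshold (ties reject). Thresholds are normally chosen inside
#' the gap between the imposter and genuine score distributions.
#'
#' @param probe,enrolled `cancellable_template` objects (or bit vectors).
#' @param threshold Decision threshold; default 0.5, the midpoint of the
#'   admissible band between typical imposter and genuine scores.
#' @return A list with `match` (logical), `score`, and `threshold`.
#' @export
verify_template <- function(probe, enrolled, threshold = 0.5) {
  score <- correlation_score(probe, enrolled)
  list(match = score > threshold, score = score, threshold = threshold)
}

#' Export an ROC curve as CSV
#'
#' Writes one row per threshold (threshold, FPR, TPR) with the EER and AROC
#' recorded in `#`-prefixed header comments, ready for external plotting.
#'
#' @param roc A [roc_curve()] object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eer=%.10g", roc$eer), con)
  writeLines(sprintf("# aroc=%.10g", roc$aroc), con)
  # 17 significant digits so thresholds read back as the exact doubles
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  writeLines("threshold,fpr,tpr", con)
  writeLines(paste(fmt(roc$points$threshold), fmt(roc$points$fpr),
                   fmt(roc$points$tpr), sep = ","), con)
  invisible(path)
}
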