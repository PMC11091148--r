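#' Configuration for the decorrelation-based separation algorithm
#'
#' The 2x2 convolutive separator estimates two FIR cross-filters of order `q`
#' (so `q + 1` taps each) by minimising the sum of squared output
#' cross-correlations over the lag window `l1..l2`. Iteration alternates the
#' two coupled closed-form weight solutions until the relative change in the
#' cost drops below `conv_tol` (default 1e-4, i.e. 0.01%) or `max_iter` is
#' reached.
#'
#' @param q Separation filter order (>= 0); each filter has `q + 1` taps.
#' @param l1,l2 Integer lag-window bounds, `l1 <= l2`. The cost sums squared
#'   output cross-correlations over lags `l1..l2`.
#' @param max_iter Maximum number of alternating iterations (>= 1).
#' @param conv_tol Relative cost-change convergence threshold (> 0).
#' @param ridge Non-negative Tikhonov factor applied to the normal equations
#'   as `ridge * mean(diag(psi'psi)) * I`, guarding near-singular systems.
#' @return An object of class `bss_config`.
#' @export
bss_config <- function(q = 4L, l1 = -25L, l2 = 25L, max_iter = 100L,
                       conv_tol = 1e-4, ridge = 1e-8) {
  q <- as.integer(q); l1 <- as.integer(l1); l2 <- as.integer(l2)
  if (q < 0L) stop("bss_config: q must be >= 0", call. = FALSE)
  if (l2 < l1) stop("bss_config: need l1 <= l2", call. = FALSE)
  if (max_iter < 1L) stop("bss_config: max_iter must be >= 1", call. = FALSE)
  if (conv_tol <= 0) stop("bss_config: conv_tol must be positive",
                          call. = FALSE)
  if (ridge < 0) stop("bss_config: ridge must be non-negative", call. = FALSE)
  structure(list(q = q, l1 = l1, l2 = l2, max_iter = as.integer(max_iter),
                 conv_tol = conv_tol, ridge = ridge), class = "bss_config")
}

#' FIR cross-coupling mixing system
#'
#' Describes the 2x2 convolutive mixture with unit direct paths: observation
#' one is source one plus `h12` applied to source two, and observation two is
#' `h21` applied to source one plus source two.
#'
#' @param h12,h21 Numeric FIR coefficient vectors (cross paths). The direct
#'   paths are fixed at unity by convention.
#' @return An object of class `mixing_system` with fields `h12`, `h21`, `p`.
#' @export
mixing_system <- function(h12, h21) {
  h12 <- as.numeric(h12); h21 <- as.numeric(h21)
  if (!all(is.finite(h12)) || !all(is.finite(h21))) {
    stop("mixing_system: coefficients must be finite", call. = FALSE)
  }
  p <- max(length(h12), length(h21)) - 1L
  pad <- function(h) c(h, numeric(p + 1L - length(h)))
  structure(list(h12 = pad(h12), h21 = pad(h21), p = p),
            class = "mixing_system")
}

#' Mix two sources through a convolutive 2x2 system
#'
#' Forms the observations `x1 = s1 + h12 * s2` and `x2 = h21 * s1 + s2`
#' (causal FIR convolution, outputs truncated to the input length). Sources
#' are mean-centred first, matching the zero-mean assumption of the
#' separation model.
#'
#' @param s1,s2 Equal-length [signal1d()] sources.
#' @param mix A [mixing_system()].
#' @return A list with observations `x1` and `x2` (`signal1d`).
#' @export
convolutive_mix <- function(s1, s2, mix) {
  if (length(s1) != length(s2)) {
    stop("convolutive_mix: sources must have equal length", call. = FALSE)
  }
  if (!inherits(mix, "mixing_system")) {
    stop("convolutive_mix: mix must be a mixing_system", call. = FALSE)
  }
  a <- as_samples(s1) - mean(as_samples(s1))
  b <- as_samples(s2) - mean(as_samples(s2))
  x1 <- a + fir_apply(b, mix$h12)
  x2 <- fir_apply(a, mix$h21) + b
  list(x1 = resignal(x1, s1, label = "mix:x1"),
       x2 = resignal(x2, s2, label = "mix:x2"))
}

#' Biased sample cross-correlation at a single lag
#'
#' Returns the biased estimator `(1/N) * sum_k a(k) b(k+l)` over the valid
#' overlap, the statistic whose squared sum over a lag window defines the
#' separation cost. Symmetric under `(a, b, l) -> (b, a, -l)`.
#'
#' @param a,b Numeric vectors of equal length.
#' @param l Integer lag with `|l| < length(a)`.
#' @return A scalar correlation estimate.
#' @export
xcorr_lag <- function(a, b, l) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (length(b) != n) stop("xcorr_lag: equal lengths required", call. = FALSE)
  l <- as.integer(l)
  if (abs(l) >= n) stop("xcorr_lag: |l| must be < signal length",
                        call. = FALSE)
  if (l >= 0L) sum(a[seq_len(n - l)] * b[seq_len(n - l) + l]) / n
  else sum(a[seq_len(n + l) - l] * b[seq_len(n + l)]) / n
}

# vector of biased cross-correlations over a lag range
xcorr_range <- function(a, b, lags) {
  vapply(lags, function(l) xcorr_lag(a, b, l), numeric(1L))
}

#' Build the correlation workspace for one observation pair
#'
#' Precomputes every sample correlation statistic the iterative updates
#' need: the cross-correlation vector of the observations over the lag
#' window, the two shifted autocorrelation matrices, and the stacked
#' cross-correlation matrix feeding the bilinear term. Signals are
#' mean-centred before estimation. Matrix layouts (with `L = l2 - l1 + 1`):
#' \itemize{
#'   \item `q_plus_x2x2` is `(q+1) x L`, entry `(i, j) = r_x2x2(l_j + i)`,
#'     `i = 0..q`;
#'   \item `q_minus_x1x1` is `(q+1) x L`, entry `(i, j) = r_x1x1(l_j - i)`;
#'   \item `r_x2x1` is `(2q+1) x L`, row offsets `u = -q..q`, entry
#'     `(u, j) = r_x2x1(l_j + u)`.
#' }
#'
#' @param x1,x2 Equal-length signals with
#'   `length >= 2 * (q + max(|l1|, |l2|))`.
#' @param cfg A [bss_config()].
#' @return An object of class `bss_workspace`.
#' @export
build_workspace <- function(x1, x2, cfg) {
  stopifnot(inherits(cfg, "bss_config"))
  n <- length(x1)
  if (length(x2) != n) {
    stop("build_workspace: signals must have equal length", call. = FALSE)
  }
  need <- 2L * (cfg$q + max(abs(cfg$l1), abs(cfg$l2)))
  if (n < max(need, 2L)) {
    stop("build_workspace: signals too short (need >= ", need,
         " samples for q = ", cfg$q, ", lags ", cfg$l1, "..", cfg$l2, ")",
         call. = FALSE)
  }
  a <- as.numeric(x1) - mean(as.numeric(x1))
  b <- as.numeric(x2) - mean(as.numeric(x2))
  q <- cfg$q
  lags <- cfg$l1:cfg$l2
  L <- length(lags)
  # autocorrelations via symmetry r(-m) = r(m)
  amax <- max(abs(c(cfg$l1 - q, cfg$l2 + q)))
  r22 <- xcorr_range(b, b, 0:amax)
  r11 <- xcorr_range(a, a, 0:amax)
  auto <- function(r, m) r[abs(m) + 1L]
  qp <- outer(0:q, lags, function(i, l) auto(r22, l + i))
  qm <- outer(0:q, lags, function(i, l) auto(r11, l - i))
  cross_lags <- (cfg$l1 - q):(cfg$l2 + q)
  r21 <- xcorr_range(b, a, cross_lags)  # r_x2x1(m) = E[x2(k) x1(k+m)]
  names(r21) <- as.character(cross_lags)
  rmat <- outer(-q:q, lags, function(u, l) r21[as.character(l + u)])
  dimnames(rmat) <- NULL
  structure(list(
    r_x1x2 = xcorr_range(a, b, lags),
    q_plus_x2x2 = matrix(qp, nrow = q + 1L),
    q_minus_x1x1 = matrix(qm, nrow = q + 1L),
    r_x2x1 = matrix(rmat, nrow = 2L * q + 1L),
    lags = lags, q = q, n = n,
    x1c = a, x2c = b
  ), class = "bss_workspace")
}

# (2q+1) x (q+1) banded matrices carrying the partner weight so that
# t(r_x2x1) %*% A(w2) %*% w1 reproduces sum_{i,j} w1(i) w2(j) r_x2x1(l+i-j).
a_mat <- function(w2, q) {
  outer(-q:q, 0:q, function(u, i) {
    k <- i - u
    ifelse(k >= 0L & k <= q, w2[pmax(k, 0L) + 1L], 0)
  })
}

b_mat <- function(w1, q) {
  outer(-q:q, 0:q, function(u, j) {
    k <- j + u
    ifelse(k >= 0L & k <= q, w1[pmax(k, 0L) + 1L], 0)
  })
}

#' Closed-form output cross-correlation for given weights
#'
#' Evaluates the output cross-correlation vector over the configured lag
#' window directly from workspace statistics, without filtering any signal:
#' the observation cross-correlation plus the two affine autocorrelation
#' terms plus the bilinear term coupling both weight vectors. With
#' `w1 = w2 = 0` this is exactly the observation cross-correlation.
#'
#' @param ws A [build_workspace()] result.
#' @param w1,w2 Numeric weight vectors of length `q + 1`.
#' @return Numeric vector of predicted cross-correlations at lags `l1..l2`.
#' @export
predicted_xcorr <- function(ws, w1, w2) {
  stopifnot(inherits(ws, "bss_workspace"))
  q <- ws$q
  w1 <- as.numeric(w1); w2 <- as.numeric(w2)
  if (length(w1) != q + 1L || length(w2) != q + 1L) {
    stop("predicted_xcorr: weights must have length q + 1 = ", q + 1L,
         call. = FALSE)
  }
  as.numeric(
    ws$r_x1x2 +
      crossprod(ws$q_plus_x2x2, w1) +
      crossprod(ws$q_minus_x1x1, w2) +
      crossprod(ws$r_x2x1, a_mat(w2, q) %*% w1)
  )
}

#' Decorrelation cost
#'
#' The scalar objective of the separation: the sum of squared output
#' cross-correlations over the lag window, `sum_l r^2(l) = r'r`.
#'
#' @param r_y1y2 Non-empty numeric cross-correlation vector.
#' @return Non-negative scalar; zero iff all elements are zero.
#' @export
bss_cost <- function(r_y1y2) {
  if (length(r_y1y2) == 0L) {
    stop("bss_cost: empty cross-correlation vector", call. = FALSE)
  }
  sum(as.numeric(r_y1y2)^2)
}

#' One alternating update of the separation weights
#'
#' Solves the two coupled least-squares problems in sequence: `w1` from the
#' normal equations holding `w2` fixed, then `w2` holding the updated `w1`
#' fixed. Each sub-update exactly minimises the cost over its own weight
#' vector, so the cost never increases across a call.
#'
#' @param ws A [build_workspace()] result.
#' @param w1,w2 Current weight vectors (length `q + 1`).
#' @param cfg The [bss_config()] (supplies the ridge factor).
#' @return List with updated `w1` and `w2`.
#' @export
update_weights <- function(ws, w1, w2, cfg) {
  stopifnot(inherits(ws, "bss_workspace"), inherits(cfg, "bss_config"))
  q <- ws$q
  solve_ls <- function(psi, rhs) {
    g <- crossprod(psi)
    scale <- mean(diag(g))
    if (!is.finite(scale) || scale <= 0) return(numeric(q + 1L))
    g <- g + diag(cfg$ridge * scale, q + 1L)
    out <- tryCatch(solve(g, crossprod(psi, rhs)),
                    error = function(e) NULL)
    if (is.null(out)) {
      stop("update_weights: singular normal equations; set ridge > 0 in ",
           "bss_config()", call. = FALSE)
    }
    as.numeric(-out)
  }
  psi1 <- t(ws$q_plus_x2x2) + crossprod(ws$r_x2x1, a_mat(w2, q))
  w1_new <- solve_ls(psi1, ws$r_x1x2 + as.numeric(crossprod(ws$q_minus_x1x1, w2)))
  psi2 <- t(ws$q_minus_x1x1) + crossprod(ws$r_x2x1, b_mat(w1_new, q))
  w2_new <- solve_ls(psi2, ws$r_x1x2 + as.numeric(crossprod(ws$q_plus_x2x2, w1_new)))
  list(w1 = w1_new, w2 = w2_new)
}

#' Separate a 2x2 convolutive mixture by output decorrelation
#'
#' Starting from zero weights, alternates the two closed-form weight updates
#' until the relative change of the decorrelation cost falls below
#' `cfg$conv_tol` or `cfg$max_iter` iterations are reached. The outputs are
#' `y1 = x1 + w1 * x2` and `y2 = x2 + w2 * x1` (mean-centred observations,
#' causal FIR filtering). On convolutive mixtures of independent sources
#' with `q >= p` the weights approach the negated cross filters, so each
#' output carries a single source; on already-independent inputs (ECG plus
#' audio) the same minimisation delivers the decorrelating distortion that
#' the template stage builds on.
#'
#' @param x1,x2 Equal-length observations ([signal1d()] or numeric).
#' @param cfg A [bss_config()].
#' @return An object of class `bss_separation` with elements `w1`, `w2`,
#'   `y1`, `y2`, `cost_trajectory` (cost at zero weights first, then after
#'   each iteration), `iterations`, and `converged`. Non-convergence within
#'   `max_iter` is reported through `converged = FALSE`, not an error.
#' @examples
#' s1 <- signal1d(rnorm(2000), 500); s2 <- signal1d(rnorm(2000), 500)
#' xs <- convolutive_mix(s1, s2, mixing_system(h12 = 0.4, h21 = 0.3))
#' fit <- bss_separate(xs$x1, xs$x2, bss_config(q = 0, l1 = -5, l2 = 5))
#' fit$w1
#' @export
bss_separate <- function(x1, x2, cfg = bss_config()) {
  stopifnot(inherits(cfg, "bss_config"))
  if (length(x1) != length(x2)) {
    stop("bss_separate: observations must have equal length", call. = FALSE)
  }
  ws <- build_workspace(x1, x2, cfg)
  q <- cfg$q
  w1 <- numeric(q + 1L); w2 <- numeric(q + 1L)
  cost <- bss_cost(predicted_xcorr(ws, w1, w2))
  trajectory <- cost
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    upd <- update_weights(ws, w1, w2, cfg)
    w1 <- upd$w1; w2 <- upd$w2
    new_cost <- bss_cost(predicted_xcorr(ws, w1, w2))
    trajectory <- c(trajectory, new_cost)
    rel <- abs(cost - new_cost) / max(cost, .Machine$double.xmin)
    cost <- new_cost
    if (rel < cfg$conv_tol || new_cost < 1e-30) {
      converged <- TRUE
      break
    }
  }
  fs <- if (inherits(x1, "signal1d")) sig_fs(x1) else 1
  structure(list(
    w1 = w1, w2 = w2,
    y1 = signal1d(ws$x1c + fir_apply(ws$x2c, w1), fs = fs, label = "bss:y1"),
    y2 = signal1d(ws$x2c + fir_apply(ws$x1c, w2), fs = fs, label = "bss:y2"),
    cost_trajectory = trajectory,
    iterations = iter,
    converged = converged,
    config = cfg
  ), class = "bss_separation")
}

#' @export
print.bss_separation <- function(x, ...) {
  cat(sprintf(
    "<bss_separation> q = %d, lags %d..%d\n  iterations: %d (%s)\n  cost: %.4g -> %.4g (ratio %.3g)\n",
    x$config$q, x$config$l1, x$config$l2, x$iterations,
    if (x$converged) "converged" else "max_iter reached",
    x$cost_trajectory[1L], utils::tail(x$cost_trajectory, 1L),
    utils::tail(x$cost_trajectory, 1L) / max(x$cost_trajectory[1L],
                                             .Machine$double.xmin)))
  invisible(x)
}

#' Tidy methods for separation fits
#'
#' `tidy()` returns the per-iteration cost trajectory; `glance()` returns a
#' one-row summary (iterations, convergence flag, initial/final cost and
#' their ratio).
#'
#' @param x A `bss_separation` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @exportS3Method generics::tidy
tidy.bss_separation <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$cost_trajectory) - 1L,
                 cost = x$cost_trajectory)
}

#' @rdname tidy.bss_separation
#' @exportS3Method generics::glance
glance.bss_separation <- function(x, ...) {
  c0 <- x$cost_trajectory[1L]
  cf <- utils::tail(x$cost_trajectory, 1L)
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 cost_initial = c0, cost_final = cf,
                 cost_ratio = cf / max(c0, .Machine$double.xmin))
}

#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.bss_separation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "decorrelation cost (log scale)",
                  title = "Cost trajectory of alternating weight updates") +
    ggplot2::theme_minimal()
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
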