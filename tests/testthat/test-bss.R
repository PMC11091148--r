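test_that("convolutive mixing reproduces FIR impulse responses", {
  n <- 64L
  # zero-mean "doublet" probe so mean-centring is a no-op
  imp <- signal1d(c(1, -1, numeric(n - 2L)), 1)
  zeros <- signal1d(numeric(n) + 0, 1)
  mix <- convolutive_mix(imp, zeros, mixing_system(h12 = 0, h21 = 0.3))
  expect_equal(as.numeric(mix$x1), as.numeric(imp))
  expect_equal(as.numeric(mix$x2), 0.3 * as.numeric(imp))

  s <- white_pair(256, seed = 4)
  ident <- convolutive_mix(s$s1, s$s2, mixing_system(h12 = c(0, 0), h21 = c(0, 0)))
  expect_equal(as.numeric(ident$x1),
               as.numeric(s$s1) - mean(as.numeric(s$s1)))

  mix2 <- convolutive_mix(zeros, imp, mixing_system(h12 = c(0.4, 0.2), h21 = 0))
  expect_equal(as.numeric(mix2$x1)[1:4], c(0.4, -0.2, -0.2, 0))
  expect_error(convolutive_mix(imp, signal1d(1:10, 1), mixing_system(0, 0)),
               "equal length")
})

test_that("xcorr_lag matches the biased-estimator definition", {
  expect_equal(xcorr_lag(c(1, -1, 1, -1), c(1, -1, 1, -1), 0), 1.0)
  expect_equal(xcorr_lag(c(1, 1, -1, -1), c(1, -1, 1, -1), 0), 0.0)
  expect_equal(xcorr_lag(c(1, 0, 0, 0), c(0, 1, 0, 0), 1), 0.25)
  # symmetry under (a, b, l) -> (b, a, -l)
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  for (l in c(-7, -1, 0, 2, 13)) {
    expect_equal(xcorr_lag(a, b, l), xcorr_lag(b, a, -l))
  }
  expect_error(xcorr_lag(a, b, 50), "length")
})

test_that("workspace matrices have the stated shapes and decay off-lag", {
  s <- white_pair(10000, seed = 10)
  ws <- build_workspace(s$s1, s$s2, bss_config(q = 2, l1 = -5, l2 = 5))
  expect_equal(dim(ws$q_plus_x2x2), c(3L, 11L))
  expect_equal(dim(ws$q_minus_x1x1), c(3L, 11L))
  expect_equal(dim(ws$r_x2x1), c(5L, 11L))
  expect_length(ws$r_x1x2, 11L)

  ws0 <- build_workspace(s$s1, s$s2, bss_config(q = 0, l1 = 0, l2 = 0))
  expect_equal(as.numeric(ws0$r_x1x2),
               xcorr_lag(as.numeric(s$s1) - mean(as.numeric(s$s1)),
                         as.numeric(s$s2) - mean(as.numeric(s$s2)), 0))

  # white-noise autocorrelation off lag zero decays as 1/sqrt(n)
  off <- ws$q_plus_x2x2[cbind(1:3, 6:8)]  # entries with lag offset != 0 ...
  lagmat <- outer(0:2, -5:5, "+")
  expect_lt(max(abs(ws$q_plus_x2x2[lagmat != 0])), 3 / sqrt(10000))
  expect_error(build_workspace(s$s1, signal1d(rnorm(100), 500),
                               bss_config()), "equal length")
  expect_error(
    build_workspace(signal1d(rnorm(30), 500), signal1d(rnorm(30), 500),
                    bss_config(q = 4, l1 = -25, l2 = 25)),
    "too short")
})

test_that("closed-form cross-correlation agrees with brute-force filtering", {
  s <- white_pair(5000, seed = 12)
  mixed <- convolutive_mix(s$s1, s$s2,
                           mixing_system(h12 = c(0.5, -0.2), h21 = c(0.3)))
  for (q in c(0L, 2L)) {
    cfg <- bss_config(q = q, l1 = -10, l2 = 10)
    ws <- build_workspace(mixed$x1, mixed$x2, cfg)
    withr::with_seed(q + 1L, {
      w1 <- runif(q + 1L, -0.5, 0.5); w2 <- runif(q + 1L, -0.5, 0.5)
    })
    pred <- predicted_xcorr(ws, w1, w2)
    emp <- empirical_output_xcorr(mixed$x1, mixed$x2, w1, w2, -10:10)
    expect_lt(max(abs(pred - emp)), 2 * (1 + q + 10) / 5000)
    # zero weights reproduce the observation cross-correlation exactly
    expect_equal(predicted_xcorr(ws, numeric(q + 1L), numeric(q + 1L)),
                 as.numeric(ws$r_x1x2))
    # affine in w1 at fixed w2: p(a w1) - p(0) scales linearly
    p0 <- predicted_xcorr(ws, numeric(q + 1L), w2)
    p1 <- predicted_xcorr(ws, w1, w2)
    p2 <- predicted_xcorr(ws, 2 * w1, w2)
    expect_equal(p2 - p0, 2 * (p1 - p0), tolerance = 1e-12)
  }
  expect_error(predicted_xcorr(
    build_workspace(s$s1, s$s2, bss_config(q = 1, l1 = -2, l2 = 2)),
    c(0.1), c(0.1, 0.2)), "length q \\+ 1")
})

test_that("the decorrelation cost is the squared norm of the lag vector", {
  expect_equal(bss_cost(c(0, 0, 0)), 0)
  expect_equal(bss_cost(c(0.3, -0.4)), 0.25)
  r <- c(0.1, -0.2, 0.05)
  expect_equal(bss_cost(2 * r), 4 * bss_cost(r))
  expect_error(bss_cost(numeric(0)), "empty")
})

test_that("weight updates solve the coupled normal equations", {
  # independent observations: right-hand sides vanish, so do the weights
  s <- white_pair(10000, seed = 14)
  cfg <- bss_config(q = 1, l1 = -5, l2 = 5)
  ws <- build_workspace(s$s1, s$s2, cfg)
  upd <- update_weights(ws, c(0, 0), c(0, 0), cfg)
  expect_lt(max(abs(c(upd$w1, upd$w2))), 5 / sqrt(10000))

  # scalar analytic fixed point: x1 = s1 + c s2, x2 = s2 gives w1 = -c
  mixed <- convolutive_mix(s$s1, s$s2, mixing_system(h12 = 0.5, h21 = 0))
  cfg0 <- bss_config(q = 0, l1 = 0, l2 = 0)
  ws0 <- build_workspace(mixed$x1, mixed$x2, cfg0)
  upd0 <- update_weights(ws0, 0, 0, cfg0)
  expect_equal(upd0$w1, -0.5, tolerance = 0.05)

  # a converged state is a fixed point: one more sweep moves the cost by
  # less than the convergence threshold
  fit <- bss_separate(mixed$x1, mixed$x2, bss_config(q = 0, l1 = -3, l2 = 3,
                                                     max_iter = 5000))
  expect_true(fit$converged)
  ws2 <- build_workspace(mixed$x1, mixed$x2, fit$config)
  extra <- update_weights(ws2, fit$w1, fit$w2, fit$config)
  c_before <- bss_cost(predicted_xcorr(ws2, fit$w1, fit$w2))
  c_after <- bss_cost(predicted_xcorr(ws2, extra$w1, extra$w2))
  expect_lt(abs(c_before - c_after) / max(c_before, .Machine$double.xmin),
            fit$config$conv_tol)
})

test_that("separation recovers the negated mixing filters on white mixtures", {
  s <- white_pair(10000, seed = 1)
  mixed <- convolutive_mix(s$s1, s$s2,
                           mixing_system(h12 = c(0.4, 0.2), h21 = c(0.3, 0.1)))
  fit <- bss_separate(mixed$x1, mixed$x2,
                      bss_config(q = 1, l1 = -10, l2 = 10, max_iter = 5000))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$w1 - c(-0.4, -0.2))), 0.05)
  expect_lt(max(abs(fit$w2 - c(-0.3, -0.1))), 0.05)
  expect_lte(tail(fit$cost_trajectory, 1), fit$cost_trajectory[1])
})

test_that("degenerate and scaled inputs behave predictably", {
  s <- white_pair(4000, seed = 16)
  zeros <- signal1d(numeric(4000) + 0, 500)
  cfg <- bss_config(q = 1, l1 = -5, l2 = 5)
  fit <- bss_separate(s$s1, zeros, cfg)
  expect_equal(as.numeric(fit$y1),
               as.numeric(s$s1) - mean(as.numeric(s$s1)))
  expect_equal(fit$w1, c(0, 0))

  # scale equivariance: alpha * inputs -> alpha * outputs, same weights
  fit1 <- bss_separate(s$s1, s$s2, cfg)
  fit2 <- bss_separate(signal1d(3 * as.numeric(s$s1), 500),
                       signal1d(3 * as.numeric(s$s2), 500), cfg)
  expect_equal(fit2$w1, fit1$w1, tolerance = 1e-8)
  expect_equal(as.numeric(fit2$y1), 3 * as.numeric(fit1$y1),
               tolerance = 1e-8)
})

test_that("cost trajectory is monotone and tidy/glance expose it", {
  pair <- ecg_audio_pair(n = 5000L)
  fit <- bss_separate(pair$ecg, pair$audio, bss_config(q = 2, l1 = -10,
                                                       l2 = 10))
  expect_true(all(diff(fit$cost_trajectory) <= 1e-12))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(fit$cost_trajectory))
  gl <- generics::glance(fit)
  expect_lte(gl$cost_final, gl$cost_initial)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
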