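test_that("overlapping-waves test finds the known crossing in a constructed fixture", {
  # cluster A dominates windows 1-8, B dominates 9-16, with subject noise
  set.seed(50)
  nw <- 16; ns <- 8
  profA <- c(rep(0.8, 8), rep(0.55, 8))
  profB <- c(rep(0.55, 8), rep(0.8, 8))
  tgs <- lapply(1:ns, function(s) {
    rbind(t(replicate(3, profA + rnorm(nw, 0, 0.02))),
          t(replicate(3, profB + rnorm(nw, 0, 0.02))))
  })
  assign6 <- structure(list(cluster = rep(1:2, each = 3), k = 2L),
                       class = "cluster_assignment")
  wt <- overlapping_waves_test(tgs, assign6)
  best <- wt[wt$is_best, ]
  expect_true(all(best$cluster[best$window <= 8] == 1))
  expect_true(all(best$cluster[best$window >= 9] == 2))
  # all windows decode reliably here, so no tier is masked
  expect_true(all(wt$reliable))
  # the non-best cluster is reliably worse away from the crossing
  worse <- wt[!wt$is_best & wt$window %in% c(1:6, 11:16), ]
  expect_true(all(worse$tier >= 1))
  expect_true(all(wt$p_adj >= 0 & wt$p_adj <= 1, na.rm = TRUE))
  expect_error(overlapping_waves_test(tgs[1], assign6), "2 subjects")
})

test_that("generalization width counts significant test windows", {
  spec <- window_spec(epoch_ms = 400, window_ms = 50, step_ms = 50)
  nw <- spec$n_windows
  flat <- lapply(1:6, function(s) matrix(0.5, nw, nw))
  w0 <- generalization_width(flat, spec)
  expect_true(all(w0$width == 0))
  perfect <- lapply(1:6, function(s) matrix(1.0, nw, nw))
  w1 <- generalization_width(perfect, spec)
  expect_true(all(w1$width == nw))
  expect_true(all(w1$proportion == 1))
  # i.i.d. chance accuracies: false-positive rate near the nominal threshold
  set.seed(51)
  fp <- replicate(40, {
    null <- lapply(1:8, function(s) matrix(rnorm(nw * nw, 0.5, 0.05), nw, nw))
    mean(generalization_width(null, spec, p_threshold = 0.01)$width) / nw
  })
  expect_lt(abs(mean(fp) - 0.01), 0.01)
  bad <- flat; bad[[2]] <- matrix(0.5, nw + 1, nw + 1)
  expect_error(generalization_width(bad, spec), "mismatch")
})

test_that("piecewise fit recovers a noiseless hinge and prefers lines for linear data", {
  x <- seq(0, 1550, by = 50)
  y <- pmin(0.2 + 0.0016 * x, 0.2 + 0.0016 * 450)   # hinge at x = 450
  pf <- piecewise_fit(x, y, max_breakpoints = 2)
  expect_equal(unname(pf$n_breakpoints), 1)
  expect_equal(unname(pf$breakpoints), 450)
  # with noise and an off-grid hinge, a breakpoint lands within resolution
  set.seed(54)
  yh <- pmin(0.2 + 0.0016 * x, 0.2 + 0.0016 * 468.75) + rnorm(length(x), 0, 0.02)
  ph <- piecewise_fit(x, yh, max_breakpoints = 2)
  expect_gte(ph$n_breakpoints, 1)
  expect_lt(min(abs(ph$breakpoints - 468.75)), 100)
  expect_gt(pf$segment_slopes[1], 0)
  expect_lt(abs(pf$segment_slopes[2]), 1e-6)
  expect_gt(pf$r_squared, 0.999)
  ylin <- 0.1 + 0.0005 * x
  expect_equal(piecewise_fit(x, ylin, max_breakpoints = 2)$n_breakpoints, 0)
  # zero breakpoints equals ordinary least squares exactly
  set.seed(52)
  yn <- ylin + rnorm(length(x), 0, 0.05)
  p0 <- piecewise_fit(x, yn, max_breakpoints = 0)
  ols <- lm(yn ~ x)
  expect_equal(unname(p0$coef), unname(coef(ols)), tolerance = 1e-10)
  expect_error(piecewise_fit(1:3, 1:2), "length")
})

test_that("VoC: trivial limits, shift invariance and quadratic scaling", {
  el <- data.frame(electrode = 1:3, y = c(-60, -40, -20))
  nw <- 11
  cfm <- cbind(rep(1, nw),                       # constant -> no nonzero deltas
               seq(0, 1, length.out = nw),      # linear ramp -> equal deltas
               rep(c(1, -1), length.out = nw))  # alternating +-1
  v <- coefficient_voc(cfm, el, lag_windows = 1)
  expect_true(is.na(v$voc[1]))
  expect_equal(v$voc[2], 0)
  n <- nw - 1                                   # deltas of +-2, mean zero
  expect_equal(v$voc[3], 4 * n / (n - 1))
  # adding a constant changes nothing; scaling the series scales VoC by c^2
  v2 <- coefficient_voc(cfm + 10, el, lag_windows = 1)
  expect_equal(v2$voc, v$voc)
  v3 <- coefficient_voc(cfm * 3, el, lag_windows = 1)
  expect_equal(v3$voc[3], 9 * v$voc[3])
  expect_error(coefficient_voc(cfm, el, lag_windows = 11), "lag")
  # lag 5 on 160 windows leaves 155 deltas
  cf160 <- matrix(rnorm(160), 160, 1)
  v155 <- coefficient_voc(cf160, data.frame(electrode = 1, y = 0),
                          lag_windows = 5)
  expect_equal(v155$n_nonzero, 155)
})

test_that("VoC gradient: recovery fixture and degrees of freedom", {
  set.seed(53)
  subs <- sprintf("s%02d", 1:8)
  voc <- do.call(rbind, lapply(subs, function(s) {
    y <- runif(20, -64, -8)
    data.frame(subject = s, electrode = 1:20, y = y,
               voc = y + 64 + rnorm(20, 0, 0.5), n_nonzero = 10)
  }))
  g <- voc_gradient(voc)
  expect_equal(g$decile_slope, 1, tolerance = 0.1)
  expect_gt(g$decile_r_squared, 0.95)
  expect_equal(g$slope_df, 7)
  expect_lt(g$slope_p, 0.01)
  expect_equal(nrow(g$decile), 10)
  # flat VoC: no gradient signal
  vf <- voc; vf$voc <- 5
  gf <- suppressWarnings(voc_gradient(vf))
  expect_equal(gf$decile_slope, 0, tolerance = 1e-10)
  expect_error(voc_gradient(voc[1:5, ]), "fewer than 10")
})
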