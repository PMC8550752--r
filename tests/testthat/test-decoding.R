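test_that("window arithmetic reproduces the standard geometries", {
  spec <- window_spec()
  expect_equal(spec$n_windows, 160L)
  expect_equal(spec$n_nonoverlapping, 32L)
  expect_equal(spec$starts_ms[1], 0)
  expect_equal(tail(spec$starts_ms, 1), 1590)
  one <- window_spec(epoch_ms = 500, window_ms = 500)
  expect_equal(one$n_windows, 1L)
  expect_error(window_spec(epoch_ms = 40, window_ms = 50), "longer")
  # degradation for arbitrary epochs
  s2 <- window_spec(epoch_ms = 437, window_ms = 50, step_ms = 10)
  expect_equal(s2$n_windows, floor((437 - 50) / 10) + 1L)
  expect_equal(s2$n_nonoverlapping, floor(437 / 50))
})

test_that("sliding features are electrode-major and sized n_el * samples", {
  set.seed(1)
  ep <- array(rnorm(4 * 3 * 120), c(4, 3, 120))
  spec <- window_spec(epoch_ms = 120, window_ms = 50, step_ms = 10)
  fl <- sliding_window_features(ep, spec)
  expect_length(fl, spec$n_windows)
  expect_equal(dim(fl[[1]]), c(4, 150))
  # electrode-major: first 50 features are electrode 1's samples
  expect_equal(fl[[1]][2, 1:50], ep[2, 1, 1:50])
  expect_equal(fl[[1]][2, 51:100], ep[2, 2, 1:50])
  expect_equal(fl[[3]][1, 1:50], ep[1, 1, 21:70])
  expect_error(sliding_window_features(ep[, , 1:40, drop = FALSE], spec),
               "samples")
})

test_that("plain decoder: separable, constant and permuted-label cases", {
  set.seed(10)
  x <- matrix(c(rnorm(30, -2), rnorm(30, 2)), ncol = 1)
  y <- rep(0:1, each = 30)
  d <- fit_plain_decoder(x, y)
  expect_equal(d$cv_accuracy, 1.0)
  expect_equal(mean(predict(d, x) == y), 1.0)
  # constant feature: LOO prediction is the training majority class
  xc <- matrix(1, 60, 1)
  yb <- rep(c(0, 1), c(20, 40))
  expect_equal(fit_plain_decoder(xc, yb)$cv_accuracy, 40 / 60)
  # permuted labels: accuracy inside the 95% binomial band around 0.5
  set.seed(11)
  xr <- matrix(rnorm(60 * 3), 60, 3)
  yr <- sample(rep(0:1, 30))
  band <- qbinom(c(0.025, 0.975), 60, 0.5) / 60
  acc <- fit_plain_decoder(xr, yr)$cv_accuracy
  expect_gte(acc, band[1] - 0.1)  # LOO is slightly pessimistic under the null
  expect_lte(acc, band[2])
  expect_error(fit_plain_decoder(xr, rep(1, 60)), "single class")
})

test_that("closed-form maximal penalty zeroes the L1 decoder (glmnet oracle)", {
  set.seed(20)
  n <- 60; p <- 40
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(0:1, each = n / 2)
  x[, 1] <- x[, 1] + y          # informative feature
  st <- decodyn:::fit_standardizer(x)
  xs <- decodyn:::apply_standardizer(x, st)
  lmax <- l1_max_lambda(xs, y)
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                        standardize = FALSE,
                        lambda = c(lmax * 1.05, lmax, lmax * 0.5))
  expect_equal(sum(abs(fit$beta[, 1])), 0)  # above the closed-form maximum
  expect_equal(sum(abs(fit$beta[, 2])), 0)  # at it
  expect_gt(sum(abs(fit$beta[, 3])), 0)     # below it
})

test_that("nested L1 decoder: fold structure, separable and null data", {
  set.seed(21)
  n <- 100
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20)
  x[, 1:3] <- x[, 1:3] + 2 * y          # cleanly separable
  d <- fit_l1_decoder_nested(x, y, n_lambda = 25)
  expect_length(d$fold_accuracy, 10)    # 10 hold-out sets of 10
  expect_gt(d$cv_accuracy, 0.9)
  expect_equal(length(d$coef), 20)
  # null features: accuracy near chance, heavy regularization
  set.seed(22)
  xn <- matrix(rnorm(n * 20), n, 20)
  dn <- fit_l1_decoder_nested(xn, y, n_lambda = 25)
  expect_lt(abs(dn$cv_accuracy - 0.5), 0.2)
  expect_error(fit_l1_decoder_nested(x, rep(0, n)), "single class")
})

test_that("temporal generalization: constant code gives constant rows", {
  set.seed(30)
  n <- 40
  y <- rep(0:1, each = n / 2)
  f <- matrix(rnorm(n * 4), n, 4); f[, 1] <- f[, 1] + 2 * y
  feats <- replicate(5, f, simplify = FALSE)   # identical at all windows
  decs <- lapply(feats, fit_plain_decoder, labels = y)
  tg <- temporal_generalization(decs, feats, y)
  expect_equal(dim(tg$accuracy), c(5, 5))
  expect_true(all(tg$accuracy >= 0 & tg$accuracy <= 1))
  off <- tg$accuracy; diag(off) <- NA
  for (r in 1:5) {
    vals <- stats::na.omit(off[r, ])
    expect_equal(max(vals) - min(vals), 0)
  }
  expect_equal(diag(tg$accuracy),
               vapply(decs, function(d) d$cv_accuracy, 0))
  bad <- feats; bad[[2]] <- f[, 1:3]
  expect_error(temporal_generalization(decs, bad, y), "mismatch")
})

test_that("profile clustering recovers block structure and is permutation-stable", {
  set.seed(40)
  p1 <- c(rep(0.9, 10), rep(0.5, 10))
  p2 <- c(rep(0.5, 10), rep(0.9, 10))
  m <- rbind(t(replicate(6, p1 + rnorm(20, 0, 0.01))),
             t(replicate(6, p2 + rnorm(20, 0, 0.01))))
  cl <- cluster_profiles(m, k = 2)
  expect_equal(cl$cluster[1:6], rep(cl$cluster[1], 6))
  expect_equal(cl$cluster[7:12], rep(cl$cluster[7], 6))
  expect_false(cl$cluster[1] == cl$cluster[7])
  # permutation invariance up to relabeling
  perm <- sample(12)
  cl2 <- cluster_profiles(m[perm, ], k = 2)
  expect_equal(length(unique(paste(cl$cluster[perm], cl2$cluster))), 2)
  # singleton clusters reproduce the rows
  cls <- cluster_profiles(m, k = 12)
  expect_equal(sort(unique(cls$cluster)), 1:12)
  expect_equal(cls$profiles[cls$cluster, ], unname(m), tolerance = 1e-12)
  expect_error(cluster_profiles(m, k = 13), "exceeds")
})

test_that("binomial thresholds match exact tail sums", {
  # brute-force oracle on a small case
  brute <- function(n, ntests, alpha) {
    pmf <- dbinom(0:n, n, 0.5)
    for (k in 0:n) if (ntests * sum(pmf[(k + 2):(n + 1)]) < alpha) return(k)
  }
  for (case in list(c(10, 3, 0.2), c(25, 7, 0.05), c(12, 1, 0.9))) {
    got <- binomial_threshold(case[1], case[2], case[3])$threshold
    expect_equal(got, brute(case[1], case[2], case[3]))
  }
  t60 <- binomial_threshold(60, 330)
  expect_equal(t60$threshold, 44)
  expect_lt(t60$p_corrected, 0.05)
  # the inclusive convention would give one more
  expect_gte(330 * t60$p_inclusive, 0.05)
  expect_equal(binomial_threshold(100, 320)$threshold, 68)
  expect_error(binomial_threshold(60, 330, alpha = 1.2), "alpha")
})

test_that("unit-category correlations and the critical band", {
  env <- generate_environment(env_config(seed = 2))
  lab <- as.integer(env$domain_label[env$domain_label %in% c(1, 2)] == 2)
  act <- array(rnorm(60 * 4 * 5), c(60, 4, 5))
  act[, 1, ] <- lab                        # unit 1 mirrors the label
  act[, 2, ] <- 0.7                        # constant unit
  traj <- structure(list(activations = act), class = "trajectory_tensor")
  uc <- unit_category_correlation(traj, lab)
  expect_equal(unname(uc$r[1, ]), rep(1, 5))
  expect_true(all(is.na(uc$r[2, ])))
  expect_equal(uc$critical_r, 0.254, tolerance = 1e-3)
})

test_that("channel subsampling is seeded, size-checked and identity at k = n", {
  act <- array(rnorm(6 * 10 * 3), c(6, 10, 3))
  traj <- structure(list(activations = act, unit_layer = rep("hub", 10)),
                    class = "trajectory_tensor")
  s1 <- subsample_channels(traj, k = 3, seed = 5)
  s2 <- subsample_channels(traj, k = 3, seed = 5)
  expect_identical(s1$subsampled_units, s2$subsampled_units)
  expect_equal(dim(s1$activations), c(6, 3, 3))
  sid <- subsample_channels(traj, k = 10, seed = 1)
  expect_equal(sid$activations, act)
  expect_error(subsample_channels(traj, k = 11), "exceeds")
})
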