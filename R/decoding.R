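#' Sliding-window geometry
#'
#' Defines the sliding-window scheme used for decoding: windows of
#' `window_ms` advancing in `step_ms` increments across an epoch of
#' `epoch_ms`, sampled at `sampling_rate_hz`. Window w covers samples
#' `[start, start + window)` with starts `0, step, 2*step, ...`. The
#' default geometry (1640 ms epoch, 50 ms windows, 10 ms steps at 1000 Hz)
#' yields 160 windows, of which 32 are fully non-overlapping.
#'
#' @param epoch_ms Epoch length in ms post stimulus onset (default 1640).
#' @param window_ms Window length in ms (default 50).
#' @param step_ms Step between window starts in ms (default 10).
#' @param sampling_rate_hz Sampling rate (default 1000).
#' @return An object of class `window_spec` with `n_windows`,
#'   `n_nonoverlapping`, `starts_ms` and the geometry fields.
#' @export
window_spec <- function(epoch_ms = 1640, window_ms = 50, step_ms = 10,
                        sampling_rate_hz = 1000) {
  if (window_ms > epoch_ms) stop("window longer than epoch")
  n_windows <- floor((epoch_ms - window_ms) / step_ms) + 1L
  structure(list(
    epoch_ms = epoch_ms, window_ms = window_ms, step_ms = step_ms,
    sampling_rate_hz = sampling_rate_hz,
    n_windows = as.integer(n_windows),
    n_nonoverlapping = as.integer(floor(epoch_ms / window_ms)),
    starts_ms = seq(0, by = step_ms, length.out = n_windows)
  ), class = "window_spec")
}

# Indices (into 1..n_windows) of the fully non-overlapping window subset:
# starts at multiples of window_ms, up to floor(epoch/window) windows.
nonoverlapping_windows <- function(spec) {
  starts <- seq(0, by = spec$window_ms, length.out = spec$n_nonoverlapping)
  idx <- match(starts, spec$starts_ms)
  idx[!is.na(idx)]
}

#' Extract per-window feature matrices from stimulus epochs
#'
#' Cuts each stimulus's averaged voltage epoch into sliding windows and
#' concatenates the within-window samples electrode-major (all samples of
#' electrode 1, then electrode 2, ...), giving one feature matrix
#' (stimuli x electrodes*samples_per_window) per window.
#'
#' @param epochs 3-d array, stimuli x electrodes x samples (samples at
#'   `sampling_rate_hz` starting at stimulus onset).
#' @param spec A [window_spec()].
#' @return List of length `n_windows` of feature matrices.
#' @export
sliding_window_features <- function(epochs, spec = window_spec()) {
  stopifnot(length(dim(epochs)) == 3)
  ns <- dim(epochs)[3]
  spw <- round(spec$window_ms * spec$sampling_rate_hz / 1000)
  step <- round(spec$step_ms * spec$sampling_rate_hz / 1000)
  need <- (spec$n_windows - 1L) * step + spw
  if (ns < need) stop("epoch has ", ns, " samples; geometry needs ", need)
  n_el <- dim(epochs)[2]
  lapply(seq_len(spec$n_windows), function(w) {
    s0 <- (w - 1L) * step
    # electrode-major: features ordered electrode, then sample offset
    m <- epochs[, , s0 + seq_len(spw), drop = FALSE]          # stim x el x spw
    m <- aperm(m, c(1L, 3L, 2L))                               # stim x spw x el
    dim(m) <- c(dim(epochs)[1], spw * n_el)
    m
  })
}

#' Closed-form maximal L1 penalty
#'
#' The smallest L1 penalty at which every coefficient of an
#' intercept-only-initialised logistic lasso is exactly zero:
#' `max_j |x_j' (y - mean(y))| / n` for standardized features.
#'
#' @param x Feature matrix (observations x features), already standardized.
#' @param y 0/1 labels.
#' @return Scalar penalty.
#' @export
l1_max_lambda <- function(x, y) {
  r <- y - mean(y)
  max(abs(crossprod(x, r))) / length(y)
}

# z-score with training-set parameters; zero-variance columns pass through.
fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
apply_standardizer <- function(x, st) sweep(sweep(x, 2, st$mu), 2, st$sd, "/")

# stratified fold assignment: balanced classes into k folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < k && length(unique(y)) > 1 && length(idx) < 1)
      stop("cannot stratify: class with no members")
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(split(y, fold), function(s) length(unique(s)), 1L) < 2))
    stop("degenerate folds: a fold contains a single class")
  fold
}

#' Plain logistic decoder with leave-one-out diagonal accuracy
#'
#' Unregularized logistic regression (via `glm`, binomial family) on
#' mean-centered features, as used for the simulated hub decoding.
#' The diagonal accuracy is leave-one-out: each item is predicted from a
#' model fit on the remaining items. The returned decoder is refit on all
#' items for testing at other time points.
#'
#' @param features Numeric matrix (items x features).
#' @param labels 0/1 vector.
#' @return An object of class `decoder` with `coef`, `intercept`,
#'   `cv_accuracy` (LOO), `center` (feature means), `kind = "plain"`.
#' @export
fit_plain_decoder <- function(features, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  x <- scale(features, center = TRUE, scale = FALSE)
  ctr <- attr(x, "scaled:center")
  n <- nrow(x)
  correct <- logical(n)
  sep <- FALSE
  for (i in seq_len(n)) {
    xi <- scale(features[-i, , drop = FALSE], center = TRUE, scale = FALSE)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, xi), labels[-i],
                                           family = stats::binomial()))
    sep <- sep || !fit$converged
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0          # aliased (constant) features drop out
    xt <- features[i, ] - attr(xi, "scaled:center")
    pr <- stats::plogis(sum(c(1, xt) * cf))
    correct[i] <- (pr > 0.5) == (labels[i] == 1)
  }
  full <- suppressWarnings(stats::glm.fit(cbind(1, x), labels,
                                          family = stats::binomial()))
  fc <- full$coefficients
  fc[is.na(fc)] <- 0
  structure(list(
    coef = fc[-1], intercept = fc[1],
    center = ctr, scale = NULL, kind = "plain",
    cv_accuracy = mean(correct), separable = sep || !full$converged
  ), class = "decoder")
}

#' L1-regularized logistic decoder with nested cross-validation
#'
#' Outer stratified 10-fold cross-validation estimates hold-out accuracy; in
#' each outer training set a 9-fold cross-validation selects the L1 penalty
#' from a log-spaced grid running from the closed-form all-zero penalty
#' ([l1_max_lambda()]) down to `1e-4` of it. Ties in inner-CV accuracy are
#' broken toward stronger regularization. Features are z-scored with
#' parameters estimated inside each training fold. The final decoder is fit
#' on all data at the penalty selected by 10-fold cross-validation on the
#' full data.
#'
#' @param features Numeric matrix (stimuli x features).
#' @param labels 0/1 vector (balanced classes assumed for stratification).
#' @param n_lambda Grid size (default 50).
#' @param n_outer,n_inner Fold counts (defaults 10 and 9).
#' @param nested If `FALSE`, skip the outer loop and take hold-out accuracy
#'   from the full-data cross-validation at the selected penalty (a cheaper
#'   single-level scheme for large scripted runs; the default matches the
#'   nested procedure).
#' @param folds Optional fixed stratified fold assignment (integer vector)
#'   reused for the full-data cross-validation — the convention for
#'   sliding-window analyses, where one partition is shared by all windows
#'   of a subject so that window-to-window coefficient changes reflect the
#'   data, not fold resampling. Default: drawn fresh.
#' @return A `decoder` with `coef`, `intercept`, `center`, `scale`,
#'   `lambda`, `fold_accuracy` (per outer fold), `cv_accuracy` (their mean),
#'   `kind = "l1"`.
#' @export
fit_l1_decoder_nested <- function(features, labels, n_lambda = 50L,
                                  n_outer = 10L, n_inner = 9L, nested = TRUE,
                                  folds = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  st0 <- fit_standardizer(features)
  lam_max <- l1_max_lambda(apply_standardizer(features, st0), labels)
  if (lam_max <= 0) lam_max <- 1e-3
  grid <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = n_lambda))

  cv_grid <- function(x, y, k, fold = NULL) {
    # k-fold CV over the fixed grid. The penalty minimizing mean hold-out
    # binomial deviance is selected (deviance is smooth in the penalty,
    # where hold-out accuracy plateaus and makes the selection unstable
    # from window to window); ties break toward stronger penalties via
    # which.min's first-match rule on the decreasing grid. Hold-out
    # accuracies at the selected penalty are returned alongside.
    if (is.null(fold)) fold <- stratified_folds(y, k)
    acc <- matrix(NA_real_, k, length(grid))
    dev <- matrix(NA_real_, k, length(grid))
    for (f in seq_len(k)) {
      tr <- fold != f
      st <- fit_standardizer(x[tr, , drop = FALSE])
      fit <- glmnet::glmnet(apply_standardizer(x[tr, , drop = FALSE], st),
                            y[tr], family = "binomial", alpha = 1,
                            lambda = grid, standardize = FALSE, thresh = 1e-5)
      pr <- stats::predict(fit, apply_standardizer(x[!tr, , drop = FALSE], st),
                           s = grid, type = "response")
      pr <- matrix(pmin(pmax(as.numeric(pr), 1e-12), 1 - 1e-12),
                   ncol = length(grid))
      yt <- y[!tr]
      dev[f, ] <- -2 * colMeans(yt * log(pr) + (1 - yt) * log(1 - pr))
      acc[f, ] <- colMeans((pr > 0.5) == (yt == 1))
    }
    sel <- which.min(colMeans(dev))
    list(lambda = grid[sel], sel = sel, acc = acc)
  }
  select_lambda <- function(x, y, k) cv_grid(x, y, k)$lambda

  fold_acc <- NULL
  if (nested) {
    outer <- stratified_folds(labels, n_outer)
    fold_acc <- numeric(n_outer)
    for (f in seq_len(n_outer)) {
      tr <- outer != f
      lam <- select_lambda(features[tr, , drop = FALSE], labels[tr], n_inner)
      st <- fit_standardizer(features[tr, , drop = FALSE])
      fit <- glmnet::glmnet(apply_standardizer(features[tr, , drop = FALSE], st),
                            labels[tr], family = "binomial", alpha = 1,
                            lambda = grid, standardize = FALSE, thresh = 1e-5)
      pr <- stats::predict(fit, apply_standardizer(features[!tr, , drop = FALSE], st),
                           s = lam, type = "class")
      fold_acc[f] <- mean(as.numeric(pr) == labels[!tr])
    }
  }

  full_cv <- cv_grid(features, labels, n_outer, fold = folds)
  lam_full <- full_cv$lambda
  fit <- glmnet::glmnet(apply_standardizer(features, st0), labels,
                        family = "binomial", alpha = 1, lambda = grid,
                        standardize = FALSE, thresh = 1e-5)
  beta <- as.numeric(stats::predict(fit, s = lam_full, type = "coefficients"))
  if (!nested) {
    # single-level scheme: hold-out accuracy taken from the selection folds
    # at the selected penalty
    fold_acc <- full_cv$acc[, full_cv$sel]
  }
  structure(list(
    coef = beta[-1], intercept = beta[1],
    center = st0$mu, scale = st0$sd, kind = "l1",
    lambda = lam_full, lambda_max = lam_max, lambda_grid = grid,
    fold_accuracy = fold_acc, cv_accuracy = mean(fold_acc),
    nested = nested
  ), class = "decoder")
}

#' Predict class labels from a fitted decoder
#'
#' Applies the decoder's own standardization (centering, and scaling for L1
#' decoders) before the linear rule.
#'
#' @param object A `decoder`.
#' @param newdata Feature matrix with the decoder's feature dimension.
#' @param ... Unused.
#' @return Integer 0/1 predictions.
#' @export
predict.decoder <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$coef))
    stop("feature dimension mismatch: decoder has ", length(object$coef),
         ", data has ", ncol(newdata))
  x <- sweep(newdata, 2, object$center)
  if (!is.null(object$scale)) x <- sweep(x, 2, object$scale, "/")
  eta <- object$intercept + as.numeric(x %*% object$coef)
  as.integer(eta > 0)
}

#' Train-everywhere / test-everywhere temporal generalization
#'
#' Builds the train-window x test-window accuracy matrix: the diagonal holds
#' each window's cross-validated hold-out accuracy; off-diagonal entries are
#' the accuracy of each window's final (all-data) decoder applied to the
#' features of every other window, using the training window's own
#' standardization parameters.
#'
#' @param decoders List of `decoder` objects, one per window.
#' @param features_all_windows List of feature matrices (same stimuli), one
#'   per window.
#' @param labels 0/1 labels for the stimuli.
#' @return An object of class `tg_result`: `accuracy` (n x n matrix),
#'   `decoders`, `labels`.
#' @export
temporal_generalization <- function(decoders, features_all_windows, labels) {
  n <- length(decoders)
  if (length(features_all_windows) != n)
    stop("need one feature matrix per decoder")
  p <- length(decoders[[1]]$coef)
  for (f in features_all_windows)
    if (ncol(f) != p)
      stop("feature dimension mismatch: decoder has ", p,
           ", data has ", ncol(f))
  labels <- as.integer(labels)
  # fold each decoder's standardization into raw-space coefficients, then
  # score all decoders at a test window with one matrix product
  B <- vapply(decoders, function(d) {
    b <- d$coef
    if (!is.null(d$scale)) b <- b / d$scale
    b
  }, numeric(p))
  b0 <- vapply(decoders, function(d) {
    b <- d$coef
    if (!is.null(d$scale)) b <- b / d$scale
    d$intercept - sum(d$center * b)
  }, 0)
  acc <- matrix(NA_real_, n, n)
  for (te in seq_len(n)) {
    eta <- sweep(features_all_windows[[te]] %*% B, 2, b0, "+")
    acc[, te] <- colMeans((eta > 0) == (labels == 1))
  }
  diag(acc) <- vapply(decoders, function(d) d$cv_accuracy, 0)
  structure(list(accuracy = acc, decoders = decoders, labels = labels),
            class = "tg_result")
}

#' Cluster temporal-generalization profiles
#'
#' Hierarchically clusters the rows of a temporal-generalization accuracy
#' matrix (each row is one train-window's accuracy-over-time profile) using
#' pairwise cosine distance and complete agglomeration, cutting the tree at
#' `k` clusters.
#'
#' @param tg A `tg_result`, or a plain accuracy matrix.
#' @param k Number of clusters (default 10).
#' @return An object of class `cluster_assignment`: `cluster` (id per row),
#'   `k`, `profiles` (k x n matrix of per-cluster mean profiles), `hclust`.
#' @export
cluster_profiles <- function(tg, k = 10L) {
  m <- if (inherits(tg, "tg_result")) tg$accuracy else tg
  if (k > nrow(m)) stop("k exceeds number of rows")
  if (k < 2 && nrow(m) > 1) stop("k must be at least 2")
  nrm <- sqrt(rowSums(m^2))
  cosd <- 1 - tcrossprod(m / nrm)
  cosd[cosd < 0] <- 0
  hc <- stats::hclust(stats::as.dist(cosd), method = "complete")
  cl <- stats::cutree(hc, k = k)
  # relabel clusters in order of first appearance for determinism
  cl <- match(cl, unique(cl))
  prof <- t(vapply(seq_len(max(cl)), function(ci)
    colMeans(m[cl == ci, , drop = FALSE]), numeric(ncol(m))))
  structure(list(cluster = cl, k = as.integer(k), profiles = prof,
                 hclust = hc), class = "cluster_assignment")
}

#' Bonferroni-corrected exact binomial accuracy threshold
#'
#' The smallest correct-count `k` out of `n_items` (chance 0.5) whose
#' one-tailed exact binomial tail probability, Bonferroni-corrected for
#' `n_tests` comparisons, falls below `alpha`. The strict-inequality tail
#' `P(X > k)` is used; the inclusive tail `P(X >= k)` is also returned for
#' audit.
#'
#' @param n_items Items per decoding test.
#' @param n_tests Number of comparisons corrected for.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List: `threshold` (minimum correct count), `p_strict`
#'   (`P(X > threshold)`), `p_inclusive` (`P(X >= threshold)`),
#'   `p_corrected` (`n_tests * p_strict`).
#' @export
binomial_threshold <- function(n_items, n_tests, alpha = 0.05) {
  if (n_items < 1 || n_tests < 1) stop("n_items and n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  for (k in 0:n_items) {
    p <- stats::pbinom(k, n_items, 0.5, lower.tail = FALSE)
    if (n_tests * p < alpha) {
      return(list(threshold = k,
                  p_strict = p,
                  p_inclusive = stats::pbinom(k - 1, n_items, 0.5,
                                              lower.tail = FALSE),
                  p_corrected = n_tests * p))
    }
  }
  stop("no threshold below alpha exists for these parameters")
}

#' Per-unit correlation between activation and category label
#'
#' Pearson correlation between each unit's activation and the binary
#' category label, at every timepoint, with the two-tailed critical |r| at
#' `alpha` from the t distribution with `n - 2` degrees of freedom.
#' Constant-activation units yield `NA`.
#'
#' @param traj A `trajectory_tensor` (items x units x frames).
#' @param labels 0/1 vector over items.
#' @param alpha Significance level for the critical band (default 0.05).
#' @return List: `r` (units x frames matrix), `critical_r`.
#' @export
unit_category_correlation <- function(traj, labels, alpha = 0.05) {
  a <- traj$activations
  n <- dim(a)[1]
  r <- apply(a, c(2, 3), function(v)
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, labels))
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  list(r = r, critical_r = tc / sqrt(n - 2 + tc^2))
}

#' Randomly subsample recorded channels
#'
#' Selects `k` units uniformly without replacement from a trajectory tensor,
#' emulating the sparse spatial sampling of a cortical electrode array.
#'
#' @param traj A `trajectory_tensor`.
#' @param k Number of units to keep (default 3).
#' @param seed RNG seed (reproducible selection).
#' @return The reduced `trajectory_tensor`.
#' @export
subsample_channels <- function(traj, k = 3L, seed = 1L) {
  nu <- dim(traj$activations)[2]
  if (k > nu) stop("k exceeds the number of recorded units")
  set.seed(seed)
  sel <- sort(sample.int(nu, k))
  traj$activations <- traj$activations[, sel, , drop = FALSE]
  traj$unit_layer <- traj$unit_layer[sel]
  traj$subsampled_units <- sel
  traj
}

#' Temporal generalization of the simulated naming task
#'
#' The full simulation decoding pipeline for one trajectory tensor: features
#' at timepoint t are the activations of a random subsample of `k` hub
#' units; a plain logistic decoder is fit per timepoint (mean-centered
#' features, LOO diagonal) and tested at every other timepoint; the
#' procedure is repeated `n_subsamples` times and the accuracy matrices
#' averaged.
#'
#' @param traj A `trajectory_tensor` from [simulate_naming()] with a
#'   `label` element.
#' @param k Units per subsample (default 3).
#' @param n_subsamples Number of repeated subsamples averaged (default 10).
#' @param seed Base RNG seed (subsample i uses `seed + i - 1`).
#' @return A `tg_result` whose `accuracy` is the subsample-averaged matrix.
#' @export
decode_trajectory <- function(traj, k = 3L, n_subsamples = 10L, seed = 1L) {
  stopifnot(!is.null(traj$label))
  nt <- dim(traj$activations)[3]
  accs <- array(NA_real_, c(n_subsamples, nt, nt))
  last <- NULL
  for (i in seq_len(n_subsamples)) {
    sub <- subsample_channels(traj, k, seed + i - 1L)
    feats <- lapply(seq_len(nt), function(f) sub$activations[, , f])
    dec <- lapply(feats, fit_plain_decoder, labels = traj$label)
    tg <- temporal_generalization(dec, feats, traj$label)
    accs[i, , ] <- tg$accuracy
    last <- tg
  }
  last$accuracy <- apply(accs, c(2, 3), mean)
  last$n_subsamples <- n_subsamples
  last
}
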