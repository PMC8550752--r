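#' Overlapping-waves test: which classifier cluster is best when?
#'
#' Applies a group-level cluster assignment to each subject's
#' temporal-generalization matrix, giving a per-subject mean accuracy
#' profile for every cluster. At each test window the best cluster is the
#' one with the highest across-subject mean accuracy; every other cluster
#' is compared to it by a paired t-test, and p-values are Benjamini-
#' Hochberg adjusted across all (cluster, window) comparisons. Each
#' comparison is then assigned a significance tier. Windows where even the
#' best cluster does not decode reliably are masked: their tiers are `NA`,
#' mirroring the blacked-out timepoints of the reference display. Without
#' this mask the best-vs-rest comparisons are anti-conservative under a
#' global null, because the best cluster is selected as the maximum. When
#' `n_items` is supplied the gate is the Bonferroni-corrected exact
#' binomial accuracy threshold over all cluster x window tests (the same
#' machinery used for cluster breadth); otherwise a one-tailed one-sample
#' t-test against chance at `reliability_alpha` is used, which is itself
#' max-selected and only partially calibrated.
#'
#' @param tg_list List of per-subject `tg_result` objects (or plain
#'   accuracy matrices) with a common geometry.
#' @param assignment A `cluster_assignment` computed on the group-mean
#'   matrix.
#' @param tiers Adjusted-p thresholds defining increasingly strict tiers
#'   (default `c(0.05, 0.01, 0.001)`).
#' @param scope `"all"` (default) adjusts jointly across every cluster x
#'   window comparison; `"window"` adjusts within each window.
#' @param reliability_alpha Level of the per-window reliability gate
#'   (default 0.05).
#' @param n_items Items per decoding test; when given, the reliability
#'   gate is the exact corrected binomial threshold (recommended).
#' @return An object of class `waves_table`: data frame with columns
#'   `cluster`, `window`, `mean_accuracy`, `is_best`, `reliable`, `p`,
#'   `p_adj`, `tier` (`NA` on unreliable windows; 0 = best or
#'   indistinguishable from best; 1..length(tiers) = reliably worse at
#'   increasingly strict thresholds), plus attributes.
#' @export
overlapping_waves_test <- function(tg_list, assignment,
                                   tiers = c(0.05, 0.01, 0.001),
                                   scope = c("all", "window"),
                                   reliability_alpha = 0.05,
                                   n_items = NULL) {
  scope <- match.arg(scope)
  mats <- lapply(tg_list, function(x)
    if (inherits(x, "tg_result")) x$accuracy else x)
  ns <- length(mats)
  if (ns < 2) stop("need at least 2 subjects for paired comparisons")
  k <- assignment$k
  nw <- ncol(mats[[1]])
  # per-subject cluster-mean profiles: subjects x clusters x windows
  prof <- array(NA_real_, c(ns, k, nw))
  for (s in seq_len(ns))
    for (ci in seq_len(k))
      prof[s, ci, ] <- colMeans(mats[[s]][assignment$cluster == ci, ,
                                          drop = FALSE])
  gm <- apply(prof, c(2, 3), mean)              # clusters x windows
  rel_thr <- if (!is.null(n_items))
    binomial_threshold(n_items, k * nw, alpha = reliability_alpha)$threshold /
      n_items else NULL
  rows <- list()
  for (w in seq_len(nw)) {
    best <- which.max(gm[, w])
    ab <- prof[, best, w]
    rel <- if (!is.null(rel_thr)) mean(ab) > rel_thr else
      if (stats::sd(ab) == 0) mean(ab) > 0.5 else
        stats::t.test(ab, mu = 0.5,
                      alternative = "greater")$p.value < reliability_alpha
    for (ci in seq_len(k)) {
      p <- if (ci == best || k < 2) NA_real_ else {
        d <- prof[, best, w] - prof[, ci, w]
        if (stats::sd(d) == 0) as.numeric(mean(d) > 0) else
          stats::t.test(prof[, best, w], prof[, ci, w], paired = TRUE,
                        alternative = "greater")$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        cluster = ci, window = w, mean_accuracy = gm[ci, w],
        is_best = ci == best, reliable = rel, p = p)
    }
  }
  tab <- do.call(rbind, rows)
  if (scope == "all") {
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  } else {
    tab$p_adj <- NA_real_
    for (w in unique(tab$window)) {
      i <- tab$window == w
      tab$p_adj[i] <- stats::p.adjust(tab$p[i], method = "BH")
    }
  }
  tab$tier <- 0L
  for (i in seq_along(tiers))
    tab$tier[!is.na(tab$p_adj) & tab$p_adj < tiers[i]] <- i
  tab$tier[!tab$reliable] <- NA_integer_
  structure(tab, class = c("waves_table", "data.frame"),
            tiers = tiers, n_subjects = ns)
}

#' Generalization-width series across train windows
#'
#' For decoders fit at each train window, counts the test windows at which
#' decoding accuracy reliably exceeds chance across subjects (one-tailed
#' one-sample t-test against 0.5 at `p_threshold`, uncorrected). The width
#' series over the fully non-overlapping window subset is the input to
#' [piecewise_fit()].
#'
#' @param tg_list List of per-subject `tg_result` objects or accuracy
#'   matrices with a common geometry.
#' @param spec The [window_spec()] describing the geometry.
#' @param p_threshold Uncorrected threshold (default 0.01, about one
#'   expected false positive across 160 test windows).
#' @return An object of class `width_series`: data frame with `window`,
#'   `start_ms`, `width` (count), `proportion`, `nonoverlapping` (logical);
#'   attribute `spec`.
#' @export
generalization_width <- function(tg_list, spec, p_threshold = 0.01) {
  mats <- lapply(tg_list, function(x)
    if (inherits(x, "tg_result")) x$accuracy else x)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims != dims[, 1])) stop("geometry mismatch across subjects")
  nw <- dims[1, 1]
  if (nw != spec$n_windows) stop("matrix size does not match window spec")
  arr <- simplify2array(mats)                      # train x test x subject
  pmat <- matrix(NA_real_, nw, nw)
  for (tr in seq_len(nw)) for (te in seq_len(nw)) {
    a <- arr[tr, te, ]
    pmat[tr, te] <- if (stats::sd(a) == 0) {
      if (mean(a) > 0.5) 0 else 1
    } else stats::t.test(a, mu = 0.5, alternative = "greater")$p.value
  }
  width <- rowSums(pmat < p_threshold)
  nov <- seq_len(nw) %in% nonoverlapping_windows(spec)
  structure(data.frame(window = seq_len(nw), start_ms = spec$starts_ms,
                       width = width, proportion = width / nw,
                       nonoverlapping = nov),
            class = c("width_series", "data.frame"), spec = spec)
}

# design matrix of a continuous piecewise-linear (hinge) model
hinge_design <- function(x, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  X
}

#' Continuous piecewise-linear fit with BIC breakpoint selection
#'
#' Fits hinge models with 0..`max_breakpoints` breakpoints by least squares,
#' choosing breakpoint locations by exhaustive grid search over candidate
#' positions (interior observed x values by default) and the number of
#' breakpoints by minimum BIC. Segments are continuous at the breakpoints.
#'
#' @param x,y Numeric vectors; for a `width_series` use
#'   `piecewise_fit_width()`.
#' @param max_breakpoints Largest breakpoint count considered (default 2).
#' @param candidates Candidate breakpoint locations (default: interior
#'   unique x values).
#' @return An object of class `piecewise_fit`: `breakpoints`, `coef`
#'   (intercept, base slope, hinge slope increments), `segment_slopes`,
#'   `fitted`, `bic` (named vector per breakpoint count), `n_breakpoints`,
#'   `r_squared`, `r_squared_first_segment`.
#' @export
piecewise_fit <- function(x, y, max_breakpoints = 2L, candidates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  o <- order(x); x <- x[o]; y <- y[o]
  if (is.null(candidates)) candidates <- unique(x[-c(1, n)])
  candidates <- sort(candidates[candidates > min(x) & candidates < max(x)])

  sse_of <- function(breaks) {
    X <- hinge_design(x, breaks)
    if (qr(X)$rank < ncol(X)) return(list(sse = Inf, fit = NULL))
    fit <- stats::lm.fit(X, y)
    list(sse = sum(fit$residuals^2), fit = fit)
  }
  best <- list()
  bics <- numeric(max_breakpoints + 1)
  names(bics) <- 0:max_breakpoints
  for (m in 0:max_breakpoints) {
    if (n < 2 * (m + 1)) { bics[m + 1] <- Inf; next }
    if (m == 0) {
      cand_sets <- list(numeric(0))
    } else {
      if (length(candidates) < m) { bics[m + 1] <- Inf; next }
      cand_sets <- utils::combn(candidates, m, simplify = FALSE)
    }
    sse_best <- Inf; set_best <- NULL; fit_best <- NULL
    for (cs in cand_sets) {
      r <- sse_of(cs)
      if (r$sse < sse_best - 1e-12) {
        sse_best <- r$sse; set_best <- cs; fit_best <- r$fit
      }
    }
    if (!is.finite(sse_best)) { bics[m + 1] <- Inf; next }
    # parameters: intercept + slope + per breakpoint (location + slope change)
    kpar <- 2 + 2 * m
    sse_best <- max(sse_best, 1e-12)
    bics[m + 1] <- n * log(sse_best / n) + kpar * log(n)
    best[[m + 1]] <- list(breaks = set_best, fit = fit_best, sse = sse_best)
  }
  m_sel <- unname(which.min(bics)) - 1L
  sel <- best[[m_sel + 1]]
  coefs <- sel$fit$coefficients
  slopes <- cumsum(coefs[-1])                       # slope within each segment
  fitted <- as.numeric(hinge_design(x, sel$breaks) %*% coefs)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sel$sse / sst else NA_real_
  r2_first <- NA_real_
  p_first <- NA_real_
  if (m_sel >= 1) {
    seg <- x <= sel$breaks[1]
    if (sum(seg) >= 3) {
      lf <- stats::lm(y[seg] ~ x[seg])
      sm <- suppressWarnings(summary(lf))
      r2_first <- sm$r.squared
      p_first <- stats::coef(sm)[2, 4]
    }
  } else if (n >= 3) {
    lf <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(lf))
    r2_first <- sm$r.squared
    p_first <- stats::coef(sm)[2, 4]
  }
  structure(list(
    breakpoints = sel$breaks, coef = coefs, segment_slopes = slopes,
    fitted = fitted, x = x, y = y, bic = bics,
    n_breakpoints = m_sel, r_squared = r2,
    r_squared_first_segment = r2_first, p_first_segment = p_first
  ), class = "piecewise_fit")
}

#' @rdname piecewise_fit
#' @param width A `width_series`; the fit uses the fully non-overlapping
#'   window subset (independent observations).
#' @param ... Passed to [piecewise_fit()].
#' @export
piecewise_fit_width <- function(width, ...) {
  w <- width[width$nonoverlapping, ]
  piecewise_fit(w$start_ms, w$proportion, ...)
}

#' Variability of change (VoC) of decoder coefficients per electrode
#'
#' For each electrode's per-window summed signed coefficient series, takes
#' deltas between each window and the window `lag_windows` later (the next
#' fully non-overlapping window under the default geometry), and computes
#' the variance of the strictly non-zero deltas. Electrodes whose
#' coefficients change little or ramp at a constant rate have small VoC;
#' coefficients that fluctuate in magnitude or sign have large VoC.
#'
#' @param coef_by_window Matrix windows x electrodes of summed signed
#'   within-window coefficients (see [decode_subject()]).
#' @param electrodes Electrode table (with MNI `y`) aligned to the columns.
#' @param subject Subject identifier attached to the rows.
#' @param lag_windows Delta lag in windows (default 5 = 50 ms at a 10 ms
#'   step).
#' @return A data frame (class `voc_table`): `subject`, `electrode`, `y`,
#'   `voc` (NA when fewer than 2 non-zero deltas), `n_nonzero`.
#' @export
coefficient_voc <- function(coef_by_window, electrodes, subject = "s01",
                            lag_windows = 5L) {
  nw <- nrow(coef_by_window)
  if (lag_windows >= nw) stop("lag must be smaller than the window count")
  idx <- seq_len(nw - lag_windows)
  voc <- apply(coef_by_window, 2, function(cf) {
    d <- cf[idx + lag_windows] - cf[idx]
    nz <- d[d != 0]
    if (length(nz) < 2) NA_real_ else stats::var(nz)
  })
  nnz <- apply(coef_by_window, 2, function(cf) {
    d <- cf[idx + lag_windows] - cf[idx]
    sum(d != 0)
  })
  structure(data.frame(subject = subject,
                       electrode = electrodes$electrode,
                       y = electrodes$y, voc = voc, n_nonzero = nnz,
                       row.names = NULL),
            class = c("voc_table", "data.frame"))
}

#' Anterior-posterior gradient of VoC
#'
#' Two complementary tests of whether VoC increases toward anterior sites:
#' (1) electrodes pooled across subjects are split into deciles by MNI y,
#' and mean VoC is regressed on mean y across deciles (OLS, with r-squared
#' and p); (2) a per-subject OLS slope of VoC on y, tested against zero by
#' a one-tailed one-sample t-test (df = subjects - 1).
#'
#' @param voc A `voc_table` pooled over subjects (rbind of per-subject
#'   tables); rows with `NA` VoC are dropped.
#' @return List: `decile` (data frame decile, mean_y, mean_voc),
#'   `decile_slope`, `decile_r_squared`, `decile_p`, `subject_slopes`
#'   (named vector), `slope_t`, `slope_df`, `slope_p` (one-tailed, slopes
#'   greater than zero).
#' @export
voc_gradient <- function(voc) {
  v <- voc[!is.na(voc$voc), ]
  if (nrow(v) < 10) stop("fewer than 10 electrodes with defined VoC")
  dec <- cut(rank(v$y, ties.method = "first"),
             breaks = seq(0, nrow(v), length.out = 11), labels = FALSE)
  decile <- data.frame(
    decile = seq_len(10),
    mean_y = vapply(seq_len(10), function(d) mean(v$y[dec == d]), 0),
    mean_voc = vapply(seq_len(10), function(d) mean(v$voc[dec == d]), 0))
  dl <- stats::lm(mean_voc ~ mean_y, data = decile)
  ds <- summary(dl)
  slopes <- vapply(split(v, v$subject), function(sv) {
    if (nrow(sv) < 3 || stats::sd(sv$y) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(voc ~ y, data = sv))[2])
  }, 0)
  slopes <- slopes[!is.na(slopes)]
  tt <- if (length(slopes) >= 2 && stats::sd(slopes) > 0)
    stats::t.test(slopes, mu = 0, alternative = "greater") else NULL
  list(
    decile = decile,
    decile_slope = unname(stats::coef(dl)[2]),
    decile_r_squared = ds$r.squared,
    decile_p = stats::coef(ds)[2, 4],
    subject_slopes = slopes,
    slope_t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    slope_df = length(slopes) - 1L,
    slope_p = if (is.null(tt)) NA_real_ else tt$p.value
  )
}
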