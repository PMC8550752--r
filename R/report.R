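#' Classical MDS embedding of settling trajectories
#'
#' Stacks the activation patterns of every item at every timepoint into one
#' configuration and computes a classical (Torgerson) multidimensional
#' scaling of their Euclidean distances — double-centered squared-distance
#' matrix, top eigenvectors scaled by root eigenvalues (`stats::cmdscale`).
#' The embedding is deterministic up to component sign.
#'
#' @param traj A `trajectory_tensor` (items x units x frames).
#' @param n_components Embedding dimension (default 3).
#' @return List: `coords` (items x frames x components array),
#'   `eigenvalues` (all eigenvalues of the centered matrix), `n_items`,
#'   `n_frames`.
#' @export
mds_trajectories <- function(traj, n_components = 3L) {
  a <- traj$activations
  ni <- dim(a)[1]; nu <- dim(a)[2]; nf <- dim(a)[3]
  if (ni * nf < n_components) stop("fewer rows than components")
  # rows ordered item-major: (item 1, frame 1), (item 2, frame 1), ...
  m <- matrix(aperm(a, c(1, 3, 2)), ni * nf, nu)
  fit <- stats::cmdscale(stats::dist(m), k = n_components, eig = TRUE)
  coords <- array(fit$points, c(ni, nf, n_components))
  list(coords = coords, eigenvalues = fit$eig, n_items = ni, n_frames = nf)
}

#' Per-window map of summed decoder coefficients at electrode coordinates
#'
#' Joins each window's summed signed coefficients with the electrode MNI
#' coordinates, for flat scatter visualization and TSV export (surface
#' projection is out of scope). Positive values mean a positive voltage
#' deflection signals category 1 at that site and window.
#'
#' @param coef_by_window Windows x electrodes matrix of summed signed
#'   coefficients (see [decode_subject()]).
#' @param electrodes Electrode table with `electrode`, `x`, `y`, `z`.
#' @param starts_ms Window start times (defaults to row index).
#' @param subject Optional subject id column.
#' @return Long data frame: `subject`, `window`, `start_ms`, `electrode`,
#'   `x`, `y`, `z`, `coefficient`.
#' @export
coefficient_map <- function(coef_by_window, electrodes,
                            starts_ms = NULL, subject = "s01") {
  if (ncol(coef_by_window) != nrow(electrodes))
    stop("electrodes missing coordinates for columns: ",
         paste(setdiff(seq_len(ncol(coef_by_window)),
                       seq_len(nrow(electrodes))), collapse = ", "))
  if (is.null(starts_ms)) starts_ms <- seq_len(nrow(coef_by_window))
  nw <- nrow(coef_by_window); ne <- ncol(coef_by_window)
  data.frame(
    subject = subject,
    window = rep(seq_len(nw), each = ne),
    start_ms = rep(starts_ms, each = ne),
    electrode = rep(electrodes$electrode, nw),
    x = rep(electrodes$x, nw), y = rep(electrodes$y, nw),
    z = rep(electrodes$z, nw),
    coefficient = as.numeric(t(coef_by_window)))
}

#' Plot helpers (require ggplot2)
#'
#' `plot_tg_matrix` draws a train x test accuracy heat map;
#' `plot_cluster_profiles` the per-cluster mean accuracy time courses;
#' `plot_width_fit` the generalization-width series with its piecewise
#' fit; `plot_coefficient_map` a flat y/x scatter of summed coefficients
#' for one window.
#'
#' @param tg A `tg_result` or accuracy matrix.
#' @param starts_ms Window start times.
#' @return A ggplot object.
#' @export
plot_tg_matrix <- function(tg, starts_ms = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  m <- if (inherits(tg, "tg_result")) tg$accuracy else tg
  if (is.null(starts_ms)) starts_ms <- seq_len(nrow(m))
  df <- expand.grid(train = starts_ms, test = starts_ms)
  df$accuracy <- as.numeric(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$test, .data$train,
                                   fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "test window (ms)", y = "train window (ms)",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tg_matrix
#' @param assignment A `cluster_assignment`.
#' @export
plot_cluster_profiles <- function(assignment, starts_ms = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  p <- assignment$profiles
  if (is.null(starts_ms)) starts_ms <- seq_len(ncol(p))
  df <- data.frame(cluster = factor(rep(seq_len(nrow(p)), ncol(p))),
                   time = rep(starts_ms, each = nrow(p)),
                   accuracy = as.numeric(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$accuracy,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "test window (ms)", y = "mean accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tg_matrix
#' @param fit A `piecewise_fit`.
#' @export
plot_width_fit <- function(fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(x = fit$x, y = fit$y, fitted = fit$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::geom_vline(xintercept = fit$breakpoints, linetype = 3) +
    ggplot2::labs(x = "train window start (ms)",
                  y = "generalization width (proportion)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tg_matrix
#' @param map Output of [coefficient_map()] filtered to one window.
#' @export
plot_coefficient_map <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(map, ggplot2::aes(.data$y, .data$x,
                                    colour = .data$coefficient)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey80",
                                    high = "red") +
    ggplot2::labs(x = "MNI y (posterior to anterior)", y = "MNI x") +
    ggplot2::theme_minimal()
}

#' Run the full analysis pipeline
#'
#' Chains the stages — environment generation, network training, simulated
#' naming and hub decoding, synthetic cohort generation, preprocessing,
#' sliding-window decoding, and the four-signature statistics — under one
#' seed, writing TSV/JSON artifacts to an output directory. Stages can be
#' toggled; disabled downstream stages are skipped.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed; every stage derives its own stream from it.
#' @param stages Character subset of `c("simulation", "ecog")`.
#' @param env_cfg,cohort_cfg Module configurations (defaults used if NULL).
#' @param train_epochs Epochs for the simulation stage's training.
#' @param sim_subsamples Hub subsamples averaged per trajectory.
#' @param spec Window spec for the ECoG stage.
#' @param nested Use nested CV for the L1 decoders (see
#'   [fit_l1_decoder_nested()]).
#' @param n_lambda L1 grid size.
#' @param k_clusters Cluster count for profile clustering.
#' @param write_files Write TSV/JSON artifacts (default TRUE).
#' @return A list report: per-stage outputs plus `verdicts`, the four
#'   signature checks (constant decodability, local generalization,
#'   widening window, anterior VoC gradient) where computed.
#' @export
run_pipeline <- function(out_dir = tempfile("decodyn_run_"), seed = 1L,
                         stages = c("simulation", "ecog"),
                         env_cfg = NULL, cohort_cfg = NULL,
                         train_epochs = 4000L, sim_subsamples = 10L,
                         spec = window_spec(), nested = FALSE,
                         n_lambda = 30L, k_clusters = 10L,
                         write_files = TRUE) {
  if (write_files) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = seed, stages = stages, timing = list())
  verdicts <- list()

  if ("simulation" %in% stages) {
    t0 <- Sys.time()
    if (is.null(env_cfg)) env_cfg <- env_config(seed = seed)
    env <- generate_environment(env_cfg)
    net <- init_network(net_architecture_for(env), seed = seed)
    net <- train_network(net, env, epochs = train_epochs, seed = seed)
    correct <- evaluate_outputs(net, env, seed = seed)
    traj <- simulate_naming(net, env, domain_pair = "all",
                            noise_seed = seed, perm_seed = seed + 1L)
    tgs <- lapply(seq_along(traj), function(i)
      decode_trajectory(traj[[i]], n_subsamples = sim_subsamples,
                        seed = seed + 10L * i))
    sim_acc <- Reduce(`+`, lapply(tgs, function(x) x$accuracy)) / length(tgs)
    mds <- mds_trajectories(settle(net, "visual", env$visual,
                                   n_intervals = 8L, record_layers = "hub",
                                   seed = seed + 2L))
    report$simulation <- list(correct_side = correct, tg_accuracy = sim_acc,
                              mds_eigenvalues = mds$eigenvalues[1:10])
    thr33 <- binomial_threshold(length(traj[[1]]$label), 10 * ncol(sim_acc))
    verdicts$sim_decodable <- all(diag(sim_acc)[-(1:2)] >
                                    thr33$threshold / length(traj[[1]]$label))
    if (write_files) {
      write_environment(env, file.path(out_dir, "environment.tsv"))
      utils::write.table(sim_acc, file.path(out_dir, "sim_tg_matrix.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
    report$timing$simulation <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("ecog" %in% stages) {
    t0 <- Sys.time()
    if (is.null(cohort_cfg)) cohort_cfg <- cohort_config(seed = seed)
    cohort <- generate_cohort(cohort_cfg)
    epochs <- preprocess_cohort(cohort)
    dec <- decode_cohort(epochs, spec, nested = nested, n_lambda = n_lambda)
    cl <- cluster_profiles(dec$group_mean, k = k_clusters)
    waves <- overlapping_waves_test(dec$per_subject, cl,
                                    n_items = cohort_cfg$n_stimuli)
    width <- generalization_width(dec$per_subject, spec)
    pw <- piecewise_fit_width(width)
    voc <- do.call(rbind, lapply(names(dec$per_subject), function(s) {
      tg <- dec$per_subject[[s]]
      coefficient_voc(tg$coef_by_window, tg$electrodes, subject = s,
                      lag_windows = max(1L, round(50 / spec$step_ms)))
    }))
    grad <- tryCatch(voc_gradient(voc), error = function(e)
      list(decile = NULL, decile_slope = NA_real_,
           decile_r_squared = NA_real_, decile_p = NA_real_,
           subject_slopes = NULL, slope_t = NA_real_,
           slope_df = NA_integer_, slope_p = NA_real_))
    thr <- binomial_threshold(cohort_cfg$n_stimuli,
                              k_clusters * spec$n_nonoverlapping)
    onset_w <- which(spec$starts_ms >= cohort_cfg$onset_ms +
                       cohort_cfg$ramp_ms)
    diag_acc <- diag(dec$group_mean)
    verdicts$constant_decodability <-
      all(diag_acc[onset_w] > thr$threshold / cohort_cfg$n_stimuli)
    early <- onset_w[1:max(1, round(length(onset_w) / 8))]
    late <- utils::tail(seq_len(spec$n_windows), round(spec$n_windows / 5))
    rel_thr <- thr$threshold / cohort_cfg$n_stimuli
    verdicts$local_generalization <-
      mean(dec$group_mean[early, late]) < rel_thr &&
      mean(dec$group_mean[late, late]) > rel_thr
    verdicts$widening_window <- pw$n_breakpoints >= 1 &&
      pw$segment_slopes[1] > 0
    verdicts$anterior_voc_gradient <- !is.na(grad$slope_p) &&
      grad$slope_p < 0.05
    report$ecog <- list(group_mean = dec$group_mean, clusters = cl,
                        waves = waves, width = width, piecewise = pw,
                        voc = voc, voc_gradient = grad,
                        threshold = thr)
    if (write_files) {
      utils::write.table(dec$group_mean,
                         file.path(out_dir, "ecog_tg_matrix.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      utils::write.table(width, file.path(out_dir, "width_series.tsv"),
                         sep = "\t", row.names = FALSE)
      utils::write.table(voc, file.path(out_dir, "voc_table.tsv"),
                         sep = "\t", row.names = FALSE)
      for (s in names(dec$per_subject)) {
        tg <- dec$per_subject[[s]]
        utils::write.table(
          coefficient_map(tg$coef_by_window, tg$electrodes,
                          starts_ms = spec$starts_ms, subject = s),
          file.path(out_dir, paste0("coefficients_", s, ".tsv")),
          sep = "\t", row.names = FALSE)
      }
    }
    report$timing$ecog <- as.numeric(Sys.time() - t0, units = "secs")
  }

  report$verdicts <- verdicts
  if (write_files) {
    summ <- list(seed = seed, verdicts = verdicts,
                 timing = report$timing)
    if (!is.null(report$ecog)) {
      summ$breakpoints <- report$ecog$piecewise$breakpoints
      summ$first_segment_slope <- report$ecog$piecewise$segment_slopes[1]
      summ$voc_slope_t <- report$ecog$voc_gradient$slope_t
      summ$voc_slope_df <- report$ecog$voc_gradient$slope_df
      summ$voc_slope_p <- report$ecog$voc_gradient$slope_p
      summ$threshold <- report$ecog$threshold$threshold
    }
    jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report$out_dir <- out_dir
  report
}
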