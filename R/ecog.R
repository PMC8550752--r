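#' Configuration of the synthetic ECoG cohort
#'
#' Parameters of a simulated patient cohort emulating subdural recordings
#' over left ventral temporal cortex during a picture-naming task. Each
#' electrode carries a category-signed spatiotemporal loading
#' `w_e(t) = A_e * cos(theta_e(t)) * g(t)`, where `g(t)` ramps up from
#' `onset_ms` and the phase `theta_e(t)` advances at a rate proportional to
#' the electrode's anteriority (normalized MNI y) and slows with time
#' constant `rotation_tau_ms`. Posterior loadings are therefore static
#' (a stable, feature-like code) while anterior loadings rotate through
#' sign reversals before stabilizing — a dynamic code. Item-level structure
#' comes from a per-item multiplicative jitter of the category signal, and
#' measurement noise is AR(1) per trial and electrode.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param electrodes_per_subject Integer range (min, max) of ventral
#'   temporal electrodes per subject (default c(16, 24), mean 20).
#' @param mni_y_range Posterior-to-anterior span of electrode MNI y
#'   coordinates (default c(-64, -8); more positive = more anterior).
#' @param n_stimuli Stimuli per subject (default 100; half per category).
#' @param n_sessions Repetitions of each stimulus (default 4).
#' @param sampling_rate_hz Acquisition rate, 1000 or 2000 (default 1000).
#' @param baseline_ms Pre-stimulus baseline span (default 200).
#' @param epoch_ms Post-onset epoch span (default 1640).
#' @param onset_ms Latency at which the category signal ramps on
#'   (default 200).
#' @param ramp_ms Rise time of the signal envelope (default 100).
#' @param effect_amplitude_uv Peak category loading amplitude in microvolts
#'   at the posterior end (default 6).
#' @param amp_gradient Fractional increase of the loading amplitude from
#'   the posterior to the anterior end of the strip (default 0.6): the
#'   anterior hub carries the strongest category signal, consistent with
#'   its role as the cross-modal semantic hub.
#' @param rotation_rate_hz Initial phase velocity of the most anterior
#'   electrode, in cycles/s (default 1.6); 0 gives a fully static code.
#' @param rotation_base Minimum effective anteriority for the decaying
#'   rotation (default 0.25): during early settling the whole strip's code
#'   evolves somewhat (so decoders trained at the earliest informative
#'   windows do not generalize late anywhere), while the persistent
#'   dynamics — residual drift and reorientations — remain scaled by true
#'   anteriority.
#' @param rotation_tau_ms Rotation decay time constant (default 500):
#'   the code largely stabilizes a few hundred ms after onset.
#' @param rotation_floor Fraction of the initial phase velocity that
#'   persists after stabilization (default 0.08), leaving a slow residual
#'   drift at anterior sites through the whole epoch.
#' @param code_jump_sd SD (radians, at the most anterior site) of the
#'   discrete reorientations of the code direction (default 1.2). The
#'   anterior code direction is piecewise-constant: coherent within blocks
#'   of about `code_block_ms`, then jumping by an anteriority-scaled random
#'   angle at block boundaries — so decoders can exploit anterior sites
#'   fully within a window, while the *meaning* of an anterior deflection
#'   changes from one window to the next. Shared across stimuli and
#'   sessions (it is a property of the code, not noise); gated off when
#'   `rotation_rate_hz = 0`.
#' @param code_block_ms Length of the coherent blocks (default 120).
#' @param item_jitter SD of the per-item multiplicative signal jitter,
#'   shared across electrodes (default 0.3).
#' @param electrode_jitter SD of the per-item, per-electrode signal
#'   component (default 0.7). This gives every electrode partially unique
#'   category information, so decoders gain from pooling sites — as they
#'   do on real multichannel recordings — instead of riding one best
#'   electrode.
#' @param ar_coef Per-sample AR(1) coefficient of the measurement noise
#'   (default 0.995 at 1000 Hz, i.e. an autocorrelation of about 0.78
#'   across the 50 ms window lag — field-potential noise is dominated by
#'   low frequencies, and this temporal coherence is what keeps decoder
#'   coefficients stable across neighboring windows wherever the
#'   underlying code is static).
#' @param noise_sd_uv Marginal SD of the AR(1) noise in microvolts
#'   (default 15, chosen so single-subject hold-out accuracy is high but
#'   below ceiling).
#' @param artifact_prob Per-trial probability of injecting a > 500 uV
#'   excursion, exercising the artifact-rejection path (default 0).
#' @param seed RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8L, electrodes_per_subject = c(16L, 24L),
                          mni_y_range = c(-64, -8), n_stimuli = 100L,
                          n_sessions = 4L, sampling_rate_hz = 1000,
                          baseline_ms = 200, epoch_ms = 1640, onset_ms = 200,
                          ramp_ms = 100, effect_amplitude_uv = 6,
                          amp_gradient = 0.6,
                          rotation_rate_hz = 1.6, rotation_base = 0.25,
                          rotation_tau_ms = 500,
                          rotation_floor = 0.08, code_jump_sd = 1.2,
                          code_block_ms = 120,
                          item_jitter = 0.3, electrode_jitter = 0.7,
                          ar_coef = 0.995,
                          noise_sd_uv = 15, artifact_prob = 0, seed = 1L) {
  if (n_subjects < 1 || n_stimuli < 2 || n_sessions < 1)
    stop("counts must be positive (and n_stimuli >= 2)")
  if (n_stimuli %% 2 != 0) stop("n_stimuli must be even (balanced categories)")
  if (length(electrodes_per_subject) != 2 ||
      electrodes_per_subject[1] > electrodes_per_subject[2] ||
      electrodes_per_subject[1] < 1)
    stop("electrodes_per_subject must be a valid (min, max) range")
  if (!sampling_rate_hz %in% c(1000, 2000))
    stop("sampling_rate_hz must be 1000 or 2000")
  if (mni_y_range[1] >= mni_y_range[2]) stop("mni_y_range must increase")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic ECoG cohort
#'
#' Produces raw per-trial voltage epochs (baseline + post-onset) for every
#' subject, stimulus and session under the model described in
#' [cohort_config()]. Fully seed-reproducible.
#'
#' @param cfg A [cohort_config()].
#' @return An object of class `ecog_cohort`: per subject a list with
#'   `electrodes` (data frame: electrode, x, y, z), `trials` (4-d array
#'   stimuli x electrodes x samples x sessions), `label` (0/1 per
#'   stimulus); plus the `config`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  dt <- 1000 / cfg$sampling_rate_hz                      # ms per sample
  n_pre <- round(cfg$baseline_ms / dt)
  n_post <- round(cfg$epoch_ms / dt)
  ns <- n_pre + n_post
  t_ms <- (seq_len(ns) - 1) * dt - cfg$baseline_ms       # onset at t = 0

  label <- rep(0:1, each = cfg$n_stimuli / 2)
  sgn <- ifelse(label == 1, 1, -1)

  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    rng_e <- seq(cfg$electrodes_per_subject[1], cfg$electrodes_per_subject[2])
    n_e <- rng_e[sample.int(length(rng_e), 1)]
    y <- sort(stats::runif(n_e, cfg$mni_y_range[1], cfg$mni_y_range[2]))
    electrodes <- data.frame(
      electrode = seq_len(n_e),
      x = stats::rnorm(n_e, -36, 4),
      y = y,
      z = stats::rnorm(n_e, -24, 3)
    )
    ant <- (y - cfg$mni_y_range[1]) / diff(cfg$mni_y_range)   # 0 = posterior
    amp <- cfg$effect_amplitude_uv * (1 + cfg$amp_gradient * ant) *
      stats::runif(n_e, 0.9, 1.1)
    # per-electrode base code direction: positive or negative loading
    # (lateral/medial-like bimodality) with small angular jitter, so every
    # static site carries a usable loading
    phi <- pi * stats::rbinom(n_e, 1, 0.5) + stats::rnorm(n_e, 0, 0.35)

    # spatiotemporal loading, electrodes x samples: the phase advances at a
    # rate set by anteriority, decaying toward a small persistent floor
    rel <- pmax(t_ms - cfg$onset_ms, 0)                        # ms past onset
    g <- pmin(rel / cfg$ramp_ms, 1)                            # envelope
    tau <- cfg$rotation_tau_ms
    phase_t <- (tau * (1 - exp(-rel / tau)) * (1 - cfg$rotation_floor) +
                  cfg$rotation_floor * rel) / 1000             # s
    ant_rot <- cfg$rotation_base + (1 - cfg$rotation_base) * ant
    theta <- outer(2 * pi * cfg$rotation_rate_hz * ant_rot, phase_t) + phi
    if (cfg$rotation_rate_hz > 0 && cfg$code_jump_sd > 0) {
      # piecewise-constant reorientation of the code direction: each
      # electrode's phase takes an anteriority-scaled random jump at its
      # own block boundaries and is constant in between
      bl <- cfg$code_block_ms / dt                 # samples per block
      off <- stats::runif(n_e, 0, bl)              # desynchronized bounds
      blk <- floor(outer(off, seq_len(ns) - 1, function(o, t) (t + o) / bl))
      nblk <- max(blk) + 1L
      jumps <- matrix(stats::rnorm(n_e * nblk, 0, cfg$code_jump_sd),
                      n_e, nblk)
      jumps[, 1] <- 0
      walk <- t(apply(jumps, 1, cumsum))
      P <- matrix(walk[cbind(rep(seq_len(n_e), ns), as.vector(blk) + 1L)],
                  n_e, ns)
      theta <- theta + P * ant
    }
    loading <- (amp * cos(theta)) * rep(g, each = n_e)

    jit <- pmax(stats::rnorm(cfg$n_stimuli, 1, cfg$item_jitter), 0)
    eta <- matrix(stats::rnorm(cfg$n_stimuli * n_e, 0, cfg$electrode_jitter),
                  cfg$n_stimuli, n_e)
    strength <- sgn * (jit + eta)                  # stimulus x electrode

    innov_sd <- cfg$noise_sd_uv * sqrt(1 - cfg$ar_coef^2)
    sig <- aperm(array(loading, c(n_e, ns, cfg$n_stimuli)), c(3, 1, 2)) *
      array(strength, c(cfg$n_stimuli, n_e, ns))               # stim x el x ns
    trials <- array(NA_real_, c(cfg$n_stimuli, n_e, ns, cfg$n_sessions))
    for (ses in seq_len(cfg$n_sessions)) {
      eps <- matrix(stats::rnorm(ns * cfg$n_stimuli * n_e, 0, innov_sd),
                    ns, cfg$n_stimuli * n_e)
      noise <- stats::filter(eps, cfg$ar_coef, method = "recursive")
      noise <- array(as.numeric(noise), c(ns, cfg$n_stimuli, n_e))
      trials[, , , ses] <- sig + aperm(noise, c(2, 3, 1))
      if (cfg$artifact_prob > 0) {
        hit <- which(stats::runif(cfg$n_stimuli) < cfg$artifact_prob)
        for (i in hit) {
          e <- sample.int(n_e, 1); p <- sample.int(ns, 1)
          trials[i, e, p, ses] <- trials[i, e, p, ses] +
            sample(c(-1, 1), 1) * stats::runif(1, 600, 900)
        }
      }
    }
    subjects[[s]] <- list(electrodes = electrodes, trials = trials,
                          label = label)
  }
  names(subjects) <- sprintf("s%02d", seq_len(cfg$n_subjects))
  structure(list(subjects = subjects, config = cfg), class = "ecog_cohort")
}

#' Preprocess raw cohort trials into per-stimulus epochs
#'
#' Applies the standard chain: traces acquired at 2000 Hz are down-sampled
#' to 1000 Hz by averaging successive sample pairs; each trial and electrode
#' is baseline-corrected by subtracting the mean of the pre-stimulus window;
#' trials containing any |voltage| > `reject_uv` are rejected and logged;
#' surviving repetitions are averaged per stimulus; and the epoch is cropped
#' to the post-onset window.
#'
#' @param cohort An `ecog_cohort`.
#' @param reject_uv Artifact rejection limit in microvolts (default 500).
#' @param extra_rejects Optional list (per subject) of data frames with
#'   columns `stimulus`, `session` naming additional trials to drop (the
#'   stand-in for visual-inspection rejection).
#' @return An object of class `stimulus_epochs`: per subject `epochs`
#'   (stimuli x electrodes x post-onset samples at 1000 Hz), `label`,
#'   `electrodes`, and a `rejected` log (data frame subject, stimulus,
#'   session, reason).
#' @export
preprocess_cohort <- function(cohort, reject_uv = 500, extra_rejects = NULL) {
  stopifnot(inherits(cohort, "ecog_cohort"))
  cfg <- cohort$config
  out <- vector("list", length(cohort$subjects))
  rejlog <- list()
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    tr <- sub$trials
    if (cfg$sampling_rate_hz == 2000) {
      d <- dim(tr)
      if (d[3] %% 2 != 0) stop("2000 Hz epoch must have an even sample count")
      tr <- (tr[, , seq(1, d[3], 2), , drop = FALSE] +
             tr[, , seq(2, d[3], 2), , drop = FALSE]) / 2
    }
    n_pre <- round(cfg$baseline_ms / 1)                 # samples at 1000 Hz
    n_post <- round(cfg$epoch_ms / 1)
    d <- dim(tr)
    if (d[3] != n_pre + n_post)
      stop("sample count inconsistent with baseline + epoch length")
    n_stim <- d[1]; n_e <- d[2]; n_ses <- d[4]
    epochs <- array(0, c(n_stim, n_e, n_post))
    kept <- matrix(0L, n_stim, 1)
    drop_tbl <- if (!is.null(extra_rejects)) extra_rejects[[s]] else NULL
    for (i in seq_len(n_stim)) {
      acc <- array(0, c(n_e, n_post)); nk <- 0L
      for (ses in seq_len(n_ses)) {
        ep <- tr[i, , , ses]
        if (!is.matrix(ep)) ep <- matrix(ep, n_e, n_pre + n_post)
        base <- rowMeans(ep[, seq_len(n_pre), drop = FALSE])
        ep <- ep - base
        if (max(abs(ep)) > reject_uv) {
          rejlog[[length(rejlog) + 1]] <- data.frame(
            subject = names(cohort$subjects)[s], stimulus = i, session = ses,
            reason = "amplitude")
          next
        }
        if (!is.null(drop_tbl) &&
            any(drop_tbl$stimulus == i & drop_tbl$session == ses)) {
          rejlog[[length(rejlog) + 1]] <- data.frame(
            subject = names(cohort$subjects)[s], stimulus = i, session = ses,
            reason = "manual")
          next
        }
        acc <- acc + ep[, n_pre + seq_len(n_post), drop = FALSE]
        nk <- nk + 1L
      }
      if (nk == 0L)
        stop("stimulus ", i, " of subject ", names(cohort$subjects)[s],
             " has no surviving trials")
      epochs[i, , ] <- acc / nk
      kept[i] <- nk
    }
    out[[s]] <- list(epochs = epochs, label = sub$label,
                     electrodes = sub$electrodes, n_kept = as.integer(kept))
  }
  names(out) <- names(cohort$subjects)
  rejected <- if (length(rejlog)) do.call(rbind, rejlog) else
    data.frame(subject = character(), stimulus = integer(),
               session = integer(), reason = character())
  structure(list(subjects = out, rejected = rejected,
                 config = cohort$config), class = "stimulus_epochs")
}

#' Save / load a cohort as a plain-text container
#'
#' Writes a directory holding `config.json`, and per subject an
#' `electrodes.tsv` (electrode, x, y, z), `label.tsv`, and one
#' `trials_sXX.tsv.gz`-free plain TSV per session (rows = stimulus x
#' electrode, columns = samples). The round trip is lossless to full double
#' precision.
#'
#' @param cohort An `ecog_cohort`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ecog_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfgl <- unclass(cohort$config)
  jsonlite::write_json(cfgl, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in seq_along(cohort$subjects)) {
    sd <- file.path(path, names(cohort$subjects)[s])
    dir.create(sd, showWarnings = FALSE)
    sub <- cohort$subjects[[s]]
    utils::write.table(sub$electrodes, file.path(sd, "electrodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(stimulus = seq_along(sub$label),
                                  label = sub$label),
                       file.path(sd, "label.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d <- dim(sub$trials)
    for (ses in seq_len(d[4])) {
      tr3 <- array(sub$trials[, , , ses], d[1:3])
      m <- t(matrix(aperm(tr3, c(3, 2, 1)), nrow = d[3]))
      utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                         file.path(sd, sprintf("trials_session%02d.tsv", ses)),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  cfgl <- jsonlite::read_json(file.path(path, "config.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(cohort_config, cfgl)
  dt <- 1000 / cfg$sampling_rate_hz
  ns <- round((cfg$baseline_ms + cfg$epoch_ms) / dt)
  dirs <- sort(list.dirs(path, recursive = FALSE))
  subjects <- vector("list", length(dirs))
  for (s in seq_along(dirs)) {
    electrodes <- utils::read.table(file.path(dirs[s], "electrodes.tsv"),
                                    header = TRUE, sep = "\t")
    lab <- utils::read.table(file.path(dirs[s], "label.tsv"),
                             header = TRUE, sep = "\t")
    n_e <- nrow(electrodes)
    n_stim <- nrow(lab)
    files <- sort(list.files(dirs[s], pattern = "^trials_session",
                             full.names = TRUE))
    trials <- array(NA_real_, c(n_stim, n_e, ns, length(files)))
    for (ses in seq_along(files)) {
      m <- as.matrix(utils::read.table(files[ses], sep = "\t"))
      if (nrow(m) != n_stim * n_e || ncol(m) != ns)
        stop("malformed container: ", files[ses], " has ", nrow(m), " x ",
             ncol(m), " values; expected ", n_stim * n_e, " x ", ns)
      trials[, , , ses] <- aperm(array(t(m), c(ns, n_e, n_stim)), c(3, 2, 1))
    }
    subjects[[s]] <- list(electrodes = electrodes, trials = trials,
                          label = lab$label)
  }
  names(subjects) <- basename(dirs)
  structure(list(subjects = subjects, config = cfg), class = "ecog_cohort")
}

#' Decode one subject's stimulus epochs across sliding windows
#'
#' Fits one L1 logistic decoder per sliding window
#' ([fit_l1_decoder_nested()]) and tests every decoder at every window,
#' returning the subject's temporal-generalization result.
#'
#' @param subject One element of a `stimulus_epochs` object (`epochs`,
#'   `label`, `electrodes`).
#' @param spec A [window_spec()].
#' @param ... Passed to [fit_l1_decoder_nested()] (e.g. `nested`,
#'   `n_lambda`).
#' @return A `tg_result` with an added `coef_by_window` matrix
#'   (windows x electrodes: within-window summed signed coefficients) and
#'   the subject's `electrodes` table.
#' @export
decode_subject <- function(subject, spec = window_spec(), ...) {
  feats <- sliding_window_features(subject$epochs, spec)
  # one stratified partition shared by every window of the subject
  folds <- decodyn:::stratified_folds(subject$label, 10L)
  decs <- lapply(feats, fit_l1_decoder_nested, labels = subject$label,
                 folds = folds, ...)
  tg <- temporal_generalization(decs, feats, subject$label)
  n_e <- dim(subject$epochs)[2]
  spw <- round(spec$window_ms * spec$sampling_rate_hz / 1000)
  tg$coef_by_window <- t(matrix(vapply(decs, function(d)
    colSums(matrix(d$coef, spw, n_e)), numeric(n_e)), n_e, length(decs)))
  tg$electrodes <- subject$electrodes
  tg$spec <- spec
  tg
}

#' Decode every subject of a preprocessed cohort
#'
#' @param epochs A `stimulus_epochs` object.
#' @param spec A [window_spec()].
#' @param ... Passed to [decode_subject()].
#' @return List with `per_subject` (list of `tg_result`) and `group_mean`
#'   (mean accuracy matrix across subjects).
#' @export
decode_cohort <- function(epochs, spec = window_spec(), ...) {
  per <- lapply(epochs$subjects, decode_subject, spec = spec, ...)
  acc <- Reduce(`+`, lapply(per, function(x) x$accuracy)) / length(per)
  list(per_subject = per, group_mean = acc, spec = spec)
}
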