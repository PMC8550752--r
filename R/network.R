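#' Architecture of the recurrent hub-and-spokes network
#'
#' Five layers — visual I/O, visual hidden, cross-modal hub, verbal hidden,
#' verbal I/O — connected by reciprocal pairs
#' (visual <-> visual-hidden <-> hub <-> verbal-hidden <-> verbal), with an
#' independent weight matrix in each direction. All units use a
#' continuous-time sigmoid activation with time constant `tau`; each settling
#' interval comprises `1/tau` asynchronous update sweeps. I/O units carry a
#' fixed, untrainable bias (`io_bias`) that keeps them near-off at rest;
#' clamped input units receive a constant external input of `ext_strength`
#' added to their net input for the whole episode.
#'
#' @param n_visual Number of visual I/O units (match the environment's
#'   `n_visual_bits`).
#' @param n_verbal Number of verbal I/O units (match `ncol(env$verbal)`).
#' @param n_visual_hidden,n_verbal_hidden Hidden layer sizes (default 30).
#' @param n_hub Hub layer size (default 25).
#' @param tau Time constant (default 0.25).
#' @param io_bias Fixed I/O unit bias (default -3).
#' @param ext_strength External input to clamped ON units (default +6, so a
#'   clamped unit's net input starts at +3).
#' @return An object of class `net_architecture`.
#' @export
net_architecture <- function(n_visual = 48L, n_verbal = 102L,
                             n_visual_hidden = 30L, n_hub = 25L,
                             n_verbal_hidden = 30L, tau = 0.25,
                             io_bias = -3, ext_strength = 6) {
  layers <- c(visual = as.integer(n_visual),
              visual_hidden = as.integer(n_visual_hidden),
              hub = as.integer(n_hub),
              verbal_hidden = as.integer(n_verbal_hidden),
              verbal = as.integer(n_verbal))
  if (any(layers < 1)) stop("all layer sizes must be >= 1")
  structure(list(
    layers = layers,
    conn_from = c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L),
    conn_to   = c(2L, 1L, 3L, 2L, 4L, 3L, 5L, 4L),
    io_layers = c(1L, 5L),
    tau = tau, io_bias = io_bias, ext_strength = ext_strength,
    updates_per_interval = as.integer(round(1 / tau))
  ), class = "net_architecture")
}

#' @rdname net_architecture
#' @param env An `env_spec`; convenience constructor sizing the I/O layers
#'   from the environment.
#' @param ... Passed on to [net_architecture()].
#' @export
net_architecture_for <- function(env, ...) {
  net_architecture(n_visual = ncol(env$visual), n_verbal = ncol(env$verbal), ...)
}

conn_names <- function(arch) {
  ln <- names(arch$layers)
  paste0(ln[arch$conn_from], "->", ln[arch$conn_to])
}

n_units <- function(arch) sum(arch$layers)

unit_layer <- function(arch) rep(names(arch$layers), arch$layers)

layer_units <- function(arch, layer) {
  off <- c(0L, cumsum(arch$layers))
  i <- match(layer, names(arch$layers))
  if (is.na(i)) stop("unknown layer: ", layer)
  seq.int(off[i] + 1L, off[i + 1L])
}

flatten_weights <- function(net) {
  unlist(lapply(net$weights, as.vector), use.names = FALSE)
}

unflatten_weights <- function(arch, w) {
  out <- list()
  pos <- 0L
  for (c in seq_along(arch$conn_from)) {
    nt <- arch$layers[arch$conn_to[c]]
    nf <- arch$layers[arch$conn_from[c]]
    out[[c]] <- matrix(w[pos + seq_len(nt * nf)], nt, nf)
    pos <- pos + nt * nf
  }
  names(out) <- conn_names(arch)
  out
}

#' Initialize a network with small random weights
#'
#' Every weight (and every trainable hidden bias) is drawn from a uniform
#' distribution on \[-1, 1\]; I/O biases are set to the fixed `io_bias` and
#' flagged untrainable.
#'
#' @param arch A [net_architecture()].
#' @param seed RNG seed; the same seed reproduces identical weights.
#' @return An object of class `sem_network` with elements `arch`, `weights`
#'   (named list of matrices, one per directed connection, target x source),
#'   `bias` (per-unit vector) and `seed`.
#' @export
init_network <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "net_architecture"))
  set.seed(seed)
  weights <- list()
  for (c in seq_along(arch$conn_from)) {
    nt <- arch$layers[arch$conn_to[c]]
    nf <- arch$layers[arch$conn_from[c]]
    weights[[c]] <- matrix(stats::runif(nt * nf, -1, 1), nt, nf)
  }
  names(weights) <- conn_names(arch)
  nu <- n_units(arch)
  bias <- stats::runif(nu, -1, 1)
  io <- unlist(lapply(arch$io_layers, function(l)
    layer_units(arch, names(arch$layers)[l])))
  bias[io] <- arch$io_bias
  structure(list(arch = arch, weights = weights, bias = bias,
                 seed = as.integer(seed), trained = FALSE),
            class = "sem_network")
}

# Build the external-input matrix (npat x nunits) clamping one modality.
ext_matrix <- function(arch, modality, patterns) {
  nu <- n_units(arch)
  ext <- matrix(0, nrow(patterns), nu)
  idx <- layer_units(arch, modality)
  if (length(idx) != ncol(patterns)) stop("pattern width does not match layer")
  ext[, idx] <- patterns * arch$ext_strength
  ext
}

# Full target matrix (npat x nunits): visual + verbal patterns, NA-free;
# only I/O units are read by the loss.
target_matrix <- function(arch, visual, verbal) {
  nu <- n_units(arch)
  tgt <- matrix(0, nrow(visual), nu)
  tgt[, layer_units(arch, "visual")] <- visual
  tgt[, layer_units(arch, "verbal")] <- verbal
  tgt
}

# The training set: for each item one visual->verbal and one verbal->visual
# trial, targets fully specifying both modalities.
training_set <- function(arch, env) {
  ext_v <- ext_matrix(arch, "visual", env$visual)
  ext_w <- ext_matrix(arch, "verbal", env$verbal)
  tgt <- target_matrix(arch, env$visual, env$verbal)
  list(ext = rbind(ext_v, ext_w), targets = rbind(tgt, tgt),
       item = rep(env$item_id, 2),
       direction = rep(c("visual", "verbal"), each = nrow(env$visual)))
}

#' Settle the network on a set of input patterns
#'
#' Runs the asynchronous settling dynamics: per update sweep each unit is
#' visited once in a freshly permuted order (shared across the pattern batch)
#' and updated as `a <- a + tau * (sigmoid(net) - a)` using the latest values
#' of all other units. The state at input onset (resting activations
#' `sigmoid(bias)`) is logged as frame 0, then one frame per sweep.
#'
#' @param net A `sem_network`.
#' @param modality `"visual"` or `"verbal"`: which I/O layer is clamped.
#' @param patterns 0/1 matrix (items x layer width); ON bits receive the
#'   external input.
#' @param n_intervals Settling intervals (5 in training, 8 at test); sweeps =
#'   `n_intervals * updates_per_interval`.
#' @param record_layers Character vector of layer names to log (default all).
#' @param targets Optional full target matrix enabling early stopping.
#' @param stop_tolerance Early-stop tolerance on I/O units (train mode only);
#'   ignored when `targets` is `NULL`.
#' @param seed Seed for the per-sweep update-order permutations.
#' @return A `trajectory_tensor`: list with `activations` (items x units x
#'   frames array), `unit_layer`, `stop_sweep`, `sweeps_run`, and metadata.
#' @export
settle <- function(net, modality, patterns, n_intervals = 8L,
                   record_layers = names(net$arch$layers), targets = NULL,
                   stop_tolerance = 0.2, seed = 1L) {
  stopifnot(inherits(net, "sem_network"))
  arch <- net$arch
  ext <- ext_matrix(arch, modality, patterns)
  rec <- unlist(lapply(record_layers, layer_units, arch = arch))
  res <- cpp_settle(unname(arch$layers), arch$conn_from, arch$conn_to,
                    arch$io_layers, flatten_weights(net), net$bias, ext,
                    targets, arch$tau,
                    as.integer(n_intervals) * arch$updates_per_interval,
                    stop_tolerance, as.integer(seed), rec)
  structure(list(
    activations = res$activations,
    unit_layer = unit_layer(arch)[rec],
    stop_sweep = res$stop_sweep,
    sweeps_run = res$sweeps_run,
    noise_amplitude = 0,
    trained = isTRUE(net$trained)
  ), class = "trajectory_tensor")
}

#' Train the network by backpropagation through settling
#'
#' Full-batch gradient descent on squared-error loss between target patterns
#' (applied to every visual and verbal unit at every logged settling frame)
#' and activations, with gradients propagated back through the exact
#' permuted asynchronous update sequence. The loss uses the conventional
#' half factor (`L = 0.5 * sum((a - t)^2)`, output derivative `a - t`),
#' which descends smoothly at the reference learning rate where the doubled
#' derivative convention oscillates. Settling is halted early for a
#' pattern once every I/O unit is within `stop_tolerance` of its target;
#' frames beyond that point contribute no error. I/O biases stay fixed.
#'
#' @param net A `sem_network` (freshly initialized or partially trained).
#' @param env The `env_spec` providing the 2-per-item training trials.
#' @param epochs Training epochs (default 30000).
#' @param lr Learning rate on the summed batch gradient (default 0.002).
#' @param momentum Optional batch momentum on the weight step (default 0:
#'   plain gradient descent; at this batch size and learning rate momentum
#'   overshoots and destabilizes the loss).
#' @param n_intervals Settling intervals during training (default 5).
#' @param stop_tolerance Early-stop tolerance (default 0.2).
#' @param seed Seed for the update-order permutation stream.
#' @return The trained `sem_network`, with a `loss` element holding the
#'   per-epoch loss curve.
#' @export
train_network <- function(net, env, epochs = 30000L, lr = 0.002,
                          momentum = 0, n_intervals = 5L,
                          stop_tolerance = 0.2, seed = 1L) {
  stopifnot(inherits(net, "sem_network"), inherits(env, "env_spec"))
  arch <- net$arch
  ts <- training_set(arch, env)
  res <- cpp_train(unname(arch$layers), arch$conn_from, arch$conn_to,
                   arch$io_layers, flatten_weights(net), net$bias, ts$ext,
                   ts$targets, arch$tau,
                   as.integer(n_intervals) * arch$updates_per_interval,
                   stop_tolerance, as.integer(seed), 0.5,
                   as.integer(epochs), lr, momentum)
  net$weights <- unflatten_weights(arch, res$W)
  net$bias <- res$bias
  net$loss <- as.numeric(res$loss)
  net$trained <- TRUE
  net
}

# Loss and exact gradient for a fixed update-order seed; used by the
# finite-difference oracle tests.
network_loss_grad <- function(net, env, n_intervals = 5L,
                              stop_tolerance = -1, seed = 1L) {
  arch <- net$arch
  ts <- training_set(arch, env)
  cpp_loss_grad(unname(arch$layers), arch$conn_from, arch$conn_to,
                arch$io_layers, flatten_weights(net), net$bias, ts$ext,
                ts$targets, arch$tau,
                as.integer(n_intervals) * arch$updates_per_interval,
                stop_tolerance, as.integer(seed), 1.0)
}

#' Fraction of output units on the correct side of the midpoint
#'
#' Settles the network on every training trial (both directions) and scores
#' each visual and verbal target unit at the final settling frame as correct
#' when its activation lies on the target's side of 0.5.
#'
#' @param net A `sem_network`.
#' @param env The environment the network was trained on.
#' @param n_intervals Settling intervals (default 5, as in training).
#' @param stop_tolerance Early-stop tolerance (default 0.2, as in training).
#' @param seed Permutation seed.
#' @return The correct-side fraction (scalar in \[0, 1\]).
#' @export
evaluate_outputs <- function(net, env, n_intervals = 5L, stop_tolerance = 0.2,
                             seed = 1L) {
  arch <- net$arch
  ts <- training_set(arch, env)
  rec <- unlist(lapply(c("visual", "verbal"), layer_units, arch = arch))
  res <- cpp_settle(unname(arch$layers), arch$conn_from, arch$conn_to,
                    arch$io_layers, flatten_weights(net), net$bias, ts$ext,
                    ts$targets, arch$tau,
                    as.integer(n_intervals) * arch$updates_per_interval,
                    stop_tolerance, as.integer(seed), rec)
  act <- res$activations                      # npat x n_io x frames
  tgt <- ts$targets[, rec, drop = FALSE]
  final <- matrix(NA_real_, nrow(tgt), ncol(tgt))
  for (p in seq_len(nrow(tgt))) {
    f <- min(res$stop_sweep[p], res$sweeps_run) + 1L  # frame index
    final[p, ] <- act[p, , f]
  }
  mean((final > 0.5) == (tgt > 0.5))
}

#' Simulate the picture-naming task and record noisy hub trajectories
#'
#' Clamps visual input for the items of one domain pair (30 + 30 items),
#' settles for 8 intervals (32 sweeps, 33 logged frames), records the hub
#' units, and distorts every logged activation with i.i.d. uniform noise on
#' `[-noise_amplitude, +noise_amplitude]` to emulate measurement error.
#'
#' @param net A `sem_network` (an untrained network is accepted, useful for
#'   null checks, and flagged in the result).
#' @param env The environment.
#' @param domain_pair Integer vector of 2 domain ids, or `"all"` for every
#'   pair of domains in turn.
#' @param noise_amplitude Half-width of the uniform noise (default 0.005).
#' @param noise_seed Seed for the noise draws.
#' @param record_layers Layers to record (default `"hub"`; set to all layer
#'   names to enable layer-wise contrasts).
#' @param perm_seed Seed for update-order permutations.
#' @return For a single pair, a `trajectory_tensor` with a `label` element
#'   (0/1 by domain); for `"all"`, a list of one tensor per pair.
#' @export
simulate_naming <- function(net, env, domain_pair = "all",
                            noise_amplitude = 0.005, noise_seed = 1L,
                            record_layers = "hub", perm_seed = 1L) {
  doms <- sort(unique(env$domain_label))
  if (identical(domain_pair, "all")) {
    prs <- utils::combn(doms, 2, simplify = FALSE)
    out <- lapply(seq_along(prs), function(i)
      simulate_naming(net, env, prs[[i]], noise_amplitude,
                      noise_seed + i - 1L, record_layers, perm_seed))
    names(out) <- vapply(prs, paste, "", collapse = "-")
    return(out)
  }
  stopifnot(length(domain_pair) == 2, all(domain_pair %in% doms))
  keep <- env$domain_label %in% domain_pair
  traj <- settle(net, "visual", env$visual[keep, , drop = FALSE],
                 n_intervals = 8L, record_layers = record_layers,
                 seed = perm_seed)
  if (noise_amplitude > 0) {
    set.seed(noise_seed)
    traj$activations <- traj$activations +
      stats::runif(length(traj$activations), -noise_amplitude, noise_amplitude)
  }
  traj$noise_amplitude <- noise_amplitude
  traj$label <- as.integer(env$domain_label[keep] == domain_pair[2])
  traj$item_id <- env$item_id[keep]
  traj$domain_pair <- domain_pair
  traj
}
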