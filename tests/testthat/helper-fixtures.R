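# Small fixtures shared across test files; everything is generated in code.

tiny_env <- function(seed = 2) {
  generate_environment(env_config(
    n_domains = 1, n_categories_per_domain = 1, n_items_per_category = 3,
    n_visual_bits = 5, seed = seed))
}

tiny_net <- function(env = tiny_env(), seed = 3) {
  init_network(net_architecture_for(env, n_visual_hidden = 4, n_hub = 3,
                                    n_verbal_hidden = 4), seed = seed)
}

small_cohort_cfg <- function(...) {
  cohort_config(n_subjects = 2, electrodes_per_subject = c(4, 5),
                n_stimuli = 20, n_sessions = 2, epoch_ms = 400,
                baseline_ms = 200, onset_ms = 100, ramp_ms = 50,
                effect_amplitude_uv = 8, noise_sd_uv = 10, seed = 11, ...)
}

# loss of a network under a fixed permutation seed (oracle helper)
net_loss <- function(net, env, n_intervals = 2, seed = 7) {
  decodyn:::network_loss_grad(net, env, n_intervals = n_intervals,
                              stop_tolerance = -1, seed = seed)$loss
}
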