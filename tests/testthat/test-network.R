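test_that("initialization is uniform in [-1, 1], seeded, with fixed I/O biases", {
  env <- generate_environment(env_config(seed = 1))
  arch <- net_architecture_for(env)
  expect_equal(unname(arch$layers["hub"]), 25L)
  n1 <- init_network(arch, seed = 7)
  n2 <- init_network(arch, seed = 7)
  expect_identical(n1$weights, n2$weights)
  w <- decodyn:::flatten_weights(n1)
  expect_true(all(w >= -1 & w <= 1))
  expect_lt(abs(mean(w)), 3 / sqrt(length(w)))  # mean ~ 0 within 3 SE
  io <- c(decodyn:::layer_units(arch, "visual"),
          decodyn:::layer_units(arch, "verbal"))
  expect_true(all(n1$bias[io] == -3))
  hid <- setdiff(seq_len(decodyn:::n_units(arch)), io)
  expect_true(all(n1$bias[hid] >= -1 & n1$bias[hid] <= 1))
})

test_that("settling follows the geometric closed form step for step", {
  # all weights zero: each unit's net input is constant, so
  # a_k = sig(u) + (a_0 - sig(u)) (1 - tau)^k exactly
  env <- tiny_env()
  net <- tiny_net(env)
  net$weights <- lapply(net$weights, function(w) w * 0)
  ones <- matrix(1, 1, ncol(env$visual))
  tr <- settle(net, "visual", ones, n_intervals = 8, seed = 1)
  expect_equal(dim(tr$activations)[3], 33)
  k <- 0:32
  vis1 <- tr$activations[1, which(tr$unit_layer == "visual")[1], ]
  closed <- plogis(3) + (plogis(-3) - plogis(3)) * 0.75^k
  expect_lt(max(abs(vis1 - closed)), 1e-12)
  # unclamped I/O unit stays at rest
  tr0 <- settle(net, "visual", ones * 0, n_intervals = 8, seed = 1)
  verb <- tr0$activations[1, which(tr0$unit_layer == "verbal")[1], ]
  expect_lt(max(abs(verb - plogis(-3))), 1e-12)
})

test_that("activations stay strictly inside (0, 1)", {
  env <- tiny_env()
  net <- tiny_net(env)
  net$weights <- lapply(net$weights, function(w) w * 20)  # extreme weights
  tr <- settle(net, "visual", env$visual, n_intervals = 8, seed = 2)
  expect_true(all(tr$activations > 0 & tr$activations < 1))
})

test_that("analytic gradients match centered finite differences", {
  env <- tiny_env()
  net <- tiny_net(env)
  g <- decodyn:::network_loss_grad(net, env, n_intervals = 2,
                                   stop_tolerance = -1, seed = 7)
  w0 <- decodyn:::flatten_weights(net)
  eps <- 1e-5
  idx <- round(seq(1, length(w0), length.out = 12))
  for (i in idx) {
    for (sgn in c(1, -1)) {
      wp <- w0; wp[i] <- wp[i] + sgn * eps
      np <- net; np$weights <- decodyn:::unflatten_weights(net$arch, wp)
      assign(if (sgn > 0) "lp" else "lm",
             decodyn:::network_loss_grad(np, env, n_intervals = 2,
                                         stop_tolerance = -1, seed = 7)$loss)
    }
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - g$dW[i]) / max(abs(num), 1e-6), 1e-4)
  }
  # trainable hidden biases, including the initial-state path
  hid <- which(decodyn:::unit_layer(net$arch) %in%
                 c("visual_hidden", "hub", "verbal_hidden"))[1:4]
  for (u in hid) {
    np <- net; np$bias[u] <- np$bias[u] + eps
    lp <- net_loss(np, env)
    nm <- net; nm$bias[u] <- nm$bias[u] - eps
    lm <- net_loss(nm, env)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - g$dbias[u]) / max(abs(num), 1e-6), 1e-4)
  }
  # untrainable I/O biases receive no gradient
  io <- which(decodyn:::unit_layer(net$arch) %in% c("visual", "verbal"))
  expect_true(all(g$dbias[io] == 0))
})

test_that("training reduces loss and lr = 0 leaves weights untouched", {
  env <- tiny_env()
  net <- tiny_net(env)
  t0 <- train_network(net, env, epochs = 40, lr = 0, seed = 5)
  expect_equal(t0$weights, net$weights, tolerance = 0)
  tr <- train_network(net, env, epochs = 150, lr = 0.002, seed = 5)
  expect_lt(tail(tr$loss, 1), tr$loss[1])
  # near-monotone decrease at a small learning rate
  tr2 <- train_network(net, env, epochs = 80, lr = 2e-4, seed = 5)
  dif <- diff(tr2$loss)
  expect_true(all(dif < 1e-3 * abs(tr2$loss[-length(tr2$loss)])))
})

test_that("correct-side evaluation matches a counting oracle on zero weights", {
  env <- generate_environment(env_config(seed = 8))
  arch <- net_architecture_for(env)
  net <- init_network(arch, 1)
  net$weights <- lapply(net$weights, function(w) w * 0)
  # with zero weights, clamped ON inputs sit at sig(+3) > 0.5 (correct,
  # target 1); every other I/O unit sits at sig(-3) < 0.5 (correct iff
  # target 0). Count directly from the environment.
  n_vis <- ncol(env$visual); n_verb <- ncol(env$verbal)
  n_items <- nrow(env$visual)
  total <- 2 * n_items * (n_vis + n_verb)
  # visual-input trials: all visual units correct; verbal units correct iff 0
  c_v <- n_items * n_vis + sum(env$verbal == 0)
  # verbal-input trials: all verbal units correct; visual units correct iff 0
  c_w <- n_items * n_verb + sum(env$visual == 0)
  expect_equal(evaluate_outputs(net, env, seed = 2), (c_v + c_w) / total)
})

test_that("simulated naming yields a noisy 60 x hub x 33 tensor per pair", {
  env <- generate_environment(env_config(seed = 4))
  net <- init_network(net_architecture_for(env), 2)
  tr <- simulate_naming(net, env, domain_pair = c(1, 2), noise_seed = 9,
                        perm_seed = 3)
  expect_equal(dim(tr$activations), c(60, 25, 33))
  expect_equal(sum(tr$label == 1), 30)
  clean <- simulate_naming(net, env, domain_pair = c(1, 2),
                           noise_amplitude = 0, perm_seed = 3)
  expect_lte(max(abs(tr$activations - clean$activations)), 0.005)
  clean2 <- simulate_naming(net, env, domain_pair = c(1, 2),
                            noise_amplitude = 0, perm_seed = 3)
  expect_identical(clean$activations, clean2$activations)
  all3 <- simulate_naming(net, env, domain_pair = "all", perm_seed = 3)
  expect_length(all3, 3)
  expect_named(all3, c("1-2", "1-3", "2-3"))
})

test_that("hidden layers can be recorded for layer-wise contrasts", {
  env <- tiny_env()
  net <- tiny_net(env)
  tr <- settle(net, "visual", env$visual, n_intervals = 8,
               record_layers = c("visual_hidden", "hub"), seed = 1)
  expect_equal(dim(tr$activations)[2], 4 + 3)
  expect_equal(unique(tr$unit_layer), c("visual_hidden", "hub"))
})
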