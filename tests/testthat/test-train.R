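test_that("compute_lambda is the negative/positive cell ratio", {
  expect_equal(compute_lambda(matrix(c(1, 1, 0, 0, 0, 0), 2, 3)), 2)
  expect_equal(compute_lambda(matrix(c(1, 0, 1, 0), 2, 2)), 1)
  # catalogue-scale ratio from the published counts
  n <- random_assoc(495, 383, 5430, seed = 2)
  expect_equal(compute_lambda(n), (495 * 383 - 5430) / 5430)
  expect_error(compute_lambda(matrix(1, 2, 2)), "negative")
  expect_error(compute_lambda(matrix(0, 2, 2)), "positive")
})

test_that("weighted_ce_loss matches hand values and the cell oracle", {
  # one positive + one negative at score 0.5, lambda 1: log 2
  expect_equal(weighted_ce_loss(matrix(0.5, 1, 2), matrix(c(1, 0), 1, 2),
                                lambda_weight = 1)$total, log(2))
  # perfect-fit limit goes to 0
  near <- matrix(c(1 - 1e-12, 1e-12), 1, 2)
  expect_lt(weighted_ce_loss(near, matrix(c(1, 0), 1, 2), 1)$total, 1e-8)

  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(runif(20), 5, 4)
    y <- random_assoc(5, 4, 6)
    lam <- compute_lambda(y)
    expect_equal(weighted_ce_loss(p, y, lam)$total,
                 oracle_weighted_ce(p, y, lam), tolerance = 1e-12)
    # lambda = 1 reduces to the unweighted mean binary cross-entropy
    expect_equal(weighted_ce_loss(p, y, 1)$total,
                 -mean(y * log(p) + (1 - y) * log(1 - p)),
                 tolerance = 1e-12)
  }
  expect_error(weighted_ce_loss(matrix(0.5, 2, 2), matrix(0, 3, 3), 1),
               "shapes")
})

test_that("loss is invariant under consistent permutation of miRNAs", {
  set.seed(31)
  p <- matrix(runif(30), 6, 5)
  y <- random_assoc(6, 5, 8)
  lam <- compute_lambda(y)
  perm <- sample(6)
  expect_equal(weighted_ce_loss(p, y, lam)$total,
               weighted_ce_loss(p[perm, ], y[perm, ], lam)$total,
               tolerance = 1e-12)
})

test_that("training runs, makes progress, and respects epochs = 0", {
  sim <- tiny_sim()
  net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)

  cfg0 <- lagcn_config(epoch = 0, emb_dim = 8, seed = 3)
  fit0 <- lagcn_train(net, cfg0)
  expect_equal(nrow(fit0$loss_trace), 0)
  expect_identical(fit0$state$layer_weights,
                   init_model_state(35, 8, 3, "bilinear",
                                    seed = lagcn:::derive_seed(3, "init")
                   )$layer_weights)

  for (seed in c(1, 2, 3)) {
    cfg <- lagcn_config(epoch = 40, emb_dim = 8, seed = seed)
    fit <- lagcn_train(net, cfg)
    expect_true(all(is.finite(fit$loss_trace$total)))
    expect_lt(fit$loss_trace$total[40], fit$loss_trace$total[1])
  }
})

test_that("training is bit-reproducible given the master seed", {
  sim <- tiny_sim()
  net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)
  cfg <- lagcn_config(epoch = 25, emb_dim = 8, seed = 17)
  f1 <- lagcn_train(net, cfg)
  f2 <- lagcn_train(net, cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$state, f2$state)
})

test_that("prediction is deterministic and separates planted structure", {
  sim <- tiny_sim()
  net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)
  cfg <- lagcn_config(epoch = 60, emb_dim = 8, seed = 2)
  fit <- lagcn_train(net, cfg)
  expect_identical(predict(fit, net), predict(fit, net))

  # untrained zero decoder scores everything 0.5
  st <- fit$state
  st$decoder_weight <- st$decoder_weight * 0
  z <- encode(net, st)$fused
  expect_equal(decode(z, st$decoder_weight, net$n_m),
               matrix(0.5, 20, 15), ignore_attr = TRUE)

  # trained scores rank true positives above true negatives (3 seeds)
  seps <- vapply(c(5, 6, 7), function(s) {
    sim_s <- tiny_sim(seed = s)
    net_s <- build_network(sim_s$n, sim_s$s_m, sim_s$s_d, mu = 6)
    fit_s <- lagcn_train(net_s, lagcn_config(epoch = 60, emb_dim = 8,
                                             seed = s))
    p <- predict(fit_s, net_s)
    mean(p[unclass(sim_s$n) == 1]) - mean(p[unclass(sim_s$n) == 0])
  }, 0)
  expect_true(all(seps > 0))
})

test_that("inner-product decoder ablation keeps W_dec frozen", {
  sim <- tiny_sim()
  net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)
  fit <- lagcn_train(net, lagcn_config(epoch = 15, emb_dim = 8,
                                       decoder = "inner", seed = 4))
  expect_equal(fit$state$decoder_weight, diag(8))
})

test_that("ranked predictions exclude known pairs and sort by score", {
  sim <- tiny_sim()
  net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)
  fit <- lagcn_train(net, lagcn_config(epoch = 20, emb_dim = 8, seed = 8))
  top <- predict_ranked(fit, net, top = 50)
  expect_equal(nrow(top), 50)
  expect_false(any(top$known))
  expect_true(all(diff(top$score) <= 0))
  all_pairs <- predict_ranked(fit, net, top = Inf, include_known = TRUE)
  expect_equal(nrow(all_pairs), 20 * 15)
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- tiny_sim()
  net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)
  fit <- lagcn_train(net, lagcn_config(epoch = 10, emb_dim = 8, seed = 6))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "total", "positive_term", "negative_term"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs, 10)
  expect_equal(gl$attention_layer1 + gl$attention_layer2 +
                 gl$attention_layer3, 1, tolerance = 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
})
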