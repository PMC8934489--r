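test_that("gcn_layer is the propagation rule with optional rectifier", {
  set.seed(21)
  x <- matrix(rnorm(12 * 5), 12, 5)
  w <- matrix(rnorm(5 * 4), 5, 4)
  # identity adjacency and weight: propagation returns X unchanged
  expect_equal(gcn_layer(x, diag(12), diag(5), activate = FALSE), x)
  # dense oracle on a random 12-node instance
  a <- sym_normalize(random_symmetric(12))
  expect_equal(gcn_layer(x, a, w, activate = TRUE),
               pmax(a %*% x %*% w, 0), tolerance = 1e-12)
  # all-negative pre-activation is killed
  expect_equal(gcn_layer(-abs(x), diag(12), diag(5) * 2, activate = TRUE),
               matrix(0, 12, 5))
  expect_error(gcn_layer(x * NA, a, w), "non-finite")
})

test_that("attention_combine matches the softmax-weighted-sum oracle", {
  set.seed(22)
  layers <- replicate(3, matrix(rnorm(20), 5, 4), simplify = FALSE)
  # one-hot limit selects a single layer
  expect_equal(attention_combine(layers, c(1000, -1000, -1000)),
               layers[[1]], tolerance = 1e-6)
  # uniform logits give the arithmetic mean
  expect_equal(attention_combine(layers, c(2, 2, 2)),
               (layers[[1]] + layers[[2]] + layers[[3]]) / 3)
  for (i in 1:10) {
    logits <- rnorm(3)
    expect_equal(attention_combine(layers, logits),
                 oracle_attention(layers, logits), tolerance = 1e-12)
  }
  expect_error(attention_combine(layers, c(1, 2)), "one attention logit")
})

test_that("attention output stays in the element-wise convex hull", {
  set.seed(23)
  for (i in 1:20) {
    layers <- replicate(4, matrix(rnorm(12), 3, 4), simplify = FALSE)
    z <- attention_combine(layers, rnorm(4) * 5)
    lo <- pmin(layers[[1]], layers[[2]], layers[[3]], layers[[4]])
    hi <- pmax(layers[[1]], layers[[2]], layers[[3]], layers[[4]])
    expect_true(all(z >= lo - 1e-12 & z <= hi + 1e-12))
  }
})

test_that("decode is the bilinear logistic score", {
  # scalar hand case: logistic(2 * 1 * 3)
  z <- matrix(c(2, 3), 2, 1)
  expect_equal(decode(z, matrix(1), n_m = 1)[1, 1], 1 / (1 + exp(-6)),
               tolerance = 1e-9)
  # zero embeddings or zero decoder weight give uniform 0.5
  expect_equal(decode(matrix(0, 5, 3), diag(3), n_m = 2),
               matrix(0.5, 2, 3))
  set.seed(24)
  zr <- matrix(rnorm(21), 7, 3)
  expect_equal(decode(zr, matrix(0, 3, 3), n_m = 4), matrix(0.5, 4, 3))
  p <- decode(zr, matrix(rnorm(9), 3), n_m = 4)
  expect_true(all(p > 0 & p < 1))
})

test_that("decode is invariant to shifting all attention logits", {
  set.seed(25)
  layers <- replicate(3, matrix(rnorm(24), 6, 4), simplify = FALSE)
  w <- matrix(rnorm(16), 4)
  logits <- rnorm(3)
  p1 <- decode(attention_combine(layers, logits), w, n_m = 4)
  p2 <- decode(attention_combine(layers, logits + 7.3), w, n_m = 4)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("encode runs the layer stack and reduces correctly", {
  sim <- tiny_sim()
  net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)
  st <- init_model_state(35, emb_dim = 8, layers = 3, seed = 31)
  emb <- encode(net, st)
  expect_length(emb$per_layer, 3)
  expect_equal(dim(emb$fused), c(35, 8))
  expect_true(all(is.finite(emb$fused)))

  # single layer reduces to one propagation step
  st1 <- init_model_state(35, emb_dim = 8, layers = 1, seed = 31)
  emb1 <- encode(net, st1)
  expect_equal(emb1$per_layer[[1]],
               gcn_layer(net$features, net$normalized,
                         st1$layer_weights[[1]]))
  expect_equal(emb1$fused, emb1$per_layer[[1]])

  # zero middle weight zeroes everything downstream
  st0 <- st
  st0$layer_weights[[2]] <- st0$layer_weights[[2]] * 0
  emb0 <- encode(net, st0)
  expect_equal(emb0$per_layer[[2]], matrix(0, 35, 8), ignore_attr = TRUE)
  expect_equal(emb0$per_layer[[3]], matrix(0, 35, 8), ignore_attr = TRUE)

  # associations-only ablation (mu = 0) stays finite despite isolated nodes
  net0 <- build_network(sim$n, sim$s_m, sim$s_d, mu = 0)
  expect_true(all(is.finite(encode(net0, st)$fused)))
})

test_that("edge_dropout is symmetric, seeded and unbiased", {
  a <- sym_normalize(random_symmetric(6, seed = 41))
  expect_identical(edge_dropout(a, 0), a)
  d1 <- edge_dropout(a, 0.5, seed = 99)
  expect_identical(d1, edge_dropout(a, 0.5, seed = 99))
  expect_equal(d1, t(d1))
  expect_true(all(d1[a == 0] == 0))
  expect_error(edge_dropout(a, 1), "rate")

  # unbiasedness: Monte-Carlo mean within 3 SEs element-wise
  set.seed(42)
  reps <- 10000
  acc <- matrix(0, 6, 6)
  for (r in seq_len(reps)) acc <- acc + edge_dropout(a, 0.6)
  m <- acc / reps
  # var of (a / (1-p)) * Bernoulli(1-p) is a^2 p / (1-p)
  se <- sqrt(a^2 * 0.6 / (1 - 0.6)) / sqrt(reps)
  expect_true(all(abs(m - a) <= 3 * se + 1e-12))
})

test_that("model initialisation is seeded and architecture-shaped", {
  st <- init_model_state(30, emb_dim = 16, layers = 3, seed = 5)
  expect_identical(st, init_model_state(30, emb_dim = 16, layers = 3, seed = 5))
  expect_equal(dim(st$layer_weights[[1]]), c(30, 16))
  expect_equal(dim(st$layer_weights[[2]]), c(16, 16))
  expect_equal(st$attention, c(0, 0, 0))
  expect_equal(sum(lagcn:::softmax(st$attention)), 1)
  inner <- init_model_state(30, 16, 3, decoder = "inner", seed = 5)
  expect_equal(inner$decoder_weight, diag(16))
})

test_that("analytic gradients match finite differences", {
  sim <- tiny_sim(seed = 77)
  net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)
  st <- init_model_state(35, emb_dim = 5, layers = 3, seed = 13)
  ntr <- unclass(sim$n)
  lam <- compute_lambda(ntr)
  loss_at <- function(s) {
    fw <- lagcn:::forward_train(net$features, net$normalized, s, 0)
    weighted_ce_loss(decode(fw$z, s$decoder_weight, net$n_m), ntr, lam)$total
  }
  fw <- lagcn:::forward_train(net$features, net$normalized, st, 0)
  bw <- lagcn:::backward_train(fw, net$features, net$normalized, st, ntr, lam)
  eps <- 1e-6
  set.seed(14)
  fd_check <- function(path_get, path_set, grad) {
    for (i in sample(length(grad), min(4, length(grad)))) {
      up <- st; v <- path_get(up); v[i] <- v[i] + eps; up <- path_set(up, v)
      dn <- st; v <- path_get(dn); v[i] <- v[i] - eps; dn <- path_set(dn, v)
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(grad[i], fd, tolerance = 1e-4)
    }
  }
  fd_check(function(s) s$layer_weights[[1]],
           function(s, v) { s$layer_weights[[1]][] <- v; s },
           bw$layer_weights[[1]])
  fd_check(function(s) s$layer_weights[[3]],
           function(s, v) { s$layer_weights[[3]][] <- v; s },
           bw$layer_weights[[3]])
  fd_check(function(s) s$attention,
           function(s, v) { s$attention <- v; s }, bw$attention)
  fd_check(function(s) s$decoder_weight,
           function(s, v) { s$decoder_weight[] <- v; s }, bw$decoder_weight)
})
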