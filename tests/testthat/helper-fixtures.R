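# Shared fixture builders. Everything is generated in code; tests that
# need randomness set their own seed.

random_symmetric <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(runif(n * n), n)
  (a + t(a)) / 2
}

random_assoc <- function(n_m, n_d, n_pos, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- matrix(0, n_m, n_d)
  n[sample(n_m * n_d, n_pos)] <- 1
  n
}

tiny_sim <- function(seed = 42) {
  simulate_associations(20, 15, rank = 3, density = 0.1,
                        similarity_noise = 0.2, seed = seed)
}

# Independent brute-force oracles, coded as directly as possible so
# they share nothing with the implementation under test.

oracle_sym_normalize <- function(a) {
  d <- rowSums(a)
  out <- matrix(0, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (d[i] > 0 && d[j] > 0) out[i, j] <- a[i, j] / sqrt(d[i] * d[j])
    }
  }
  out
}

oracle_weighted_ce <- function(scores, labels, lambda) {
  total <- 0
  for (i in seq_len(nrow(scores))) {
    for (j in seq_len(ncol(scores))) {
      p <- min(max(scores[i, j], 1e-10), 1 - 1e-10)
      total <- total + if (labels[i, j] == 1) lambda * log(p) else log(1 - p)
    }
  }
  -total / length(scores)
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  wins / (length(pos) * length(neg))
}

oracle_gip <- function(n, axis) {
  p <- if (axis == "mirna") n else t(n)
  gamma <- 1 / mean(rowSums(p^2))
  k <- matrix(0, nrow(p), nrow(p))
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(p))) {
      k[i, j] <- exp(-gamma * sum((p[i, ] - p[j, ])^2))
    }
  }
  k
}

oracle_attention <- function(layers, logits) {
  w <- exp(logits) / sum(exp(logits))
  out <- layers[[1]] * 0
  for (l in seq_along(layers)) out <- out + w[l] * layers[[l]]
  out
}
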