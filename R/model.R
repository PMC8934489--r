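#' Single graph-convolution layer
#'
#' One step of the layerwise propagation rule
#' \eqn{X^{(l+1)} = \sigma(\hat A X^{(l)} W^{(l)})}, with
#' \eqn{\sigma} the rectified linear unit when `activate` is `TRUE` and
#' the identity otherwise. No bias term is used. The product is
#' computed as \eqn{\hat A (X W)}, the cheaper association order when
#' the embedding width is small.
#'
#' @param x Node feature/embedding matrix (nodes x width).
#' @param a_norm Symmetrically normalised adjacency.
#' @param w Weight matrix (width x new width).
#' @param activate Apply ReLU? Default `TRUE`.
#' @return The propagated embedding matrix.
#' @export
gcn_layer <- function(x, a_norm, w, activate = TRUE) {
  if (!all(is.finite(x)) || !all(is.finite(a_norm)) || !all(is.finite(w))) {
    stop("non-finite values in gcn_layer inputs", call. = FALSE)
  }
  h <- a_norm %*% (x %*% w)
  if (activate) h[h < 0] <- 0
  h
}

#' Fuse per-layer embeddings with softmax attention
#'
#' Layer attention combines the embeddings produced by each
#' convolution layer into a single representation
#' \eqn{Z = \sum_l \mathrm{softmax}(\alpha)_l X^{(l)}}. Because the
#' weights are a softmax, Z is a convex combination of the layer
#' embeddings and is invariant to adding a constant to all logits.
#'
#' @param per_layer List of equally shaped embedding matrices.
#' @param attention_logits Numeric vector of unnormalised attention
#'   logits, one per layer.
#' @return The fused embedding matrix.
#' @export
attention_combine <- function(per_layer, attention_logits) {
  if (length(per_layer) != length(attention_logits)) {
    stop("one attention logit per layer is required", call. = FALSE)
  }
  dims <- vapply(per_layer, dim, integer(2))
  if (length(per_layer) > 1 && any(dims != dims[, 1])) {
    stop("layer embeddings have mismatched shapes", call. = FALSE)
  }
  a <- softmax(attention_logits)
  Reduce(`+`, Map(`*`, a, per_layer))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Decode pairwise association scores from fused embeddings
#'
#' The bilinear logistic decoder
#' \eqn{a' = \mathrm{sigmoid}(Z_m W_{dec} Z_d^T)} scores every
#' miRNA-disease pair from the miRNA block (first `n_m` rows) and the
#' disease block (last `n_d` rows) of the fused embedding. With
#' `decoder_weight = I` this reduces to the inner-product decoder.
#'
#' @param z Fused embedding, (n_m + n_d) x emb_dim.
#' @param decoder_weight emb_dim x emb_dim matrix.
#' @param n_m Number of miRNA nodes (rows 1..n_m of `z`).
#' @return n_m x n_d score matrix with entries strictly in (0, 1).
#' @export
decode <- function(z, decoder_weight, n_m) {
  z_m <- z[seq_len(n_m), , drop = FALSE]
  z_d <- z[-seq_len(n_m), , drop = FALSE]
  logits <- z_m %*% decoder_weight %*% t(z_d)
  if (!all(is.finite(logits))) stop("non-finite decoder logits", call. = FALSE)
  sigmoid(logits)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Symmetric edge dropout on the normalised adjacency
#'
#' Zeroes each nonzero entry independently with probability `rate`,
#' applying the same decision to (i, j) and (j, i) so the matrix stays
#' symmetric, and rescales survivors by 1/(1 - rate) so the operator is
#' unbiased in expectation. Applied fresh at every training epoch
#' (`adjdp`); disabled at inference.
#'
#' @param a_norm Symmetric matrix.
#' @param rate Dropout probability in \[0, 1).
#' @param seed Optional integer; when given, the mask is drawn from a
#'   local RNG seeded with it, leaving the global RNG untouched.
#' @return The dropped, rescaled matrix (the input itself when
#'   `rate = 0`).
#' @export
edge_dropout <- function(a_norm, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("dropout rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(a_norm)
  draw <- function() {
    u <- matrix(stats::runif(length(a_norm)), nrow(a_norm))
    lo <- lower.tri(u)
    u[lo] <- t(u)[lo]
    u
  }
  u <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  a_norm * (u >= rate) / (1 - rate)
}

# Element (embedding) dropout with inverted scaling; returns the
# dropped matrix and the scaled mask for backprop.
element_dropout <- function(h, rate) {
  if (rate == 0) return(list(h = h, mask = NULL))
  mask <- matrix((stats::runif(length(h)) >= rate) / (1 - rate), nrow(h))
  list(h = h * mask, mask = mask)
}

#' Initialise LAGCN model parameters
#'
#' Weights use variance-scaled (Glorot) uniform initialisation,
#' attention logits start at zero (uniform softmax, 1/L each), and the
#' bilinear decoder weight is Glorot-initialised as well (or frozen to
#' the identity for the inner-product decoder).
#'
#' @param n_nodes Number of network nodes (feature width of X^(0)).
#' @param emb_dim Embedding width. Default 64.
#' @param layers Number of convolution layers. Default 3.
#' @param decoder `"bilinear"` (trainable W_dec) or `"inner"` (W_dec
#'   frozen to I).
#' @param seed Integer seed for reproducible initialisation.
#' @return A `lagcn_state` list: `layer_weights`, `attention`
#'   (logits), `decoder_weight`, plus the architecture fields.
#' @export
init_model_state <- function(n_nodes, emb_dim = 64, layers = 3,
                             decoder = c("bilinear", "inner"), seed = 1L) {
  decoder <- match.arg(decoder)
  stopifnot(layers >= 1, emb_dim >= 1)
  with_local_seed(seed, {
    glorot <- function(fan_in, fan_out) {
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    }
    lw <- vector("list", layers)
    lw[[1]] <- glorot(n_nodes, emb_dim)
    if (layers > 1) {
      for (l in 2:layers) lw[[l]] <- glorot(emb_dim, emb_dim)
    }
    structure(list(
      layer_weights = lw,
      attention = rep(0, layers),
      decoder_weight = if (decoder == "bilinear") glorot(emb_dim, emb_dim)
                       else diag(emb_dim),
      decoder = decoder,
      emb_dim = emb_dim,
      layers = layers,
      n_nodes = n_nodes
    ), class = "lagcn_state")
  })
}

#' Run the GCN encoder
#'
#' Propagates the initial features through all convolution layers (the
#' input of each layer is the output of the previous one, ReLU at every
#' layer) and returns the per-layer embeddings together with the
#' attention-fused embedding.
#'
#' @param net A `hetero_network` (or any list with `normalized`,
#'   `features`, `n_m`).
#' @param state A `lagcn_state`.
#' @param a_norm Optional adjacency override (e.g. after
#'   [edge_dropout()]); defaults to `net$normalized`.
#' @return A list with `per_layer` (list of L embedding matrices) and
#'   `fused` (Z).
#' @export
encode <- function(net, state, a_norm = NULL) {
  a_norm <- a_norm %||% net$normalized
  h <- net$features
  per_layer <- vector("list", state$layers)
  for (l in seq_len(state$layers)) {
    h <- gcn_layer(h, a_norm, state$layer_weights[[l]], activate = TRUE)
    per_layer[[l]] <- h
  }
  list(per_layer = per_layer,
       fused = attention_combine(per_layer, state$attention))
}

# Evaluate an expression under a temporary RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic derivation of named sub-seeds from one master seed, so
# fold assignment, weight init and dropout draw from independent
# streams. Kept inside 32-bit integer range.
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}
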