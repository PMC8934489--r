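#' Training configuration
#'
#' Bundles the model and optimisation hyperparameters with their
#' published defaults: 250 epochs, embedding width 64, Adam learning
#' rate 0.01, adjacency edge dropout `adjdp = 0.6`, embedding element
#' dropout `dp = 0.4`, similarity penalty `simw = 6`, three convolution
#' layers. Training is full-graph: every miRNA-disease cell enters the
#' loss at every epoch, with no early stopping, schedule or weight
#' decay.
#'
#' @param epoch Number of full-graph gradient steps.
#' @param emb_dim Embedding width.
#' @param lr Adam learning rate.
#' @param adjdp Edge-dropout rate on the normalised adjacency, in
#'   \[0, 1).
#' @param dp Element-dropout rate on each layer embedding, in \[0, 1).
#' @param simw Similarity penalty factor mu used when the network is
#'   built through [lagcn_cv()] or the CLI.
#' @param layers Number of convolution layers.
#' @param decoder `"bilinear"` or `"inner"` (identity decoder weight,
#'   frozen).
#' @param threshold Score threshold for recall/accuracy.
#' @param seed Master seed; all randomness (init, dropout, folds)
#'   derives from it through named streams.
#' @return A `lagcn_config` list.
#' @export
lagcn_config <- function(epoch = 250, emb_dim = 64, lr = 0.01,
                         adjdp = 0.6, dp = 0.4, simw = 6, layers = 3,
                         decoder = c("bilinear", "inner"),
                         threshold = 0.5, seed = 1L) {
  decoder <- match.arg(decoder)
  stopifnot(epoch >= 0, emb_dim >= 1, lr > 0, layers >= 1,
            adjdp >= 0, adjdp < 1, dp >= 0, dp < 1, simw >= 0,
            threshold > 0, threshold < 1)
  structure(list(epoch = as.integer(epoch), emb_dim = as.integer(emb_dim),
                 lr = lr, adjdp = adjdp, dp = dp, simw = simw,
                 layers = as.integer(layers), decoder = decoder,
                 threshold = threshold, seed = as.integer(seed)),
            class = "lagcn_config")
}

#' Class-imbalance weight
#'
#' The weighted cross-entropy multiplies the positive-class term by
#' \eqn{\lambda = |y^-| / |y^+|}, the ratio of unobserved to observed
#' pairs in the training matrix, so the rare positives are not swamped
#' by the ~97% negative cells.
#'
#' @param n_train Binary training association matrix.
#' @return The scalar weight.
#' @export
#'
#' @examples
#' compute_lambda(matrix(c(1, 1, 0, 0, 0, 0), 2, 3))  # 4/2 = 2
compute_lambda <- function(n_train) {
  n_train <- unclass(n_train)
  pos <- sum(n_train == 1)
  neg <- sum(n_train == 0)
  if (pos == 0) stop("no positive pairs: lambda undefined", call. = FALSE)
  if (neg == 0) stop("no negative pairs: lambda undefined", call. = FALSE)
  neg / pos
}

#' Imbalance-weighted cross-entropy loss
#'
#' \deqn{L = -\frac{1}{AB}\Big(\lambda \sum_{(i,j) \in y^+} \log a'_{ij}
#'   + \sum_{(i,j) \in y^-} \log(1 - a'_{ij})\Big)}
#' over all A x B miRNA-disease cells of the training matrix. Scores
#' are clipped to \[1e-10, 1 - 1e-10\] before the logarithms, since the
#' loss is undefined at exactly 0 or 1.
#'
#' @param scores n_m x n_d score matrix in (0, 1).
#' @param n_train Binary training association matrix, same shape.
#' @param lambda_weight Positive-class weight; defaults to
#'   [compute_lambda()] of `n_train`.
#' @return A `lagcn_loss` list: `total`, `positive_term`,
#'   `negative_term`, `lambda_weight`.
#' @export
weighted_ce_loss <- function(scores, n_train,
                             lambda_weight = compute_lambda(n_train)) {
  n_train <- unclass(n_train)
  if (!all(dim(scores) == dim(n_train))) {
    stop("score and label matrices have different shapes", call. = FALSE)
  }
  p <- pmin(pmax(scores, 1e-10), 1 - 1e-10)
  pos <- sum(log(p[n_train == 1]))
  neg <- sum(log(1 - p[n_train == 0]))
  structure(list(
    total = -(lambda_weight * pos + neg) / length(n_train),
    positive_term = pos,
    negative_term = neg,
    lambda_weight = lambda_weight
  ), class = "lagcn_loss")
}

# Forward pass with dropout, keeping every intermediate needed by the
# backward pass. Element dropout is applied to each layer output and
# the dropped embedding feeds both the next layer and the attention
# fusion.
forward_train <- function(x0, a_drop, state, dp) {
  L <- state$layers
  pre <- h_drop <- masks <- vector("list", L)
  h <- x0
  for (l in seq_len(L)) {
    pre[[l]] <- a_drop %*% (h %*% state$layer_weights[[l]])
    act <- pre[[l]]
    act[act < 0] <- 0
    ed <- element_dropout(act, dp)
    h_drop[[l]] <- ed$h
    masks[l] <- list(ed$mask)  # may be NULL when dp = 0
    h <- ed$h
  }
  alpha <- softmax(state$attention)
  z <- Reduce(`+`, Map(`*`, alpha, h_drop))
  list(pre = pre, h_drop = h_drop, masks = masks, alpha = alpha, z = z)
}

# Analytic gradients of the weighted cross-entropy w.r.t. all trainable
# parameters. `fw` is the cache from forward_train; returns gradients
# matching the state layout plus the loss terms.
backward_train <- function(fw, x0, a_drop, state, n_train, lambda_weight) {
  n_m <- nrow(n_train)
  L <- state$layers
  z_m <- fw$z[seq_len(n_m), , drop = FALSE]
  z_d <- fw$z[-seq_len(n_m), , drop = FALSE]
  w_dec <- state$decoder_weight
  logits <- z_m %*% w_dec %*% t(z_d)
  p <- sigmoid(logits)
  loss <- weighted_ce_loss(p, n_train, lambda_weight)

  # d loss / d logits for the clipped weighted CE; the clip region has
  # zero gradient only at machine-saturated scores, so the plain form
  # is used: -(1/AB) * (lambda*y*(1-p) - (1-y)*p)
  ab <- length(n_train)
  g <- -(lambda_weight * n_train * (1 - p) - (1 - n_train) * p) / ab

  d_wdec <- crossprod(z_m, g %*% z_d)
  d_zm <- g %*% z_d %*% t(w_dec)
  d_zd <- crossprod(g, z_m %*% w_dec)
  d_z <- rbind(d_zm, d_zd)

  # attention softmax backward: ds_l = <dZ, H_l>, then the softmax
  # Jacobian folds them into logit gradients
  ds <- vapply(fw$h_drop, function(h) sum(d_z * h), 0)
  a <- fw$alpha
  d_att <- a * (ds - sum(a * ds))

  d_w <- vector("list", L)
  d_h <- a[L] * d_z  # gradient flowing into layer L's dropped output
  for (l in L:1) {
    if (!is.null(fw$masks[[l]])) d_h <- d_h * fw$masks[[l]]
    d_pre <- d_h * (fw$pre[[l]] > 0)
    h_in <- if (l == 1) x0 else fw$h_drop[[l - 1]]
    ad_pre <- a_drop %*% d_pre           # a_drop symmetric
    d_w[[l]] <- crossprod(h_in, ad_pre)
    if (l > 1) {
      d_h <- tcrossprod(ad_pre, state$layer_weights[[l]]) + a[l - 1] * d_z
    }
  }
  list(layer_weights = d_w, attention = d_att, decoder_weight = d_wdec,
       loss = loss)
}

# One Adam step over a flat list of parameter arrays.
adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train the layer-attention GCN
#'
#' Full-graph training: at every epoch the normalised adjacency gets a
#' fresh symmetric edge-dropout mask (`adjdp`), the encoder runs with
#' element dropout `dp` on each layer embedding, all miRNA-disease
#' cells enter the weighted cross-entropy, and one Adam step updates
#' the layer weights, attention logits and (for the bilinear decoder)
#' the decoder weight. Deterministic given `config$seed`.
#'
#' @param net A `hetero_network` built from the *training* association
#'   matrix (held-out positives must already be masked).
#' @param config A [lagcn_config()].
#' @param n_train Binary label matrix for the loss; defaults to the
#'   association block of `net$features`.
#' @return A `lagcn_fit`: the trained `state`, the `loss_trace` tibble
#'   (epoch, total, positive_term, negative_term), `lambda_weight` and
#'   the config echo.
#' @export
lagcn_train <- function(net, config = lagcn_config(), n_train = NULL) {
  n_m <- net$n_m
  n_train <- unclass(n_train %||% net$features[seq_len(n_m), -seq_len(n_m),
                                              drop = FALSE])
  lambda_weight <- compute_lambda(n_train)
  state <- init_model_state(net$n_m + net$n_d, config$emb_dim, config$layers,
                            config$decoder,
                            seed = derive_seed(config$seed, "init"))
  flatten <- function(s) c(s$layer_weights,
                           list(att = s$attention, dec = s$decoder_weight))
  opt <- list(t = 0,
              m = lapply(flatten(state), function(p) p * 0),
              v = lapply(flatten(state), function(p) p * 0))
  trace <- matrix(NA_real_, config$epoch, 3)

  if (config$epoch > 0) {
    with_local_seed(derive_seed(config$seed, "dropout"), {
      for (ep in seq_len(config$epoch)) {
        a_drop <- edge_dropout(net$normalized, config$adjdp)
        fw <- forward_train(net$features, a_drop, state, config$dp)
        bw <- backward_train(fw, net$features, a_drop, state,
                             n_train, lambda_weight)
        if (!is.finite(bw$loss$total)) {
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        }
        trace[ep, ] <- c(bw$loss$total, bw$loss$positive_term,
                         bw$loss$negative_term)
        grads <- c(bw$layer_weights,
                   list(att = bw$attention, dec = bw$decoder_weight))
        if (config$decoder == "inner") grads$dec <- grads$dec * 0
        upd <- adam_step(flatten(state), grads, opt, config$lr)
        opt <- upd$opt
        state$layer_weights <- upd$params[seq_len(config$layers)]
        state$attention <- upd$params$att
        state$decoder_weight <- upd$params$dec
      }
    })
  }

  structure(list(
    state = state,
    loss_trace = tibble::tibble(
      epoch = seq_len(config$epoch),
      total = trace[, 1],
      positive_term = trace[, 2],
      negative_term = trace[, 3]
    ),
    lambda_weight = lambda_weight,
    config = config,
    optimizer = "adam",
    net_dims = c(n_m = net$n_m, n_d = net$n_d)
  ), class = "lagcn_fit")
}

#' Score all miRNA-disease pairs with a trained model
#'
#' Deterministic inference: both dropouts disabled, the full normalised
#' adjacency used, scores from encode -> attention fusion -> decoder.
#'
#' @param object A `lagcn_fit`.
#' @param net The `hetero_network` to score (typically the one trained
#'   on).
#' @param ... Unused.
#' @return n_m x n_d matrix of association probabilities in (0, 1),
#'   with entity ids as dimnames.
#' @export
predict.lagcn_fit <- function(object, net, ...) {
  emb <- encode(net, object$state)
  p <- decode(emb$fused, object$state$decoder_weight, net$n_m)
  dimnames(p) <- list(net$mirna_ids, net$disease_ids)
  p
}

#' Ranked novel-association predictions
#'
#' Returns the highest-scoring pairs as a tibble, excluding already
#' known (training-positive) pairs unless `include_known = TRUE`.
#'
#' @param fit A `lagcn_fit`.
#' @param net The network scored.
#' @param top Number of rows to keep; `Inf` for all.
#' @param include_known Keep known positives in the ranking?
#' @return A tibble (mirna, disease, score, known) sorted by
#'   non-increasing score.
#' @export
predict_ranked <- function(fit, net, top = 50, include_known = FALSE) {
  p <- predict(fit, net)
  n_m <- net$n_m
  known <- net$features[seq_len(n_m), -seq_len(n_m), drop = FALSE] == 1
  out <- tibble::tibble(
    mirna = rep(net$mirna_ids, times = net$n_d),
    disease = rep(net$disease_ids, each = net$n_m),
    score = as.vector(p),
    known = as.vector(known)
  )
  if (!include_known) out <- dplyr::filter(out, !.data$known)
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  if (is.finite(top)) out <- dplyr::slice_head(out, n = as.integer(top))
  out
}

#' @export
print.lagcn_fit <- function(x, ...) {
  cat("LAGCN fit:", x$config$layers, "GCN layers, emb_dim",
      x$config$emb_dim, ",", x$config$decoder, "decoder\n")
  cat("  network:", x$net_dims["n_m"], "miRNAs x", x$net_dims["n_d"],
      "diseases; lambda =", format(x$lambda_weight, digits = 5), "\n")
  if (nrow(x$loss_trace) > 0) {
    cat("  loss:", format(x$loss_trace$total[1], digits = 5), "->",
        format(x$loss_trace$total[nrow(x$loss_trace)], digits = 5),
        "over", nrow(x$loss_trace), "epochs\n")
  }
  invisible(x)
}
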