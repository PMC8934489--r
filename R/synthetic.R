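#' Simulate a bipartite association network with planted structure
#'
#' Generates data matching the statistical regime of curated
#' miRNA-disease catalogues: a sparse binary bipartite matrix with
#' low-rank latent structure (the real catalogue is 495 x 383 at about
#' 2.9% density), plus similarity matrices correlated with the same
#' latent factors — encoding the homophily assumption that similar
#' miRNAs associate with similar diseases, which is exactly what the
#' model exploits.
#'
#' Latent factors U (n_m x rank) and V (n_d x rank) are drawn with
#' independent standard normal entries; the positives are the top
#' `ceiling(density * n_m * n_d)` cells of U V^T, so the positive
#' count is pinned exactly. Similarities are Gaussian kernels on the
#' factor rows (bandwidth 1/rank), blended towards the identity by
#' `similarity_noise`: at 1 both similarity matrices are exactly the
#' identity and carry no signal.
#'
#' @param n_m,n_d Numbers of miRNAs and diseases.
#' @param rank Latent dimension; at most `min(n_m, n_d)`.
#' @param density Target positive fraction in (0, 1).
#' @param similarity_noise Blend weight towards the identity, in
#'   \[0, 1\].
#' @param seed Integer seed; the triple is deterministic given it.
#' @return A `mdn_sim` list: `n` (an [association_matrix()]), `s_m`,
#'   `s_d` (validated similarity matrices), `factors` (U, V), and the
#'   spec echo.
#' @export
#'
#' @examples
#' sim <- simulate_associations(30, 20, rank = 3, density = 0.1, seed = 7)
#' sum(sim$n)  # ceiling(0.1 * 600) = 60
simulate_associations <- function(n_m, n_d, rank = 4, density = 0.03,
                                  similarity_noise = 0.2, seed = 1L) {
  stopifnot(density > 0, density < 1, rank >= 1, rank <= min(n_m, n_d),
            similarity_noise >= 0, similarity_noise <= 1)
  n_pos <- ceiling(density * n_m * n_d)
  if (n_pos < 1 || n_pos >= n_m * n_d) {
    stop("density leaves one class empty", call. = FALSE)
  }
  out <- with_local_seed(seed, {
    u <- matrix(stats::rnorm(n_m * rank), n_m, rank)
    v <- matrix(stats::rnorm(n_d * rank), n_d, rank)
    scores <- tcrossprod(u, v)
    cut <- sort(scores, decreasing = TRUE)[n_pos]
    n <- matrix(as.numeric(scores >= cut), n_m, n_d)
    # ties at the cut could overshoot the count; break them by order
    if (sum(n) > n_pos) {
      extra <- which(scores == cut)
      n[extra[-seq_len(length(extra) - (sum(n) - n_pos))]] <- 0
    }
    list(u = u, v = v, n = n)
  })
  latent_kernel <- function(f) {
    d2 <- as.matrix(stats::dist(f))^2
    k <- exp(-d2 / rank)
    (1 - similarity_noise) * k + similarity_noise * diag(nrow(f))
  }
  s_m <- latent_kernel(out$u)
  s_d <- latent_kernel(out$v)
  mirna_ids <- sprintf("mir-%03d", seq_len(n_m))
  disease_ids <- sprintf("disease-%03d", seq_len(n_d))
  dimnames(s_m) <- list(mirna_ids, mirna_ids)
  dimnames(s_d) <- list(disease_ids, disease_ids)
  structure(list(
    n = association_matrix(out$n, mirna_ids, disease_ids),
    s_m = validate_similarity(s_m),
    s_d = validate_similarity(s_d),
    factors = list(u = out$u, v = out$v),
    spec = list(n_m = n_m, n_d = n_d, rank = rank, density = density,
                similarity_noise = similarity_noise, seed = as.integer(seed))
  ), class = "mdn_sim")
}

#' @export
print.mdn_sim <- function(x, ...) {
  s <- x$spec
  cat("Synthetic miRNA-disease network: ", s$n_m, " x ", s$n_d,
      ", rank ", s$rank, ", ", sum(x$n), " positives (density ",
      format(sum(x$n) / (s$n_m * s$n_d), digits = 3), ")\n", sep = "")
  invisible(x)
}
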