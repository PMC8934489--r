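#' Assemble the penalised block adjacency of the heterogeneous network
#'
#' Stacks within-type similarity and between-type association into one
#' adjacency over miRNA and disease nodes,
#' \deqn{A = \begin{bmatrix} \mu S^m & N \\ N^T & \mu S^d \end{bmatrix},}
#' where the penalty factor \eqn{\mu} (the `simw` hyperparameter)
#' controls how strongly similarity edges contribute relative to
#' association edges. `mu = 0` drops the similarity blocks entirely,
#' the associations-only ablation.
#'
#' @param s_m miRNA-miRNA similarity matrix (n_m x n_m).
#' @param s_d disease-disease similarity matrix (n_d x n_d).
#' @param n Association matrix (n_m x n_d).
#' @param mu Non-negative penalty factor. Default 6.
#'
#' @return Symmetric (n_m + n_d) square matrix; miRNAs occupy the first
#'   n_m indices, diseases the rest.
#' @export
#'
#' @examples
#' build_adjacency(matrix(1), matrix(1), matrix(1), mu = 6)
build_adjacency <- function(s_m, s_d, n, mu = 6) {
  n <- unclass(n)
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0) {
    stop("mu must be a non-negative scalar", call. = FALSE)
  }
  if (nrow(s_m) != nrow(n)) {
    stop("miRNA axis mismatch: similarity is ", nrow(s_m),
         " but association has ", nrow(n), " rows", call. = FALSE)
  }
  if (nrow(s_d) != ncol(n)) {
    stop("disease axis mismatch: similarity is ", nrow(s_d),
         " but association has ", ncol(n), " columns", call. = FALSE)
  }
  rbind(cbind(mu * s_m, n), cbind(t(n), mu * s_d))
}

#' Initial node features of the heterogeneous network
#'
#' The feature matrix is the zero-diagonal-block form
#' \deqn{X^{(0)} = \begin{bmatrix} 0 & N \\ N^T & 0 \end{bmatrix},}
#' so each node's initial feature vector is its binary association
#' profile. Equals [build_adjacency()] at `mu = 0`.
#'
#' @param n Association matrix.
#' @return Symmetric binary (n_m + n_d) square matrix.
#' @export
build_features <- function(n) {
  n <- unclass(n)
  n_m <- nrow(n)
  n_d <- ncol(n)
  rbind(cbind(matrix(0, n_m, n_m), n),
        cbind(t(n), matrix(0, n_d, n_d)))
}

#' Degree matrix of a non-negative adjacency
#'
#' @param a Square non-negative matrix.
#' @return Diagonal matrix of row sums. Zero-degree rows (isolated
#'   nodes, possible in the `mu = 0` ablation) yield zero diagonal
#'   entries; [sym_normalize()] guards the division.
#' @export
degree_matrix <- function(a) {
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (any(a < 0)) stop("adjacency has negative entries", call. = FALSE)
  diag(rowSums(a), nrow(a))
}

#' Symmetric Laplacian normalisation
#'
#' Computes \eqn{\hat A = D^{-1/2} A D^{-1/2}} with D the degree
#' matrix. For zero-degree nodes the corresponding entry of
#' \eqn{D^{-1/2}} is defined as 0, so their rows and columns of
#' \eqn{\hat A} are zero rather than NaN; no self-loops are added,
#' since the penalised block adjacency already carries diagonal mass
#' through the unit-diagonal similarities. The result is symmetric
#' with spectral radius at most 1.
#'
#' @param a Square symmetric non-negative matrix.
#' @param tol Symmetry tolerance. Default `1e-8`.
#' @return The normalised matrix.
#' @export
#'
#' @examples
#' sym_normalize(matrix(c(6, 1, 1, 6), 2, 2))
sym_normalize <- function(a, tol = 1e-8) {
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (any(a < 0)) stop("adjacency has negative entries", call. = FALSE)
  if (max(abs(a - t(a))) > tol) {
    stop("adjacency asymmetric beyond tolerance", call. = FALSE)
  }
  deg <- rowSums(a)
  d_inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  a * outer(d_inv_sqrt, d_inv_sqrt)
}

#' Build the full heterogeneous network container
#'
#' Convenience constructor running [build_adjacency()],
#' [build_features()] and [sym_normalize()], with an optional Gaussian
#' interaction profile fallback when similarity matrices are absent.
#'
#' @param n An [association_matrix()].
#' @param s_m,s_d Similarity matrices, or `NULL` to use the fallback.
#' @param mu Penalty factor (`simw`). Default 6.
#' @param similarity_fallback `"gip"` to fill missing similarities with
#'   [gip_kernel()]; `"none"` (default) to insist they are supplied.
#'
#' @return An object of class `hetero_network`: a list with `adjacency`,
#'   `features`, `normalized`, `n_m`, `n_d`, `mu` and the entity ids.
#' @export
build_network <- function(n, s_m = NULL, s_d = NULL, mu = 6,
                          similarity_fallback = c("none", "gip")) {
  similarity_fallback <- match.arg(similarity_fallback)
  if (is.null(s_m)) {
    if (similarity_fallback == "none") {
      stop("no miRNA similarity supplied; pass s_m or set ",
           "similarity_fallback = \"gip\"", call. = FALSE)
    }
    s_m <- gip_kernel(n, "mirna")
  }
  if (is.null(s_d)) {
    if (similarity_fallback == "none") {
      stop("no disease similarity supplied; pass s_d or set ",
           "similarity_fallback = \"gip\"", call. = FALSE)
    }
    s_d <- gip_kernel(n, "disease")
  }
  s_m <- validate_similarity(unclass(s_m))
  s_d <- validate_similarity(unclass(s_d))
  adj <- build_adjacency(s_m, s_d, n, mu)
  structure(list(
    adjacency = adj,
    features = build_features(n),
    normalized = sym_normalize(adj),
    n_m = nrow(n),
    n_d = ncol(n),
    mu = mu,
    mirna_ids = rownames(n) %||% paste0("m", seq_len(nrow(n))),
    disease_ids = colnames(n) %||% paste0("d", seq_len(ncol(n)))
  ), class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("Heterogeneous miRNA-disease network\n")
  cat("  miRNAs:  ", x$n_m, "\n")
  cat("  diseases:", x$n_d, "\n")
  cat("  nodes:   ", x$n_m + x$n_d, "  penalty mu =", x$mu, "\n")
  invisible(x)
}
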