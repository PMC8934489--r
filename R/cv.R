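#' Partition known associations into cross-validation folds
#'
#' Randomly divides the positive cells of the association matrix into
#' `k` subsets of (as near as possible) equal size; fold sizes differ by
#' at most one. Deterministic given the seed.
#'
#' @param n Binary association matrix.
#' @param k Number of folds. Default 5.
#' @param seed Integer seed.
#' @return A `fold_split` list: `assignments` tibble (mirna index,
#'   disease index, fold), `k`, `seed`.
#' @export
kfold_split <- function(n, k = 5, seed = 1L) {
  n <- unclass(n)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  pos <- which(n == 1, arr.ind = TRUE)
  if (nrow(pos) < k) {
    stop("fewer positive pairs (", nrow(pos), ") than folds (", k, ")",
         call. = FALSE)
  }
  folds <- with_local_seed(seed, {
    sample(rep(seq_len(k), length.out = nrow(pos)))
  })
  structure(list(
    assignments = tibble::tibble(mirna = pos[, 1], disease = pos[, 2],
                                 fold = folds),
    k = k, seed = as.integer(seed)
  ), class = "fold_split")
}

#' Mask one fold's positives out of the association matrix
#'
#' Sets the held-out fold's positive cells to zero. The masked matrix
#' is used both to rebuild the training adjacency and as the loss
#' labels, so the encoder never sees a test edge.
#'
#' @param n Binary association matrix.
#' @param split A [kfold_split()] result.
#' @param fold Fold index in 1..k to hold out.
#' @return The masked matrix, same dimnames.
#' @export
mask_fold <- function(n, split, fold) {
  if (fold < 1 || fold > split$k) {
    stop("fold must be in 1..", split$k, call. = FALSE)
  }
  held <- dplyr::filter(split$assignments, .data$fold == !!fold)
  out <- unclass(n)
  out[cbind(held$mirna, held$disease)] <- 0
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random
#' positive outscores a uniformly random negative, with ties counted
#' one half. Computed via midranks, so it is exact and invariant under
#' any strictly increasing transform of the scores.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1 = positive), same length.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Thresholded classification metrics
#'
#' A pair is predicted positive when its score is at least the
#' threshold; recall = TP/(TP+FN) and accuracy =
#' (TP+TN)/(TP+TN+FP+FN). With no positive labels recall is undefined
#' and reported as `NA` rather than zero.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector.
#' @param threshold Score cut in (0, 1). Default 0.5.
#' @return Named list with `recall` and `accuracy`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n_pos <- tp + fn
  list(recall = if (n_pos > 0) tp / n_pos else NA_real_,
       accuracy = (tp + tn) / length(labels))
}

#' Five-fold cross-validation of the layer-attention GCN
#'
#' For each fold: the held-out positives are masked out of the
#' association matrix, the heterogeneous network is rebuilt from the
#' masked matrix (masking both the adjacency and the loss labels — a
#' leak check asserts this every fold), the model is trained, and the
#' fold is evaluated on the masked positives (label 1) against all
#' never-positive cells (label 0); no negative sampling is performed.
#'
#' @param n An [association_matrix()].
#' @param s_m,s_d Similarity matrices, or `NULL` with a fallback.
#' @param config A [lagcn_config()]; its `simw` is the penalty mu and
#'   its `seed` the master seed for folds, initialisation and dropout.
#' @param k Number of folds. Default 5.
#' @param similarity_fallback Passed to [build_network()].
#' @return A `lagcn_cv` object: `per_fold` tibble (fold, auc, recall,
#'   accuracy, n_test_pos, n_test_neg), `summary` tibble of means and
#'   standard deviations, the fold split, config echo and masking
#'   record.
#' @export
lagcn_cv <- function(n, s_m = NULL, s_d = NULL, config = lagcn_config(),
                     k = 5, similarity_fallback = c("none", "gip")) {
  similarity_fallback <- match.arg(similarity_fallback)
  n <- association_matrix(unclass(n), rownames(n), colnames(n))
  split <- kfold_split(n, k, seed = derive_seed(config$seed, "folds"))
  never_pos <- unclass(n) == 0

  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    n_train <- mask_fold(n, split, f)
    held <- dplyr::filter(split$assignments, .data$fold == !!f)
    test_pos <- cbind(held$mirna, held$disease)

    # leak check: every test positive must be absent from the training
    # labels (and hence from the adjacency built from them)
    if (any(n_train[test_pos] != 0)) {
      stop("leak detected in fold ", f, ": test positive present in the ",
           "training matrix", call. = FALSE)
    }

    net <- build_network(
      association_matrix(n_train, rownames(n), colnames(n)),
      s_m = s_m, s_d = s_d, mu = config$simw,
      similarity_fallback = similarity_fallback
    )
    adj_pos <- cbind(test_pos[, 1], net$n_m + test_pos[, 2])
    stopifnot(all(net$adjacency[adj_pos] == 0),
              all(net$features[adj_pos] == 0))

    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, paste0("fold", f))
    fit <- lagcn_train(net, fold_config)
    p <- predict(fit, net)

    test_idx <- rbind(test_pos, which(never_pos, arr.ind = TRUE))
    labels <- c(rep(1, nrow(test_pos)), rep(0, sum(never_pos)))
    scores <- p[test_idx]
    tm <- threshold_metrics(scores, labels, config$threshold)
    tibble::tibble(
      fold = f,
      auc = auc_score(scores, labels),
      recall = tm$recall,
      accuracy = tm$accuracy,
      n_test_pos = nrow(test_pos),
      n_test_neg = sum(never_pos),
      final_loss = if (nrow(fit$loss_trace) > 0) {
        fit$loss_trace$total[nrow(fit$loss_trace)]
      } else NA_real_
    )
  })

  summary_tbl <- per_fold |>
    tidyr::pivot_longer(c("auc", "recall", "accuracy"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")

  structure(list(
    per_fold = per_fold,
    summary = summary_tbl,
    split = split,
    config = config,
    k = k,
    masking = "held-out positives removed from both adjacency and loss labels",
    optimizer = "adam"
  ), class = "lagcn_cv")
}

#' @export
print.lagcn_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (master seed ", x$config$seed, ")\n",
      sep = "")
  print(x$summary)
  invisible(x)
}
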