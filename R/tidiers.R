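#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained LAGCN fit
#'
#' Returns the per-epoch loss trace as a tibble, one row per epoch.
#'
#' @param x A `lagcn_fit`.
#' @param ... Unused.
#' @return A tibble with columns epoch, total, positive_term,
#'   negative_term.
#' @method tidy lagcn_fit
#' @export
tidy.lagcn_fit <- function(x, ...) x$loss_trace

#' One-row summary of a trained LAGCN fit
#'
#' @param x A `lagcn_fit`.
#' @param ... Unused.
#' @return A tibble with the architecture, imbalance weight, learned
#'   attention distribution and final loss.
#' @method glance lagcn_fit
#' @export
glance.lagcn_fit <- function(x, ...) {
  a <- softmax(x$state$attention)
  tibble::tibble(
    layers = x$config$layers,
    emb_dim = x$config$emb_dim,
    decoder = x$config$decoder,
    epochs = nrow(x$loss_trace),
    lambda_weight = x$lambda_weight,
    final_loss = if (nrow(x$loss_trace) > 0) {
      x$loss_trace$total[nrow(x$loss_trace)]
    } else NA_real_,
    attention_layer1 = a[1],
    attention_layer2 = if (length(a) > 1) a[2] else NA_real_,
    attention_layer3 = if (length(a) > 2) a[3] else NA_real_
  )
}

#' Tidy a cross-validation report
#'
#' @param x A `lagcn_cv`.
#' @param ... Unused.
#' @return The per-fold metric tibble.
#' @method tidy lagcn_cv
#' @export
tidy.lagcn_cv <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation report
#'
#' @param x A `lagcn_cv`.
#' @param ... Unused.
#' @return A tibble with mean and sd of AUC, recall and accuracy.
#' @method glance lagcn_cv
#' @export
glance.lagcn_cv <- function(x, ...) {
  s <- x$summary
  get <- function(m, col) s[[col]][s$metric == m]
  tibble::tibble(
    k = x$k,
    mean_auc = get("auc", "mean"), sd_auc = get("auc", "sd"),
    mean_recall = get("recall", "mean"), sd_recall = get("recall", "sd"),
    mean_accuracy = get("accuracy", "mean"),
    sd_accuracy = get("accuracy", "sd"),
    threshold = x$config$threshold,
    seed = x$config$seed
  )
}

#' Plot the training loss trace
#'
#' @param object A `lagcn_fit`.
#' @param ... Unused.
#' @return A ggplot of total loss against epoch.
#' @method autoplot lagcn_fit
#' @export
autoplot.lagcn_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$total)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy",
                  title = "LAGCN training loss") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `lagcn_cv`.
#' @param ... Unused.
#' @return A ggplot with one point per fold and metric, plus the mean.
#' @method autoplot lagcn_cv
#' @export
autoplot.lagcn_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold,
                              c("auc", "recall", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "value", colour = "fold",
                  title = "Cross-validation metrics by fold") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
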