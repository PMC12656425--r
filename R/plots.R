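#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

utils::globalVariables("density")

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a training fit into its per-epoch history
#' @param x A `voxfuse_fit` from [train()].
#' @param ... Unused.
#' @return Tibble with `epoch`, `lr`, `train_loss`, `val_loss`,
#'   `train_acc`, `val_acc`.
#' @export
tidy.voxfuse_fit <- function(x, ...) x$history

#' One-row summary of a training fit
#' @param x A `voxfuse_fit`.
#' @param ... Unused.
#' @export
glance.voxfuse_fit <- function(x, ...) {
  tibble::tibble(
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)]
  )
}

#' Tidy an evaluation report into metric/value pairs
#' @param x An `eval_report` from [evaluate()].
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    metric = setdiff(names(m), "n"),
    value = as.numeric(m[setdiff(names(m), "n")])
  )
}

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
glance.eval_report <- function(x, ...) x$metrics

#' Tidy an attribution report into feature scores
#' @param x An `attribution_report`.
#' @param ... Unused.
#' @export
tidy.attribution_report <- function(x, ...) x$scores

#' One-row summary of an attribution report
#' @param x An `attribution_report`.
#' @param ... Unused.
#' @export
glance.attribution_report <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_features = nrow(x$scores),
    normalized = x$normalized,
    residual = if (is.null(x$residual)) NA_real_ else x$residual,
    seed = x$seed
  )
}

#' Tidy a cross-validation report into per-fold metrics
#' @param x A `cv_report` from [cross_validate()].
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' Summary of a cross-validation report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One row per metric with mean and variance across folds.
#' @export
glance.cv_report <- function(x, ...) x$summary

#' Tidy a confidence report into per-class quantiles
#' @param x A `confidence_report`.
#' @param ... Unused.
#' @export
tidy.confidence_report <- function(x, ...) x$quantiles

#' One-row summary of a confidence report
#' @param x A `confidence_report`.
#' @param ... Unused.
#' @export
glance.confidence_report <- function(x, ...) {
  tibble::tibble(overlap = x$overlap, n = nrow(x$scores))
}

#' Plot training history
#'
#' Train and validation loss per epoch, with the best (restored) checkpoint
#' marked.
#'
#' @param object A `voxfuse_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voxfuse_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[c("epoch", "train_loss", "val_loss")],
    c("train_loss", "val_loss"),
    names_to = "series", values_to = "loss"
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(
      title = "Training history",
      subtitle = sprintf("best checkpoint at epoch %d", object$best_epoch),
      x = "epoch", y = "cross-entropy loss", colour = NULL
    )
}

#' Plot the ROC curve of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  sc <- object$confidences
  thr <- sort(unique(c(-Inf, sc$p_pd, Inf)), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- sc$p_pd >= t
    tibble::tibble(
      fpr = sum(pred & sc$truth == 0) / max(sum(sc$truth == 0), 1),
      tpr = sum(pred & sc$truth == 1) / max(sum(sc$truth == 1), 1)
    )
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(
      title = sprintf("ROC curve (AUC = %.3f)", object$metrics$auc),
      x = "false positive rate", y = "true positive rate"
    )
}

#' Plot feature-importance scores
#'
#' @param object An `attribution_report`.
#' @param top_n Show at most this many features (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attribution_report <- function(object, top_n = 20, ...) {
  s <- utils::head(object$scores[order(-abs(object$scores$score)), ], top_n)
  s$feature <- stats::reorder(s$feature, abs(s$score))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("Feature importance (%s)", object$method),
      x = if (object$method == "mdi") "normalized MDI" else "Shapley value",
      y = NULL
    )
}

#' Plot per-class confidence distributions
#'
#' @param object A `confidence_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confidence_report <- function(object, ...) {
  d <- object$scores
  d$class <- ifelse(d$truth == 1, "pd", "healthy")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_pd, fill = .data$class)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 20, alpha = 0.5, position = "identity", boundary = 0
    ) +
    ggplot2::labs(
      title = sprintf("Confidence distribution (overlap %.3f)", object$overlap),
      x = "predicted PD probability", y = "density", fill = "true class"
    )
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$folds,
    cols = c("accuracy", "precision", "recall", "specificity", "f1", "auc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold))) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(
      title = sprintf("%d-fold subject-wise cross-validation", object$k),
      x = NULL, y = "metric value", colour = "fold"
    )
}
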