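#' Plot per-fold accuracies of an evaluation report
#'
#' One bar per held-out domain with the mean accuracy as a dashed line.
#'
#' @param object A `brada_eval` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brada_eval
#' @export
autoplot.brada_eval <- function(object, ...) {
  df <- object$per_fold
  df$domain <- paste(df$database_id, df$subject_id, sep = "/")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$domain, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "held-out domain", y = "accuracy",
      title = sprintf("%s | %s | mean %.3f", object$protocol,
                      object$config$method, object$mean_accuracy)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot a subspace-dimension search curve
#'
#' @param object A `brada_h_search` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brada_h_search
#' @export
autoplot.brada_h_search <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$h, y = .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_h, linetype = "dotted") +
    ggplot2::labs(x = "subspace dimension h", y = "mean LOSO accuracy",
                  title = sprintf("best h = %d", object$best_h)) +
    ggplot2::theme_minimal()
}

#' 2-D PCA view of feature samples
#'
#' Convenience hook for eyeballing inter-subject spread before and after
#' adaptation: projects rows onto their first two principal components,
#' colored by subject (or any metadata column).
#'
#' @param x A [feature_table] or a `brada_embedding`.
#' @param color_by Metadata column to color points by (default
#'   `"subject_id"`).
#' @return A ggplot object.
#' @export
plot_feature_pca <- function(x, color_by = "subject_id") {
  if (inherits(x, "feature_table")) {
    values <- x$values
    meta <- x$sample_meta
  } else if (inherits(x, "brada_embedding")) {
    values <- x$Z
    meta <- x$sample_meta
  } else {
    stop("Expected a feature_table or brada_embedding.", call. = FALSE)
  }
  pc <- stats::prcomp(values, rank. = 2)
  df <- tibble::tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                       group = as.factor(meta[[color_by]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   color = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(color = color_by) +
    ggplot2::theme_minimal()
}
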