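#' Plot per-iteration cross-validation AUCs
#'
#' A boxplot of the repeated-CV AUC distribution with the mean and the
#' percentile interval marked.
#'
#' @param object A `tsp_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tsp_cv <- function(object, ...) {
  dat <- tidy(object)
  value <- if (object$auc_mode == "pooled") dat$auc_pooled else dat$auc_per_fold
  df <- tibble::tibble(model = object$spec$id %||% "model", auc = value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 1) +
    ggplot2::annotate("pointrange", x = 1.35, y = object$mean_auc,
                      ymin = object$ci95[["lower"]],
                      ymax = object$ci95[["upper"]], colour = "firebrick") +
    ggplot2::labs(y = "cross-validated AUC", x = NULL,
                  title = sprintf("%d x %d-fold CV", object$n_iter, object$k)) +
    ggplot2::theme_minimal()
}

#' Compare cross-validated models across a specification grid
#'
#' Mean AUC with percentile intervals per model, in the style of a
#' model-grid comparison figure.
#'
#' @param grid Result of [run_cv_grid()].
#' @return A ggplot object.
#' @export
plot_cv_grid <- function(grid) {
  stopifnot(is.data.frame(grid), all(c("model_id", "mean_auc") %in% names(grid)))
  df <- dplyr::mutate(grid,
                      model_id = factor(.data$model_id,
                                        levels = grid$model_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_id, y = .data$mean_auc)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "model", y = "mean cross-validated AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot of one gene pair's reversal
#'
#' Expression of gene `v` against gene `u`, coloured by class, with the
#' identity line that the pair indicator thresholds on. A reversal pair
#' shows the two classes on opposite sides of the line.
#'
#' @param expression Expression data.
#' @param labels 0/1 outcome vector.
#' @param gene_u,gene_v Gene identifiers.
#' @return A ggplot object.
#' @export
plot_pair <- function(expression, labels, gene_u, gene_v) {
  x <- as_expr_matrix(expression)
  labels <- check_labels(labels, ncol(x))
  df <- tibble::tibble(
    x_u = x[resolve_gene(x, gene_u), ],
    x_v = x[resolve_gene(x, gene_v), ],
    class = factor(labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_u, y = .data$x_v,
                                   colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = gene_u, y = gene_v) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted logistic model
#'
#' @param object A `tsp_logit` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tsp_logit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "coefficient (log-odds)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
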