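#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_line labs theme_minimal position_dodge geom_step
NULL

#' @export
ggplot2::autoplot

#' SAM quantile plot
#'
#' Observed d statistics against the permutation expected order statistics;
#' the dashed band at `+/- delta` shows the call region, called genes are
#' highlighted.
#'
#' @param object A `sam_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sam_fit <- function(object, ...) {
  tab <- dplyr::arrange(object$table, .data$d)
  ggplot(tab, aes(x = .data$dbar, y = .data$d, colour = .data$called)) +
    geom_point(size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_abline(slope = 1, intercept = c(-1, 1) * object$delta,
                linetype = 3) +
    labs(x = "expected order statistic", y = "observed d",
         colour = "called") +
    theme_minimal()
}

#' Hub degree plot of a co-expression network
#'
#' Top genes by number of gene-gene links.
#'
#' @param object A `coexpr_network`.
#' @param top Number of genes shown (default 20).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.coexpr_network <- function(object, top = 20, ...) {
  hubs <- utils::head(hub_degrees(object), top)
  hubs$gene <- factor(hubs$gene, levels = rev(hubs$gene))
  ggplot(hubs, aes(x = .data$degree, y = .data$gene)) +
    geom_col() +
    labs(x = "gene-gene links", y = NULL) +
    theme_minimal()
}

#' Link-strength histogram plot
#'
#' Bar chart of gene-gene link counts per correlation-strength bin, dodged
#' by group when histograms from several groups are combined.
#'
#' @param histogram Tibble from [link_histogram()] (optionally row-bound over
#'   groups).
#' @return A ggplot.
#' @export
plot_link_histogram <- function(histogram) {
  histogram$bin <- sprintf("%.1f-%.1f", histogram$bin_lo, histogram$bin_hi)
  p <- ggplot(histogram,
              aes(x = .data$bin, y = .data$count,
                  fill = if ("group" %in% names(histogram)) .data$group else NULL))
  p + geom_col(position = position_dodge()) +
    labs(x = "link strength |rho|", y = "gene-gene links", fill = NULL) +
    theme_minimal()
}

#' Out-of-fold ROC curve of a cross-validated classifier
#'
#' @param object A `texture_cv` from a binary task.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.texture_cv <- function(object, ...) {
  if (!is.finite(object$auc)) stop("ROC available for binary tasks only",
                                   call. = FALSE)
  roc <- pROC::roc(response = object$oof$truth, predictor = object$oof$prob,
                   levels = levels(object$oof$truth), direction = "<",
                   quiet = TRUE)
  df <- tibble::tibble(fpr = 1 - roc$specificities, tpr = roc$sensitivities)
  df <- df[order(df$fpr, df$tpr), ]
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("out-of-fold ROC (AUC %.3f)", object$auc)) +
    theme_minimal()
}

#' Standard-curve plot
#'
#' @param object A `standard_curve`.
#' @param quantity,ct The points the curve was fitted to (optional).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.standard_curve <- function(object, quantity = NULL, ct = NULL, ...) {
  p <- ggplot() +
    geom_abline(slope = object$slope, intercept = object$intercept) +
    labs(x = "log10 quantity", y = "Ct",
         title = sprintf("efficiency %.3f, R^2 %.4f",
                         object$efficiency, object$r_squared)) +
    theme_minimal()
  if (!is.null(quantity)) {
    p <- p + geom_point(data = tibble::tibble(x = log10(quantity), y = ct),
                        aes(x = .data$x, y = .data$y))
  }
  p
}
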