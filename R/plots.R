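# Diagnostic plots for the selection cascade and the fitted model.
# All functions return ggplot objects; run_all() writes them to PDF.

#' Spearman correlation heatmap of training features
#'
#' @param train standardized training feature table (typically restricted
#'   to the univariate survivors).
#' @return a ggplot object.
#' @export
plot_correlation_heatmap <- function(train) {
  feats <- .feature_cols(train)
  rho <- cor(as.matrix(train[, feats, drop = FALSE]), method = "spearman")
  df <- data.frame(
    f1 = factor(rep(feats, times = length(feats)), levels = feats),
    f2 = factor(rep(feats, each = length(feats)), levels = feats),
    rho = as.vector(rho)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$f1, .data$f2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' Cross-validated deviance against the LASSO penalty
#'
#' @param trace the `trace` element of [run_selection()] output.
#' @return a ggplot object.
#' @export
plot_cv_error <- function(trace) {
  cv <- trace$lasso_cv
  ggplot2::ggplot(cv, ggplot2::aes(log(.data$lambda), .data$cvm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cvm - .data$cvsd,
                                      ymax = .data$cvm + .data$cvsd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(trace$lasso_lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "binomial deviance (10-fold CV)") +
    ggplot2::theme_minimal()
}

#' LASSO coefficient paths
#'
#' @param trace the `trace` element of [run_selection()] output.
#' @return a ggplot object.
#' @export
plot_coefficient_paths <- function(trace) {
  path <- trace$lasso_path
  cv <- trace$lasso_cv
  df <- data.frame(
    feature = rep(rownames(path), times = ncol(path)),
    lambda = rep(cv$lambda[seq_len(ncol(path))], each = nrow(path)),
    beta = as.vector(path)
  )
  ggplot2::ggplot(df, ggplot2::aes(log(.data$lambda), .data$beta,
                                   group = .data$feature)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = log(trace$lasso_lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' ROC curves of one or more evaluation reports
#'
#' @param reports named list of `eval_report` objects (e.g. training and
#'   testing partitions).
#' @return a ggplot object.
#' @export
plot_roc <- function(reports) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(partition = sprintf("%s (AUC %.3f)", nm, r$metrics[["auc"]]),
               fpr = r$roc$fpr, tpr = r$roc$tpr)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Radiomics-score waterfall plot
#'
#' Per-subject scores of a partition, sorted, coloured by true label; bars
#' on the wrong side of the zero line are misclassifications at the 0.5
#' probability threshold.
#'
#' @param report an `eval_report`.
#' @return a ggplot object.
#' @export
plot_score_waterfall <- function(report) {
  sc <- report$scores[order(report$scores$score), ]
  sc$rank <- seq_len(nrow(sc))
  sc$group <- factor(ifelse(sc$label == 1, "case", "control"))
  ggplot2::ggplot(sc, ggplot2::aes(.data$rank, .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "subject (sorted)", y = "radiomics score",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
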