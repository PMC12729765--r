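# Plotting utilities for cross-validation results: ROC curve, decision
# curve, and the per-class score distribution. ggplot2 is suggested rather
# than imported; each function errors with a clear message when it is
# missing.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' ROC curve of pooled out-of-fold scores
#'
#' The dashed diagonal is the chance baseline (AUC = 0.5).
#'
#' @param cv A `ceus_cv_result` from [cross_validate()].
#' @return A ggplot object.
#' @export
plot_roc <- function(cv) {
  need_ggplot()
  r <- roc_auc(cv$scores$label, cv$scores$score)
  curve <- r$curve[order(r$curve$fpr, r$curve$tpr), ]
  ggplot2::ggplot(curve, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (pooled out-of-fold), AUC = %.3f", r$auc)) +
    ggplot2::theme_minimal()
}

#' Decision-curve plot with treat-all / treat-none references
#'
#' @param dc A `net_benefit_curve` from [decision_curve()].
#' @return A ggplot object.
#' @export
plot_decision_curve <- function(dc) {
  need_ggplot()
  ggplot2::ggplot(dc, ggplot2::aes(x = threshold)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = treat_all), linetype = "dotdash",
                       colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = net_benefit), colour = "#b2182b",
                       linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(-0.1, max(dc$net_benefit, 0.05) + 0.05)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit") +
    ggplot2::theme_minimal()
}

#' Box plot of out-of-fold scores by true class
#'
#' @param cv A `ceus_cv_result`.
#' @param test Annotate with a Mann-Whitney p-value comparing the two
#'   classes' scores.
#' @return A ggplot object.
#' @export
plot_score_box <- function(cv, test = TRUE) {
  need_ggplot()
  df <- cv$scores
  df$class <- factor(df$label, levels = c(0, 1),
                     labels = c("non-metastatic", "metastatic"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = class, y = score)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "Predicted probability of metastasis") +
    ggplot2::theme_minimal()
  if (test && length(unique(df$label)) == 2) {
    w <- stats::wilcox.test(score ~ label, data = df, exact = FALSE)
    p <- p + ggplot2::ggtitle(sprintf("Mann-Whitney p = %.2g", w$p.value))
  }
  p
}
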