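#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_abline labs theme_minimal facet_wrap coord_equal
#' @export
ggplot2::autoplot

#' Plot a ROC or precision-recall curve
#'
#' @param object an `ispip_curve` from [roc_pr_curves()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ispip_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    theme_minimal()
  if (kind == "ROC") {
    p <- p + geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
      labs(x = "False positive rate", y = "True positive rate",
           title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc")))
  } else {
    p <- p + labs(x = "Recall", y = "Precision",
                  title = sprintf("PR curve (AUC = %.3f)", attr(object, "auc")))
  }
  p + coord_equal(xlim = c(0, 1), ylim = c(0, 1))
}

#' Plot an evaluation: pooled curves plus per-protein metric spread
#'
#' @param object an `ispip_evaluation`.
#' @param ... unused.
#' @return a ggplot object (per-protein F and MCC distributions).
#' @export
autoplot.ispip_evaluation <- function(object, ...) {
  df <- object$per_protein |>
    tidyr::pivot_longer(c("f_score", "mcc"), names_to = "metric",
                        values_to = "value")
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "#a6bddb") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    theme_minimal() +
    labs(x = NULL, y = "Per-protein value",
         title = sprintf("Single-threshold metrics (%s)", object$score_col))
}

#' Compare pooled curves of several predictors
#'
#' @param table labelled score tibble.
#' @param score_cols prediction columns to overlay.
#' @param kind `"PR"` or `"ROC"`.
#' @return a ggplot object with one curve per predictor, AUC in the
#'   legend.
#' @export
plot_curve_comparison <- function(table, score_cols, kind = c("PR", "ROC")) {
  kind <- match.arg(kind)
  dfs <- purrr::map(score_cols, function(col) {
    cv <- roc_pr_curves(table[[col]], table$label)
    curve <- if (kind == "ROC") cv$roc else cv$pr
    as_tibble(curve) |>
      mutate(predictor = sprintf("%s (AUC %.3f)", col, attr(curve, "auc")))
  }) |> purrr::list_rbind()
  p <- ggplot(dfs, aes(x = .data$x, y = .data$y,
                       colour = .data$predictor)) +
    geom_line(linewidth = 0.7) +
    theme_minimal() +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1))
  if (kind == "ROC") {
    p + geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                    colour = "grey60") +
      labs(x = "False positive rate", y = "True positive rate")
  } else {
    p + labs(x = "Recall", y = "Precision")
  }
}
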