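#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ROC and precision-recall curves of an evaluation
#'
#' @param object An `fm_eval` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot object (ROC and PR curves, faceted).
#' @method autoplot fm_eval
#' @export
autoplot.fm_eval <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(x = object$roc$fpr, y = object$roc$tpr,
           panel = sprintf("ROC (AUC = %.3f)", object$auc_roc)),
    tibble(x = object$pr$recall, y = object$pr$precision,
           panel = sprintf("Precision-recall (AP = %.3f)",
                           object$average_precision))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot forest feature importances
#'
#' @param object An `fm_model`.
#' @param ... Unused.
#' @return A ggplot bar chart of MDI importance per dinucleotide.
#' @method autoplot fm_model
#' @export
autoplot.fm_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$dinucleotide, .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "dinucleotide", y = "MDI importance") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of rho values by dinucleotide
#'
#' Violin/box view of the per-island fragmentation odds ratios; a
#' horizontal line marks the uniform expectation rho = 1.
#'
#' @param rho Rho tibble from [compute_rho()].
#' @param drop_zero Drop the rho = 0 convention values (absent
#'   dinucleotide or no events) before plotting (default TRUE).
#' @return A ggplot object.
#' @export
plot_rho_profile <- function(rho, drop_zero = TRUE) {
  long <- tidyr::pivot_longer(
    dplyr::select(rho, "island_id", dplyr::all_of(rho_cols())),
    cols = dplyr::all_of(rho_cols()),
    names_to = "dinucleotide", values_to = "rho"
  )
  long$dinucleotide <- sub("^rho_", "", long$dinucleotide)
  if (drop_zero) long <- dplyr::filter(long, .data$rho > 0)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dinucleotide, y = .data$rho)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "dinucleotide", y = expression(rho)) +
    ggplot2::theme_minimal()
}
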