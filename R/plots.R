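#' Plot per-cell agreement between truth and prediction
#'
#' Violin-and-point view of the per-cell Pearson `r` and zero-filtered
#' Spearman `rho*` distributions from a [evaluate_counts()] result.
#'
#' @param object A `quant_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.quant_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_cell, c("r", "rho_star"),
                            names_to = "metric", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_jitter(width = 0.08, size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "per-cell correlation",
                  title = sprintf("RMSE %.4f | FPR %.5f | FNR %.5f",
                                  object$rmse, object$fpr, object$fnr)) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Knee plot of barcode totals
#'
#' Barcodes ranked by total UMI count on log-log axes; the standard view
#' for choosing a cell-count cutoff.
#'
#' @param mat Barcode-by-gene count matrix.
#' @param n_top Optionally mark the top-N cutoff.
#' @return A ggplot object.
#' @export
plot_knee <- function(mat, n_top = NULL) {
  totals <- sort(Matrix::rowSums(mat), decreasing = TRUE)
  df <- tibble::tibble(rank = seq_along(totals), total = totals)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$total)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "total UMI count") +
    ggplot2::theme_minimal()
  if (!is.null(n_top) && n_top <= nrow(df)) {
    p <- p + ggplot2::geom_vline(xintercept = n_top, linetype = "dashed")
  }
  p
}

#' Plot DFK counts across overhang settings
#'
#' Companion to the overhang-monotonicity property: the DFK set can only
#' grow as the overhang increases.
#'
#' @param cdbg Target `cdbg`.
#' @param dlist D-list sequences.
#' @param overhangs Integer vector of overhang settings to profile.
#' @return A ggplot object.
#' @export
plot_dfk_overhang <- function(cdbg, dlist, overhangs = 1:3) {
  counts <- vapply(overhangs, function(h)
    extract_dfks(dlist, cdbg, overhang = h)$report$dfk_count, numeric(1))
  df <- tibble::tibble(overhang = overhangs, dfks = counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overhang, y = .data$dfks)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "D-list overhang", y = "distinct DFKs") +
    ggplot2::theme_minimal()
}
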