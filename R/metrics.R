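#' Evaluate a program count matrix against a truth matrix
#'
#' Compares a program output matrix to a ground-truth matrix over the same
#' barcodes and genes (aligned by label; differing label sets are an
#' error). Reported quantities:
#'
#' * `rmse`: `sqrt(mean((y - yhat)^2))` over all n x m entries.
#' * `fpr`: fraction of all entries with truth 0 but prediction > 0
#'   ("false positive representation"; the denominator is the full matrix
#'   size, not the negative count).
#' * `fnr`: fraction of all entries with truth > 0 but prediction 0.
#' * `r`: per-cell Pearson correlation over all genes.
#' * `rho_star`: per-cell Spearman correlation (average ranks) computed
#'   after dropping gene pairs that are `(0, 0)` in both matrices. Setting
#'   `rho_pairs = "both_nonzero"` instead keeps only genes nonzero in both
#'   matrices -- a stricter reading; the default follows the displayed
#'   definition of excluding exact `(0, 0)` pairs.
#'
#' Cells where a correlation is undefined (fewer than two usable pairs, or
#' a constant vector) are excluded from the medians and counted in
#' `n_undefined_r` / `n_undefined_rho`.
#'
#' @param truth,pred Barcode-by-gene matrices with dimnames (dense or
#'   sparse).
#' @param rho_pairs Pair-filtering rule for `rho_star` (see above).
#' @return Object of class `quant_metrics`.
#' @export
evaluate_counts <- function(truth, pred,
                            rho_pairs = c("drop_double_zero",
                                          "both_nonzero")) {
  rho_pairs <- match.arg(rho_pairs)
  if (is.null(dimnames(truth)) || is.null(dimnames(pred))) {
    stop("matrices must carry barcode and gene dimnames")
  }
  if (!setequal(rownames(truth), rownames(pred)) ||
      !setequal(colnames(truth), colnames(pred))) {
    stop("barcode or gene label sets differ between truth and prediction")
  }
  pred <- pred[rownames(truth), colnames(truth), drop = FALSE]
  y <- as.matrix(truth)
  yhat <- as.matrix(pred)
  n <- nrow(y)
  m <- ncol(y)

  rmse <- sqrt(mean((y - yhat)^2))
  fpr <- mean(y == 0 & yhat > 0)
  fnr <- mean(y > 0 & yhat == 0)

  per_cell <- tibble::tibble(
    barcode = rownames(y),
    r = vapply(seq_len(n), function(i) {
      suppressWarnings(stats::cor(y[i, ], yhat[i, ]))
    }, numeric(1)),
    rho_star = vapply(seq_len(n), function(i) {
      keep <- if (rho_pairs == "drop_double_zero") {
        !(y[i, ] == 0 & yhat[i, ] == 0)
      } else {
        y[i, ] > 0 & yhat[i, ] > 0
      }
      if (sum(keep) < 2) return(NA_real_)
      suppressWarnings(stats::cor(y[i, keep], yhat[i, keep],
                                  method = "spearman"))
    }, numeric(1))
  )
  structure(
    list(
      rmse = rmse, fpr = fpr, fnr = fnr,
      median_r = stats::median(per_cell$r, na.rm = TRUE),
      median_rho_star = stats::median(per_cell$rho_star, na.rm = TRUE),
      per_cell = per_cell,
      n_undefined_r = sum(is.na(per_cell$r)),
      n_undefined_rho = sum(is.na(per_cell$rho_star)),
      n = n, m = m, rho_pairs = rho_pairs
    ),
    class = "quant_metrics"
  )
}

#' @export
print.quant_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "quant_metrics over %d cells x %d genes\n",
    "  RMSE      %.5f\n  FPR       %.5f\n  FNR       %.5f\n",
    "  median r  %.4f   median rho* %.4f\n"),
    x$n, x$m, x$rmse, x$fpr, x$fnr, x$median_r, x$median_rho_star))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cell metric values
#' @param x A `quant_metrics` object.
#' @param ... Unused.
#' @return Tibble `barcode`, `r`, `rho_star`.
#' @export
tidy.quant_metrics <- function(x, ...) x$per_cell

#' One-row metric summary
#' @param x A `quant_metrics` object.
#' @param ... Unused.
#' @return One-row tibble with `rmse`, `fpr`, `fnr`, `median_r`,
#'   `median_rho_star`, `n_cells`, `n_genes`.
#' @export
glance.quant_metrics <- function(x, ...) {
  tibble::tibble(
    rmse = x$rmse, fpr = x$fpr, fnr = x$fnr,
    median_r = x$median_r, median_rho_star = x$median_rho_star,
    n_cells = x$n, n_genes = x$m
  )
}

#' Select the top barcodes by total count
#'
#' The `n_top` barcodes with the highest total UMI counts; ties at the
#' cutoff are broken lexicographically by barcode so the selection is
#' deterministic.
#'
#' @param mat Barcode-by-gene matrix with rownames.
#' @param n_top Number of barcodes to keep.
#' @return Character vector of selected barcodes.
#' @export
top_barcodes <- function(mat, n_top) {
  stopifnot(n_top >= 1)
  totals <- Matrix::rowSums(mat)
  if (n_top > length(totals)) {
    warning("n_top exceeds the number of barcodes; returning all")
    n_top <- length(totals)
  }
  ord <- order(-totals, rownames(mat))
  rownames(mat)[ord[seq_len(n_top)]]
}

#' Conform a matrix to given row/column universes
#'
#' Pads missing barcodes/genes with zero rows/columns and reorders, so two
#' matrices can be compared by label.
#'
#' @param mat Sparse or dense matrix with dimnames.
#' @param barcodes,genes Target label vectors.
#' @return Sparse matrix of dim `length(barcodes)` x `length(genes)`.
#' @export
conform_matrix <- function(mat, barcodes, genes) {
  t_mat <- methods::as(methods::as(mat, "generalMatrix"), "TsparseMatrix")
  ri <- match(rownames(mat)[t_mat@i + 1L], barcodes)
  ci <- match(colnames(mat)[t_mat@j + 1L], genes)
  keep <- !is.na(ri) & !is.na(ci)
  Matrix::sparseMatrix(
    i = ri[keep], j = ci[keep], x = t_mat@x[keep],
    dims = c(length(barcodes), length(genes)),
    dimnames = list(barcodes, genes)
  )
}
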