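#' Pearson correlation profile of a test sample against training samples
#'
#' The similarity that drives personalized training-set selection: the
#' Pearson correlation between the test sample's full gene-expression vector
#' and each training sample's, computed over all genes of the shared feature
#' space (no gene pre-filtering).
#'
#' @param test_vector Numeric vector of length `n_genes`.
#' @param train_matrix Numeric matrix, `n_train` x `n_genes`.
#' @return Numeric vector of length `n_train`, each entry in `[-1, 1]`.
#' @export
pearson_profile <- function(test_vector, train_matrix) {
  test_vector <- as.numeric(test_vector)
  if (!is.matrix(train_matrix)) train_matrix <- rbind(train_matrix)
  if (length(test_vector) != ncol(train_matrix)) {
    abort("`test_vector` length must equal the number of training genes.")
  }
  if (length(test_vector) < 2) abort("At least two genes are required for a correlation.")
  if (sd(test_vector) == 0) abort("Test sample has a constant expression profile; PCC is undefined.")
  row_sds <- apply(train_matrix, 1, sd)
  if (any(row_sds == 0)) {
    offender <- which(row_sds == 0)[1]
    nm <- rownames(train_matrix)[offender] %||% as.character(offender)
    abort(sprintf("Training sample '%s' has a constant expression profile; PCC is undefined.", nm))
  }
  as.numeric(cor(test_vector, t(train_matrix)))
}

#' Select the personalized training subset by correlation threshold
#'
#' Applies the strict-inequality selection rule: in `signed` mode (the
#' default) a training sample is kept when `|PCC| > threshold`, so both
#' strongly positively and strongly negatively correlated patients enter the
#' personalized training set; in `positive_only` mode (the ablation) only
#' `PCC > threshold` samples are kept. Samples exactly at the threshold are
#' excluded. Training order is preserved; an empty selection is returned as
#' such — the classifier layer owns the fallback.
#'
#' @param pcc Numeric vector of correlations, one per training sample.
#' @param threshold Correlation threshold in (0, 1).
#' @param mode `"signed"` or `"positive_only"`.
#' @return A `selection_result`: list with `selected_indices`, `pcc_values`
#'   (of the selected samples), `n_positive`, `n_negative`, `threshold`,
#'   `mode`.
#' @export
#' @examples
#' select_training_subset(c(0.3, -0.2, 0.05), 0.15)
select_training_subset <- function(pcc, threshold, mode = c("signed", "positive_only")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single value in (0, 1).")
  }
  keep <- if (mode == "signed") abs(pcc) > threshold else pcc > threshold
  idx <- which(keep)
  structure(list(
    selected_indices = idx,
    pcc_values = pcc[idx],
    n_positive = sum(pcc[idx] > 0),
    n_negative = sum(pcc[idx] < 0),
    threshold = threshold,
    mode = mode
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d selected (|PCC| > %g, %s): %d positive, %d negative\n",
              length(x$selected_indices), x$threshold, x$mode, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(index = x$selected_indices, pcc = x$pcc_values,
                 threshold = x$threshold, mode = x$mode)
}

#' Inclusive arithmetic grid of correlation thresholds
#'
#' The default grid, `threshold_grid(0.15, 0.275, 0.025)`, is the six-value
#' threshold set the PCMT ensemble averages over; it is built robustly to
#' floating-point drift so the stop value is always included when it lies on
#' the grid.
#'
#' @param start,stop Grid endpoints, `start <= stop`.
#' @param step Positive increment.
#' @return Numeric vector `start, start + step, ...` up to `stop`.
#' @export
#' @examples
#' threshold_grid(0.15, 0.275, 0.025)
threshold_grid <- function(start = 0.15, stop = 0.275, step = 0.025) {
  if (step <= 0) abort("`step` must be positive.")
  if (start > stop) abort("`start` must not exceed `stop`.")
  n <- floor((stop - start) / step + 1e-9)
  start + step * (0:n)
}

#' Per-test-sample selection summary table
#'
#' Convenience report of how many training samples each test sample selects
#' at each threshold (and the positive/negative split), the quantity behind
#' training-set-size and correlation-sign diagnostics.
#'
#' @param train A `pcmt_dataset` of training samples.
#' @param newdata Numeric matrix of test samples (rows) over the same genes.
#' @param thresholds Numeric vector of thresholds.
#' @param mode Selection mode, see [select_training_subset()].
#' @return A tibble with columns `sample_id`, `threshold`, `n_selected`,
#'   `n_positive`, `n_negative`.
#' @export
selection_summary <- function(train, newdata, thresholds = threshold_grid(),
                              mode = c("signed", "positive_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "pcmt_dataset"))
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  ids <- rownames(newdata) %||% paste0("test_", seq_len(nrow(newdata)))
  purrr::map_dfr(seq_len(nrow(newdata)), function(i) {
    pcc <- pearson_profile(newdata[i, ], train$expr)
    purrr::map_dfr(thresholds, function(t) {
      sel <- select_training_subset(pcc, t, mode)
      tibble::tibble(sample_id = ids[i], threshold = t,
                     n_selected = length(sel$selected_indices),
                     n_positive = sel$n_positive, n_negative = sel$n_negative)
    })
  })
}
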