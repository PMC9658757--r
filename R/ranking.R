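# Leave-one-out coefficient matrix: row i holds the coefficient vector of
# the model that predicted sample i. `fit_fun(train, test_vector)` must
# return a numeric coefficient vector (zeros for fallback fits).
loocv_coefficients <- function(d, fit_fun) {
  n <- n_samples(d)
  out <- matrix(0, n, n_genes(d), dimnames = list(sample_ids(d), gene_ids(d)))
  for (i in seq_len(n)) {
    train <- filter_dataset(d, samples = -i)
    out[i, ] <- fit_fun(train, d$expr[i, ])
  }
  out
}

pc_coef_fun <- function(threshold, mode, inverse_regularization) {
  function(train, test_vector) {
    pcc <- pearson_profile(test_vector, train$expr)
    sel <- select_training_subset(pcc, threshold, mode)
    idx <- sel$selected_indices
    labels <- train$samples$label[idx]
    if (length(idx) < 2 || length(unique(labels)) < 2) return(numeric(n_genes(train)))
    tryCatch(
      fit_l1_logistic(train$expr[idx, , drop = FALSE], labels,
                      inverse_regularization)$coefficients,
      error = function(e) numeric(n_genes(train)))
  }
}

rank_tibble <- function(scores, top_k, subtype) {
  ord <- order(-scores, names(scores))
  k <- min(top_k, length(scores))
  tibble::tibble(subtype = subtype, rank = seq_len(k),
                 gene_id = names(scores)[ord[seq_len(k)]],
                 score = unname(scores[ord[seq_len(k)]]))
}

#' Per-subtype gene ranking from personalized-classifier coefficients
#'
#' Runs whole-cohort leave-one-out prediction with a single-threshold
#' personalized classifier (default threshold 0.2), collects every sample's
#' fitted coefficient vector, pools the coefficients of each subtype's
#' members, and ranks genes by mean absolute coefficient within the subtype
#' (ties broken by gene id; genes whose coefficients are identically zero
#' never outrank a nonzero-scored gene). The conventional report takes the
#' top 20 genes for each of five intrinsic subtypes.
#'
#' @param d A subtype-annotated `pcmt_dataset`.
#' @param threshold Correlation threshold for the personalized models
#'   (default 0.2).
#' @param top_k Number of genes to report per subtype (default 20).
#' @param mode,inverse_regularization Passed to the personalized fits.
#' @return A `pcmt_ranking`: tibble with columns `subtype`, `rank`,
#'   `gene_id`, `score`; the full per-subtype mean |coefficient| matrix is
#'   attached as attribute `score_matrix` (subtypes x genes) with member
#'   counts in attribute `subtype_n`.
#' @export
subtype_rankings <- function(d, threshold = 0.2, top_k = 20,
                             mode = "signed", inverse_regularization = 1) {
  stopifnot(inherits(d, "pcmt_dataset"))
  if (is.null(d$samples[["subtype"]])) abort("`d` has no subtype annotation.")
  if (top_k > n_genes(d)) abort("`top_k` exceeds the number of genes.")
  cf <- abs(loocv_coefficients(d, pc_coef_fun(threshold, mode, inverse_regularization)))
  subtypes <- sort(unique(d$samples[["subtype"]]))
  keep <- subtypes[vapply(subtypes, function(s) sum(d$samples[["subtype"]] == s) >= 2, logical(1))]
  if (length(keep) < length(subtypes)) {
    warn(sprintf("Subtype(s) with < 2 members excluded: %s",
                 paste(setdiff(subtypes, keep), collapse = ", ")))
  }
  score_matrix <- t(vapply(keep, function(s)
    colMeans(cf[d$samples[["subtype"]] == s, , drop = FALSE]), numeric(n_genes(d))))
  rownames(score_matrix) <- keep
  res <- purrr::map_dfr(keep, function(s) rank_tibble(score_matrix[s, ], top_k, s))
  structure(res,
            class = c("pcmt_ranking", class(res)),
            score_matrix = score_matrix,
            subtype_n = vapply(keep, function(s) sum(d$samples[["subtype"]] == s), numeric(1)),
            threshold = threshold)
}

#' Pooled-model gene ranking
#'
#' The comparator ranking: genes ordered by the mean absolute coefficient of
#' the pooled L1-logistic model over leave-one-out refits (or, optionally, a
#' single full-cohort fit).
#'
#' @param d A `pcmt_dataset`.
#' @param top_k Number of genes to report (default 20).
#' @param method `"loocv"` (average over leave-one-out refits, default) or
#'   `"single_fit"`.
#' @param inverse_regularization Passed to [fit_l1_logistic()].
#' @return A `pcmt_ranking` tibble (`subtype == "all"`), with attribute
#'   `scores` holding the full mean |coefficient| vector.
#' @export
pooled_ranking <- function(d, top_k = 20, method = c("loocv", "single_fit"),
                           inverse_regularization = 1) {
  method <- match.arg(method)
  stopifnot(inherits(d, "pcmt_dataset"))
  if (top_k > n_genes(d)) abort("`top_k` exceeds the number of genes.")
  if (method == "loocv") {
    cf <- abs(loocv_coefficients(d, function(train, test_vector)
      fit_l1_logistic(train$expr, train$samples$label, inverse_regularization)$coefficients))
    scores <- colMeans(cf)
  } else {
    scores <- abs(fit_l1_logistic(d$expr, d$samples$label,
                                  inverse_regularization)$coefficients)
  }
  names(scores) <- gene_ids(d)
  res <- rank_tibble(scores, top_k, "all")
  structure(res, class = c("pcmt_ranking", class(res)), scores = scores)
}
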