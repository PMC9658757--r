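# Fit an L1-logistic model on the training subset `idx` and predict the test
# vector. Degenerate subsets (empty, single-class, or a failed solver call on
# a pathologically small subset) fall back to the full training cohort's
# poor-class prevalence; the fallback is flagged in the return value.
fit_pc_subset <- function(train, idx, prevalence, inverse_regularization, test_vector) {
  labels <- train$samples$label[idx]
  if (length(idx) < 2 || length(unique(labels)) < 2) {
    return(list(prob = prevalence, fallback = TRUE, n_selected = length(idx)))
  }
  prob <- tryCatch({
    fit <- fit_l1_logistic(train$expr[idx, , drop = FALSE], labels,
                           inverse_regularization)
    predict(fit, test_vector)
  }, error = function(e) NA_real_)
  if (is.na(prob)) {
    return(list(prob = prevalence, fallback = TRUE, n_selected = length(idx)))
  }
  list(prob = prob, fallback = FALSE, n_selected = length(idx))
}

#' Personalized classifier for one test sample
#'
#' Implements the single-threshold personalized classifier: compute the
#' Pearson correlation between the test sample and every training sample,
#' keep the training samples whose correlation passes the threshold
#' (absolute value in `signed` mode), train an L1-logistic model on that
#' subset only, and return its predicted probability of the poor class for
#' the test sample. When the selected subset is empty or contains a single
#' outcome class, the prediction falls back to the poor-class prevalence of
#' the full training cohort (flagged via the `"fallback"` attribute).
#'
#' @param train A `pcmt_dataset` of training samples.
#' @param test_vector Numeric expression vector over the training genes.
#' @param threshold Correlation threshold in (0, 1).
#' @param mode `"signed"` (default) or `"positive_only"`.
#' @param inverse_regularization Passed to [fit_l1_logistic()].
#' @return Probability of the poor class, with attributes `fallback`
#'   (logical) and `n_selected`.
#' @export
personalized_classifier <- function(train, test_vector, threshold,
                                    mode = c("signed", "positive_only"),
                                    inverse_regularization = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "pcmt_dataset"))
  pcc <- pearson_profile(test_vector, train$expr)
  sel <- select_training_subset(pcc, threshold, mode)
  res <- fit_pc_subset(train, sel$selected_indices,
                       mean(train$samples$label), inverse_regularization,
                       test_vector)
  structure(res$prob, fallback = res$fallback, n_selected = res$n_selected)
}

#' Multi-threshold personalized prediction for one test sample
#'
#' The PCMT ensemble: one personalized classifier per correlation threshold,
#' with the final prediction the unweighted arithmetic mean of the
#' per-threshold probabilities. The correlation profile is computed once and
#' shared across thresholds.
#'
#' @inheritParams personalized_classifier
#' @param thresholds Non-empty numeric vector of thresholds; default the
#'   six-value grid [threshold_grid()].
#' @param sample_id Identifier recorded in the result.
#' @return A `prediction_record`: list with `sample_id`,
#'   `per_threshold_probs` (named by threshold), `pcmt_prob`,
#'   `per_threshold_n_selected`, `per_threshold_fallback`.
#' @export
pcmt_predict <- function(train, test_vector, thresholds = threshold_grid(),
                         mode = c("signed", "positive_only"),
                         inverse_regularization = 1, sample_id = "test") {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "pcmt_dataset"))
  if (!length(thresholds)) abort("`thresholds` must be non-empty.")
  pcc <- pearson_profile(test_vector, train$expr)
  prevalence <- mean(train$samples$label)
  per <- lapply(thresholds, function(t) {
    sel <- select_training_subset(pcc, t, mode)
    fit_pc_subset(train, sel$selected_indices, prevalence,
                  inverse_regularization, test_vector)
  })
  probs <- vapply(per, `[[`, numeric(1), "prob")
  names(probs) <- format(thresholds)
  n_sel <- vapply(per, `[[`, numeric(1), "n_selected")
  names(n_sel) <- names(probs)
  fb <- vapply(per, `[[`, logical(1), "fallback")
  names(fb) <- names(probs)
  structure(list(sample_id = sample_id,
                 per_threshold_probs = probs,
                 pcmt_prob = mean(probs),
                 per_threshold_n_selected = n_sel,
                 per_threshold_fallback = fb),
            class = "prediction_record")
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("<prediction_record> %s: PCMT prob = %.3f over %d thresholds\n",
              x$sample_id, x$pcmt_prob, length(x$per_threshold_probs)))
  invisible(x)
}

#' @export
tidy.prediction_record <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id,
                 threshold = as.numeric(names(x$per_threshold_probs)),
                 prob = unname(x$per_threshold_probs),
                 n_selected = unname(x$per_threshold_n_selected),
                 fallback = unname(x$per_threshold_fallback),
                 pcmt_prob = x$pcmt_prob)
}

#' Predict a table of test samples with PCMT
#'
#' Vectorized convenience wrapper around [pcmt_predict()] returning one row
#' per test sample by threshold, plus the ensemble average.
#'
#' @inheritParams pcmt_predict
#' @param newdata Numeric matrix of test samples over the training genes.
#' @return A tibble (see [tidy.prediction_record()]) over all test samples.
#' @export
predict_cohort <- function(train, newdata, thresholds = threshold_grid(),
                           mode = c("signed", "positive_only"),
                           inverse_regularization = 1) {
  mode <- match.arg(mode)
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  ids <- rownames(newdata) %||% paste0("test_", seq_len(nrow(newdata)))
  purrr::map_dfr(seq_len(nrow(newdata)), function(i) {
    tidy(pcmt_predict(train, newdata[i, ], thresholds, mode,
                      inverse_regularization, sample_id = ids[i]))
  })
}
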