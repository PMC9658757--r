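#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney statistic: the probability that a randomly
#' chosen positive (poor-outcome) sample receives a higher score than a
#' randomly chosen negative one, with ties counting one half. Implemented
#' with midranks, which is exactly equivalent to pair counting.
#'
#' @param labels Binary 0/1 vector, both classes present.
#' @param scores Numeric score vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) abort("`labels` and `scores` must have equal length.")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present to compute an AUC.")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired t-test between two aligned score vectors
#'
#' Two-sided paired t-test used to compare models across folds or held-out
#' studies (element i of both vectors must come from the same fold/study).
#' A zero-variance difference vector is degenerate: the p-value is 1 when
#' the mean difference is 0 and `NA` (with `degenerate = TRUE`) otherwise.
#'
#' @param scores_a,scores_b Numeric vectors of equal length >= 2.
#' @return A one-row tibble: `mean_diff`, `statistic`, `p_value`,
#'   `degenerate`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2) {
    abort("`scores_a` and `scores_b` must have equal length >= 2.")
  }
  d <- scores_a - scores_b
  if (sd(d) < .Machine$double.eps^0.5) {
    return(tibble::tibble(mean_diff = mean(d), statistic = NA_real_,
                          p_value = if (abs(mean(d)) < .Machine$double.eps^0.5) 1 else NA_real_,
                          degenerate = TRUE))
  }
  tt <- t.test(scores_a, scores_b, paired = TRUE)
  tibble::tibble(mean_diff = unname(tt$estimate), statistic = unname(tt$statistic),
                 p_value = tt$p.value, degenerate = FALSE)
}

new_evaluation_report <- function(scheme, auc_scores, predictions, pairwise_p,
                                  seed = NA_integer_, log = character()) {
  structure(list(scheme = scheme, auc_scores = auc_scores,
                 predictions = predictions, pairwise_p = pairwise_p,
                 seed = seed, log = log),
            class = "pcmt_evaluation")
}

#' @export
print.pcmt_evaluation <- function(x, ...) {
  cat(sprintf("<pcmt_evaluation> scheme = %s\n", x$scheme))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.pcmt_evaluation <- function(x, ...) x$auc_scores

#' @export
glance.pcmt_evaluation <- function(x, ...) {
  x$auc_scores |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_auc = mean(.data$auc, na.rm = TRUE),
                     sd_auc = sd(.data$auc, na.rm = TRUE),
                     n_units = sum(!is.na(.data$auc)), .groups = "drop")
}

# Stratified fold assignment: deal each class's shuffled members round-robin
# over folds. Re-drawn (and logged) if any fold ends up single-class, which
# can only happen when a class has fewer members than folds.
make_stratified_folds <- function(labels, n_folds, max_tries = 100) {
  log <- character()
  for (try in seq_len(max_tries)) {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample(n_folds), length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(labels[fold == f])) == 2, logical(1)))
    if (ok) return(list(fold = fold, log = log))
    log <- c(log, sprintf("fold draw %d had a single-class fold; re-drawn", try))
  }
  abort("Could not build stratified folds with both classes in every fold.")
}

pairwise_tests <- function(auc_scores) {
  models <- unique(auc_scores$model)
  if (length(models) < 2) {
    return(tibble::tibble(model_a = character(), model_b = character(),
                          mean_diff = numeric(), statistic = numeric(),
                          p_value = numeric(), degenerate = logical()))
  }
  wide <- tidyr::pivot_wider(auc_scores, id_cols = "unit",
                             names_from = "model", values_from = "auc")
  pairs <- utils::combn(models, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    keep <- !is.na(wide[[p[1]]]) & !is.na(wide[[p[2]]])
    if (sum(keep) < 2) return(NULL)
    dplyr::bind_cols(tibble::tibble(model_a = p[1], model_b = p[2]),
                     paired_t_test(wide[[p[1]]][keep], wide[[p[2]]][keep]))
  })
}

eval_predictions <- function(train, test, models) {
  purrr::imap_dfr(models, function(spec, nm) {
    tibble::tibble(model = nm,
                   sample_id = sample_ids(test),
                   prob = predict_probs(spec, train, test$expr),
                   label = test$samples$label,
                   subtype = test$samples[["subtype"]] %||% NA_character_,
                   study = test$samples[["study"]] %||% NA_character_)
  })
}

#' Repeated stratified five-fold cross-validation
#'
#' Splits the cohort into `n_folds` class-stratified folds, `n_repeats`
#' times, and evaluates every model on identical fold assignments within a
#' repeat (so paired comparisons are valid). With the defaults of 5 folds
#' and 8 repeats each model receives exactly 40 AUC scores. Pairwise paired
#' t-tests over the per-fold AUCs are included in the report.
#'
#' @param d A `pcmt_dataset` (>= 10 samples, both classes).
#' @param models A (optionally named) list of model specifications, see
#'   [model_specs].
#' @param n_repeats Number of repeats (default 8).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment (and any stochastic
#'   model internals run downstream of it).
#' @return A `pcmt_evaluation` report: per-(model, repeat, fold) AUCs,
#'   retained per-sample predictions, and pairwise p-values.
#' @export
run_five_fold <- function(d, models, n_repeats = 8, n_folds = 5, seed = 1) {
  stopifnot(inherits(d, "pcmt_dataset"))
  if (n_samples(d) < 10) abort("Five-fold evaluation needs at least 10 samples.")
  models <- name_models(models)
  set.seed(seed)
  log <- character()
  out <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    folds <- make_stratified_folds(d$samples$label, n_folds)
    log <<- c(log, folds$log)
    purrr::map_dfr(seq_len(n_folds), function(f) {
      test_idx <- which(folds$fold == f)
      train <- filter_dataset(d, samples = -test_idx)
      test <- filter_dataset(d, samples = test_idx)
      preds <- eval_predictions(train, test, models)
      preds$repeat_id <- r
      preds$fold <- f
      preds
    })
  })
  auc_scores <- out |>
    dplyr::group_by(.data$model, .data$repeat_id, .data$fold) |>
    dplyr::summarise(auc = auc(.data$label, .data$prob), .groups = "drop") |>
    dplyr::mutate(unit = paste0("r", .data$repeat_id, "_f", .data$fold))
  new_evaluation_report("five_fold_repeated", auc_scores, out,
                        pairwise_tests(auc_scores), seed, log)
}

#' Leave-one-study-out cross-validation
#'
#' Holds out each study in turn, trains every model on the remaining
#' studies, and scores one AUC per (model, study). A held-out study whose
#' labels are single-class gets an `NA` AUC and is excluded from the paired
#' tests (logged).
#'
#' @inheritParams run_five_fold
#' @return A `pcmt_evaluation` report with one AUC per (model, study).
#' @export
run_loso <- function(d, models, seed = 1) {
  stopifnot(inherits(d, "pcmt_dataset"))
  if (is.null(d$samples[["study"]])) abort("`d` has no study annotation.")
  studies <- unique(d$samples[["study"]])
  if (length(studies) < 2) abort("Leave-one-study-out needs at least two studies.")
  models <- name_models(models)
  set.seed(seed)
  log <- character()
  preds <- purrr::map_dfr(studies, function(s) {
    test_idx <- which(d$samples[["study"]] == s)
    train <- filter_dataset(d, samples = -test_idx)
    test <- filter_dataset(d, samples = test_idx)
    p <- eval_predictions(train, test, models)
    p$unit <- s
    p
  })
  auc_scores <- preds |>
    dplyr::group_by(.data$model, .data$unit) |>
    dplyr::summarise(auc = if (length(unique(.data$label)) == 2)
      auc(.data$label, .data$prob) else NA_real_, .groups = "drop")
  undef <- unique(auc_scores$unit[is.na(auc_scores$auc)])
  if (length(undef)) {
    log <- c(log, sprintf("study '%s' is single-class; AUC undefined and excluded from paired tests", undef))
  }
  new_evaluation_report("loso", auc_scores, preds, pairwise_tests(auc_scores),
                        seed, log)
}

#' Leave-one-out cross-validation
#'
#' Predicts every sample from a model trained on all other samples, retains
#' the full per-sample probability vector for downstream subtype slicing,
#' and reports a single pooled AUC per model.
#'
#' @inheritParams run_five_fold
#' @return A `pcmt_evaluation` report (`unit == "all"`); per-sample
#'   predictions are in `$predictions`.
#' @export
run_loocv <- function(d, models, seed = 1) {
  stopifnot(inherits(d, "pcmt_dataset"))
  if (n_samples(d) < 4) abort("Leave-one-out evaluation needs at least 4 samples.")
  models <- name_models(models)
  set.seed(seed)
  preds <- purrr::map_dfr(seq_len(n_samples(d)), function(i) {
    train <- filter_dataset(d, samples = -i)
    test <- filter_dataset(d, samples = i)
    eval_predictions(train, test, models)
  })
  auc_scores <- preds |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(auc = auc(.data$label, .data$prob), .groups = "drop") |>
    dplyr::mutate(unit = "all")
  new_evaluation_report("loocv", auc_scores, preds,
                        pairwise_tests(auc_scores[0, ]), seed)
}

#' Subtype-restricted AUC from a leave-one-out report
#'
#' Slices the pooled leave-one-out probabilities by subtype and computes one
#' AUC per (model, subtype) on that slice alone. Subtype slices with a
#' single outcome class get an `NA` AUC.
#'
#' @param report A `pcmt_evaluation` from [run_loocv()] on a
#'   subtype-annotated dataset.
#' @return A tibble: `model`, `subtype`, `auc`, `n`.
#' @export
subtype_auc <- function(report) {
  stopifnot(inherits(report, "pcmt_evaluation"))
  preds <- report$predictions
  if (all(is.na(preds$subtype))) abort("The evaluated dataset has no subtype annotation.")
  preds |>
    dplyr::group_by(.data$model, .data$subtype) |>
    dplyr::summarise(auc = if (length(unique(.data$label)) == 2)
      auc(.data$label, .data$prob) else NA_real_,
      n = dplyr::n(), .groups = "drop")
}

#' Subtype-internal leave-one-out evaluation
#'
#' The comparator path for subtype-restricted accuracy: pooled models are
#' trained and leave-one-out evaluated *within* each subtype, whereas the
#' personalized ensemble's subtype AUC slices whole-cohort leave-one-out
#' probabilities (see [subtype_auc()]).
#'
#' @inheritParams run_five_fold
#' @param min_n Smallest subtype size evaluated (default 10).
#' @return A tibble: `model`, `subtype`, `auc`, `n`.
#' @export
run_subtype_loocv <- function(d, models, seed = 1, min_n = 10) {
  stopifnot(inherits(d, "pcmt_dataset"))
  if (is.null(d$samples[["subtype"]])) abort("`d` has no subtype annotation.")
  purrr::map_dfr(unique(d$samples[["subtype"]]), function(st) {
    idx <- which(d$samples[["subtype"]] == st)
    if (length(idx) < min_n || length(unique(d$samples$label[idx])) < 2) {
      return(tibble::tibble(model = names(name_models(models)),
                            subtype = st, auc = NA_real_, n = length(idx)))
    }
    rep <- run_loocv(filter_dataset(d, samples = idx), models, seed = seed)
    dplyr::mutate(rep$auc_scores[, c("model", "auc")], subtype = st,
                  n = length(idx), .after = "model")
  })
}
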