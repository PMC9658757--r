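#' Number of top features giving a target chance overlap
#'
#' When two independent random selections of X features are drawn from
#' `total_features`, the expected number they share is `X^2 / total`.
#' Inverting that relation, the number of top features to select so that the
#' chance-expected overlap equals `expected_overlaps` is the largest integer
#' X with `X^2 / total <= expected`, i.e. `floor(sqrt(total * expected))`.
#' With 12,750 features and expected overlaps 5, 10, 20, 30, 50 this gives
#' 252, 357, 504, 618 and 798.
#'
#' @param total_features Total number of features (>= 1).
#' @param expected_overlaps Target chance overlap (>= 1).
#' @return Integer count of top features.
#' @export
#' @examples
#' top_feature_count(12750, 5)
top_feature_count <- function(total_features, expected_overlaps) {
  if (any(total_features < 1) || any(expected_overlaps < 1)) {
    abort("`total_features` and `expected_overlaps` must be positive.")
  }
  x <- floor(sqrt(as.numeric(total_features) * as.numeric(expected_overlaps)))
  # guard against sqrt() landing a hair under/over an exact integer
  x <- x + (((x + 1)^2) <= total_features * expected_overlaps)
  as.integer(x)
}

#' Observed-over-expected feature overlap ratio
#'
#' The split-half stability statistic: the number of top features two
#' disjoint sample halves have in common, divided by the chance-expected
#' overlap for selections of that size. A random ranking averages 1; values
#' well above 1 indicate robust feature selection.
#'
#' @param top_a,top_b Character vectors of selected feature ids, equal size.
#' @param expected_overlaps The chance-expected overlap for this selection
#'   size (the level the size was derived from via [top_feature_count()]).
#' @return Nonnegative ratio.
#' @export
overlap_ratio <- function(top_a, top_b, expected_overlaps) {
  if (length(top_a) != length(top_b)) {
    abort("`top_a` and `top_b` must contain the same number of features.")
  }
  length(intersect(top_a, top_b)) / expected_overlaps
}

# Top-k selection: decreasing score, ties broken by a random permutation
# (reproducible under the caller's seed). A deterministic tie-break (for
# example, by gene id) would make two sparse models agree on the tied
# zero-score genes they pad their lists with, manufacturing overlap that the
# chance-expectation denominator does not account for.
top_features <- function(scores, k) {
  ord <- order(-scores, sample.int(length(scores)))
  names(scores)[ord[seq_len(min(k, length(scores)))]]
}

#' Personalized-classifier feature-importance scores for a partition
#'
#' Within a sample partition, every sample is predicted by a personalized
#' classifier (single threshold, default 0.175) trained on the remaining
#' partition samples, and the per-gene importance score is the average of
#' the absolute model coefficients over all samples. Degenerate selections
#' fall back as usual and contribute all-zero coefficient vectors.
#' Intercepts are not gene features and are excluded.
#'
#' @param partition A `pcmt_dataset` (both classes present, n >= 4).
#' @param threshold Correlation threshold (default 0.175).
#' @param random_neighbors If `TRUE`, each sample's training subset is
#'   replaced by a uniformly random subset of the same size as its true
#'   signed selection (the robustness control).
#' @param mode,inverse_regularization Passed through to selection/fitting.
#' @return Named nonnegative numeric vector over genes.
#' @export
pc_feature_scores <- function(partition, threshold = 0.175,
                              random_neighbors = FALSE,
                              mode = "signed", inverse_regularization = 1) {
  stopifnot(inherits(partition, "pcmt_dataset"))
  n <- n_samples(partition)
  if (n < 4) abort("Partition too small for leave-one-out feature scoring.")
  total <- numeric(n_genes(partition))
  for (i in seq_len(n)) {
    rest_idx <- setdiff(seq_len(n), i)
    rest <- filter_dataset(partition, samples = rest_idx)
    pcc <- pearson_profile(partition$expr[i, ], rest$expr)
    sel <- select_training_subset(pcc, threshold, mode)
    idx <- sel$selected_indices
    if (random_neighbors) idx <- sample.int(n - 1, length(idx))
    labels <- rest$samples$label[idx]
    if (length(idx) >= 2 && length(unique(labels)) == 2) {
      cf <- tryCatch(
        fit_l1_logistic(rest$expr[idx, , drop = FALSE], labels,
                        inverse_regularization)$coefficients,
        error = function(e) numeric(n_genes(partition)))
      total <- total + abs(cf)
    }
    # degenerate selections contribute a zero coefficient vector
  }
  scores <- total / n
  names(scores) <- gene_ids(partition)
  scores
}

#' Split-half feature-robustness analysis
#'
#' Repeatedly partitions the cohort into two disjoint, class-stratified
#' halves; in each half every model produces a per-gene importance score;
#' the top `X` features (with `X` from [top_feature_count()] per
#' expected-overlap level, ties broken by gene id) are compared between the
#' halves via [overlap_ratio()]. The canonical model set is the true
#' personalized classifier, its random-neighbor control, and the pooled
#' logistic and random-forest comparators.
#'
#' @param d A `pcmt_dataset` (n >= 8, both classes).
#' @param models Named list of model specifications with a
#'   [feature_scores()] method.
#' @param levels Expected-overlap levels (default `c(5, 10, 20, 30, 50)`).
#' @param n_repeats Number of random half-splits (default 20).
#' @param seed Integer seed.
#' @return A `pcmt_robustness` report: tibble `ratios` with one row per
#'   (model, level, repeat), plus `top_feature_counts` and the call
#'   settings.
#' @export
run_robustness <- function(d,
                           models = list(pc = pc_model(0.175),
                                         pc_random = pc_random_model(0.175),
                                         pooled_lr = pooled_lr_model(),
                                         pooled_rf = pooled_rf_model()),
                           levels = c(5, 10, 20, 30, 50),
                           n_repeats = 20, seed = 1) {
  stopifnot(inherits(d, "pcmt_dataset"))
  if (n_samples(d) < 8) abort("Robustness analysis needs at least 8 samples.")
  models <- name_models(models)
  counts <- top_feature_count(n_genes(d), levels)
  set.seed(seed)
  ratios <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    # class-stratified half split, as equal as parity allows
    half <- logical(n_samples(d))
    for (cl in unique(d$samples$label)) {
      idx <- sample(which(d$samples$label == cl))
      half[idx[seq_len(floor(length(idx) / 2))]] <- TRUE
    }
    halves <- list(filter_dataset(d, samples = which(half)),
                   filter_dataset(d, samples = which(!half)))
    purrr::imap_dfr(models, function(spec, nm) {
      sc <- lapply(halves, function(h) feature_scores(spec, h))
      purrr::map_dfr(seq_along(levels), function(li) {
        tops <- lapply(sc, top_features, k = counts[li])
        tibble::tibble(model = nm, level = levels[li], repeat_id = r,
                       top_count = counts[li],
                       observed_overlap = length(intersect(tops[[1]], tops[[2]])),
                       ratio = overlap_ratio(tops[[1]], tops[[2]], levels[li]))
      })
    })
  })
  structure(list(ratios = ratios, levels = levels,
                 top_feature_counts = counts, n_repeats = n_repeats,
                 seed = seed, n_genes = n_genes(d)),
            class = "pcmt_robustness")
}

#' @export
print.pcmt_robustness <- function(x, ...) {
  cat(sprintf("<pcmt_robustness> %d repeats, levels %s (top counts %s)\n",
              x$n_repeats, paste(x$levels, collapse = "/"),
              paste(x$top_feature_counts, collapse = "/")))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.pcmt_robustness <- function(x, ...) x$ratios

#' @export
glance.pcmt_robustness <- function(x, ...) {
  x$ratios |>
    dplyr::group_by(.data$model, .data$level) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio), sd_ratio = sd(.data$ratio),
                     .groups = "drop")
}

#' Share of total importance carried by the top fraction of features
#'
#' Concentration statistic for an importance-score vector: the proportion of
#' the total score mass held by the top `ceiling(top_fraction * n)` features.
#' A uniform score vector yields approximately `top_fraction`; a one-hot
#' vector yields 1 for any fraction. Scale-invariant and non-decreasing in
#' `top_fraction`.
#'
#' @param scores Nonnegative numeric vector, not all zero.
#' @param top_fraction Fraction in (0, 1], default 0.05.
#' @return Share in `[0, 1]`.
#' @export
#' @examples
#' concentration_share(c(4, 3, 2, 1), 0.5)
concentration_share <- function(scores, top_fraction = 0.05) {
  if (any(scores < 0)) abort("`scores` must be nonnegative.")
  if (all(scores == 0)) abort("`scores` are all zero; concentration is undefined.")
  if (top_fraction <= 0 || top_fraction > 1) abort("`top_fraction` must be in (0, 1].")
  k <- ceiling(top_fraction * length(scores))
  sum(sort(scores, decreasing = TRUE)[seq_len(k)]) / sum(scores)
}
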