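#' Fit an L1-penalized logistic regression
#'
#' The base learner used everywhere in the package: lasso-penalized logistic
#' regression at a single fixed penalty, giving the sparse coefficient
#' vectors that feed both prediction and feature scoring. The penalty is
#' parameterized by the conventional inverse regularization strength `C`
#' (larger = weaker penalty); internally the coordinate-descent solver is
#' run with `lambda = 1 / (n * C)`, which places the penalty on the same
#' per-observation scale. Features are not re-standardized: inputs are
#' assumed already normalized upstream.
#'
#' @param train_matrix Numeric matrix, samples x genes.
#' @param train_labels Binary 0/1 labels, both classes present.
#' @param inverse_regularization Positive scalar `C`; default 1.
#' @return A `fitted_linear_model`: list with named `coefficients` (length
#'   `n_genes`), `intercept`, `training_sample_count`, `lambda`.
#' @export
fit_l1_logistic <- function(train_matrix, train_labels, inverse_regularization = 1) {
  if (!is.matrix(train_matrix)) train_matrix <- rbind(train_matrix)
  y <- as.numeric(train_labels)
  n <- nrow(train_matrix)
  if (n < 2) abort("At least two training samples are required.")
  if (length(unique(y)) < 2) {
    abort(class = "pcmt_single_class_error",
          message = "Training labels contain a single class; cannot fit a classifier.")
  }
  if (inverse_regularization <= 0) abort("`inverse_regularization` must be positive.")
  x <- train_matrix
  padded <- FALSE
  if (ncol(x) == 1) {            # the solver needs >= 2 columns
    x <- cbind(x, `.pad.` = 0)
    padded <- TRUE
  }
  lam <- 1 / (n * inverse_regularization)
  # small personalized subsets routinely trip glmnet's informational
  # "fewer than 8 observations" warning; degeneracy is handled upstream
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                   lambda = lam * c(16, 8, 4, 2, 1),
                   standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  cf <- as.numeric(stats::coef(fit, s = lam))
  coefs <- cf[-1]
  if (padded) coefs <- coefs[1]
  names(coefs) <- colnames(train_matrix)
  structure(list(coefficients = coefs, intercept = cf[1],
                 training_sample_count = n, lambda = lam),
            class = "fitted_linear_model")
}

#' @export
print.fitted_linear_model <- function(x, ...) {
  cat(sprintf("<fitted_linear_model> %d genes (%d nonzero), n_train = %d\n",
              length(x$coefficients), sum(x$coefficients != 0),
              x$training_sample_count))
  invisible(x)
}

#' @export
predict.fitted_linear_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  as.numeric(plogis(object$intercept + newdata %*% object$coefficients))
}

#' @export
tidy.fitted_linear_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.fitted_linear_model <- function(x, ...) {
  tibble::tibble(n_train = x$training_sample_count, lambda = x$lambda,
                 n_nonzero = sum(x$coefficients != 0))
}

# ---- model specifications ---------------------------------------------------
# A model spec is a lightweight S3 object consumed by the cross-validation and
# robustness harnesses through two generics: predict_probs() (probability of
# the poor class for each test row) and feature_scores() (a nonnegative
# per-gene importance vector learned from a dataset).

#' Model specifications for the evaluation and robustness harnesses
#'
#' Comparator and method specifications passed to [run_five_fold()],
#' [run_loso()], [run_loocv()] and [run_robustness()]:
#' * `pcmt_model()` — the multi-threshold personalized ensemble (the method);
#' * `pc_model()` — a single personalized classifier at one threshold;
#' * `pc_random_model()` — personalized classifier with uniformly random
#'   neighbor sets of the sizes the true selection would pick (the
#'   robustness control);
#' * `pooled_lr_model()` — one L1-logistic model on all training samples;
#' * `pooled_rf_model()` — a seeded random forest comparator (100 trees,
#'   impurity importance);
#' * `constant_model()` — an uninformative score, for harness checks.
#'
#' @param thresholds Numeric vector of correlation thresholds.
#' @param threshold Single correlation threshold.
#' @param mode `"signed"` or `"positive_only"` selection.
#' @param inverse_regularization Passed to [fit_l1_logistic()].
#' @param n_trees,seed Random-forest size and seed.
#' @param prob Constant probability returned by `constant_model()`.
#' @return A model-spec object with a `label` attribute used in reports.
#' @name model_specs
NULL

#' @rdname model_specs
#' @export
pcmt_model <- function(thresholds = threshold_grid(), mode = c("signed", "positive_only"),
                       inverse_regularization = 1) {
  mode <- match.arg(mode)
  if (!length(thresholds)) abort("`thresholds` must be non-empty.")
  structure(list(thresholds = thresholds, mode = mode,
                 inverse_regularization = inverse_regularization,
                 label = if (mode == "signed") "pcmt" else "pcmt_pos"),
            class = c("model_pcmt", "pcmt_model_spec"))
}

#' @rdname model_specs
#' @export
pc_model <- function(threshold, mode = c("signed", "positive_only"),
                     inverse_regularization = 1) {
  mode <- match.arg(mode)
  structure(list(thresholds = threshold, mode = mode,
                 inverse_regularization = inverse_regularization,
                 label = paste0("pc_", format(threshold))),
            class = c("model_pc", "model_pcmt", "pcmt_model_spec"))
}

#' @rdname model_specs
#' @export
pc_random_model <- function(threshold = 0.175, inverse_regularization = 1) {
  structure(list(threshold = threshold,
                 inverse_regularization = inverse_regularization,
                 label = "pc_random"),
            class = c("model_pc_random", "pcmt_model_spec"))
}

#' @rdname model_specs
#' @export
pooled_lr_model <- function(inverse_regularization = 1) {
  structure(list(inverse_regularization = inverse_regularization, label = "pooled_lr"),
            class = c("model_pooled_lr", "pcmt_model_spec"))
}

#' @rdname model_specs
#' @export
pooled_rf_model <- function(n_trees = 100, seed = 1) {
  structure(list(n_trees = n_trees, seed = seed, label = "pooled_rf"),
            class = c("model_pooled_rf", "pcmt_model_spec"))
}

#' @rdname model_specs
#' @export
constant_model <- function(prob = 0.5) {
  structure(list(prob = prob, label = "constant"),
            class = c("model_constant", "pcmt_model_spec"))
}

model_label <- function(spec) spec$label

# name a list of specs by their labels, keeping user-supplied names
name_models <- function(models) {
  if (inherits(models, "pcmt_model_spec")) models <- list(models)
  nms <- names(models) %||% rep("", length(models))
  auto <- vapply(models, model_label, character(1))
  nms[nms == ""] <- auto[nms == ""]
  names(models) <- make.unique(nms)
  models
}

#' Predict poor-class probabilities from a model specification
#'
#' @param spec A model specification, see [model_specs].
#' @param train A `pcmt_dataset` of training samples.
#' @param newdata Numeric matrix of test samples over the same genes.
#' @param ... Passed to methods.
#' @return Numeric vector of probabilities, one per test row.
#' @export
predict_probs <- function(spec, train, newdata, ...) UseMethod("predict_probs")

#' @export
predict_probs.model_pcmt <- function(spec, train, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  vapply(seq_len(nrow(newdata)), function(i) {
    pcmt_predict(train, newdata[i, ], thresholds = spec$thresholds,
                 mode = spec$mode,
                 inverse_regularization = spec$inverse_regularization)$pcmt_prob
  }, numeric(1))
}

#' @export
predict_probs.model_pc_random <- function(spec, train, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  prevalence <- mean(train$samples$label)
  vapply(seq_len(nrow(newdata)), function(i) {
    pcc <- pearson_profile(newdata[i, ], train$expr)
    k <- length(select_training_subset(pcc, spec$threshold, "signed")$selected_indices)
    idx <- if (k > 0) sample.int(n_samples(train), k) else integer(0)
    fit_pc_subset(train, idx, prevalence, spec$inverse_regularization, newdata[i, ])$prob
  }, numeric(1))
}

#' @export
predict_probs.model_pooled_lr <- function(spec, train, newdata, ...) {
  fit <- fit_l1_logistic(train$expr, train$samples$label, spec$inverse_regularization)
  predict(fit, newdata)
}

#' @export
predict_probs.model_pooled_rf <- function(spec, train, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  fit <- fit_ranger(train, spec)
  pred <- predict(fit, data = as.data.frame(newdata))$predictions
  as.numeric(pred[, "1"])
}

#' @export
predict_probs.model_constant <- function(spec, train, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  rep(spec$prob, nrow(newdata))
}

fit_ranger <- function(train, spec) {
  df <- as.data.frame(train$expr)
  df$.outcome <- factor(train$samples$label, levels = c(0, 1))
  if (length(unique(train$samples$label)) < 2) {
    abort(class = "pcmt_single_class_error",
          message = "Training labels contain a single class; cannot fit a classifier.")
  }
  ranger::ranger(dependent.variable.name = ".outcome", data = df,
                 num.trees = spec$n_trees, probability = TRUE,
                 importance = "impurity", seed = spec$seed,
                 num.threads = 1)
}

#' Fit a pooled (non-personalized) comparator model
#'
#' One model for the whole training cohort: either the L1-logistic model or a
#' seeded random forest. Both expose probability predictions through
#' [predict_probs()] and a per-gene feature-importance vector (absolute
#' coefficients for the logistic model; impurity importance for the forest).
#'
#' @param train A `pcmt_dataset`.
#' @param family `"l1_logistic"` or `"random_forest"`.
#' @param seed Seed for the random forest.
#' @param ... Passed to the spec constructor.
#' @return A `pooled_model` with elements `fit`, `spec`, `importance`
#'   (named nonnegative vector over genes).
#' @export
fit_pooled_model <- function(train, family = c("l1_logistic", "random_forest"),
                             seed = 1, ...) {
  family <- match.arg(family)
  if (family == "l1_logistic") {
    spec <- pooled_lr_model(...)
    fit <- fit_l1_logistic(train$expr, train$samples$label, spec$inverse_regularization)
    imp <- abs(fit$coefficients)
  } else {
    spec <- pooled_rf_model(seed = seed, ...)
    fit <- fit_ranger(train, spec)
    imp <- fit$variable.importance[gene_ids(train)]
  }
  names(imp) <- gene_ids(train)
  structure(list(fit = fit, spec = spec, family = family, importance = imp),
            class = "pooled_model")
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf("<pooled_model> family = %s, %d genes\n", x$family, length(x$importance)))
  invisible(x)
}

#' @export
predict.pooled_model <- function(object, newdata, ...) {
  if (object$family == "l1_logistic") {
    predict(object$fit, newdata)
  } else {
    if (is.null(dim(newdata))) newdata <- rbind(newdata)
    as.numeric(predict(object$fit, data = as.data.frame(newdata))$predictions[, "1"])
  }
}

#' Per-gene feature-importance scores of a model specification
#'
#' Used by the split-half robustness analysis: each model maps a data
#' partition to a nonnegative importance score per gene. Personalized
#' specifications score genes by within-partition leave-one-out averaging of
#' absolute coefficients (see [pc_feature_scores()]); pooled specifications
#' use a single fit's absolute coefficients or impurity importances.
#'
#' @inheritParams predict_probs
#' @param d A `pcmt_dataset` (the partition to score on).
#' @return Named nonnegative numeric vector over the genes of `d`.
#' @export
feature_scores <- function(spec, d, ...) UseMethod("feature_scores")

#' @export
feature_scores.model_pcmt <- function(spec, d, ...) {
  pc_feature_scores(d, threshold = spec$thresholds[1],
                    inverse_regularization = spec$inverse_regularization)
}

#' @export
feature_scores.model_pc_random <- function(spec, d, ...) {
  pc_feature_scores(d, threshold = spec$threshold, random_neighbors = TRUE,
                    inverse_regularization = spec$inverse_regularization)
}

#' @export
feature_scores.model_pooled_lr <- function(spec, d, ...) {
  fit <- fit_l1_logistic(d$expr, d$samples$label, spec$inverse_regularization)
  abs(fit$coefficients)
}

#' @export
feature_scores.model_pooled_rf <- function(spec, d, ...) {
  fit <- fit_ranger(d, spec)
  imp <- fit$variable.importance[gene_ids(d)]
  names(imp) <- gene_ids(d)
  imp
}
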