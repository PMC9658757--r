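test_that("AUC matches the pair-counting oracle and its tie/ranking conventions", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 1), c(0.5, 0.5)), 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "Both classes")

  set.seed(30)
  for (rep in 1:20) {
    n <- 20
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(round(runif(n), 2))  # rounding induces ties
    expect_lt(abs(auc(labels, scores) - auc_pairs(labels, scores)), 1e-12)
  }
})

test_that("AUC is monotone-invariant and complements under score negation", {
  set.seed(31)
  labels <- rbinom(30, 1, 0.5)
  scores <- rnorm(30)  # tie-free almost surely
  a <- auc(labels, scores)
  expect_equal(auc(labels, exp(scores)), a)          # strictly monotone map
  expect_equal(auc(labels, plogis(scores)), a)
  expect_equal(auc(labels, -scores), 1 - a)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  labels <- rbinom(50, 1, 0.3)
  scores <- rnorm(50)
  expect_equal(auc(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("paired t-test matches the textbook formula and flags degenerate differences", {
  same <- paired_t_test(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  const <- paired_t_test(c(0.7, 0.8, 0.9), c(0.6, 0.7, 0.8))
  expect_true(const$degenerate)
  expect_true(is.na(const$p_value))

  set.seed(33)
  a <- runif(40); b <- runif(40)
  got <- paired_t_test(a, b)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(40))
  expect_lt(abs(got$statistic - tstat), 1e-10)
  expect_lt(abs(got$p_value - 2 * stats::pt(-abs(tstat), 39)), 1e-10)
})

test_that("repeated five-fold evaluation yields 5 x repeats AUCs on shared folds", {
  cfg <- generator_config(n_samples = 60, n_genes = 30,
                          n_signal_genes_per_subtype = 5, seed = 34)
  d <- generate_cohort(cfg)
  models <- list(pooled_lr = pooled_lr_model(), constant = constant_model())
  rep8 <- run_five_fold(d, models, n_repeats = 8, seed = 7)
  a <- tidy(rep8)
  expect_equal(sum(a$model == "pooled_lr"), 40)
  expect_equal(sum(a$model == "constant"), 40)
  expect_true(all(a$auc >= 0 & a$auc <= 1))

  # identical fold assignments across models within a repeat
  fold_map <- rep8$predictions |>
    dplyr::distinct(.data$model, .data$sample_id, .data$repeat_id, .data$fold) |>
    tidyr::pivot_wider(names_from = "model", values_from = "fold")
  expect_identical(fold_map$pooled_lr, fold_map$constant)

  # constant scores give AUC exactly one half everywhere
  expect_true(all(a$auc[a$model == "constant"] == 0.5))

  # determinism under the seed
  rep8b <- run_five_fold(d, models, n_repeats = 8, seed = 7)
  expect_equal(tidy(rep8b), a)
})

test_that("leave-one-study-out scores one AUC per held-out study", {
  d3 <- generate_cohort(generator_config(n_samples = 60, n_genes = 30,
                                         n_signal_genes_per_subtype = 5,
                                         n_studies = 3, seed = 35))
  rep3 <- run_loso(d3, list(pooled_lr = pooled_lr_model()))
  expect_equal(nrow(tidy(rep3)), 3)

  d12 <- generate_cohort(generator_config(n_samples = 144, n_genes = 30,
                                          n_signal_genes_per_subtype = 5,
                                          n_studies = 12, seed = 36))
  rep12 <- run_loso(d12, list(pooled_lr = pooled_lr_model()))
  expect_equal(nrow(tidy(rep12)), 12)

  # a model scoring constant within each study is uninformative per study
  rep_const <- run_loso(d3, list(constant = constant_model(0.42)))
  expect_true(all(tidy(rep_const)$auc == 0.5))
})

test_that("a single-class held-out study gets an undefined AUC and leaves paired tests intact", {
  d <- tiny_dataset(24, 10, seed = 37, studies = rep(c("A", "B", "C"), each = 8))
  d$samples$label[d$samples[["study"]] == "B"] <- 1  # degenerate study
  d$samples$label[d$samples[["study"]] != "B"] <- rep_len(c(0, 1), 16)
  rep <- run_loso(d, list(pooled_lr = pooled_lr_model(), constant = constant_model()))
  a <- tidy(rep)
  expect_true(is.na(a$auc[a$model == "pooled_lr" & a$unit == "B"]))
  expect_false(anyNA(a$auc[a$unit != "B"]))
  expect_false(any(rep$pairwise_p$degenerate & is.na(rep$pairwise_p$p_value)))
  expect_match(paste(rep$log, collapse = " "), "single-class")
})

test_that("leave-one-out retains one probability per sample and a pooled AUC", {
  d <- tiny_dataset(10, 8, seed = 38)
  rep <- run_loocv(d, list(constant = constant_model(), pooled_lr = pooled_lr_model()))
  expect_equal(sum(rep$predictions$model == "constant"), 10)
  expect_equal(sum(rep$predictions$model == "pooled_lr"), 10)
  expect_equal(nrow(tidy(rep)), 2)

  # strong signal: a personalized classifier ranks nearly perfectly
  strong <- separable_dataset(30, seed = 39)
  rep2 <- run_loocv(strong, list(pc = pc_model(0.2)))
  expect_gt(tidy(rep2)$auc, 0.9)
})

test_that("label shuffling drives the pooled AUC to chance", {
  set.seed(40)
  base <- generate_cohort(generator_config(n_samples = 100, n_genes = 40,
                                           n_signal_genes_per_subtype = 5,
                                           seed = 41))
  aucs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    shuffled <- pcmt_dataset(base$expr, sample(base$samples$label),
                             subtypes = base$samples[["subtype"]])
    tidy(run_loocv(shuffled, list(pooled_lr = pooled_lr_model())))$auc
  }, numeric(1))
  expect_true(all(aucs > 0.3 & aucs < 0.7))
})

test_that("subtype-restricted AUCs equal direct slice recomputation", {
  d <- generate_cohort(generator_config(n_samples = 90, n_genes = 40,
                                        n_signal_genes_per_subtype = 5, seed = 42))
  rep <- run_loocv(d, list(pc = pc_model(0.2), constant = constant_model()))
  by_sub <- subtype_auc(rep)

  preds <- rep$predictions[rep$predictions$model == "pc", ]
  for (st in unique(preds$subtype)) {
    sl <- preds[preds$subtype == st, ]
    want <- if (length(unique(sl$label)) == 2) auc(sl$label, sl$prob) else NA_real_
    got <- by_sub$auc[by_sub$model == "pc" & by_sub$subtype == st]
    expect_equal(got, want)
  }

  # identical predictions across subtypes -> identical per-subtype AUCs is a
  # special case covered by the constant model (all 0.5 or NA)
  cst <- by_sub[by_sub$model == "constant", ]
  expect_true(all(is.na(cst$auc) | cst$auc == 0.5))

  # a slice equal to the full cohort reproduces the pooled AUC
  one <- pcmt_dataset(d$expr, d$samples$label,
                      subtypes = rep("all", n_samples(d)))
  rep_one <- run_loocv(one, list(pc = pc_model(0.2)))
  expect_equal(subtype_auc(rep_one)$auc, tidy(rep_one)$auc)
})

test_that("subtype-internal leave-one-out runs the comparator path", {
  d <- generate_cohort(generator_config(n_samples = 90, n_genes = 30,
                                        n_signal_genes_per_subtype = 5, seed = 43))
  tab <- run_subtype_loocv(d, list(pooled_lr = pooled_lr_model()))
  expect_setequal(unique(tab$subtype), unique(d$samples[["subtype"]]))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1, na.rm = TRUE))
  expect_equal(sum(tab$n), n_samples(d))
})
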