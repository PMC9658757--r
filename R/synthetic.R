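#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort with the statistical structure the personalized
#' classifier assumes: `n_subtypes` latent subtypes whose members are
#' positively Pearson-correlated with each other and lowly/negatively
#' correlated across subtypes (driven by sign-structured centroids over a
#' block of non-discriminative genes), disjoint subtype-specific signal-gene
#' blocks whose logistic effects reverse sign between subtypes, a calibrated
#' poor-outcome prevalence, and multi-study batch structure as per-study
#' mean shifts.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_subtypes Number of latent subtypes.
#' @param subtype_proportions Simplex vector of subtype sizes (default
#'   equal).
#' @param n_signal_genes_per_subtype Discriminative genes per subtype
#'   (disjoint blocks; `n_subtypes * n_signal_genes_per_subtype` must not
#'   exceed `n_genes`).
#' @param signal_effect Logistic effect per unit expression on a subtype's
#'   own signal genes (sign alternates across subtypes).
#' @param centroid_scale Magnitude of the sign-structured centroid entries;
#'   controls the within/cross-subtype correlation contrast.
#' @param noise_sd Gaussian noise standard deviation.
#' @param poor_prevalence_target Target poor-class fraction (default 0.28,
#'   the 455/1616 imbalance of the motivating compendium).
#' @param n_studies Number of studies; each applies a per-gene mean shift.
#' @param study_shift_sd Standard deviation of the study mean shifts.
#' @param seed Integer seed; the same seed yields a bit-identical cohort.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 400, n_genes = 500, n_subtypes = 3,
                             subtype_proportions = NULL,
                             n_signal_genes_per_subtype = 20,
                             signal_effect = 0.5, centroid_scale = 1,
                             noise_sd = 1, poor_prevalence_target = 0.28,
                             n_studies = 4, study_shift_sd = 0.25, seed = 1) {
  if (is.null(subtype_proportions)) {
    subtype_proportions <- rep(1 / n_subtypes, n_subtypes)
  }
  if (length(subtype_proportions) != n_subtypes ||
      abs(sum(subtype_proportions) - 1) > 1e-8 || any(subtype_proportions <= 0)) {
    abort("`subtype_proportions` must be positive and sum to 1 over `n_subtypes`.")
  }
  if (n_signal_genes_per_subtype * n_subtypes > n_genes) {
    abort("Signal genes exceed the total gene count: reduce `n_signal_genes_per_subtype`.")
  }
  if (noise_sd <= 0 || centroid_scale <= 0 || signal_effect <= 0) {
    abort("`noise_sd`, `centroid_scale` and `signal_effect` must be positive.")
  }
  if (poor_prevalence_target <= 0 || poor_prevalence_target >= 1) {
    abort("`poor_prevalence_target` must be in (0, 1).")
  }
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_subtypes = n_subtypes,
                 subtype_proportions = subtype_proportions,
                 n_signal_genes_per_subtype = n_signal_genes_per_subtype,
                 signal_effect = signal_effect, centroid_scale = centroid_scale,
                 noise_sd = noise_sd,
                 poor_prevalence_target = poor_prevalence_target,
                 n_studies = n_studies, study_shift_sd = study_shift_sd,
                 seed = seed),
            class = "generator_config")
}

# Subtype centroid matrix (K x n_genes): zero on the signal region, and on
# centroid block l equal to +scale for subtype l and -scale/(K-1) for the
# others, so centroid inner products are positive within and negative across
# subtypes.
subtype_centroids <- function(cfg) {
  K <- cfg$n_subtypes
  C <- matrix(0, K, cfg$n_genes)
  n_sig_total <- K * cfg$n_signal_genes_per_subtype
  centroid_genes <- setdiff(seq_len(cfg$n_genes), seq_len(n_sig_total))
  if (length(centroid_genes) == 0 || K == 1) return(C)
  blocks <- split(centroid_genes, rep_len(seq_len(K), length(centroid_genes)))
  for (k in seq_len(K)) {
    for (l in seq_len(K)) {
      C[k, blocks[[l]]] <- if (k == l) cfg$centroid_scale else -cfg$centroid_scale / (K - 1)
    }
  }
  C
}

# Subtype effect matrix (K x n_genes): subtype k has effect
# (-1)^(k+1) * signal_effect on its own signal block, zero elsewhere.
subtype_effects <- function(cfg) {
  K <- cfg$n_subtypes
  B <- matrix(0, K, cfg$n_genes)
  for (k in seq_len(K)) {
    block <- ((k - 1) * cfg$n_signal_genes_per_subtype + 1):(k * cfg$n_signal_genes_per_subtype)
    B[k, block] <- (-1)^(k + 1) * cfg$signal_effect
  }
  B
}

#' Generate a synthetic expression cohort
#'
#' Draws a cohort under `cfg` (see [generator_config()]): expression =
#' subtype centroid + study mean shift + Gaussian noise; outcome labels are
#' Bernoulli draws from a logistic model whose coefficients are nonzero only
#' on the sample's own subtype signal genes, with the intercept calibrated
#' by root-finding so the expected poor fraction matches the configured
#' prevalence target. The exact generating quantities are retained in the
#' `"oracle"` attribute (`true_prob`, per-subtype `effects`, `intercept`,
#' `centroids`) so tests can compute the Bayes-optimal AUC.
#'
#' @param cfg A [generator_config()].
#' @return A subtype- and study-annotated `pcmt_dataset` with attribute
#'   `"oracle"`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; g <- cfg$n_genes; K <- cfg$n_subtypes
  # deterministic subtype counts matching the proportions, shuffled order
  counts <- floor(cfg$subtype_proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  subtype <- sample(rep(seq_len(K), counts))
  study <- sample(rep_len(seq_len(cfg$n_studies), n))

  C <- subtype_centroids(cfg)
  S <- matrix(rnorm(cfg$n_studies * g, 0, cfg$study_shift_sd), cfg$n_studies, g)
  X <- C[subtype, , drop = FALSE] + S[study, , drop = FALSE] +
    matrix(rnorm(n * g, 0, cfg$noise_sd), n, g)

  B <- subtype_effects(cfg)
  eta <- rowSums(X * B[subtype, , drop = FALSE])
  intercept <- uniroot(function(b) mean(plogis(b + eta)) - cfg$poor_prevalence_target,
                       c(-50, 50))$root
  p <- plogis(intercept + eta)
  labels <- rbinom(n, 1, p)

  dimnames(X) <- list(sprintf("S%04d", seq_len(n)), sprintf("G%04d", seq_len(g)))
  d <- pcmt_dataset(X, labels,
                    subtypes = paste0("subtype", subtype),
                    studies = paste0("study", study))
  attr(d, "oracle") <- list(true_prob = p, effects = B, intercept = intercept,
                            centroids = C, subtype_index = subtype, config = cfg)
  d
}

#' Monotone cross-platform distortion specification
#'
#' Describes how a second cohort measured on a different platform is warped
#' relative to the first: a per-gene affine map (positive log-normal scale,
#' Gaussian shift), a global odd-cubic monotone nonlinearity, and random
#' dropout of a fraction of genes. All-zero settings give the identity.
#'
#' @param gene_scale_sd Log-scale sd of the per-gene multiplicative factor.
#' @param gene_shift_sd Sd of the per-gene additive shift.
#' @param nonlinearity Coefficient of the cubic term `x + c * x^3`.
#' @param dropout_frac Fraction of genes absent from the second cohort.
#' @return A `platform_shift` list.
#' @export
platform_shift <- function(gene_scale_sd = 0.2, gene_shift_sd = 0.5,
                           nonlinearity = 0.1, dropout_frac = 0.1) {
  if (dropout_frac < 0 || dropout_frac >= 1) abort("`dropout_frac` must be in [0, 1).")
  if (nonlinearity < 0) abort("`nonlinearity` must be nonnegative (monotone map).")
  structure(list(gene_scale_sd = gene_scale_sd, gene_shift_sd = gene_shift_sd,
                 nonlinearity = nonlinearity, dropout_frac = dropout_frac),
            class = "platform_shift")
}

#' Generate a pair of cohorts across a platform distortion
#'
#' Draws a single double-size cohort under shared generating parameters,
#' splits it into two cohorts, and passes the second through a monotone
#' per-gene distortion plus gene dropout (see [platform_shift()]) — the
#' setting that exercises [intersect_genes()] and
#' [quantile_normalize_joint()] before cross-cohort prediction.
#'
#' @param cfg A [generator_config()]; each output cohort has
#'   `cfg$n_samples` samples.
#' @param shift A [platform_shift()] (default settings distort; use
#'   `platform_shift(0, 0, 0, 0)` for the identity).
#' @return A list with `pcmt_dataset` elements `a` and `b`.
#' @export
generate_paired_cohorts <- function(cfg, shift = platform_shift()) {
  stopifnot(inherits(cfg, "generator_config"), inherits(shift, "platform_shift"))
  big_cfg <- cfg
  big_cfg$n_samples <- 2 * cfg$n_samples
  big <- generate_cohort(big_cfg)
  a <- filter_dataset(big, samples = seq_len(cfg$n_samples))
  b <- filter_dataset(big, samples = cfg$n_samples + seq_len(cfg$n_samples))
  rownames(b$expr) <- paste0("B", rownames(b$expr))
  b$samples$sample_id <- rownames(b$expr)
  oracle <- attr(big, "oracle")
  attr(a, "oracle") <- c(oracle[c("effects", "intercept", "centroids", "config")],
                         list(true_prob = oracle$true_prob[seq_len(cfg$n_samples)]))
  b_oracle <- c(oracle[c("effects", "intercept", "centroids", "config")],
                list(true_prob = oracle$true_prob[cfg$n_samples + seq_len(cfg$n_samples)]))

  g <- n_genes(b)
  scale_g <- exp(rnorm(g, 0, shift$gene_scale_sd))
  shift_g <- rnorm(g, 0, shift$gene_shift_sd)
  y <- sweep(sweep(b$expr, 2, scale_g, `*`), 2, shift_g, `+`)
  y <- y + shift$nonlinearity * y^3
  b$expr <- y
  if (shift$dropout_frac > 0) {
    keep <- sort(sample.int(g, round((1 - shift$dropout_frac) * g)))
    b <- filter_dataset(b, genes = keep)
  }
  attr(b, "oracle") <- b_oracle
  list(a = a, b = b)
}
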