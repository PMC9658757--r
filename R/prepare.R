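#' Restrict two cohorts to their common genes
#'
#' Cross-platform prediction first reduces both cohorts to the genes they
#' share (e.g. 10,398 genes shared between an Affymetrix compendium and an
#' independent microarray cohort), in the same order in both.
#'
#' @param a,b `pcmt_dataset` objects.
#' @return A list with elements `a` and `b`, both restricted to the common
#'   gene list in identical order (order of appearance in `a`).
#' @export
intersect_genes <- function(a, b) {
  stopifnot(inherits(a, "pcmt_dataset"), inherits(b, "pcmt_dataset"))
  common <- intersect(gene_ids(a), gene_ids(b))
  if (length(common) == 0) abort("The two datasets share no gene ids.")
  list(a = filter_dataset(a, genes = common), b = filter_dataset(b, genes = common))
}

#' Center each gene at zero mean
#'
#' Subtracts the per-gene (column) mean, the usual preparation for RNA-seq
#' log-counts before pooling them with a mean-centered microarray cohort.
#' Idempotent.
#'
#' @param d A `pcmt_dataset`.
#' @return A `pcmt_dataset` whose gene columns each have mean zero.
#' @export
mean_center <- function(d) {
  stopifnot(inherits(d, "pcmt_dataset"))
  d$expr <- sweep(d$expr, 2, colMeans(d$expr))
  d
}

# Quantile-normalize the rows of `m` (one row per sample) to the reference
# distribution `ref` (sorted ascending, length ncol(m)). Ties receive the
# mean of the reference values at their tied rank positions.
qn_to_reference <- function(m, ref) {
  cs <- c(0, cumsum(ref))
  t(apply(m, 1, function(x) {
    rmin <- rank(x, ties.method = "min")
    rmax <- rank(x, ties.method = "max")
    (cs[rmax + 1] - cs[rmin]) / (rmax - rmin + 1)
  }))
}

#' Jointly quantile-normalize two cohorts
#'
#' Pools all samples of both cohorts, computes the mean-quantile reference
#' distribution (the mean of the k-th smallest values across every pooled
#' sample), and maps each sample onto it, so data from the two sources share
#' one distribution. Afterwards every sample's sorted value vector is
#' identical. Tied values within a sample receive the mean of the reference
#' values at their tied rank positions.
#'
#' @param a,b `pcmt_dataset` objects with identical gene lists (apply
#'   [intersect_genes()] first).
#' @return A list with elements `a` and `b`, quantile-normalized.
#' @export
quantile_normalize_joint <- function(a, b) {
  stopifnot(inherits(a, "pcmt_dataset"), inherits(b, "pcmt_dataset"))
  if (!identical(gene_ids(a), gene_ids(b))) {
    abort("Gene lists differ; call intersect_genes() before quantile_normalize_joint().")
  }
  pooled <- rbind(a$expr, b$expr)
  ref <- colMeans(t(apply(pooled, 1, sort)))
  a$expr <- qn_to_reference(a$expr, ref)
  b$expr <- qn_to_reference(b$expr, ref)
  list(a = a, b = b)
}

#' Outcome label from progression-free interval
#'
#' Derives the good/poor/undecided prognostic label from a progression-free
#' interval and its event indicator: `good` if the interval exceeds 5 years;
#' `poor` if it is at most 5 years and a progression event occurred;
#' `undecided` otherwise (short follow-up without an event). Undecided
#' patients are conventionally dropped before modelling.
#'
#' @param pfi_time_years Non-negative progression-free interval, in years.
#' @param event Event indicator, 0/1. Vectorized with `pfi_time_years`.
#' @param horizon_years Decision horizon (default 5 years).
#' @return Character vector in `{"good", "poor", "undecided"}`.
#' @export
#' @examples
#' label_from_pfi(c(6, 3, 3), c(0, 1, 0))
label_from_pfi <- function(pfi_time_years, event, horizon_years = 5) {
  if (anyNA(pfi_time_years) || any(pfi_time_years < 0)) {
    abort("`pfi_time_years` must be non-negative and non-missing.")
  }
  if (!all(event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  dplyr::case_when(
    pfi_time_years > horizon_years ~ "good",
    event == 1 ~ "poor",
    .default = "undecided"
  )
}
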