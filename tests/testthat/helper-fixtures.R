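# Shared fixture builders. Everything is generated in code; no files.

# tiny labelled dataset with iid noise genes
tiny_dataset <- function(n = 12, g = 6, seed = 1, subtypes = NULL, studies = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * g), n, g,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("g%02d", 1:g)))
  labels <- rep_len(c(0, 1), n)
  pcmt_dataset(x, labels, subtypes = subtypes, studies = studies)
}

# linearly separable two-gene toy: class means at +/- delta
separable_dataset <- function(n = 40, delta = 3, noise = 0.3, seed = 1) {
  set.seed(seed)
  labels <- rep_len(c(0, 1), n)
  x <- cbind(rnorm(n, ifelse(labels == 1, delta, -delta), noise),
             rnorm(n, ifelse(labels == 1, delta, -delta), noise),
             matrix(rnorm(n * 3), n, 3))
  dimnames(x) <- list(sprintf("s%02d", 1:n), sprintf("g%02d", 1:5))
  pcmt_dataset(x, labels)
}

# O(n^2) pair-counting AUC oracle (ties count one half)
auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# direct two-pass covariance/sd Pearson formula
pcc_formula <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force quantile-normalization oracle: explicit tie groups, mean of
# reference values at the tied rank positions
qn_oracle <- function(m, ref) {
  ref <- sort(ref)
  out <- m
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    ord <- order(x)
    pos_of <- integer(length(x))
    pos_of[ord] <- seq_along(x)
    for (j in seq_along(x)) {
      tied <- which(x == x[j])
      out[i, j] <- mean(ref[pos_of[tied]])
    }
  }
  out
}
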