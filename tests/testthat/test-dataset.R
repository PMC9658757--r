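test_that("construction validates shapes, duplicates, labels and missing values", {
  x <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  d <- pcmt_dataset(x * 1.0, c(0, 1, 0))
  expect_s3_class(d, "pcmt_dataset")
  expect_equal(n_samples(d), 3)
  expect_equal(n_genes(d), 2)

  expect_error(pcmt_dataset(x * 1.0, c(0, 1)), "length")
  expect_error(pcmt_dataset(x * 1.0, c(0, 2, 0)), "0 .good. or 1")
  xx <- x * 1.0; xx[2, 1] <- NA
  expect_error(pcmt_dataset(xx, c(0, 1, 0)), "missing")
  xd <- x * 1.0; rownames(xd) <- c("a", "a", "c")
  expect_error(pcmt_dataset(xd, c(0, 1, 0)), "Duplicate sample")
})

test_that("load_dataset round-trips the matrix bit-exactly and orders by the matrix file", {
  d <- tiny_dataset(5, 3, seed = 42,
                    subtypes = rep(c("A", "B"), length.out = 5),
                    studies = rep(c("x", "y"), length.out = 5))
  td <- withr::local_tempdir()
  paths <- file.path(td, c("m.tsv", "l.tsv", "a.tsv"))
  write_dataset(d, paths[1], paths[2], paths[3])
  d2 <- load_dataset(paths[1], paths[2], paths[3])
  expect_identical(d2$expr, d$expr)
  expect_equal(d2$samples, d$samples)

  # labels file in scrambled order still aligns to matrix order
  lab <- readr::read_tsv(paths[2], show_col_types = FALSE)
  readr::write_tsv(lab[rev(seq_len(nrow(lab))), ], paths[2])
  d3 <- load_dataset(paths[1], paths[2])
  expect_identical(d3$samples$label, d$samples$label)
})

test_that("load errors name the first offending id or cell position", {
  d <- tiny_dataset(4, 3)
  td <- withr::local_tempdir()
  paths <- file.path(td, c("m.tsv", "l.tsv"))
  write_dataset(d, paths[1], paths[2])

  lab <- readr::read_tsv(paths[2], show_col_types = FALSE)
  readr::write_tsv(lab[-2, ], paths[2])
  expect_error(load_dataset(paths[1], paths[2]), "s02")

  lines <- readLines(paths[1])
  lines[3] <- sub("\t[^\t]*$", "\t", lines[3])  # blank out last cell of sample 2
  writeLines(lines, paths[1])
  expect_error(load_dataset(paths[1], file.path(td, "l2.tsv")), "not found")
  writeLines(lines, paths[1])
  lab2 <- readr::read_tsv(file.path(td, "l.tsv"), show_col_types = FALSE)
  expect_error(load_dataset(paths[1], paths[2]), "row 2.*column 3")
})

test_that("intersect_genes restricts both cohorts to the shared genes in shared order", {
  a <- tiny_dataset(4, 3, seed = 1); colnames(a$expr) <- c("A", "B", "C")
  b <- tiny_dataset(5, 3, seed = 2); colnames(b$expr) <- c("B", "C", "D")
  out <- intersect_genes(a, b)
  expect_identical(gene_ids(out$a), c("B", "C"))
  expect_identical(gene_ids(out$b), c("B", "C"))
  expect_identical(out$a$expr, a$expr[, c("B", "C")])

  same <- intersect_genes(a, a)
  expect_identical(same$a$expr, a$expr)

  colnames(b$expr) <- c("X", "Y", "Z")
  expect_error(intersect_genes(a, b), "no gene ids")
})

test_that("mean_center zeroes column means and is idempotent", {
  d <- tiny_dataset(3, 2)
  d$expr[, 1] <- c(1, 2, 3); d$expr[, 2] <- c(5, 5, 5)
  c1 <- mean_center(d)
  expect_equal(unname(c1$expr[, 1]), c(-1, 0, 1))
  expect_equal(unname(c1$expr[, 2]), c(0, 0, 0))
  expect_equal(mean_center(c1)$expr, c1$expr)
})

test_that("joint quantile normalization maps all samples onto the mean-quantile reference", {
  a <- tiny_dataset(1, 3); a$expr[1, ] <- c(1, 2, 3)
  b <- tiny_dataset(1, 3, seed = 2); b$expr[1, ] <- c(4, 5, 6)
  colnames(b$expr) <- colnames(a$expr)
  out <- quantile_normalize_joint(a, b)
  expect_equal(unname(out$a$expr[1, ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$b$expr[1, ]), c(2.5, 3.5, 4.5))

  # one shared sample duplicated in both cohorts is left unchanged
  dup <- quantile_normalize_joint(a, a)
  expect_equal(dup$a$expr, a$expr)
  expect_equal(dup$b$expr, a$expr)

  # property: sorted value vectors identical across every pooled sample
  a2 <- tiny_dataset(6, 10, seed = 3); b2 <- tiny_dataset(4, 10, seed = 4)
  out2 <- quantile_normalize_joint(a2, b2)
  pooled <- rbind(out2$a$expr, out2$b$expr)
  sorted <- t(apply(pooled, 1, sort))
  expect_true(all(abs(sweep(sorted, 2, sorted[1, ])) < 1e-12))

  colnames(b2$expr)[1] <- "other"
  expect_error(quantile_normalize_joint(a2, b2), "Gene lists differ")
})

test_that("quantile normalization tie handling matches the brute-force rank/average oracle", {
  a <- tiny_dataset(2, 4, seed = 5)
  a$expr[1, ] <- c(2, 2, 2, 7)   # triple tie
  a$expr[2, ] <- c(1, 3, 3, 9)
  b <- tiny_dataset(2, 4, seed = 6)
  b$expr[1, ] <- c(0, 5, 5, 1)
  b$expr[2, ] <- c(4, 4, 8, 8)
  out <- quantile_normalize_joint(a, b)
  pooled <- rbind(a$expr, b$expr)
  ref <- colMeans(t(apply(pooled, 1, sort)))
  expect_equal(out$a$expr, qn_oracle(a$expr, ref))
  expect_equal(out$b$expr, qn_oracle(b$expr, ref))
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  a <- tiny_dataset(5, 20, seed = 7); b <- tiny_dataset(3, 20, seed = 8)
  out <- quantile_normalize_joint(a, b)
  pooled_in <- t(rbind(a$expr, b$expr))      # limma wants genes x samples
  ln <- t(limma::normalizeQuantiles(pooled_in))
  expect_equal(rbind(out$a$expr, out$b$expr), ln, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("progression-free-interval labelling follows the 5-year rule and partitions the plane", {
  expect_identical(label_from_pfi(6.0, 0), "good")
  expect_identical(label_from_pfi(3.0, 1), "poor")
  expect_identical(label_from_pfi(3.0, 0), "undecided")
  expect_identical(label_from_pfi(5.0, 1), "poor")    # boundary: <= 5 with event
  expect_identical(label_from_pfi(5.0, 0), "undecided")
  expect_error(label_from_pfi(-1, 0), "non-negative")

  set.seed(9)
  t <- runif(200, 0, 12); e <- rbinom(200, 1, 0.5)
  lab <- label_from_pfi(t, e)
  expect_true(all(lab %in% c("good", "poor", "undecided")))
  expect_identical(lab[t > 5], rep("good", sum(t > 5)))
  expect_identical(lab[t <= 5 & e == 1], rep("poor", sum(t <= 5 & e == 1)))
})
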