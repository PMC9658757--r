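#' Expression dataset container
#'
#' A `pcmt_dataset` bundles a numeric samples-by-genes expression matrix with
#' aligned per-sample annotations: a binary outcome label (1 = poor /
#' metastatic, the positive class throughout the package; 0 = good), an
#' optional molecular subtype and an optional study of origin. Every modelling
#' and evaluation function in the package takes this container.
#'
#' @param expr Numeric matrix, samples in rows, genes in columns. Row names
#'   are sample identifiers and column names are gene identifiers; both must
#'   be unique and free of missing values.
#' @param labels Binary outcome per sample (`0`/`1`), recycled names optional;
#'   length must match `nrow(expr)`.
#' @param subtypes Optional character/factor vector of per-sample subtypes.
#' @param studies Optional character/factor vector of per-sample studies.
#'
#' @return An object of class `pcmt_dataset` with elements `expr` (the
#'   matrix) and `samples` (a tibble with columns `sample_id`, `label` and,
#'   when supplied, `subtype` and `study`).
#' @export
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' d <- pcmt_dataset(x, labels = c(0, 1, 0))
#' d
pcmt_dataset <- function(expr, labels, subtypes = NULL, studies = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix (samples x genes).")
  }
  if (is.null(rownames(expr))) rownames(expr) <- paste0("sample_", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- paste0("gene_", seq_len(ncol(expr)))
  if (anyDuplicated(rownames(expr))) abort("Duplicate sample ids in `expr` row names.")
  if (anyDuplicated(colnames(expr))) abort("Duplicate gene ids in `expr` column names.")
  if (anyNA(expr) || any(!is.finite(expr))) {
    abort("Expression matrix contains missing or non-finite values.")
  }
  labels <- as.numeric(labels)
  if (length(labels) != nrow(expr)) {
    abort(sprintf("`labels` has length %d but the matrix has %d samples.",
                  length(labels), nrow(expr)))
  }
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    abort("`labels` must be 0 (good) or 1 (poor) with no missing values.")
  }
  samples <- tibble::tibble(sample_id = rownames(expr), label = labels)
  for (nm in c("subtype", "study")) {
    v <- if (nm == "subtype") subtypes else studies
    if (!is.null(v)) {
      if (length(v) != nrow(expr)) {
        abort(sprintf("`%ss` has length %d but the matrix has %d samples.",
                      nm, length(v), nrow(expr)))
      }
      samples[[nm]] <- as.character(v)
    }
  }
  structure(list(expr = expr, samples = samples), class = "pcmt_dataset")
}

#' @export
print.pcmt_dataset <- function(x, ...) {
  cat(sprintf("<pcmt_dataset> %d samples x %d genes\n", nrow(x$expr), ncol(x$expr)))
  cat(sprintf("  poor (label 1): %d / %d\n", sum(x$samples$label), nrow(x$expr)))
  if (!is.null(x$samples[["subtype"]])) {
    cat("  subtypes:", paste(names(table(x$samples[["subtype"]])), collapse = ", "), "\n")
  }
  if (!is.null(x$samples[["study"]])) {
    cat("  studies: ", paste(names(table(x$samples[["study"]])), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname pcmt_dataset
#' @param d A `pcmt_dataset`.
#' @export
n_samples <- function(d) nrow(d$expr)

#' @rdname pcmt_dataset
#' @export
n_genes <- function(d) ncol(d$expr)

#' @rdname pcmt_dataset
#' @export
gene_ids <- function(d) colnames(d$expr)

#' @rdname pcmt_dataset
#' @export
sample_ids <- function(d) rownames(d$expr)

#' Subset a dataset by sample or gene
#'
#' @param d A `pcmt_dataset`.
#' @param samples Integer/logical index or character sample ids; `NULL` keeps all.
#' @param genes Integer/logical index or character gene ids; `NULL` keeps all.
#' @return A `pcmt_dataset` restricted to the requested samples/genes.
#' @export
filter_dataset <- function(d, samples = NULL, genes = NULL) {
  stopifnot(inherits(d, "pcmt_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(d$expr)) else samples
  gi <- if (is.null(genes)) seq_len(ncol(d$expr)) else genes
  expr <- d$expr[si, gi, drop = FALSE]
  ann <- d$samples[match(rownames(expr), d$samples$sample_id), ]
  pcmt_dataset(expr, ann$label,
               subtypes = if ("subtype" %in% names(ann)) ann$subtype,
               studies = if ("study" %in% names(ann)) ann$study)
}

#' Convert between tibbles and expression datasets
#'
#' `as_pcmt_dataset()` builds the container from a wide tibble with one row
#' per sample (annotation columns plus one numeric column per gene);
#' `as_tibble()` is the inverse.
#'
#' @param df A data frame with a sample-id column, a label column, optional
#'   subtype/study columns, and numeric gene columns.
#' @param sample_col,label_col,subtype_col,study_col Column names.
#' @return `as_pcmt_dataset()` returns a `pcmt_dataset`; the `as_tibble()`
#'   method returns a wide tibble.
#' @export
as_pcmt_dataset <- function(df, sample_col = "sample_id", label_col = "label",
                            subtype_col = NULL, study_col = NULL) {
  df <- as.data.frame(df)
  ann_cols <- c(sample_col, label_col, subtype_col, study_col)
  missing_cols <- setdiff(ann_cols, names(df))
  if (length(missing_cols)) {
    abort(paste0("Column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  gene_cols <- setdiff(names(df), ann_cols)
  expr <- as.matrix(df[, gene_cols, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- as.character(df[[sample_col]])
  pcmt_dataset(expr, df[[label_col]],
               subtypes = if (!is.null(subtype_col)) df[[subtype_col]],
               studies = if (!is.null(study_col)) df[[study_col]])
}

#' @rdname as_pcmt_dataset
#' @param x A `pcmt_dataset`.
#' @param ... Unused.
#' @export
#' @importFrom tibble as_tibble
as_tibble.pcmt_dataset <- function(x, ...) {
  dplyr::bind_cols(x$samples, tibble::as_tibble(x$expr))
}

#' Read an expression dataset from delimited text
#'
#' The expression matrix is tab-delimited with samples in rows: a header row
#' of gene ids and a first column of sample ids. Labels are a two-column
#' (`sample_id`, `label`) tab-delimited table; the optional annotation table
#' has columns `sample_id` and any of `subtype`, `study`. Sample order
#' follows the matrix file. Missing or non-numeric expression cells and
#' sample-id mismatches are rejected with the offending position/id named.
#'
#' @param matrix_path Path to the expression TSV.
#' @param labels_path Path to the label TSV.
#' @param annotations_path Optional path to the annotation TSV.
#' @return A validated `pcmt_dataset`.
#' @seealso [write_dataset()] for the inverse.
#' @export
load_dataset <- function(matrix_path, labels_path, annotations_path = NULL) {
  for (p in c(matrix_path, labels_path, annotations_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  num <- read_matrix_tsv(matrix_path)
  ids <- rownames(num)

  lab_tab <- readr::read_tsv(labels_path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(lab_tab))) {
    names(lab_tab)[1:2] <- c("sample_id", "label")
  }
  lab_tab$sample_id <- as.character(lab_tab$sample_id)
  miss <- setdiff(ids, lab_tab$sample_id)
  if (length(miss)) abort(sprintf("Sample id '%s' present in the matrix but missing from the labels file.", miss[1]))
  labels <- lab_tab$label[match(ids, lab_tab$sample_id)]

  subtypes <- studies <- NULL
  if (!is.null(annotations_path)) {
    ann <- readr::read_tsv(annotations_path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (!"sample_id" %in% names(ann)) names(ann)[1] <- "sample_id"
    miss <- setdiff(ids, ann$sample_id)
    if (length(miss)) abort(sprintf("Sample id '%s' present in the matrix but missing from the annotations file.", miss[1]))
    ann <- ann[match(ids, ann$sample_id), ]
    if ("subtype" %in% names(ann)) subtypes <- ann$subtype
    if ("study" %in% names(ann)) studies <- ann$study
  }
  pcmt_dataset(num, labels, subtypes = subtypes, studies = studies)
}

#' Read a samples-by-genes matrix from delimited text
#'
#' Reads just the expression matrix in the layout [load_dataset()] expects
#' (header of gene ids, first column of sample ids), validating that every
#' cell is numeric and non-missing. Useful for unlabelled test matrices.
#'
#' @param matrix_path Path to the expression TSV.
#' @return A numeric matrix with sample-id row names.
#' @export
read_matrix_tsv <- function(matrix_path) {
  if (!file.exists(matrix_path)) abort(sprintf("File not found: %s", matrix_path))
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("Expression matrix needs a sample-id column and at least one gene column.")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) abort("Duplicate sample ids in the matrix file.")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Non-numeric or missing expression value at sample '%s' (row %d), gene '%s' (column %d).",
      ids[bad[1, 1]], bad[1, 1], colnames(vals)[bad[1, 2]], bad[1, 2]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write an expression dataset to delimited text
#'
#' Writes the matrix, labels and (when present) annotations in the layout
#' [load_dataset()] reads, so that a load/write cycle round-trips the numeric
#' matrix exactly (values are serialized at full double precision).
#'
#' @param d A `pcmt_dataset`.
#' @param matrix_path,labels_path Output paths.
#' @param annotations_path Optional output path for subtype/study columns.
#' @return Invisibly, `d`.
#' @export
write_dataset <- function(d, matrix_path, labels_path, annotations_path = NULL) {
  stopifnot(inherits(d, "pcmt_dataset"))
  mat_df <- tibble::as_tibble(d$expr)
  mat_df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(d$expr)), mat_df)
  # full-precision serialization so load_dataset() round-trips bit-exactly
  mat_chr <- mat_df
  for (j in seq(2, ncol(mat_chr))) mat_chr[[j]] <- sprintf("%.17g", mat_chr[[j]])
  readr::write_tsv(mat_chr, matrix_path, progress = FALSE)
  readr::write_tsv(d$samples[, c("sample_id", "label")], labels_path, progress = FALSE)
  if (!is.null(annotations_path)) {
    keep <- intersect(c("sample_id", "subtype", "study"), names(d$samples))
    readr::write_tsv(d$samples[, keep], annotations_path, progress = FALSE)
  }
  invisible(d)
}
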