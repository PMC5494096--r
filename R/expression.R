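#' Construct a two-group expression dataset
#'
#' Container for a log2 expression matrix with a case/control sample design,
#' the input to the differential-expression stage.
#'
#' @param values numeric matrix of log2 expression, features x samples, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param group character or factor of length `ncol(values)` with values
#'   `"case"` or `"control"`.
#' @return an object of class `expression_dataset`: a list with elements
#'   `values` (matrix) and `group` (factor with levels control, case).
#' @export
expression_dataset <- function(values, group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in `values`")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` length must equal the number of samples")
  if (!all(group %in% c("case", "control")))
    stop("`group` values must be 'case' or 'control'")
  tab <- table(group)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least 2 samples in each of 'case' and 'control'")
  structure(list(values = values,
                 group = factor(group, levels = c("control", "case"))),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d features x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix and its sample design from TSV files
#'
#' The expression file has a header row, a first column `feature_id` and one
#' column per sample; the design file has columns `sample_id` and `group`
#' (values `case`/`control`). GEO series-matrix text files are also accepted
#' for the expression table: comment lines prefixed `!` are skipped.
#'
#' @param expr_file path to the expression TSV.
#' @param design_file path to the design TSV.
#' @return an [expression_dataset()].
#' @export
read_expression_tsv <- function(expr_file, design_file) {
  expr <- utils::read.delim(expr_file, sep = "\t", header = TRUE,
                            comment.char = "!", check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2L) stop("expression file needs a feature column and >=1 sample")
  feats <- as.character(expr[[1L]])
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- feats
  design <- read_tsv(design_file)
  if (!all(c("sample_id", "group") %in% names(design)))
    stop("design file must have columns 'sample_id' and 'group'")
  missing <- setdiff(colnames(mat), design$sample_id)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  grp <- design$group[match(colnames(mat), design$sample_id)]
  expression_dataset(mat, grp)
}

#' Write an expression dataset to expression + design TSV files
#'
#' @param data an [expression_dataset()].
#' @param expr_file,design_file output paths.
#' @return invisibly, the two paths.
#' @export
write_expression_tsv <- function(data, expr_file, design_file) {
  df <- data.frame(feature_id = rownames(data$values),
                   data$values, check.names = FALSE)
  write_tsv(df, expr_file)
  write_tsv(data.frame(sample_id = colnames(data$values),
                       group = as.character(data$group)), design_file)
  invisible(c(expr_file, design_file))
}

#' Quantile-normalize an expression dataset
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of the per-rank values. Ties within a column
#' receive the mean of the reference values across the tied rank span. With
#' a single sample the data are returned unchanged with a warning.
#'
#' @param data an [expression_dataset()] or bare numeric matrix.
#' @return object of the same type with normalized values.
#' @export
quantile_normalize <- function(data) {
  mat <- if (inherits(data, "expression_dataset")) data$values else as.matrix(data)
  if (ncol(mat) < 2L) {
    warning("single-sample input: quantile normalization is the identity")
    return(data)
  }
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(norm) <- dimnames(mat)
  if (inherits(data, "expression_dataset")) {
    data$values <- norm
    data
  } else norm
}
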