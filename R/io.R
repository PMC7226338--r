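# Plain-text readers/writers for the pipeline's artifact formats.
# Numbers are serialised at 17 significant digits so a write/read round trip
# is bit-stable.

#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' non-negative numeric values (FPKM-like).
#'
#' @param path TSV file path.
#' @param dedupe_first if `TRUE`, duplicate gene ids keep their first row;
#'   duplicates are otherwise a hard error (silent aggregation hides data
#'   corruption).
#' @return genes x samples numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path, dedupe_first = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    if (!dedupe_first) {
      stopf("duplicate gene ids in %s (first: %s); pass dedupe_first = TRUE to keep first occurrences",
            path, genes[duplicated(genes)][1])
    }
    keep <- !duplicated(genes)
    warning(sprintf("dropped %d duplicate gene rows in %s", sum(!keep), path),
            call. = FALSE)
    df <- df[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validate_expression(mat)
  mat
}

#' Write a gene expression matrix as TSV
#' @param mat genes x samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat),
                   apply(mat, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel (one gene id per line)
#' @param path text file path; blank lines and `#` comments are ignored.
#' @return character vector of gene ids.
#' @export
read_panel <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) stopf("duplicate gene ids in panel %s", path)
  x
}

validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stopf("expression matrix needs gene row names and sample column names")
  }
  if (anyNA(mat)) stopf("expression matrix contains missing values")
  if (any(mat < 0)) stopf("expression values must be non-negative")
  invisible(mat)
}

# Wide matrix TSV (row label in first column).
write_matrix_tsv <- function(mat, path, row_label = "gene") {
  df <- data.frame(rownames(mat), apply(mat, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  mat
}
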