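# Plain-text readers/writers for the pipeline's tabular formats.

#' Read / write a counts matrix as TSV
#'
#' Genes are rows (first column = gene id), samples are columns. Lines
#' starting with `#` are treated as comments.
#'
#' @param path file path.
#' @return integer/numeric matrix with gene-id rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0, na.rm = TRUE)) .stop("negative counts in ", path)
  m
}

#' @rdname read_counts
#' @param mat matrix to write.
#' @param header optional comment lines (written prefixed with `#`).
#' @export
write_counts <- function(mat, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  utils::write.table(mat, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read counts from MatrixMarket triplet files
#'
#' @param mtx path to the `.mtx` file.
#' @param rows,cols paths to plain-text files with one gene / sample id per
#'   line.
#' @return dense integer matrix with dimnames.
#' @export
read_counts_mtx <- function(mtx, rows, cols) {
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(rows)
  colnames(m) <- readLines(cols)
  if (any(m < 0)) .stop("negative counts in ", mtx)
  m
}

#' @rdname read_counts_mtx
#' @param mat matrix to write.
#' @export
write_counts_mtx <- function(mat, mtx, rows, cols) {
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), mtx)
  writeLines(rownames(mat), rows)
  writeLines(colnames(mat), cols)
  invisible(mtx)
}

#' Read / write a sample metadata table
#'
#' Requires columns `sample_id`, `genotype`, `sex`, `age_cohort`, `batch`;
#' the `haplotype_group` column is derived (and checked if present).
#' @param path file path.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  .check_samples(df)
}

#' @rdname read_samples
#' @param samples sample table.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an exon count table
#'
#' Format: columns `gene_id`, `feature_id`, then one column per sample.
#' @param path file path.
#' @export
read_exon_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("gene_id", "feature_id") %in% names(df)))
    .stop("exon count table needs gene_id and feature_id columns")
  class(df) <- c("exon_count_table", "data.frame")
  df
}

#' @rdname read_exon_counts
#' @param table exon count table.
#' @export
write_exon_counts <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an ortholog table
#'
#' First two columns are the two species' gene ids; an optional
#' `homology_type` column is carried along.
#' @param path file path.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) .stop("ortholog table needs at least two id columns")
  names(df)[1:2] <- c("gene_a", "gene_b")
  df
}
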