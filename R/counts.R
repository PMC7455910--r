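#' Validate a gene-by-sample count matrix
#'
#' Checks the invariants every downstream step relies on: an integer-valued
#' matrix with no negative or missing entries and unique, non-empty gene and
#' sample identifiers. Pre-normalized (non-integer) matrices are rejected
#' because both the negative binomial likelihood and median-of-ratios size
#' factors assume raw counts.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @return the validated matrix, invisibly coerced to storage mode double.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  if (nrow(counts) == 0 && is.null(rownames(counts)))
    rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative count for gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  nonint <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint) > 0)
    stop(sprintf(
      "non-integer count for gene '%s', sample '%s'; raw counts are required",
      rownames(counts)[nonint[1, 1]], colnames(counts)[nonint[1, 2]]))
  storage.mode(counts) <- "double"
  counts
}

#' Read a count matrix from TSV, CSV or MatrixMarket files
#'
#' TSV/CSV files have genes as rows, a header of sample ids and the gene id in
#' the first column. MatrixMarket (`format = "mtx"`) input expects two
#' companion files next to `path`: `<path>.rownames` and `<path>.colnames`
#' with one gene / sample id per line.
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`; default guessed from the
#'   file extension.
#' @return validated count matrix (genes x samples) in file order.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("MatrixMarket id files do not match the matrix dimensions")
    dimnames(m) <- list(rn, cn)
    return(validate_counts(m))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("parse error: expected gene id column plus counts in ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("parse error: non-numeric count near line ",
         if (length(bad)) bad[1] + 1L else "?", " of ", path)
  }
  rownames(m) <- ids
  validate_counts(m)
}

#' Write a count matrix as TSV, CSV or MatrixMarket
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f), ...)` returns
#' an identical matrix.
#'
#' @param counts validated count matrix.
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  counts <- validate_counts(counts)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and align sample metadata
#'
#' The metadata table must contain a sample id column and a subject id column
#' (the clustering variable). Rows are aligned to the count matrix column
#' order; metadata rows for samples absent from the counts are dropped, and an
#' error lists any count-matrix sample missing from the metadata.
#'
#' @param path TSV file, or a data.frame already in memory.
#' @param counts validated count matrix whose columns define sample order.
#' @param sample_col,subject_col column names for sample and subject ids.
#' @return data.frame with one row per count-matrix sample, in column order,
#'   with columns `sample_id`, `subject_id` and all remaining covariates.
#' @export
read_metadata <- function(path, counts, sample_col = "sample_id",
                          subject_col = "subject_id") {
  md <- if (is.data.frame(path)) path else
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
  for (cc in c(sample_col, subject_col))
    if (!cc %in% names(md)) stop("metadata lacks required column '", cc, "'")
  md[[sample_col]] <- as.character(md[[sample_col]])
  if (anyDuplicated(md[[sample_col]]))
    stop("duplicated sample ids in metadata")
  missing <- setdiff(colnames(counts), md[[sample_col]])
  if (length(missing) > 0)
    stop("samples present in counts but missing from metadata: ",
         paste(missing, collapse = ", "))
  md <- md[match(colnames(counts), md[[sample_col]]), , drop = FALSE]
  out <- data.frame(sample_id = md[[sample_col]],
                    subject_id = as.character(md[[subject_col]]),
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(md), c(sample_col, subject_col))
  for (cc in extra) out[[cc]] <- md[[cc]]
  rownames(out) <- NULL
  out
}
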