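#' Median-of-ratios size factors and log offsets
#'
#' Size factor for sample s is the median over reference genes of
#' `counts[g, s] / geometric_mean(counts[g, ])`, the median-of-ratios
#' normalization popularized by the DESeq family. Genes with any zero count
#' are excluded from the reference set. The natural log of the size factor is
#' the per-sample offset entering the model's linear predictor.
#'
#' @param counts validated count matrix.
#' @return list with `size_factors`, `offsets` (= `log(size_factors)`) and
#'   `library_sizes` (raw column sums), each named by sample.
#' @export
median_of_ratios_size_factors <- function(counts) {
  counts <- validate_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has strictly positive counts in every sample; ",
         "filter genes or supply offsets computed from a pseudo-reference")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(lc) exp(stats::median(lc - loggeo)))
  list(size_factors = sf, offsets = log(sf),
       library_sizes = colSums(counts))
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / library_size[s] * 1e6` with library size the
#' raw column sum.
#'
#' @param counts validated count matrix.
#' @return G x S matrix of CPM values.
#' @export
cpm <- function(counts) {
  counts <- validate_counts(counts)
  libs <- colSums(counts)
  zero <- which(libs == 0)
  if (length(zero) > 0)
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, libs, "/") * 1e6
}

#' Low-expression filter
#'
#' Keeps a gene iff its CPM exceeds 1 (strictly) in at least `m` samples,
#' with CPM computed on the unfiltered matrix. `m` is conventionally the
#' number of samples in the smallest experimental unit of interest
#' ([smallest_unit_size()]).
#'
#' @param counts validated count matrix.
#' @param m minimum number of samples with CPM > 1.
#' @return list with `counts` (the filtered matrix) and `keep` (named logical
#'   mask over the input genes).
#' @export
filter_low_expression <- function(counts, m) {
  counts <- validate_counts(counts)
  if (m > ncol(counts)) stop("m cannot exceed the number of samples")
  keep <- rowSums(cpm(counts) > 1) >= m
  list(counts = counts[keep, , drop = FALSE], keep = keep)
}

#' Size of the smallest experimental unit
#'
#' Minimum number of samples over the cross-classification of the given
#' metadata columns; empty cells are ignored.
#'
#' @param metadata aligned metadata.
#' @param unit_columns character vector of metadata column names; empty
#'   vector returns the total sample count.
#' @return positive integer.
#' @export
smallest_unit_size <- function(metadata, unit_columns) {
  miss <- setdiff(unit_columns, names(metadata))
  if (length(miss) > 0)
    stop("unit columns not in metadata: ", paste(miss, collapse = ", "))
  if (length(unit_columns) == 0) return(nrow(metadata))
  tab <- table(metadata[unit_columns])
  min(tab[tab > 0])
}
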