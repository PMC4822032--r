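#' Median-of-ratios size factors
#'
#' Computes one scale factor per sample: the median, over genes with
#' strictly positive counts in every sample, of the ratio of the gene's
#' count in that sample to its geometric mean across all samples. This is
#' the median-of-ratios estimator used throughout count-based differential
#' expression analysis.
#'
#' @param counts Gene-by-sample matrix of non-negative counts.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- unclass(counts)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no gene has positive counts in all samples; ",
         "pre-filter the table or supply normalized counts")
  s <- apply(counts[usable, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - log_geo[usable]))
  })
  if (any(!is.finite(s) | s <= 0))
    stop("size factor estimation failed (non-positive factor)")
  unname(s)
}

#' Scale counts by size factors
#'
#' @param counts Gene-by-sample matrix.
#' @param s Size factors, one per column.
#' @return Real-valued matrix of normalized counts `K[g, i] / s[i]`.
#' @export
apply_normalization <- function(counts, s) {
  counts <- unclass(counts)
  attr(counts, "assay") <- NULL
  if (length(s) != ncol(counts))
    stop("length of size factors must match number of samples")
  sweep(counts, 2L, s, "/")
}
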