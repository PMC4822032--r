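#' Read a gene-by-sample count table
#'
#' Reads a tab-separated count table (first column gene identifiers, header
#' row of sample names, remaining cells non-negative integer read counts)
#' into a `count_matrix`.
#'
#' @param path Path to a TSV file.
#' @param assay Assay label, one of `"mRNA"` or `"RPF"`.
#' @return A `count_matrix`: an integer matrix with gene ids as rownames,
#'   sample names as colnames, and an `assay` attribute.
#' @export
read_counts <- function(path, assay = c("mRNA", "RPF")) {
  assay <- match.arg(assay)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("count table must have a gene-id column plus at least one sample column")
  gene_ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gene_ids
  count_matrix(mat, assay = assay)
}

#' Construct and validate a count matrix
#'
#' @param counts Numeric matrix of non-negative integers, gene ids as
#'   rownames, sample names as colnames.
#' @param assay Assay label (`"mRNA"` or `"RPF"`).
#' @return Validated `count_matrix` (integer storage).
#' @export
count_matrix <- function(counts, assay = c("mRNA", "RPF")) {
  assay <- match.arg(assay)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("count matrix requires gene ids as rownames")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-integer or negative count at gene '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1L, 1L]],
      colnames(counts)[bad[1L, 2L]] %||% as.character(bad[1L, 2L]),
      format(counts[bad[1L, , drop = FALSE]])))
  }
  dup <- duplicated(rownames(counts))
  if (any(dup))
    stop("duplicate gene ids in count table: ",
         paste(unique(rownames(counts)[dup]), collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(counts, assay = assay, class = c("count_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a count matrix to TSV
#'
#' @param counts A `count_matrix` (or any matrix with gene rownames).
#' @param path Output file path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(unclass(counts)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a two-condition sample design
#'
#' @param condition Character or factor vector of condition labels, one per
#'   sample, with exactly two levels; the first level (or `ref`) is the
#'   reference condition.
#' @param samples Optional sample names (defaults to names of `condition`).
#' @param ref Optional reference condition label.
#' @return A `sample_design` list with `condition`, `samples`, and the 0/1
#'   covariate vector `x` (1 = second condition).
#' @export
sample_design <- function(condition, samples = NULL, ref = NULL) {
  if (is.null(samples)) samples <- names(condition)
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(lev) != 2L)
    stop("design must contain exactly two conditions, got: ",
         paste(lev, collapse = ", "))
  if (!is.null(ref)) {
    if (!ref %in% lev) stop("ref condition not present in design")
    lev <- c(ref, setdiff(lev, ref))
  }
  x <- as.integer(condition == lev[2L])
  if (sum(x == 0L) == 0L || sum(x == 1L) == 0L)
    stop("both conditions must have at least one sample")
  structure(list(condition = condition, samples = samples,
                 levels = lev, x = x),
            class = "sample_design")
}

#' Match paired count matrices against a design
#'
#' Intersects the gene sets of the mRNA and RPF matrices (preserving the
#' mRNA input order), matches columns to the design samples, and flags
#' genes whose mean normalized count falls below `min_mean_count` in either
#' assay as untested. Filtered genes receive empty (NA) rows in results
#' rather than zeros.
#'
#' @param mrna,rpf `count_matrix` objects for the two assays.
#' @param design A `sample_design`. When sample names are available in both
#'   the matrices and the design, columns are matched by name; otherwise
#'   positional order is assumed.
#' @param min_mean_count Minimum mean normalized count required in both
#'   assays for a gene to be tested (default 1; removes all-zero
#'   degeneracies).
#' @param normalized Set `TRUE` when the tables are pre-normalized; size
#'   factors are then fixed at 1.
#' @return A list with reordered `mrna`, `rpf`, `design`, per-assay size
#'   factors, and the logical vector `tested`.
#' @export
validate_pair <- function(mrna, rpf, design, min_mean_count = 1,
                          normalized = FALSE) {
  genes <- intersect(rownames(mrna), rownames(rpf))
  if (length(genes) == 0L) stop("mRNA and RPF tables share no gene ids")
  mrna <- mrna[genes, , drop = FALSE]
  rpf <- rpf[genes, , drop = FALSE]
  if (ncol(mrna) != length(design$x) || ncol(rpf) != length(design$x))
    stop("number of samples differs between count tables and design")
  reorder_cols <- function(m) {
    if (!is.null(colnames(m)) && !is.null(design$samples) &&
        all(design$samples %in% colnames(m)))
      m[, design$samples, drop = FALSE]
    else m
  }
  mrna <- reorder_cols(mrna)
  rpf <- reorder_cols(rpf)
  if (normalized) {
    s_mrna <- rep(1, ncol(mrna))
    s_rpf <- rep(1, ncol(rpf))
  } else {
    s_mrna <- size_factors_median_of_ratios(mrna)
    s_rpf <- size_factors_median_of_ratios(rpf)
  }
  norm_mean <- function(m, s) rowMeans(sweep(unclass(m), 2L, s, "/"))
  tested <- norm_mean(mrna, s_mrna) >= min_mean_count &
    norm_mean(rpf, s_rpf) >= min_mean_count
  list(mrna = count_matrix(unclass(mrna), assay = "mRNA"),
       rpf = count_matrix(unclass(rpf), assay = "RPF"),
       design = design, s_mrna = s_mrna, s_rpf = s_rpf, tested = tested)
}

#' Write a differential-translation result table to TSV
#'
#' @param results A `delta_te` result object or its data frame.
#' @param path Output file path.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path TSV file path.
#' @return A data frame with the result columns.
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
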