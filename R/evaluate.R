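#' ROC and precision-recall evaluation of caller scores
#'
#' Sweeps thresholds over the unique scores, returning ROC points
#' (FPR, TPR), precision-recall points, and the area under the ROC curve
#' computed by the rank statistic (Mann-Whitney; ties rank-averaged,
#' equivalent to the trapezoid rule over the tied block).
#'
#' @param scores Per-gene score, larger = more confident positive call
#'   (e.g. `-log10(p)`).
#' @param labels Logical or 0/1 truth labels.
#' @return An `evaluation_result`: `roc_points`, `pr_points`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC evaluation needs at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # one point per unique threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]; fp <- cumsum(!l)[last]
  roc <- data.frame(fpr = c(0, fp / n_neg, 1), tpr = c(0, tp / n_pos, 1))
  pr <- data.frame(recall = tp / n_pos, precision = tp / (tp + fp))
  r <- rank(scores)  # ties averaged
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(roc_points = roc, pr_points = pr, auc = auc),
            class = "evaluation_result")
}

#' Ranking score from a result table
#'
#' `-log10` of the final p-value, with ties broken by the magnitude of
#' the translational log2 fold change; untested genes score `-Inf`.
#'
#' @param results A `delta_te` object or its data frame.
#' @return Numeric score per gene.
#' @export
ranking_score <- function(results) {
  df <- as.data.frame(results)
  p <- pmax(df$pvalue_final, 1e-300)
  score <- -log10(p) + 1e-9 * pmin(abs(df$delta_log2), 100)
  score[is.na(df$pvalue_final)] <- -Inf
  score
}

#' Sample-shuffling permutation control
#'
#' Builds condition-permuted designs by swapping the first
#' reference-condition sample with each treatment sample in turn (for a
#' 2 vs 2 design this yields the two distinct shuffled comparisons) and
#' reruns the full analysis on each. Shuffled designs should, in theory,
#' yield no significant differential translation.
#'
#' @param mrna,rpf `count_matrix` objects.
#' @param design A [sample_design()] with at least 2 samples per
#'   condition.
#' @param ... Passed to [delta_te()].
#' @return Named list of `delta_te` results, one per permuted design.
#' @export
permutation_run <- function(mrna, rpf, design, ...) {
  i1 <- which(design$x == 0L)
  i2 <- which(design$x == 1L)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("sample shuffling requires >= 2 samples per condition")
  out <- list()
  for (j in seq_along(i2)) {
    cond <- design$condition
    cond[i1[1L]] <- design$levels[2L]
    cond[i2[j]] <- design$levels[1L]
    perm_design <- sample_design(cond, samples = design$samples,
                                 ref = design$levels[1L])
    nm <- sprintf("swap_%s_%s", design$samples[i1[1L]] %||% i1[1L],
                  design$samples[i2[j]] %||% i2[j])
    out[[nm]] <- delta_te(mrna, rpf, perm_design, ...)
  }
  out
}
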