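#' Joint probability matrix of two discrete posteriors
#'
#' Outer product of two distributions on one shared grid. Row `i`,
#' column `j` carries `p1[i] * p2[j]`; the implied effect difference is
#' `grid[i] - grid[j]` (axis 1 minus axis 2). Intended for inspection and
#' for validating the marginal-based fast paths at small grid sizes; the
#' gene loop never materializes the full matrix.
#'
#' @param p1,p2 Probability vectors on the same grid.
#' @param grid The shared grid values.
#' @return A `joint_matrix`: the dense matrix with the grid attached.
#' @export
joint_matrix <- function(p1, p2, grid) {
  if (length(p1) != length(p2) || length(p1) != length(grid))
    stop("joint_matrix requires both distributions on one shared grid")
  structure(outer(p1, p2), grid = grid, class = c("joint_matrix", "matrix", "array"))
}

#' Two-sided p-value from a joint probability matrix
#'
#' Twice the smaller of the lower- and upper-triangle sums, where the
#' main diagonal (difference exactly zero) is counted in both one-sided
#' sums, and the result is capped at 1.
#'
#' @param jm A [joint_matrix()].
#' @return Two-sided p-value in (0, 1].
#' @export
pvalue_from_joint <- function(jm) {
  n <- nrow(jm)
  idx <- row(jm) - col(jm)
  p_le <- sum(jm[idx <= 0])  # delta <= 0, diagonal included
  p_ge <- sum(jm[idx >= 0])
  min(1, 2 * max(min(p_le, p_ge), 1e-300))
}

# Fast path: identical result via cumulative sums of the marginals
# (the matrix is rank-1, so triangle sums collapse to O(n)).
pvalue_from_marginals <- function(p1, p2) {
  c1 <- cumsum(p1)
  p_le <- sum(p2 * c1)                    # i <= j
  p_ge <- sum(p2 * (1 - c(0, c1[-length(c1)])))  # i >= j
  min(1, 2 * max(min(p_le, p_ge), 1e-300))
}

#' Distribution of the effect difference from a joint matrix
#'
#' Sums the joint matrix along diagonals parallel to the main diagonal,
#' yielding the discrete distribution of `delta = axis1 - axis2` on a
#' grid with the same step.
#'
#' @param jm A [joint_matrix()].
#' @param gamma Credible level for the equal-tailed interval.
#' @return A `delta_distribution`: `delta_grid`, `probs`, `pvalue`,
#'   `point_estimate`, `ci`, `gamma`.
#' @export
delta_distribution <- function(jm, gamma = 0.95) {
  n <- nrow(jm)
  grid <- attr(jm, "grid")
  step <- grid[2L] - grid[1L]
  d <- row(jm) - col(jm)
  probs <- vapply(-(n - 1L):(n - 1L),
                  function(dd) sum(jm[d == dd]), numeric(1))
  build_delta(probs, step, gamma, pvalue_from_joint(jm))
}

# Fast path: the anti-diagonal sums are the cross-correlation of the two
# marginals, computed by FFT. FFT round-off (~1e-16 absolute) is clipped;
# it is far below the 2.5% tail masses the credible interval uses, and
# the p-value always comes from the exact cumulative-sum path.
delta_from_marginals <- function(p1, p2, step, gamma = 0.95) {
  n <- length(p1)
  len <- 2L * n - 1L
  # cross-correlation sum_i p1[i] p2[i - d] by FFT, zero-padded to a
  # 2-3-5-smooth length (a prime-length transform is orders slower)
  nfft <- stats::nextn(len, c(2L, 3L, 5L))
  f <- Re(stats::fft(stats::fft(c(p1, numeric(nfft - n))) *
                     Conj(stats::fft(c(p2, numeric(nfft - n)))),
                     inverse = TRUE)) / nfft
  d <- -(n - 1L):(n - 1L)
  probs <- f[(d %% nfft) + 1L]
  probs[probs < 0] <- 0
  probs <- probs / sum(probs)
  build_delta(probs, step, gamma, pvalue_from_marginals(p1, p2))
}

build_delta <- function(probs, step, gamma, pvalue) {
  n_half <- (length(probs) + 1L) %/% 2L
  delta_grid <- (seq_along(probs) - n_half) * step
  probs <- probs / sum(probs)
  ci <- credible_interval_probs(probs, delta_grid, gamma)
  structure(list(delta_grid = delta_grid, probs = probs, pvalue = pvalue,
                 point_estimate = delta_grid[which.max(probs)],
                 ci = ci, gamma = gamma),
            class = "delta_distribution")
}

credible_interval_probs <- function(probs, grid, gamma) {
  if (!(gamma > 0 && gamma < 1)) stop("credible level must be in (0, 1)")
  tail <- (1 - gamma) / 2
  cdf <- cumsum(probs)
  below <- c(0, cdf[-length(cdf)])       # P(delta < grid[i])
  above <- 1 - cdf                       # P(delta > grid[i])
  lo <- max(which(below <= tail + 1e-12))
  hi <- min(which(above <= tail + 1e-12))
  c(grid[lo], grid[max(lo, hi)])
}

#' Equal-tailed credible interval of a delta distribution
#'
#' Smallest grid interval whose tail masses are each at most
#' `(1 - gamma) / 2`.
#'
#' @param dd A `delta_distribution`.
#' @param gamma Credible level in (0, 1).
#' @return `c(lower, upper)` in log2 units.
#' @export
credible_interval <- function(dd, gamma = dd$gamma) {
  credible_interval_probs(dd$probs, dd$delta_grid, gamma)
}

#' Merge the two pipeline results for one gene
#'
#' The final call is the more conservative sub-pipeline: the one with the
#' larger p-value. Ties go to the fold-change pipeline (fixed,
#' deterministic tie-break). If one pipeline failed, the other is used.
#'
#' @param fc_result,r_result `delta_distribution` objects (or NULL for a
#'   failed pipeline).
#' @return List with `pvalue`, `point_estimate`, `ci`, `pipeline_used`.
#' @export
merge_pipelines <- function(fc_result, r_result) {
  if (is.null(fc_result) && is.null(r_result)) return(NULL)
  if (is.null(r_result) || (!is.null(fc_result) &&
                            fc_result$pvalue >= r_result$pvalue)) {
    chosen <- fc_result; used <- "FC"
  } else {
    chosen <- r_result; used <- "R"
  }
  list(pvalue = chosen$pvalue, point_estimate = chosen$point_estimate,
       ci = chosen$ci, pipeline_used = used)
}

#' Benjamini-Hochberg adjustment over tested genes
#'
#' @param pvalues Raw p-values; NA entries (untested genes) are excluded
#'   from the number of tests and returned as NA.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Genome-wide differential translation analysis
#'
#' Runs the full two-pipeline analysis: median-of-ratios normalization
#' (unless `normalized = TRUE`), per-assay empirical-Bayes dispersion
#' estimation, per-gene grid posteriors of the log2 fold changes of mRNA
#' and RPF and of the within-condition log2 RPF-to-mRNA ratios, joint
#' probability tests of the translational log2 fold change
#' (delta = log2FC(RPF) - log2FC(mRNA), equivalently
#' log2R(C2) - log2R(C1)), selection of the more conservative pipeline
#' per gene, and Benjamini-Hochberg adjustment.
#'
#' @param mrna,rpf `count_matrix` objects (raw counts unless
#'   `normalized = TRUE`).
#' @param design A [sample_design()]; the second condition level is the
#'   treatment (positive delta = translation up in condition 2).
#' @param normalized Inputs are pre-normalized; skip size factors.
#' @param min_mean_count Mean normalized count required in both assays.
#' @param n_bins Grid size for posterior distributions (default 10000).
#' @param ci_level Credible level gamma (default 0.95).
#' @param profile_phi Profile the baseline intercept (default) or plug in.
#' @param joint_normalization Pool mRNA and RPF columns when estimating
#'   size factors (default: each assay separately).
#' @param blind_dispersion Force pooling conditions for dispersion
#'   estimation; default NULL chooses blind only for single-replicate
#'   designs.
#' @param verbose Print progress messages.
#' @return A `delta_te` object; `as.data.frame()` yields the per-gene
#'   result table.
#' @export
delta_te <- function(mrna, rpf, design, normalized = FALSE,
                     min_mean_count = 1, n_bins = 10000L, ci_level = 0.95,
                     profile_phi = TRUE, joint_normalization = FALSE,
                     blind_dispersion = NULL, verbose = FALSE) {
  vp <- validate_pair(mrna, rpf, design, min_mean_count = min_mean_count,
                      normalized = normalized)
  if (joint_normalization && !normalized) {
    s_all <- size_factors_median_of_ratios(
      cbind(unclass(vp$mrna), unclass(vp$rpf)))
    vp$s_mrna <- s_all[seq_len(ncol(vp$mrna))]
    vp$s_rpf <- s_all[-seq_len(ncol(vp$mrna))]
  }
  design <- vp$design
  if (verbose)
    message("size factors mRNA: ", paste(round(vp$s_mrna, 4), collapse = " "),
            "; RPF: ", paste(round(vp$s_rpf, 4), collapse = " "))
  disp_mrna <- estimate_dispersions(vp$mrna, vp$s_mrna, design,
                                    blind = blind_dispersion)
  disp_rpf <- estimate_dispersions(vp$rpf, vp$s_rpf, design,
                                   blind = blind_dispersion)
  genes <- rownames(vp$mrna)
  n_genes <- length(genes)
  idx1 <- design$x == 0L
  idx2 <- design$x == 1L

  na_row <- list(log2fc_mrna = NA_real_, log2fc_rpf = NA_real_,
                 log2r_c1 = NA_real_, log2r_c2 = NA_real_,
                 delta_log2 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 pvalue_fc = NA_real_, pvalue_r = NA_real_,
                 pvalue_final = NA_real_, pipeline_used = NA_character_)

  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    if (!vp$tested[g] || !is.finite(disp_mrna$shrunk[g]) ||
        !is.finite(disp_rpf$shrunk[g])) {
      rows[[g]] <- na_row
      next
    }
    km <- as.numeric(vp$mrna[g, ]); kr <- as.numeric(vp$rpf[g, ])
    am <- disp_mrna$shrunk[g]; ar <- disp_rpf$shrunk[g]
    fc_res <- tryCatch({
      post_m <- log2fc_posterior(km, vp$s_mrna, design, am,
                                 n_bins = n_bins, profile_phi = profile_phi,
                                 eval_grid = FALSE)
      post_r <- log2fc_posterior(kr, vp$s_rpf, design, ar,
                                 n_bins = n_bins, profile_phi = profile_phi,
                                 eval_grid = FALSE)
      sg <- shared_grid(post_r, post_m, n_bins)   # delta = FC(RPF) - FC(mRNA)
      dd <- delta_from_marginals(sg$p1, sg$p2, sg$step, ci_level)
      list(dd = dd, fc_mrna = post_m$mle, fc_rpf = post_r$mle)
    }, error = function(e) NULL)
    r_res <- tryCatch({
      post_c1 <- log2r_posterior(km[idx1], kr[idx1], vp$s_mrna[idx1],
                                 vp$s_rpf[idx1], am, ar, n_bins = n_bins,
                                 profile_phi = profile_phi, eval_grid = FALSE)
      post_c2 <- log2r_posterior(km[idx2], kr[idx2], vp$s_mrna[idx2],
                                 vp$s_rpf[idx2], am, ar, n_bins = n_bins,
                                 profile_phi = profile_phi, eval_grid = FALSE)
      sg <- shared_grid(post_c2, post_c1, n_bins)  # delta = R(C2) - R(C1)
      dd <- delta_from_marginals(sg$p1, sg$p2, sg$step, ci_level)
      list(dd = dd, r_c1 = post_c1$mle, r_c2 = post_c2$mle)
    }, error = function(e) NULL)
    merged <- merge_pipelines(if (is.null(fc_res)) NULL else fc_res$dd,
                              if (is.null(r_res)) NULL else r_res$dd)
    if (is.null(merged)) {
      rows[[g]] <- na_row
      next
    }
    rows[[g]] <- list(
      log2fc_mrna = if (is.null(fc_res)) NA_real_ else fc_res$fc_mrna,
      log2fc_rpf = if (is.null(fc_res)) NA_real_ else fc_res$fc_rpf,
      log2r_c1 = if (is.null(r_res)) NA_real_ else r_res$r_c1,
      log2r_c2 = if (is.null(r_res)) NA_real_ else r_res$r_c2,
      delta_log2 = merged$point_estimate,
      ci_low = merged$ci[1L], ci_high = merged$ci[2L],
      pvalue_fc = if (is.null(fc_res)) NA_real_ else fc_res$dd$pvalue,
      pvalue_r = if (is.null(r_res)) NA_real_ else r_res$dd$pvalue,
      pvalue_final = merged$pvalue,
      pipeline_used = merged$pipeline_used)
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  tab <- data.frame(gene_id = genes, tab, stringsAsFactors = FALSE)
  tab$padj <- bh_adjust(tab$pvalue_final)
  structure(list(table = tab, design = design, s_mrna = vp$s_mrna,
                 s_rpf = vp$s_rpf, dispersion_mrna = disp_mrna,
                 dispersion_rpf = disp_rpf, tested = vp$tested,
                 options = list(n_bins = n_bins, ci_level = ci_level,
                                min_mean_count = min_mean_count,
                                profile_phi = profile_phi)),
            class = "delta_te")
}

#' @export
as.data.frame.delta_te <- function(x, ...) x$table

#' @export
print.delta_te <- function(x, ...) {
  n_tested <- sum(!is.na(x$table$pvalue_final))
  cat("differential translation analysis\n")
  cat(sprintf("  genes: %d (%d tested)\n", nrow(x$table), n_tested))
  cat(sprintf("  conditions: %s vs %s\n", x$design$levels[1L],
              x$design$levels[2L]))
  cat(sprintf("  genes at padj < 0.1: %d\n",
              sum(x$table$padj < 0.1, na.rm = TRUE)))
  invisible(x)
}
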