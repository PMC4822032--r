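#' Simulation configuration
#'
#' Defines the study conditions for the synthetic ribosome-profiling
#' benchmark: a fraction of genes (10-20%) receives artificial fold
#' changes larger than 1.5, sampled as `1.5 + Gamma(shape 0.6, scale
#' 0.5)`; true positives are genes whose RPF and mRNA counts receive
#' different fold changes, true negatives receive none or the same fold
#' change in both assays.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition (1, 2, or 3).
#' @param spike_fraction Fraction of genes given fold changes; default
#'   drawn uniformly in `[0.10, 0.20]`.
#' @param gamma_shape,gamma_scale Gamma law of the fold-change excess
#'   above the 1.5 floor.
#' @param equal_change_fraction Fraction of the unspiked genes given the
#'   SAME fold change in both assays (transcription-only regulation;
#'   true negatives for differential translation).
#' @param log10_mean,log10_sd Log-normal law of baseline mean counts.
#' @param trend_a0,trend_a1 Dispersion trend `a0 + a1 / mu`.
#' @param disp_noise_sd Log-normal scatter of true dispersions around the
#'   trend (natural-log sd).
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000L, n_replicates = 2L,
                       spike_fraction = NULL, gamma_shape = 0.6,
                       gamma_scale = 0.5, equal_change_fraction = 0.05,
                       log10_mean = 2, log10_sd = 0.8,
                       trend_a0 = 0.01, trend_a1 = 2, disp_noise_sd = 0.3,
                       seed) {
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  if (!n_replicates %in% 1:3) stop("n_replicates must be 1, 2, or 3")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 spike_fraction = spike_fraction, gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale,
                 equal_change_fraction = equal_change_fraction,
                 log10_mean = log10_mean, log10_sd = log10_sd,
                 trend_a0 = trend_a0, trend_a1 = trend_a1,
                 disp_noise_sd = disp_noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw per-gene baseline means and dispersions
#'
#' Means are log-normal (log10 scale); true dispersions follow the trend
#' `a0 + a1 / mu` multiplied by log-normal noise, emulating the
#' mean-dispersion relationship of bulk ribosome-profiling counts.
#'
#' @param config A [sim_config()].
#' @return Data frame with `gene_id`, `mean_mrna`, `mean_rpf`,
#'   `disp_mrna`, `disp_rpf`.
#' @export
simulate_baseline <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  draw_means <- function() 10^stats::rnorm(n, config$log10_mean, config$log10_sd)
  draw_disp <- function(mu)
    (config$trend_a0 + config$trend_a1 / mu) *
      exp(stats::rnorm(n, 0, config$disp_noise_sd))
  mean_mrna <- draw_means()
  # RPF abundance tracks mRNA with gene-specific translational efficiency
  mean_rpf <- mean_mrna * 2^stats::rnorm(n, 0, 0.5)
  data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
             mean_mrna = mean_mrna, mean_rpf = mean_rpf,
             disp_mrna = draw_disp(mean_mrna),
             disp_rpf = draw_disp(mean_rpf),
             stringsAsFactors = FALSE)
}

#' Assign artificial fold changes and truth labels
#'
#' A `spike_fraction` of genes is selected uniformly and split equally
#' among the three true-positive categories (RPF-only, mRNA-only, both
#' assays with different fold changes). Among the remaining genes, an
#' `equal_change_fraction` receives the same fold change in both assays
#' (transcription-only regulation: a true negative for differential
#' translation). Each assigned fold change is `1.5 + Gamma(shape,
#' scale)`; direction (up or down, i.e. FC or 1/FC) is drawn per gene
#' with equal probability.
#'
#' @param config A [sim_config()].
#' @param gene_ids Gene identifiers.
#' @return A `truth_table` data frame: `gene_id`, `category`, `fc_mrna`,
#'   `fc_rpf` (multiplicative, >= 1), `direction`.
#' @export
assign_fold_changes <- function(config, gene_ids) {
  set.seed(config$seed + 1L)
  n <- length(gene_ids)
  spike_fraction <- config$spike_fraction
  if (is.null(spike_fraction)) spike_fraction <- stats::runif(1, 0.10, 0.20)
  n_spike <- round(n * spike_fraction)
  spiked <- sample.int(n, n_spike)
  category <- rep("TN_no_change", n)
  category[spiked] <- sample(c("TP_rpf_only", "TP_mrna_only",
                               "TP_both_different"),
                             n_spike, replace = TRUE)
  unspiked <- setdiff(seq_len(n), spiked)
  n_eq <- round(length(unspiked) * config$equal_change_fraction)
  eq <- sample(unspiked, n_eq)
  category[eq] <- "TN_equal_change"
  draw_fc <- function(m)
    1.5 + stats::rgamma(m, shape = config$gamma_shape,
                        scale = config$gamma_scale)
  fc_mrna <- rep(1, n); fc_rpf <- rep(1, n)
  i <- category == "TP_rpf_only"
  fc_rpf[i] <- draw_fc(sum(i))
  i <- category == "TP_mrna_only"
  fc_mrna[i] <- draw_fc(sum(i))
  i <- category == "TP_both_different"
  # redraw until the two assays' fold changes differ (equal draws would
  # silently convert a labelled positive into a transcription-only gene)
  fc_mrna[i] <- draw_fc(sum(i))
  repeat {
    same <- i & fc_mrna == fc_rpf
    fc_rpf[i] <- draw_fc(sum(i))
    if (!any(i & fc_mrna == fc_rpf)) break
  }
  i <- category == "TN_equal_change"
  fc_mrna[i] <- draw_fc(sum(i))
  fc_rpf[i] <- fc_mrna[i]
  direction <- sample(c("up", "down"), n, replace = TRUE)
  structure(data.frame(gene_id = gene_ids, category = category,
                       fc_mrna = fc_mrna, fc_rpf = fc_rpf,
                       direction = direction, stringsAsFactors = FALSE),
            class = c("truth_table", "data.frame"))
}

#' Generate count matrices from baselines and truth labels
#'
#' Condition-1 counts are negative-binomial at the baseline mean;
#' condition-2 means are multiplied by the assigned fold change (or its
#' reciprocal for "down" genes) per assay. Size factors are 1 by
#' construction.
#'
#' @param baselines Output of [simulate_baseline()].
#' @param truth Output of [assign_fold_changes()].
#' @param config A [sim_config()].
#' @return List with `mrna`, `rpf` (`count_matrix`), and `design`.
#' @export
generate_counts <- function(baselines, truth, config) {
  set.seed(config$seed + 2L)
  n <- nrow(baselines)
  reps <- config$n_replicates
  sign_fc <- ifelse(truth$direction == "up", 1, -1)
  draw <- function(mu, disp) {
    m <- matrix(0L, n, reps)
    for (j in seq_len(reps))
      m[, j] <- stats::rnbinom(n, mu = mu, size = 1 / disp)
    m
  }
  assay_counts <- function(mean_base, disp, fc) {
    c1 <- draw(mean_base, disp)
    c2 <- draw(mean_base * fc^sign_fc, disp)
    m <- cbind(c1, c2)
    rownames(m) <- baselines$gene_id
    colnames(m) <- c(paste0("control_", seq_len(reps)),
                     paste0("treated_", seq_len(reps)))
    m
  }
  mrna <- assay_counts(baselines$mean_mrna, baselines$disp_mrna, truth$fc_mrna)
  rpf <- assay_counts(baselines$mean_rpf, baselines$disp_rpf, truth$fc_rpf)
  design <- sample_design(rep(c("control", "treated"), each = reps),
                          samples = colnames(mrna))
  list(mrna = count_matrix(mrna, "mRNA"), rpf = count_matrix(rpf, "RPF"),
       design = design)
}

#' One-call simulated benchmark dataset
#'
#' @param config A [sim_config()].
#' @return List with `mrna`, `rpf`, `design`, `truth`, `baselines`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  baselines <- simulate_baseline(config)
  truth <- assign_fold_changes(config, baselines$gene_id)
  counts <- generate_counts(baselines, truth, config)
  c(counts, list(truth = truth, baselines = baselines, config = config))
}

#' Add pseudo-replicates by per-gene normal resampling
#'
#' Fits a normal distribution to each gene's existing replicate counts
#' within each condition and draws `n_extra` new values per condition,
#' truncated at zero and rounded to integers. This mimics extending a
#' deeply replicated dataset to higher replicate numbers.
#'
#' @param counts A `count_matrix`.
#' @param design A [sample_design()] for the existing columns.
#' @param n_extra Pseudo-replicates to add per condition.
#' @param seed RNG seed.
#' @return Expanded `count_matrix` with matching expanded design.
#' @export
augment_pseudo_replicates <- function(counts, design, n_extra = 1L,
                                      seed = 1L) {
  set.seed(seed)
  m <- unclass(counts)
  out_cols <- list()
  out_cond <- character(0)
  for (lev in design$levels) {
    idx <- which(design$condition == lev)
    if (length(idx) < 2L)
      stop("pseudo-replicate augmentation requires >= 2 existing replicates")
    sub <- m[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdev <- apply(sub, 1L, stats::sd)
    extra <- matrix(0L, nrow(m), n_extra)
    for (j in seq_len(n_extra)) {
      v <- stats::rnorm(nrow(m), mu, sdev)
      extra[, j] <- as.integer(round(pmax(v, 0)))
    }
    colnames(extra) <- paste0(lev, "_pseudo", seq_len(n_extra))
    out_cols[[lev]] <- cbind(sub, extra)
    out_cond <- c(out_cond, rep(lev, length(idx) + n_extra))
  }
  combined <- do.call(cbind, out_cols)
  rownames(combined) <- rownames(m)
  list(counts = count_matrix(combined, attr(counts, "assay")),
       design = sample_design(out_cond, samples = colnames(combined)))
}

#' Write a simulated dataset to TSV files
#'
#' @param sim Output of [simulate_dataset()].
#' @param prefix Output path prefix; writes `<prefix>_mrna.tsv`,
#'   `<prefix>_rpf.tsv`, `<prefix>_truth.tsv`.
#' @export
write_simulation <- function(sim, prefix) {
  write_counts(sim$mrna, paste0(prefix, "_mrna.tsv"))
  write_counts(sim$rpf, paste0(prefix, "_rpf.tsv"))
  utils::write.table(sim$truth, paste0(prefix, "_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a truth table written by [write_simulation()]
#'
#' @param path TSV path.
#' @return A `truth_table` data frame.
#' @export
read_truth <- function(path) {
  structure(utils::read.delim(path, stringsAsFactors = FALSE),
            class = c("truth_table", "data.frame"))
}
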