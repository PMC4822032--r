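ALPHA_MIN <- 1e-8

#' Negative-binomial log probability mass
#'
#' Mean/dispersion parameterization: variance = `mu + alpha * mu^2`.
#' `alpha = 0` gives the Poisson limit.
#'
#' @param k Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @param alpha Dispersion(s), `>= 0`.
#' @return Log probability mass, vectorized over arguments.
#' @export
nb_logpmf <- function(k, mu, alpha) {
  n <- max(length(k), length(mu), length(alpha))
  k <- rep_len(k, n); mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(alpha < 0)) stop("alpha must be non-negative")
  out <- numeric(n)
  pois <- alpha < 1e-12
  if (any(pois)) out[pois] <- stats::dpois(k[pois], mu[pois], log = TRUE)
  if (any(!pois))
    out[!pois] <- stats::dnbinom(k[!pois], size = 1 / alpha[!pois],
                                 mu = mu[!pois], log = TRUE)
  out
}

# Cox-Reid adjusted profile log-likelihood of the dispersion for one gene.
# Fitted means are held fixed (group means of normalized counts, the exact
# NB GLM fit for a one-hot two-group design); the adjustment term is
# -0.5 * log det(X' W X) with working weights w_i = mu_i / (1 + alpha mu_i).
cr_loglik <- function(alpha, k, mu, design_x) {
  ll <- sum(nb_logpmf(k, mu, alpha))
  w <- mu / (1 + alpha * mu)
  if (is.null(design_x)) {
    adj <- -0.5 * log(sum(w))
  } else {
    xtx11 <- sum(w); xtx12 <- sum(w * design_x); xtx22 <- sum(w * design_x^2)
    adj <- -0.5 * log(xtx11 * xtx22 - xtx12^2)
  }
  ll + adj
}

#' Gene-wise dispersion estimate
#'
#' Maximizes the Cox-Reid adjusted negative-binomial likelihood over the
#' dispersion for a single gene, with the per-condition fitted means held
#' at the group means of normalized counts. With `blind = TRUE` (used when
#' a condition has a single replicate) all samples are pooled as
#' pseudo-replicates of one group, a deliberately conservative choice.
#'
#' @param k Raw counts for one gene across samples.
#' @param s Size factors.
#' @param design A [sample_design()], ignored when `blind = TRUE`.
#' @param blind Pool both conditions as one group.
#' @return Dispersion estimate in `[alpha_min, alpha_max]`, or `NA` for an
#'   all-zero gene.
#' @export
gene_fitted_mu <- function(k, s, design, blind) {
  q <- k / s
  if (blind || is.null(design)) {
    list(mu = s * mean(q), x = NULL)
  } else {
    x <- design$x
    qhat <- ifelse(x == 1L, mean(q[x == 1L]), mean(q[x == 0L]))
    if (any(qhat == 0)) qhat[qhat == 0] <- 0.5 / mean(s)  # zero group guard
    list(mu = s * qhat, x = x)
  }
}

gene_alpha_max <- function(k, s) {
  q <- k / s
  mom <- max((stats::var(q) - mean(q)) / mean(q)^2, ALPHA_MIN, na.rm = TRUE)
  max(10, mom * 100)
}

estimate_genewise_dispersion <- function(k, s, design, blind = FALSE) {
  if (length(k) < 2L) stop("dispersion estimation requires >= 2 samples")
  if (all(k == 0)) return(NA_real_)
  fit <- gene_fitted_mu(k, s, design, blind)
  opt <- stats::optimize(function(la) cr_loglik(exp(la), k, fit$mu, fit$x),
                         interval = c(log(ALPHA_MIN), log(gene_alpha_max(k, s))),
                         maximum = TRUE, tol = 1e-8)
  exp(opt$maximum)
}

#' Fit a parametric mean-dispersion trend
#'
#' Robustly fits `alpha_tr(mu) = a0 + a1 / mu` to gene-wise dispersion
#' estimates by iteratively refitted gamma-family regression: after each
#' fit, genes whose ratio to the current trend falls outside
#' `[1e-4, 15]` are excluded and the curve refitted, up to 10 iterations.
#' With fewer than `min_genes` usable genes, or when the gamma fit fails
#' or yields a negative coefficient, the fit falls back to a flat trend at
#' the median dispersion (with a message).
#'
#' @param genewise Per-gene raw dispersion estimates (NA allowed).
#' @param mean_expr Per-gene mean normalized counts.
#' @param min_genes Minimum usable genes for the parametric fit.
#' @return A `dispersion_trend` list: coefficients `a0`, `a1`, the trend
#'   function `fn(mu)`, and `type` (`"parametric"` or `"flat"`).
#' @export
fit_dispersion_trend <- function(genewise, mean_expr, min_genes = 50L) {
  usable <- is.finite(genewise) & genewise > 10 * ALPHA_MIN &
    is.finite(mean_expr) & mean_expr > 0
  flat <- function() {
    a0 <- stats::median(genewise[is.finite(genewise)])
    if (!is.finite(a0)) a0 <- 0.1
    message("dispersion trend: falling back to flat median trend")
    structure(list(a0 = a0, a1 = 0, fn = function(mu) rep_len(a0, length(mu)),
                   type = "flat"), class = "dispersion_trend")
  }
  if (sum(usable) < min_genes) return(flat())
  d <- genewise[usable]; m <- mean_expr[usable]
  coefs <- c(a0 = stats::median(d), a1 = 0)
  keep <- rep(TRUE, length(d))
  for (it in seq_len(10L)) {
    fit <- tryCatch(
      suppressWarnings(
        stats::glm(d[keep] ~ I(1 / m[keep]),
                   family = stats::Gamma(link = "identity"),
                   start = pmax(unname(coefs), c(1e-4, 1e-4)))),
      error = function(e) NULL)
    if (is.null(fit)) return(flat())
    new_coefs <- stats::coef(fit)
    if (any(!is.finite(new_coefs)) || any(new_coefs < 0)) return(flat())
    trend <- new_coefs[1L] + new_coefs[2L] / m
    ratio <- d / trend
    new_keep <- ratio > 1e-4 & ratio < 15
    converged <- max(abs(new_coefs - coefs) / pmax(abs(coefs), 1e-6)) < 1e-4
    coefs <- new_coefs; keep <- new_keep
    if (converged) break
  }
  a0 <- unname(coefs[1L]); a1 <- unname(coefs[2L])
  structure(list(a0 = a0, a1 = a1,
                 fn = function(mu) a0 + a1 / mu, type = "parametric"),
            class = "dispersion_trend")
}

#' Shrink gene-wise dispersions toward the fitted trend
#'
#' Empirical-Bayes shrinkage on the log scale: gene-wise log dispersions
#' are modelled as the trend value plus log-normal biological scatter
#' (prior) plus sampling noise with variance `trigamma((m - p) / 2)`.
#' The prior sd is the excess of the robust residual spread over the
#' sampling noise, floored at 0.25. Each gene's shrunken value is the
#' posterior mode of this normal-normal model, which lies between the
#' gene-wise estimate and the trend. Genes whose log residual exceeds
#' twice the observed residual spread (biological scatter plus sampling
#' noise) above the trend are dispersion outliers and keep their
#' gene-wise value.
#'
#' @param genewise Per-gene raw dispersion estimates.
#' @param trend Per-gene trend values `alpha_tr(mean)`.
#' @param n_samples Number of samples used in estimation.
#' @param n_coefficients Number of fitted mean parameters (2 for a
#'   two-condition design, 1 for blind estimation).
#' @param counts,s,design,blind Optional count data (gene-by-sample
#'   matrix matching `genewise`, size factors, design). When supplied,
#'   each gene's shrunken value is the exact MAP maximizer of its
#'   Cox-Reid likelihood plus the log-normal prior; otherwise the
#'   normal-normal closed form on the log scale is used (the two agree
#'   when the likelihood is approximately log-normal in the dispersion,
#'   but the exact MAP is robust for genes whose estimate is pinned at
#'   the lower bound).
#' @return List with `shrunk` dispersions, `prior_sd`, and logical
#'   `outlier` flags.
#' @export
shrink_dispersions <- function(genewise, trend, n_samples,
                               n_coefficients = 2L, counts = NULL,
                               s = NULL, design = NULL, blind = FALSE) {
  lr <- log(genewise) - log(trend)
  df <- max(n_samples - n_coefficients, 1L)
  samp_var <- trigamma(df / 2)
  # spread estimated only from genes whose estimate is away from the
  # lower bound; boundary-pinned genes carry no usable residual
  informative <- is.finite(lr) & genewise > 100 * ALPHA_MIN
  spread <- stats::mad(lr[informative], na.rm = TRUE)^2
  if (!is.finite(spread)) spread <- 0
  prior_sd <- max(sqrt(max(spread - samp_var, 0)), 0.25)
  prior_var <- prior_sd^2
  # outliers are judged against the observed residual spread (biological
  # scatter plus sampling noise): a gene-wise estimate more than 2 sd
  # above the trend is left unshrunk rather than pulled down
  outlier_sd <- sqrt(max(spread, prior_var + samp_var))
  outlier <- is.finite(lr) & lr > 2 * outlier_sd
  if (is.null(counts)) {
    shrunk <- exp(log(trend) + lr * prior_var / (prior_var + samp_var))
  } else {
    shrunk <- vapply(seq_along(genewise), function(g) {
      if (!is.finite(genewise[g])) return(NA_real_)
      k <- as.numeric(counts[g, ])
      fit <- gene_fitted_mu(k, s, design, blind)
      post <- function(la) cr_loglik(exp(la), k, fit$mu, fit$x) +
        stats::dnorm(la, log(trend[g]), prior_sd, log = TRUE)
      opt <- stats::optimize(post, interval = c(log(ALPHA_MIN),
                                                log(gene_alpha_max(k, s))),
                             maximum = TRUE, tol = 1e-8)
      exp(opt$maximum)
    }, numeric(1))
  }
  shrunk[outlier] <- genewise[outlier]
  shrunk <- pmax(shrunk, ALPHA_MIN)
  shrunk[!is.finite(genewise)] <- NA_real_
  list(shrunk = shrunk, prior_sd = prior_sd, outlier = outlier)
}

#' Full dispersion estimation for one assay
#'
#' Gene-wise Cox-Reid estimates, parametric mean-dispersion trend, and
#' empirical-Bayes shrinkage, for one count matrix under a two-condition
#' design.
#'
#' @param counts Gene-by-sample count matrix (raw counts).
#' @param s Size factors.
#' @param design A [sample_design()].
#' @param blind Pool conditions when estimating (automatic when either
#'   condition has a single replicate).
#' @return A `dispersion_fit` data-frame-like list: per-gene `mean`,
#'   `genewise`, `trend`, `shrunk`, plus `trend_params` and `prior_sd`.
#' @export
estimate_dispersions <- function(counts, s, design, blind = NULL) {
  counts <- unclass(counts)
  if (is.null(blind))
    blind <- min(sum(design$x == 0L), sum(design$x == 1L)) < 2L
  q <- sweep(counts, 2L, s, "/")
  mean_expr <- rowMeans(q)
  genewise <- vapply(seq_len(nrow(counts)), function(g) {
    estimate_genewise_dispersion(counts[g, ], s, design, blind = blind)
  }, numeric(1))
  trend_fit <- fit_dispersion_trend(genewise, mean_expr)
  trend <- trend_fit$fn(mean_expr)
  n_coef <- if (blind) 1L else 2L
  sh <- shrink_dispersions(genewise, trend, ncol(counts), n_coef,
                           counts = counts, s = s, design = design,
                           blind = blind)
  structure(list(gene_ids = rownames(counts), mean = mean_expr,
                 genewise = genewise, trend = trend, shrunk = sh$shrunk,
                 outlier = sh$outlier, prior_sd = sh$prior_sd,
                 trend_params = c(a0 = trend_fit$a0, a1 = trend_fit$a1),
                 trend_type = trend_fit$type, blind = blind),
            class = "dispersion_fit")
}

#' Export a dispersion table
#'
#' @param fit A `dispersion_fit` from [estimate_dispersions()].
#' @param path TSV output path.
#' @export
write_dispersions <- function(fit, path) {
  utils::write.table(
    data.frame(gene_id = fit$gene_ids, mean = fit$mean,
               genewise = fit$genewise, trend = fit$trend,
               shrunk = fit$shrunk),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
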