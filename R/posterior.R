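# Hard cap on |log2 effect| used when a likelihood has a flat asymptote
# (e.g. a condition with all-zero counts): the 1e-50 drop is then never
# reached on that side and the sampling range is truncated here.
BETA_CAP <- 50

LOG_PR_DROP <- log(1e-50)

# Build a vectorized profile log-likelihood in the log2 effect beta for a
# set of samples with means s_i * phi * 2^(x_i * beta) and per-sample
# dispersions. phi is profiled out at every beta (1-D Newton on log phi)
# unless a fixed plug-in value is supplied.
make_loglik <- function(k, s, x, alpha, phi_fixed = NULL) {
  k <- as.numeric(k); s <- as.numeric(s)
  x <- as.numeric(x); alpha <- rep_len(as.numeric(alpha), length(k))
  if (is.null(phi_fixed)) {
    function(betas) .profile_loglik_grid(k, s, x, alpha, as.numeric(betas))
  } else {
    function(betas) .plugin_loglik_grid(k, s, x, alpha, as.numeric(betas),
                                        phi_fixed)
  }
}

find_beta_mle <- function(loglik) {
  opt <- stats::optimize(function(b) loglik(b), interval = c(-BETA_CAP, BETA_CAP),
                         maximum = TRUE, tol = 1e-6)
  opt$maximum
}

#' Locate the sampling range of a posterior grid
#'
#' Finds the points on each side of the likelihood peak where the
#' unnormalized posterior falls to `1e-50` of its maximum: an expanding
#' search doubles the step outward from the peak until the drop is
#' reached, then bisection refines the crossing to within `tol` log2
#' units. A side whose likelihood plateaus (asymptote above the drop,
#' e.g. all-zero counts in one condition) is truncated at `+/-50`.
#'
#' @param loglik Vectorized log-likelihood function of the log2 effect.
#' @param beta_mle Location of the likelihood peak.
#' @param tol Bisection tolerance in log2 units.
#' @return `c(lower, upper)` bounds of the sampling range.
#' @export
locate_grid_bounds <- function(loglik, beta_mle, tol = 1e-3) {
  ll_peak <- loglik(beta_mle)
  if (!is.finite(ll_peak)) stop("non-finite likelihood at peak")
  crossed <- function(b) {
    ll <- loglik(b)
    !is.finite(ll) || (ll - ll_peak) <= LOG_PR_DROP
  }
  one_side <- function(sign) {
    step <- 0.5
    inner <- beta_mle
    repeat {
      outer <- beta_mle + sign * step
      if (abs(outer) >= BETA_CAP) {
        outer <- sign * BETA_CAP
        if (!crossed(outer)) return(outer)
        break
      }
      if (crossed(outer)) break
      inner <- outer
      step <- step * 2
    }
    while (abs(outer - inner) > tol) {
      mid <- (inner + outer) / 2
      if (crossed(mid)) outer <- mid else inner <- mid
    }
    outer
  }
  c(one_side(-1), one_side(1))
}

posterior_from_loglik <- function(loglik, bounds, n_bins, kind, beta_mle,
                                  eval_grid = TRUE) {
  grid <- probs <- mode <- NULL
  if (eval_grid) {
    grid <- seq(bounds[1L], bounds[2L], length.out = n_bins)
    ll <- loglik(grid)
    ll[!is.finite(ll)] <- -Inf
    pr <- exp(ll - max(ll))
    probs <- pr / sum(pr)
    mode <- grid[which.max(probs)]
  }
  structure(list(grid = grid, probs = probs,
                 lower = bounds[1L], upper = bounds[2L],
                 mode = mode, mle = beta_mle,
                 kind = kind, loglik = loglik),
            class = "posterior_grid")
}

#' Discrete posterior of a log2 fold change across conditions
#'
#' For one gene and one assay, evaluates the negative-binomial profile
#' likelihood of the log2 fold change beta on an equally spaced grid of
#' `n_bins` values spanning the range where the posterior falls to 1e-50
#' of its peak, and normalizes to a discrete probability distribution.
#' The intercept (base expression level) is profiled out at every grid
#' point, so baseline uncertainty propagates into the distribution; pass
#' `profile_phi = FALSE` for the faster plug-in intercept (fixed at the
#' reference-condition mean).
#'
#' @param k Raw counts for one gene across all samples of the assay.
#' @param s Size factors for those samples.
#' @param design A [sample_design()].
#' @param alpha Shrunken dispersion for this gene in this assay.
#' @param n_bins Number of grid points (default 10000).
#' @param profile_phi Profile (default) or plug in the intercept.
#' @return A `posterior_grid` with fields `grid`, `probs`, `lower`,
#'   `upper`, `mode`, and the likelihood closure `loglik`.
#' @export
log2fc_posterior <- function(k, s, design, alpha, n_bins = 10000L,
                             profile_phi = TRUE, eval_grid = TRUE) {
  phi_fixed <- NULL
  if (!profile_phi) {
    q <- k / s
    phi_fixed <- max(mean(q[design$x == 0L]), 1e-8)
  }
  ll <- make_loglik(k, s, design$x, alpha, phi_fixed)
  mle <- find_beta_mle(ll)
  bounds <- locate_grid_bounds(ll, mle)
  posterior_from_loglik(ll, bounds, n_bins, "log2FC", mle, eval_grid)
}

#' Discrete posterior of the within-condition log2 RPF-to-mRNA ratio
#'
#' For one gene within a single condition, the mRNA samples have mean
#' `s_i * phi` and the RPF samples `s_i * phi * 2^beta`, each assay with
#' its own dispersion; `beta` is the log2 translational-efficiency ratio.
#' The intercept `phi` (mRNA expression) is profiled as in
#' [log2fc_posterior()].
#'
#' @param k_mrna,k_rpf Counts for the condition's mRNA and RPF samples.
#' @param s_mrna,s_rpf Matching size factors.
#' @param alpha_mrna,alpha_rpf Shrunken dispersions per assay.
#' @param n_bins Number of grid points.
#' @param profile_phi Profile (default) or plug in the intercept.
#' @return A `posterior_grid`.
#' @export
log2r_posterior <- function(k_mrna, k_rpf, s_mrna, s_rpf,
                            alpha_mrna, alpha_rpf, n_bins = 10000L,
                            profile_phi = TRUE, eval_grid = TRUE) {
  k <- c(k_mrna, k_rpf)
  s <- c(s_mrna, s_rpf)
  x <- c(rep(0, length(k_mrna)), rep(1, length(k_rpf)))
  alpha <- c(rep(alpha_mrna, length(k_mrna)), rep(alpha_rpf, length(k_rpf)))
  phi_fixed <- if (profile_phi) NULL else max(mean(k_mrna / s_mrna), 1e-8)
  ll <- make_loglik(k, s, x, alpha, phi_fixed)
  mle <- find_beta_mle(ll)
  bounds <- locate_grid_bounds(ll, mle)
  posterior_from_loglik(ll, bounds, n_bins, "log2R", mle, eval_grid)
}

#' Re-evaluate two posteriors on one shared grid
#'
#' The joint-probability operations require both distributions on the
#' same equally spaced grid: the anti-diagonal summation that yields the
#' delta distribution is only exact with a common step. Both likelihoods
#' are re-evaluated on `n_bins` points spanning the union of the two
#' sampling ranges.
#'
#' @param post1,post2 `posterior_grid` objects (must carry `loglik`).
#' @param n_bins Number of shared grid points.
#' @return List with `grid`, `p1`, `p2` (normalized probabilities) and
#'   `step`.
#' @export
shared_grid <- function(post1, post2, n_bins = 10000L) {
  lo <- min(post1$lower, post2$lower)
  hi <- max(post1$upper, post2$upper)
  grid <- seq(lo, hi, length.out = n_bins)
  renorm <- function(post) {
    ll <- post$loglik(grid)
    ll[!is.finite(ll)] <- -Inf
    pr <- exp(ll - max(ll))
    pr / sum(pr)
  }
  list(grid = grid, p1 = renorm(post1), p2 = renorm(post2),
       step = grid[2L] - grid[1L])
}
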