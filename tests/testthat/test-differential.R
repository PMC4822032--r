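unit_mass_at <- function(i, n) { p <- numeric(n); p[i] <- 1; p }

test_that("joint matrix is the outer product with marginal sums intact", {
  g <- seq(-1, 1, length.out = 5)
  p1 <- unit_mass_at(2, 5); p2 <- unit_mass_at(4, 5)
  jm <- joint_matrix(p1, p2, g)
  expect_equal(sum(jm), 1)
  expect_equal(which(jm == 1, arr.ind = TRUE)[1, ], c(row = 2, col = 4))

  u <- rep(1 / 5, 5)
  expect_true(all(abs(joint_matrix(u, u, g) - 1 / 25) < 1e-15))

  set.seed(8)
  a <- runif(5); a <- a / sum(a)
  b <- runif(5); b <- b / sum(b)
  jm2 <- joint_matrix(a, b, g)
  expect_equal(rowSums(jm2), a * sum(b), tolerance = 1e-14)
  expect_equal(colSums(jm2), b, tolerance = 1e-14)
  expect_error(joint_matrix(a, b[1:4], g), "shared grid")
})

test_that("triangle-sum p-value matches brute force and handles extremes", {
  g <- seq(-5, 5, length.out = 100)
  # same marginal on both axes: null symmetry, p ~ 1
  p <- dnorm(g, 0, 0.8); p <- p / sum(p)
  expect_gt(pvalue_from_joint(joint_matrix(p, p, g)), 0.99)

  # fully separated: p below 1e-20, against an explicit double loop
  p0 <- dnorm(g, 0, 0.2); p0 <- p0 / sum(p0)
  p3 <- dnorm(g, 3, 0.2); p3 <- p3 / sum(p3)
  jm <- joint_matrix(p3, p0, g)
  brute <- 0
  for (i in 1:100) for (j in i:100) brute <- brute + p3[i] * p0[j]
  expect_lt(pvalue_from_joint(jm), 1e-20)
  expect_equal(pvalue_from_joint(jm), min(1, 2 * brute), tolerance = 1e-12)
})

test_that("fast marginal paths equal dense computation at 200 bins", {
  set.seed(21)
  g <- seq(-4, 4, length.out = 200)
  p1 <- dnorm(g, 0.7, 0.5) + 0.1 * dnorm(g, -1, 0.3)
  p1 <- p1 / sum(p1)
  p2 <- dnorm(g, -0.2, 0.8); p2 <- p2 / sum(p2)
  jm <- joint_matrix(p1, p2, g)
  expect_equal(ribodelta:::pvalue_from_marginals(p1, p2),
               pvalue_from_joint(jm), tolerance = 1e-10)
  dd_dense <- delta_distribution(jm)
  dd_fast <- ribodelta:::delta_from_marginals(p1, p2, g[2] - g[1])
  expect_equal(dd_fast$probs, dd_dense$probs, tolerance = 1e-10)
  expect_equal(dd_fast$ci, dd_dense$ci)
  expect_equal(sum(dd_fast$probs), 1, tolerance = 1e-10)
})

test_that("delta distribution convolves point masses and Gaussians correctly", {
  g <- seq(0, 4, length.out = 81)  # step 0.05
  step <- g[2] - g[1]
  jm <- joint_matrix(unit_mass_at(61, 81), unit_mass_at(21, 81), g)  # 3 - 1
  dd <- delta_distribution(jm)
  expect_equal(dd$point_estimate, 2)
  expect_equal(sum(dd$probs), 1, tolerance = 1e-12)
  expect_equal(dd$ci, c(2, 2))

  gg <- seq(-4, 4, length.out = 401)
  pn <- dnorm(gg, 0, 1); pn <- pn / sum(pn)
  ddn <- delta_distribution(joint_matrix(pn, pn, gg))
  # difference of two N(0,1) is N(0, 2)
  sd_emp <- sqrt(sum(ddn$probs * ddn$delta_grid^2))
  expect_equal(sd_emp, sqrt(2), tolerance = 0.01)
})

test_that("credible intervals are equal-tailed at the requested level", {
  gg <- seq(-6, 6, length.out = 1201)
  pn <- dnorm(gg); pn <- pn / sum(pn)
  dd <- delta_distribution(joint_matrix(pn, unit_mass_at(601, 1201), gg))
  ci <- credible_interval(dd, 0.95)
  step <- dd$delta_grid[2] - dd$delta_grid[1]
  expect_equal(ci[1], -1.96, tolerance = 2 * step)
  expect_equal(ci[2], 1.96, tolerance = 2 * step)
  expect_equal(ci[1], -ci[2], tolerance = step)
  expect_error(credible_interval(dd, 1.2), "credible level")
})

test_that("pipeline merging keeps the more conservative result", {
  fc <- list(pvalue = 0.01, point_estimate = 1.0, ci = c(0.5, 1.5))
  r <- list(pvalue = 0.04, point_estimate = 0.9, ci = c(0.4, 1.4))
  m <- merge_pipelines(fc, r)
  expect_equal(m$pvalue, 0.04)
  expect_identical(m$pipeline_used, "R")
  tie <- merge_pipelines(list(pvalue = 0.04, point_estimate = 1, ci = c(0, 2)), r)
  expect_identical(tie$pipeline_used, "FC")
  expect_identical(merge_pipelines(fc, NULL)$pipeline_used, "FC")
  expect_null(merge_pipelines(NULL, NULL))
})

test_that("BH adjustment matches hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, NA, 0.03)), c(0.02, NA, 0.03))
})

test_that("condition swap negates effects and preserves p-values", {
  pair <- constructed_pair(c(300, 150, 400), c(260, 300, 120),
                           fc_mrna = c(1, 1.4, 1), fc_rpf = c(2, 1.4, 0.8))
  res_fwd <- delta_te(pair$mrna, pair$rpf, pair$design, n_bins = 4000L,
                      normalized = TRUE)
  design_rev <- sample_design(pair$design$condition,
                              samples = pair$design$samples, ref = "trt")
  res_rev <- delta_te(pair$mrna, pair$rpf, design_rev, n_bins = 4000L,
                      normalized = TRUE)
  f <- as.data.frame(res_fwd); r <- as.data.frame(res_rev)
  step <- 17 / 4000  # upper bound on grid step for these posteriors
  expect_equal(f$delta_log2, -r$delta_log2, tolerance = 4 * step)
  expect_equal(f$pvalue_final, r$pvalue_final, tolerance = 1e-3)
  expect_equal(f$ci_low, -r$ci_high, tolerance = 4 * step)
})

test_that("FC and R pipelines agree when mRNA is constant across conditions", {
  pair <- constructed_pair(c(300, 250), c(200, 240),
                           fc_mrna = c(1, 1), fc_rpf = c(2.2, 0.6))
  res <- as.data.frame(delta_te(pair$mrna, pair$rpf, pair$design,
                                n_bins = 4000L, normalized = TRUE))
  expect_equal(res$pvalue_fc, res$pvalue_r, tolerance = 0.1)
  expect_equal(res$delta_log2[1], log2(2.2), tolerance = 0.1)
})

test_that("p-values fall monotonically along a fold-change ladder", {
  fcs <- c(1.0, 1.5, 2, 4)
  pair <- constructed_pair(rep(300, 4), rep(300, 4),
                           fc_mrna = rep(1, 4), fc_rpf = fcs)
  res <- as.data.frame(delta_te(pair$mrna, pair$rpf, pair$design,
                                n_bins = 4000L, normalized = TRUE))
  expect_true(all(diff(res$pvalue_final) < 0))
})

test_that("sign convention: RPF up in condition 2 gives positive delta", {
  pair <- constructed_pair(rep(300, 3), rep(280, 3),
                           fc_mrna = rep(1, 3), fc_rpf = c(2, 2, 2))
  res <- as.data.frame(delta_te(pair$mrna, pair$rpf, pair$design,
                                n_bins = 4000L, normalized = TRUE))
  expect_true(all(res$delta_log2 > 0.8 & res$delta_log2 < 1.2))
  expect_true(all(res$pvalue_final < 0.05))
  expect_true(all(res$ci_low <= res$delta_log2 & res$delta_log2 <= res$ci_high))
  expect_true(all(res$padj >= res$pvalue_final))
})
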