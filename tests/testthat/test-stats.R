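test_that("z-scoring uses the sample SD and is idempotent", {
  z <- zscore_normalize(cbind(a = c(1, 3)))
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2))

  set.seed(1)
  x <- cbind(a = rnorm(50, 5, 2), b = runif(50))
  z1 <- zscore_normalize(x)
  expect_equal(unname(colMeans(z1)), c(0, 0))
  expect_equal(unname(apply(z1, 2, sd)), c(1, 1))
  expect_equal(unname(zscore_normalize(z1)), unname(z1))
  # affine invariance of correlations
  expect_equal(cor(z1)[1, 2], cor(x)[1, 2])

  expect_error(zscore_normalize(cbind(ok = rnorm(5), flat = rep(2, 5))),
               "flat")
})

test_that("OVL behaves like an overlap area", {
  set.seed(3)
  a <- rnorm(300)
  expect_lt(abs(ovl(a, a) - 1), 1e-6)
  # samples separated by many bandwidths and sample SDs: essentially no overlap
  expect_lt(ovl(a, a + 10 * max(bw.nrd0(a), sd(a))), 0.001)
  # symmetry
  b <- rnorm(250, 1, 2)
  expect_identical(ovl(a, b), ovl(b, a))
  expect_error(ovl(rep(1, 10), a), "distinct")
})

test_that("OVL decreases monotonically as two Gaussians separate", {
  set.seed(12)
  a <- rnorm(400)
  shifts <- seq(0, 6, by = 0.5)
  vals <- vapply(shifts, function(s) ovl(a, a + s), numeric(1))
  expect_true(all(diff(vals) <= 1e-10))
  expect_gt(vals[1], 0.999)
})

test_that("group comparison routes by normality and corrects by m measures", {
  set.seed(21)
  n <- 120
  feats <- data.frame(
    group = rep(c("older", "younger"), each = n),
    gauss_equal = rnorm(2 * n, 5),
    gauss_shift = c(rnorm(n, 0), rnorm(n, 1.2)),
    heavy = exp(rnorm(2 * n)))
  cmp <- compare_groups(feats, measures = c("gauss_equal", "gauss_shift",
                                            "heavy"))
  tab <- cmp$table
  expect_identical(tab$test[tab$measure == "gauss_equal"], "welch_t")
  expect_identical(tab$test[tab$measure == "gauss_shift"], "welch_t")
  # lognormal fails Shapiro-Wilk, falls back to Mann-Whitney U
  expect_identical(tab$test[tab$measure == "heavy"], "mann_whitney_u")
  # equal means: small |t|; shifted means: corrected p still tiny
  expect_lt(abs(tab$statistic[tab$measure == "gauss_equal"]), 3)
  expect_lt(tab$p_bonferroni[tab$measure == "gauss_shift"], 1e-6)
  # Welch produces fractional df
  expect_false(is.na(tab$df[tab$measure == "gauss_equal"]))
  # Bonferroni: p_bonf = min(1, m * p_raw) with m = number of measures
  expect_equal(tab$p_bonferroni, pmin(1, 3 * tab$p_raw))
  expect_true(all(tab$ovl >= 0 & tab$ovl <= 1))

  expect_error(compare_groups(data.frame(group = "a", x = 1)), "two groups")
})

test_that("statistic orientation follows the group order (group1 - group2)", {
  set.seed(33)
  feats <- data.frame(group = rep(c("older", "younger"), each = 100),
                      x = c(rnorm(100, 0), rnorm(100, 2)))
  cmp <- compare_groups(feats, measures = "x")
  expect_identical(cmp$groups[1], "older")
  expect_lt(cmp$table$statistic, 0)  # older minus younger, older lower
})

test_that("raw p-values are uniform under permuted group labels", {
  set.seed(61)
  n <- 30
  x <- rnorm(2 * n)
  p <- numeric(600)
  for (i in seq_along(p)) {
    g <- sample(rep(c("older", "younger"), each = n))
    p[i] <- compare_groups(data.frame(group = g, x = x),
                           measures = "x")$table$p_raw
  }
  # duplicate permutations can tie p-values; the KS p is then approximate
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("PCA yields orthonormal loadings, ordered variance and 100% contributions", {
  set.seed(41)
  n <- 150
  base <- rnorm(n)
  x <- cbind(a = base + rnorm(n, 0, 0.1), b = -base + rnorm(n, 0, 0.1),
             c = rnorm(n), d = 0.5 * base + rnorm(n, 0, 0.5))
  pca <- balance_pca(x)
  expect_equal(sum(pca$variance_fraction), 1)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))
  expect_equal(unname(colSums(pca$contributions)),
               rep(100, 4), tolerance = 1e-9)
  expect_equal(t(pca$loadings) %*% pca$loadings, diag(4),
               ignore_attr = TRUE, tolerance = 1e-12)
  # scores' covariance diagonal equals the eigenvalues
  ev <- pca$variance_fraction * sum(apply(zscore_normalize(x), 2, var))
  expect_equal(unname(diag(cov(pca$scores))), ev, tolerance = 1e-9)
  # full reconstruction of the z-scored input
  expect_equal(pca$scores %*% t(pca$loadings),
               zscore_normalize(x), ignore_attr = TRUE, tolerance = 1e-9)
  # sign convention: dominant loading of each component is positive
  for (j in 1:4)
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  expect_equal(pca$mean_contribution, 25)
})

test_that("confidence ellipse matches chi-square geometry", {
  set.seed(52)
  xy <- matrix(rnorm(2 * 20000), ncol = 2)
  e <- confidence_ellipse(xy, level = 0.95)
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.05)
  expect_equal(unname(e$radii), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.05)
  expect_false(e$degenerate)
  # about 95% of points fall inside
  d2 <- mahalanobis(xy, e$center, e$cov)
  expect_equal(mean(d2 <= qchisq(0.95, 2)), 0.95, tolerance = 0.01)

  # collinear points: degenerate minor axis, flagged
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_true(confidence_ellipse(line)$degenerate)

  # rotation equivariance: rotating the points rotates the ellipse
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  set.seed(53)
  pts <- cbind(rnorm(500, 0, 3), rnorm(500, 0, 1))
  e1 <- confidence_ellipse(pts)
  e2 <- confidence_ellipse(pts %*% t(Rm))
  expect_equal(e2$radii, e1$radii, tolerance = 1e-9)
  expect_equal(sort(c(e2$angle, e1$angle + th) %% pi),
               rep(mean(c(e2$angle, e1$angle + th) %% pi), 2),
               tolerance = 1e-6)
})

test_that("correlation matrix reports a computed critical threshold", {
  set.seed(71)
  x <- cbind(a = rnorm(400), b = rnorm(400))
  cm <- correlation_matrix(x)
  expect_equal(diag(cm$r), c(a = 1, b = 1))
  expect_equal(correlation_matrix(cbind(v = x[, 1], w = -x[, 1]))$r[1, 2], -1)
  # t-based critical |r| at n = 400, alpha 0.05 is ~0.098
  tcrit <- qt(0.975, 398)
  expect_equal(cm$r_critical, tcrit / sqrt(tcrit^2 + 398))

  # Monte Carlo: independent columns stay below the threshold ~95% of the time
  hits <- 0L
  for (i in 1:1000) {
    r <- cor(rnorm(400), rnorm(400))
    if (abs(r) < cm$r_critical) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.94)
})
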