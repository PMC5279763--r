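#' Z-score normalize measure columns
#'
#' Subtracts the pooled (both groups together) mean and divides by the
#' pooled sample standard deviation, column by column. All multivariate
#' analyses and the overlap coefficients operate on these normalized values.
#'
#' @param x Numeric matrix or data frame of measure columns.
#' @return Matrix of the same shape with each column mean 0, sample SD 1.
#' @export
zscore_normalize <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("x must be numeric")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(m)[sds == 0 | !is.finite(sds)]
    stop("constant or degenerate column(s): ", paste(bad, collapse = ", "))
  }
  scale(m, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Overlapping coefficient of two samples
#'
#' Area under the pointwise minimum of two kernel density estimates,
#' \deqn{OVL = \int \min(\hat{f}_1(x), \hat{f}_2(x))\,dx \in [0, 1]:}
#' 1 for identical distributions, 0 for disjoint ones. Gaussian kernels with
#' Silverman's rule-of-thumb bandwidth per sample, both densities evaluated
#' on one shared grid spanning the pooled range padded by `pad` bandwidths,
#' integrated by a Riemann sum and clipped to \[0, 1\].
#'
#' @param a,b Numeric samples, each with at least 2 distinct values.
#' @param n_grid Number of grid points (default 512).
#' @param pad Grid padding in multiples of the larger bandwidth (default 6;
#'   the Gaussian tail mass lost beyond 6 bandwidths is negligible, so
#'   identical samples score 1 to well below 1e-6).
#' @return OVL in \[0, 1\].
#' @export
ovl <- function(a, b, n_grid = 512L, pad = 6) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop("each sample needs at least 2 distinct finite values")
  h1 <- stats::bw.nrd0(a)
  h2 <- stats::bw.nrd0(b)
  h <- max(h1, h2)
  lo <- min(a, b) - pad * h
  hi <- max(a, b) + pad * h
  f1 <- stats::density(a, bw = h1, from = lo, to = hi, n = n_grid)$y
  f2 <- stats::density(b, bw = h2, from = lo, to = hi, n = n_grid)$y
  dx <- (hi - lo) / (n_grid - 1L)
  min(1, max(0, sum(pmin(f1, f2)) * dx))
}

# Shapiro-Wilk with the implementation's 5000-sample cap handled by a
# deterministic evenly spaced subsample (irrelevant at study sizes).
shapiro_safe <- function(x) {
  if (length(x) > 5000L)
    x <- x[unique(round(seq(1L, length(x), length.out = 5000L)))]
  stats::shapiro.test(x)
}

#' Compare balance measures between two groups
#'
#' For each measure: Shapiro-Wilk normality per group; if both groups look
#' normal (p > `alpha`) a Welch two-sample t-test (unequal variances,
#' fractional degrees of freedom), otherwise a Mann-Whitney U test.
#' Bonferroni correction multiplies each raw p by the number of measures.
#' The overlapping coefficient is computed per measure on the pooled
#' z-scored values split by group. Test statistics are oriented as
#' `group1 - group2` in the order of `groups`.
#'
#' @param features Feature data frame with a `group` column (e.g. from
#'   [extract_features()] or [read_features_csv()]).
#' @param measures Character vector of measure columns (default: the columns
#'   of [measure_names()] present in `features`).
#' @param groups Optional length-2 character vector fixing group order;
#'   default: `"older"` first if present, else sorted unique labels.
#' @param alpha Normality-routing significance level (default 0.05).
#' @param ovl_args List of extra arguments passed to [ovl()].
#' @return An object of class `balance_comparison`: list with `table` (one
#'   row per measure: `measure`, `W_1`, `p_shapiro_1`, `W_2`, `p_shapiro_2`,
#'   `test`, `statistic`, `df`, `p_raw`, `p_bonferroni`, `ovl`), `groups`,
#'   `n` (per-group trial counts), `alpha`, `m` (Bonferroni multiplier).
#' @export
compare_groups <- function(features, measures = NULL, groups = NULL,
                           alpha = 0.05, ovl_args = list()) {
  if (!"group" %in% names(features)) stop("features must have a group column")
  labs <- unique(as.character(features$group))
  if (length(labs) != 2L)
    stop("exactly two groups required, found ", length(labs), ": ",
         paste(labs, collapse = ", "))
  if (is.null(groups))
    groups <- if ("older" %in% labs) c("older", setdiff(labs, "older"))
              else sort(labs)
  if (!setequal(groups, labs)) stop("groups must name the two group labels")
  if (is.null(measures)) measures <- intersect(measure_names(), names(features))
  if (length(measures) == 0L) stop("no measure columns found")
  g <- as.character(features$group)
  n1 <- sum(g == groups[1]); n2 <- sum(g == groups[2])
  if (n1 < 3L || n2 < 3L) stop("each group needs at least 3 trials")
  m <- length(measures)
  z <- zscore_normalize(features[, measures, drop = FALSE])
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    x1 <- features[g == groups[1], measures[j]]
    x2 <- features[g == groups[2], measures[j]]
    sw1 <- shapiro_safe(x1); sw2 <- shapiro_safe(x2)
    normal <- sw1$p.value > alpha && sw2$p.value > alpha
    if (normal) {
      tt <- stats::t.test(x1, x2, var.equal = FALSE)
      test <- "welch_t"; statistic <- unname(tt$statistic)
      df <- unname(tt$parameter); p_raw <- tt$p.value
    } else {
      wt <- stats::wilcox.test(x1, x2, exact = FALSE, correct = TRUE)
      test <- "mann_whitney_u"; statistic <- unname(wt$statistic)
      df <- NA_real_; p_raw <- wt$p.value
    }
    o <- do.call(ovl, c(list(z[g == groups[1], j], z[g == groups[2], j]),
                        ovl_args))
    rows[[j]] <- data.frame(
      measure = measures[j],
      W_1 = unname(sw1$statistic), p_shapiro_1 = sw1$p.value,
      W_2 = unname(sw2$statistic), p_shapiro_2 = sw2$p.value,
      test = test, statistic = statistic, df = df, p_raw = p_raw,
      p_bonferroni = min(1, m * p_raw), ovl = o)
  }
  structure(list(table = do.call(rbind, rows), groups = groups,
                 n = c(n1, n2), alpha = alpha, m = m),
            class = "balance_comparison")
}

#' @export
print.balance_comparison <- function(x, digits = 4, ...) {
  cat("Balance measure comparison: ", x$groups[1], " (n = ", x$n[1],
      ") vs ", x$groups[2], " (n = ", x$n[2], ")\n", sep = "")
  cat("Bonferroni multiplier m = ", x$m,
      "; normality routing at alpha = ", x$alpha, "\n\n", sep = "")
  tab <- x$table
  out <- data.frame(measure = tab$measure, test = tab$test,
                    statistic = signif(tab$statistic, digits),
                    df = signif(tab$df, digits),
                    p_raw = signif(tab$p_raw, digits),
                    p_bonf = signif(tab$p_bonferroni, digits),
                    OVL = round(tab$ovl, 3))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.balance_comparison <- function(object, ...) {
  tab <- object$table
  sig <- tab$measure[tab$p_bonferroni < 0.05]
  cat("Measures significantly different after Bonferroni (p < 0.05): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  cat("Measures ordered by ascending OVL (most discriminative first):\n  ",
      paste(tab$measure[order(tab$ovl)], collapse = ", "), "\n", sep = "")
  invisible(object)
}

#' Write a comparison report CSV
#'
#' One row per measure with columns
#' `measure,W_<group1>,W_<group2>,test,statistic,p_raw,p_bonf,OVL`.
#'
#' @param comparison A `balance_comparison` from [compare_groups()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  tab <- comparison$table
  out <- data.frame(measure = tab$measure, W1 = tab$W_1, W2 = tab$W_2,
                    test = tab$test, statistic = tab$statistic,
                    p_raw = tab$p_raw, p_bonf = tab$p_bonferroni,
                    OVL = tab$ovl)
  names(out)[2:3] <- paste0("W_", comparison$groups)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Principal component analysis of the feature matrix
#'
#' PCA on the z-scored measures (equivalently, the eigendecomposition of the
#' raw measures' correlation matrix). The sign of each component is fixed so
#' that its largest-magnitude loading is positive. Per-variable percentage
#' contributions are the squared loadings times 100 (each component's
#' contributions sum to 100); the reference line for "average" contribution
#' is 100 divided by the number of measures.
#'
#' @param features Feature data frame or numeric matrix of measures.
#' @param measures Measure columns used (default: [measure_names()] present).
#' @param biplot_scale Display-only scaling factor for loading vectors in
#'   biplots (default 5), carried as metadata.
#' @return An object of class `balance_pca`: list with `loadings`
#'   (measures x components, unit-norm columns), `scores` (trials x
#'   components), `variance_fraction`, `contributions` (percent), `groups`
#'   (group label per trial if available), `biplot_scale`, `mean_contribution`.
#' @export
balance_pca <- function(features, measures = NULL, biplot_scale = 5) {
  if (is.data.frame(features)) {
    if (is.null(measures)) measures <- intersect(measure_names(), names(features))
    x <- as.matrix(features[, measures, drop = FALSE])
    grp <- if ("group" %in% names(features)) as.character(features$group) else NULL
  } else {
    x <- as.matrix(features)
    if (!is.null(measures)) x <- x[, measures, drop = FALSE]
    grp <- NULL
  }
  if (nrow(x) <= ncol(x))
    stop("need more trials (", nrow(x), ") than measures (", ncol(x), ")")
  z <- zscore_normalize(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  sco <- pc$x
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = rot, scores = sco, variance_fraction = vf,
                 contributions = rot^2 * 100, groups = grp,
                 biplot_scale = biplot_scale,
                 mean_contribution = 100 / ncol(x)),
            class = "balance_pca")
}

#' @export
print.balance_pca <- function(x, ...) {
  nv <- length(x$variance_fraction)
  cat("PCA of ", nrow(x$scores), " trials x ", nrow(x$loadings),
      " measures\n", sep = "")
  cum <- cumsum(x$variance_fraction) * 100
  cat("Variance explained (%): ",
      paste(sprintf("PC%d %.1f (cum %.1f)", 1:min(4, nv),
                    100 * x$variance_fraction[1:min(4, nv)],
                    cum[1:min(4, nv)]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.balance_pca <- function(object, ...) {
  print(object)
  cat("\nContributions to PC1 and PC2 (%), mean reference ",
      round(object$mean_contribution, 2), ":\n", sep = "")
  print(round(object$contributions[, 1:2, drop = FALSE], 2))
  invisible(object)
}

#' Write PCA tables (loadings, contributions, variance fractions) as CSV
#'
#' @param pca A `balance_pca`.
#' @param prefix Path prefix; writes `<prefix>_loadings.csv`,
#'   `<prefix>_contributions.csv`, `<prefix>_variance.csv`.
#' @return Character vector of the three paths, invisibly.
#' @export
write_pca_csv <- function(pca, prefix) {
  paths <- paste0(prefix, c("_loadings.csv", "_contributions.csv",
                            "_variance.csv"))
  utils::write.csv(data.frame(measure = rownames(pca$loadings),
                              pca$loadings), paths[1], row.names = FALSE)
  utils::write.csv(data.frame(measure = rownames(pca$contributions),
                              pca$contributions), paths[2], row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(pca$variance_fraction),
                              variance_fraction = pca$variance_fraction),
                   paths[3], row.names = FALSE)
  invisible(paths)
}

#' Confidence ellipse of a 2-D point cloud
#'
#' Normal-theory ellipse: center at the sample mean, axes along the
#' eigenvectors of the sample covariance, semi-axis lengths
#' \eqn{\sqrt{\lambda_j \chi^2_{2}(level)}}.
#'
#' @param xy Two-column matrix of points (at least 3).
#' @param level Coverage level (default 0.95).
#' @return List with `center`, `radii` (semi-axes, major first), `angle`
#'   (radians, major axis vs x), `degenerate` (TRUE when the minor axis
#'   collapses, e.g. collinear points), and `cov`.
#' @export
confidence_ellipse <- function(xy, level = 0.95) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("xy must have two columns")
  if (nrow(xy) < 3L) stop("need at least 3 points")
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  q <- stats::qchisq(level, df = 2)
  radii <- sqrt(lam * q)
  tol <- 1e-10 * max(lam, .Machine$double.eps)
  list(center = ctr, radii = radii,
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       degenerate = lam[2] <= tol, cov = S)
}

#' Points on a confidence ellipse boundary
#' @param ellipse Result of [confidence_ellipse()].
#' @param n Number of boundary points.
#' @return `n x 2` matrix of boundary coordinates.
#' @export
ellipse_points <- function(ellipse, n = 100L) {
  th <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(ellipse$radii[1] * cos(th), ellipse$radii[2] * sin(th))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(circ %*% t(rot), 2, ellipse$center, `+`)
}

#' Pairwise Pearson correlations with a significance threshold
#'
#' Computes the full Pearson correlation matrix of the measures and the
#' two-sided critical absolute correlation at the given alpha derived from
#' the t distribution with `n - 2` degrees of freedom:
#' \eqn{|r|_{crit} = t_{crit}/\sqrt{t_{crit}^2 + n - 2}}. The threshold is
#' computed, never hard-coded, and reported alongside the matrix.
#'
#' @param features Feature data frame or numeric matrix.
#' @param measures Measure columns (default: [measure_names()] present).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `balance_cor`: list with `r` (correlation
#'   matrix), `r_critical`, `n`, `alpha`.
#' @export
correlation_matrix <- function(features, measures = NULL, alpha = 0.05) {
  if (is.data.frame(features)) {
    if (is.null(measures)) measures <- intersect(measure_names(), names(features))
    x <- as.matrix(features[, measures, drop = FALSE])
  } else x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 trials")
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  structure(list(r = stats::cor(x), r_critical = tcrit / sqrt(tcrit^2 + n - 2),
                 n = n, alpha = alpha),
            class = "balance_cor")
}

#' @export
print.balance_cor <- function(x, digits = 2, ...) {
  cat("Pearson correlations of ", nrow(x$r), " measures over ", x$n,
      " trials\n", sep = "")
  cat("critical |r| at alpha = ", x$alpha, ": ",
      signif(x$r_critical, 3), "\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}
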