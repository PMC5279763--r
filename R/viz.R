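#' Heat-map column index of a trial
#'
#' Participants (ordered by age) occupy `slots` columns each: their trials
#' followed by one empty spacer column, `it = (np - 1) * slots + trial`.
#' With 40 participants and 11 slots the indices run 1..440.
#'
#' @param np Participant rank (1-based, ordered by age).
#' @param trial Trial number within the participant, `1..slots` (the last
#'   slot is the spacer).
#' @param slots Columns per participant (default 11 = 10 trials + 1 spacer).
#' @return Integer column index.
#' @export
trial_index <- function(np, trial, slots = 11L) {
  if (any(np < 1L)) stop("np must be >= 1")
  if (any(trial < 1L | trial > slots))
    stop("trial must lie in 1..", slots)
  (np - 1L) * slots + trial
}

# participants ordered by age (stable within equal ages), ranks 1..P
participant_order <- function(metadata) {
  pp <- unique(metadata[, c("participant", "age")])
  pp <- pp[order(pp$age, pp$participant), ]
  structure(seq_len(nrow(pp)), names = pp$participant)
}

#' Stabilogram heat map of a cohort
#'
#' Every trial is drawn as one color-shaded vertical line of ML position
#' against time, participants ordered by age, with an empty spacer column
#' after each participant. Samples outside the plate area are excluded both
#' from drawing and from the color scaling, so a rare erroneous sample
#' cannot compress the color range.
#'
#' @param cohort A [cop_cohort] on a common time base.
#' @param time_window Two-element numeric, seconds relative to each trial's
#'   start to display (default `c(6, 26)`).
#' @param plate Plate dimensions `c(width_ml, depth_ap)` in the coordinate
#'   unit (default `c(80, 60)`); ML values beyond half the width are
#'   excluded.
#' @param slots Columns per participant (default trials + 1).
#' @param col Color palette (default a diverging palette).
#' @param draw If `FALSE`, only the plotted matrix is computed and returned.
#' @param dump_csv Optional path: writes the plotted matrix as CSV.
#' @return Invisibly, the time-by-column matrix actually plotted (`NA` in
#'   spacer columns and at excluded samples).
#' @export
stabilogram_heatmap <- function(cohort, time_window = c(6, 26),
                                plate = c(80, 60), slots = NULL,
                                col = grDevices::hcl.colors(64, "Blue-Red"),
                                draw = TRUE, dump_csv = NULL) {
  stopifnot(inherits(cohort, "cop_cohort"))
  md <- cohort$metadata
  ord <- participant_order(md)
  n_trials_max <- max(md$trial)
  if (is.null(slots)) slots <- n_trials_max + 1L
  # common relative-time grid from the first trajectory's median step
  tr1 <- cohort$trajectories[[1]]
  dt <- stats::median(diff(tr1$t))
  tgrid <- seq(time_window[1], time_window[2], by = dt)
  ncol_total <- length(ord) * slots
  mat <- matrix(NA_real_, nrow = length(tgrid), ncol = ncol_total)
  half_ml <- plate[1] / 2
  for (i in seq_along(cohort$trajectories)) {
    tr <- cohort$trajectories[[i]]
    np <- ord[[as.character(md$participant[i])]]
    it <- trial_index(np, md$trial[i], slots)
    rel <- tr$t - tr$t[1]
    ml <- tr$ml
    ml[abs(ml) > half_ml] <- NA_real_   # out-of-plate: excluded from plotting
    idx <- findInterval(tgrid, rel)
    ok <- idx >= 1 & tgrid <= rel[length(rel)]
    mat[ok, it] <- ml[idx[ok]]
  }
  if (!is.null(dump_csv))
    utils::write.csv(mat, dump_csv, row.names = FALSE)
  if (draw) {
    graphics::image(x = seq_len(ncol_total), y = tgrid, z = t(mat),
                    col = col, xlab = "trials (participants ordered by age)",
                    ylab = "time (s)", main = "CoP ML stabilograms")
  }
  invisible(mat)
}

# draw one vertical violin (density polygon) at horizontal position x0
draw_violin <- function(v, x0, width = 0.4, col = "grey70", border = NA) {
  if (length(unique(v)) < 2L) return(invisible(NULL))
  d <- stats::density(v)
  w <- width * d$y / max(d$y)
  graphics::polygon(c(x0 - w, rev(x0 + w)), c(d$x, rev(d$x)),
                    col = col, border = border)
}

#' Per-participant ML distribution violins
#'
#' One violin per participant (all trials pooled), ordered by age. Bumps at
#' the extremes show the dwell under each foot; thin valleys between them
#' show fast transitions.
#'
#' @param cohort A [cop_cohort].
#' @param plate Plate dimensions; out-of-plate ML samples are excluded from
#'   plotting.
#' @param col Fill colors, recycled per group.
#' @return Invisibly, a list of the per-participant ML vectors plotted.
#' @export
cohort_violins <- function(cohort, plate = c(80, 60),
                           col = c("#d95f0288", "#1b9e7788")) {
  md <- cohort$metadata
  ord <- participant_order(md)
  half_ml <- plate[1] / 2
  per_part <- vector("list", length(ord))
  names(per_part) <- names(ord)
  grp <- character(length(ord))
  for (i in seq_along(cohort$trajectories)) {
    p <- as.character(md$participant[i])
    ml <- cohort$trajectories[[i]]$ml
    per_part[[p]] <- c(per_part[[p]], ml[abs(ml) <= half_ml])
    grp[ord[[p]]] <- as.character(md$group[i])
  }
  glev <- unique(grp)
  graphics::plot(NULL, xlim = c(0.5, length(ord) + 0.5),
                 ylim = c(-half_ml, half_ml),
                 xlab = "participants (ordered by age)", ylab = "CoP ML",
                 main = "ML distributions per participant")
  for (p in names(ord))
    draw_violin(per_part[[p]], ord[[p]],
                col = col[match(grp[ord[[p]]], glev)])
  invisible(per_part)
}

#' Overlapping group violins per measure
#'
#' Z-scored measures on a common vertical axis; for each measure the two
#' groups' violins are overlaid and annotated with the OVL, the test
#' statistic and the corrected p-value from a [compare_groups()] result.
#' Measures are ordered by ascending OVL (most discriminative first).
#'
#' @param features Feature data frame with a `group` column.
#' @param comparison A `balance_comparison` from [compare_groups()].
#' @param col Two fill colors.
#' @return Invisibly, the measure order used (character vector).
#' @export
overlapping_violins <- function(features, comparison,
                                col = c("#d95f0288", "#1b9e7788")) {
  tab <- comparison$table
  ord_measures <- tab$measure[order(tab$ovl)]
  z <- zscore_normalize(features[, tab$measure, drop = FALSE])
  g <- as.character(features$group)
  ylim <- range(z)
  graphics::plot(NULL, xlim = c(0.5, length(ord_measures) + 0.5),
                 ylim = ylim + c(0, 0.15 * diff(ylim)),
                 xaxt = "n", xlab = "", ylab = "normalized measure",
                 main = "Group overlap per measure (ordered by OVL)")
  graphics::axis(1, at = seq_along(ord_measures), labels = ord_measures,
                 las = 2, cex.axis = 0.8)
  for (j in seq_along(ord_measures)) {
    mname <- ord_measures[j]
    row <- tab[tab$measure == mname, ]
    for (k in 1:2)
      draw_violin(z[g == comparison$groups[k], mname], j, col = col[k])
    graphics::text(j, ylim[2] + 0.08 * diff(ylim),
                   labels = sprintf("%.2f\n%.3g\n%.2g", row$ovl,
                                    row$statistic, row$p_bonferroni),
                   cex = 0.55)
  }
  invisible(ord_measures)
}

#' Parallel coordinate plot of the normalized measures
#'
#' One translucent polyline per trial across the measure axes, with a
#' boxplot (1.5 IQR whiskers) behind each axis; points beyond the whiskers
#' are outliers. Axes are ordered by ascending OVL when a comparison result
#' is supplied.
#'
#' @param features Feature data frame with a `group` column.
#' @param comparison Optional `balance_comparison` used for axis ordering.
#' @param col Two line colors (with alpha), one per group.
#' @return Invisibly, the axis order used.
#' @export
parallel_coordinates <- function(features, comparison = NULL,
                                 col = c("#d95f0233", "#1b9e7733")) {
  meas <- intersect(measure_names(), names(features))
  if (!is.null(comparison)) {
    tab <- comparison$table
    meas <- tab$measure[order(tab$ovl)]
  }
  z <- zscore_normalize(features[, meas, drop = FALSE])
  g <- as.character(features$group)
  glev <- unique(g)
  graphics::plot(NULL, xlim = c(0.5, length(meas) + 0.5), ylim = range(z),
                 xaxt = "n", xlab = "", ylab = "normalized measure",
                 main = "Parallel coordinates")
  graphics::axis(1, at = seq_along(meas), labels = meas, las = 2,
                 cex.axis = 0.8)
  graphics::boxplot(as.data.frame(z), at = seq_along(meas), add = TRUE,
                    axes = FALSE, outline = TRUE, boxwex = 0.25,
                    col = "grey92", range = 1.5)
  for (i in seq_len(nrow(z)))
    graphics::lines(seq_along(meas), z[i, ], col = col[match(g[i], glev)])
  invisible(meas)
}

#' PCA biplot with group ellipses
#'
#' Trial scores on the first two components colored by group, loading
#' vectors multiplied by the display scale (default 5 - a constant factor
#' does not change the biplot's interpretation), and a 95% confidence
#' ellipse per group.
#'
#' @param pca A `balance_pca` from [balance_pca()].
#' @param groups Optional group label per trial (default: taken from the
#'   PCA object).
#' @param vector_scale Loading-vector display scale (default: the PCA
#'   object's `biplot_scale`).
#' @param level Ellipse coverage (default 0.95).
#' @param col Point/ellipse colors per group.
#' @return Invisibly, a list with the scores, scaled vectors and ellipses.
#' @export
pca_biplot <- function(pca, groups = NULL, vector_scale = NULL,
                       level = 0.95, col = c("#d95f02", "#1b9e77")) {
  if (is.null(groups)) groups <- pca$groups
  if (is.null(vector_scale)) vector_scale <- pca$biplot_scale
  sc <- pca$scores[, 1:2, drop = FALSE]
  vec <- pca$loadings[, 1:2, drop = FALSE] * vector_scale
  glev <- if (is.null(groups)) NULL else unique(groups)
  ptcol <- if (is.null(groups)) "grey40" else col[match(groups, glev)]
  graphics::plot(sc, col = ptcol, pch = 16, cex = 0.6,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * pca$variance_fraction[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * pca$variance_fraction[2]),
                 main = "PCA biplot")
  graphics::arrows(0, 0, vec[, 1], vec[, 2], length = 0.08, col = "grey25")
  graphics::text(vec * 1.08, labels = rownames(vec), cex = 0.7)
  ells <- NULL
  if (!is.null(glev)) {
    ells <- lapply(glev, function(g)
      confidence_ellipse(sc[groups == g, , drop = FALSE], level = level))
    names(ells) <- glev
    for (k in seq_along(glev))
      graphics::lines(ellipse_points(ells[[k]]), col = col[k], lwd = 2)
  }
  invisible(list(scores = sc, vectors = vec, ellipses = ells))
}

#' Scatter plot and correlation matrix
#'
#' Lower triangle: pairwise scatter plots of the z-scored measures, with
#' values beyond `clip` excluded from display only (to keep the panels'
#' aspect useful). Upper triangle: Pearson correlations computed on the
#' full, unclipped data, printed with font size proportional to `|r|`.
#'
#' @param features Feature data frame (a `group` column colors the points).
#' @param clip Display-only clipping threshold on the normalized scale
#'   (default 3.4).
#' @param alpha Significance level for the reported critical `|r|`.
#' @param col Point colors per group.
#' @return Invisibly, the [correlation_matrix()] result (computed on
#'   unclipped data).
#' @export
scatter_corr_matrix <- function(features, clip = 3.4, alpha = 0.05,
                                col = c("#d95f02", "#1b9e77")) {
  meas <- intersect(measure_names(), names(features))
  z <- zscore_normalize(features[, meas, drop = FALSE])
  cm <- correlation_matrix(features, measures = meas, alpha = alpha)
  g <- if ("group" %in% names(features)) as.character(features$group) else NULL
  glev <- if (is.null(g)) NULL else unique(g)
  ptcol <- if (is.null(g)) "grey40" else col[match(g, glev)]
  p <- length(meas)
  op <- graphics::par(mfrow = c(p, p), mar = c(0.4, 0.4, 0.4, 0.4))
  on.exit(graphics::par(op))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i > j) {
      keep <- abs(z[, j]) <= clip & abs(z[, i]) <= clip  # display only
      graphics::plot(z[keep, j], z[keep, i], pch = 16, cex = 0.3,
                     col = ptcol[keep], axes = FALSE)
      graphics::box(col = "grey80")
    } else if (i < j) {
      r <- cm$r[meas[i], meas[j]]
      graphics::plot.new()
      graphics::text(0.5, 0.5, sprintf("%.2f", r),
                     cex = 0.6 + 2.2 * abs(r))
      graphics::box(col = "grey80")
    } else {
      graphics::plot.new()
      graphics::text(0.5, 0.5, meas[i], cex = 0.9, font = 2)
      graphics::box(col = "grey80")
    }
  }
  invisible(cm)
}

#' Heat map of the normalized feature matrix
#'
#' Trials along the horizontal axis (participants ordered by age, spacer
#' column per participant), measures along the vertical axis, per-measure
#' min-max scaling for display.
#'
#' @param features Feature data frame with metadata columns.
#' @param col Sequential palette.
#' @return Invisibly, the measures-by-columns matrix plotted.
#' @export
feature_heatmap <- function(features,
                            col = grDevices::hcl.colors(64, "Reds", rev = TRUE)) {
  meas <- intersect(measure_names(), names(features))
  ord <- participant_order(features)
  slots <- max(features$trial) + 1L
  ncol_total <- length(ord) * slots
  mat <- matrix(NA_real_, nrow = length(meas), ncol = ncol_total,
                dimnames = list(meas, NULL))
  for (i in seq_len(nrow(features))) {
    it <- trial_index(ord[[as.character(features$participant[i])]],
                      features$trial[i], slots)
    mat[, it] <- as.numeric(features[i, meas])
  }
  disp <- t(apply(mat, 1, function(v) {
    rng <- range(v, na.rm = TRUE)
    (v - rng[1]) / (rng[2] - rng[1])
  }))
  graphics::image(x = seq_len(ncol_total), y = seq_along(meas), z = t(disp),
                  col = col, yaxt = "n",
                  xlab = "trials (participants ordered by age)", ylab = "",
                  main = "Normalized measures by trial")
  graphics::axis(2, at = seq_along(meas), labels = meas, las = 2,
                 cex.axis = 0.8)
  invisible(mat)
}
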