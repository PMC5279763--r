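#' CoP trajectory container
#'
#' A `cop_trajectory` holds one trial's timestamped center-of-pressure path:
#' the times `t` (seconds, strictly increasing), the medial-lateral (`ml`)
#' and anterior-posterior (`ap`) coordinates, and identifying metadata.
#' The path is the planar curve \eqn{\gamma(t_i) = (ML(t_i), AP(t_i))},
#' \eqn{i = 1, \dots, N}.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param ml Numeric vector of medial-lateral coordinates (length units,
#'   centimeters for the synthetic generator).
#' @param ap Numeric vector of anterior-posterior coordinates, same length.
#' @param participant,group,age,trial,condition Scalar trial metadata.
#'   `group` is typically an age-group label such as `"older"`/`"younger"`.
#' @param unit Length unit the coordinates are expressed in (metadata only;
#'   curvature has dimension 1/length, so reported magnitudes depend on it).
#'
#' @return An object of class `cop_trajectory`: a list with elements `t`,
#'   `ml`, `ap`, `participant`, `group`, `age`, `trial`, `condition`, `unit`.
#' @examples
#' tr <- cop_trajectory(t = seq(0, 1, by = 0.1),
#'                      ml = sin(seq(0, 1, by = 0.1)),
#'                      ap = rep(0, 11))
#' tr
#' @export
cop_trajectory <- function(t, ml, ap, participant = NA, group = NA,
                           age = NA, trial = NA, condition = NA,
                           unit = "cm") {
  t <- as.numeric(t); ml <- as.numeric(ml); ap <- as.numeric(ap)
  n <- length(t)
  if (length(ml) != n || length(ap) != n)
    stop("t, ml and ap must have equal length")
  if (n < 3L)
    stop("a CoP trajectory needs at least 3 samples, got ", n)
  if (anyNA(t) || any(!is.finite(t)))
    stop("timestamps must be finite")
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop("timestamps must be strictly increasing; violation at index ", bad)
  }
  if (any(!is.finite(ml)) || any(!is.finite(ap)))
    stop("coordinate values must be finite")
  structure(
    list(t = t, ml = ml, ap = ap,
         participant = participant, group = group, age = age,
         trial = trial, condition = condition, unit = unit),
    class = "cop_trajectory"
  )
}

#' @export
print.cop_trajectory <- function(x, ...) {
  n <- length(x$t)
  cat("CoP trajectory: ", n, " samples over ",
      format(round(x$t[n] - x$t[1], 3)), " s\n", sep = "")
  if (!is.na(x$participant))
    cat("  participant ", x$participant,
        if (!is.na(x$group)) paste0(" (", x$group, ")"),
        if (!is.na(x$trial)) paste0(", trial ", x$trial),
        if (!is.na(x$condition)) paste0(", condition ", x$condition),
        "\n", sep = "")
  cat("  ML range [", format(round(min(x$ml), 3)), ", ",
      format(round(max(x$ml), 3)), "] ", x$unit,
      "; AP range [", format(round(min(x$ap), 3)), ", ",
      format(round(max(x$ap), 3)), "] ", x$unit, "\n", sep = "")
  invisible(x)
}

#' @export
length.cop_trajectory <- function(x) length(x$t)

#' Duration of a trajectory in seconds
#' @param traj A [cop_trajectory].
#' @return Elapsed time between first and last sample.
#' @export
trajectory_duration <- function(traj) {
  traj$t[length(traj$t)] - traj$t[1]
}

#' CoP cohort container
#'
#' Bundles a list of [cop_trajectory] objects with a one-row-per-trial
#' metadata table, the usual unit of exchange between the simulator, the
#' preprocessing stage and the feature extractor.
#'
#' @param trajectories List of [cop_trajectory] objects.
#' @param metadata Data frame with one row per trajectory and columns
#'   `participant`, `group`, `age`, `trial`, `condition`.
#' @return An object of class `cop_cohort`.
#' @export
cop_cohort <- function(trajectories, metadata) {
  if (!is.list(trajectories) ||
      !all(vapply(trajectories, inherits, logical(1), "cop_trajectory")))
    stop("trajectories must be a list of cop_trajectory objects")
  if (nrow(metadata) != length(trajectories))
    stop("metadata must have exactly one row per trajectory (",
         nrow(metadata), " rows vs ", length(trajectories), " trajectories)")
  needed <- c("participant", "group", "age", "trial", "condition")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  structure(list(trajectories = trajectories, metadata = metadata),
            class = "cop_cohort")
}

#' @export
print.cop_cohort <- function(x, ...) {
  cat("CoP cohort: ", length(x$trajectories), " trials, ",
      length(unique(x$metadata$participant)), " participants, groups: ",
      paste(unique(x$metadata$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.cop_cohort <- function(x) length(x$trajectories)

#' Write / read a cohort as long-format CSV
#'
#' One row per sample, columns
#' `participant,group,age,trial,condition,t,ml,ap`. The same schema is
#' accepted for real force-plate exports.
#'
#' @param cohort A [cop_cohort].
#' @param path Output (input) CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a [cop_cohort].
#' @export
write_cohort_csv <- function(cohort, path) {
  rows <- lapply(seq_along(cohort$trajectories), function(i) {
    tr <- cohort$trajectories[[i]]
    md <- cohort$metadata[i, ]
    data.frame(participant = md$participant, group = md$group, age = md$age,
               trial = md$trial, condition = md$condition,
               t = tr$t, ml = tr$ml, ap = tr$ap)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant", "group", "age", "trial", "condition",
              "t", "ml", "ap")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("cohort CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  key <- interaction(df$participant, df$trial, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(df)), key)
  # preserve file order of first appearance
  first <- vapply(idx, min, integer(1))
  idx <- idx[order(first)]
  trajs <- vector("list", length(idx))
  meta <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    d <- df[idx[[j]], ]
    trajs[[j]] <- cop_trajectory(d$t, d$ml, d$ap,
                                 participant = d$participant[1],
                                 group = d$group[1], age = d$age[1],
                                 trial = d$trial[1],
                                 condition = d$condition[1])
    meta[[j]] <- data.frame(participant = d$participant[1],
                            group = d$group[1], age = d$age[1],
                            trial = d$trial[1], condition = d$condition[1])
  }
  cop_cohort(trajs, do.call(rbind, meta))
}
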