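#' Resample a trajectory onto a uniform grid
#'
#' Force plates often deliver non-uniformly spaced samples. All windowed
#' measures assume a fixed sampling rate, so recordings are first
#' interpolated onto an arithmetic time grid with step `1/target_rate`
#' spanning `[t[1], t[N]]`, using cubic spline interpolation (`stats::splinefun`,
#' method `"fmm"`) through every input sample. No smoothing is applied at any
#' point: the spline interpolates its knots exactly, and the package
#' deliberately offers no low-pass filtering option, because filtering can
#' remove exactly the irregularity the measures quantify.
#'
#' @param traj A [cop_trajectory] with at least 4 samples.
#' @param target_rate Target sampling rate in Hz (default 170).
#' @return A resampled [cop_trajectory] on the uniform grid.
#' @seealso [trim_ends()], [preprocess()]
#' @examples
#' tr <- cop_trajectory(c(0, 0.1, 0.25, 0.3, 0.5), ml = rnorm(5), ap = rnorm(5))
#' resample_uniform(tr, target_rate = 100)
#' @export
resample_uniform <- function(traj, target_rate = 170) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (target_rate <= 0) stop("target_rate must be positive")
  n <- length(traj$t)
  if (n < 4L)
    stop("cubic spline resampling needs at least 4 samples, got ", n)
  t0 <- traj$t[1]
  span <- traj$t[n] - t0
  grid <- t0 + seq.int(0L, floor(span * target_rate)) / target_rate
  ml <- stats::splinefun(traj$t, traj$ml, method = "fmm")(grid)
  ap <- stats::splinefun(traj$t, traj$ap, method = "fmm")(grid)
  cop_trajectory(grid, ml, ap,
                 participant = traj$participant, group = traj$group,
                 age = traj$age, trial = traj$trial,
                 condition = traj$condition, unit = traj$unit)
}

#' Trim the ends of a trial
#'
#' The first seconds of a recording are typically setup movement and the
#' last seconds may extend past the exercise, so a fixed margin is removed
#' from both ends before feature extraction (default 6 s, leaving 36 s of a
#' 48 s trial). Trimming is anchored at the first and last sample times.
#'
#' @param traj A [cop_trajectory].
#' @param trim_seconds Margin removed from each end, in seconds (default 6).
#' @return The trimmed [cop_trajectory]; metadata is preserved.
#' @export
trim_ends <- function(traj, trim_seconds = 6) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (trim_seconds < 0) stop("trim_seconds must be >= 0")
  if (trim_seconds == 0) return(traj)
  dur <- trajectory_duration(traj)
  if (dur <= 2 * trim_seconds)
    stop("trial duration (", round(dur, 3), " s) must exceed twice the trim margin (",
         2 * trim_seconds, " s)")
  lo <- traj$t[1] + trim_seconds
  hi <- traj$t[length(traj$t)] - trim_seconds
  keep <- traj$t >= lo & traj$t <= hi
  cop_trajectory(traj$t[keep], traj$ml[keep], traj$ap[keep],
                 participant = traj$participant, group = traj$group,
                 age = traj$age, trial = traj$trial,
                 condition = traj$condition, unit = traj$unit)
}

#' Standard preprocessing: resample, then trim
#'
#' Applies [resample_uniform()] followed by [trim_ends()] to a single
#' trajectory or to every trial of a cohort. Resampling first keeps window
#' sizes expressed in samples meaningful after trimming.
#'
#' @param x A [cop_trajectory] or [cop_cohort].
#' @param target_rate Sampling rate in Hz (default 170).
#' @param trim_seconds End margin in seconds (default 6).
#' @return Object of the same class as `x`.
#' @export
preprocess <- function(x, target_rate = 170, trim_seconds = 6) {
  if (inherits(x, "cop_cohort")) {
    trajs <- lapply(x$trajectories, preprocess,
                    target_rate = target_rate, trim_seconds = trim_seconds)
    return(cop_cohort(trajs, x$metadata))
  }
  trim_ends(resample_uniform(x, target_rate), trim_seconds)
}

#' CoP coordinates from force-plate moments and vertical force
#'
#' Standard convenience conversion: `ml = -my / fz`, `ap = mx / fz` (sign
#' convention of a plate with x pointing forward). Samples where `|fz|`
#' falls below `fz_threshold` are flagged invalid and returned as `NA`
#' rather than silently divided.
#'
#' @param mx,my Numeric vectors of plate moments about the x and y axes.
#' @param fz Numeric vector of vertical force, same length.
#' @param fz_threshold Minimum `|fz|` considered a valid stance sample.
#' @return A data frame with columns `ml`, `ap`, `valid`.
#' @export
cop_from_forces <- function(mx, my, fz, fz_threshold = 10) {
  n <- length(fz)
  if (length(mx) != n || length(my) != n)
    stop("mx, my and fz must have equal length")
  valid <- is.finite(fz) & abs(fz) >= fz_threshold
  ml <- ap <- rep(NA_real_, n)
  ml[valid] <- -my[valid] / fz[valid]
  ap[valid] <- mx[valid] / fz[valid]
  data.frame(ml = ml, ap = ap, valid = valid)
}
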