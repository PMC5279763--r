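#' Per-sample feature series
#'
#' A `feature_series` is a numeric vector aligned with the samples of one
#' trajectory, together with the index interval on which the measure is
#' defined. Windowed measures with half-width `n` are defined only for
#' `k = n+1, ..., N-n`; samples outside the valid range (and samples where a
#' denominator fell below the epsilon guard) are `NA`, never zero-filled.
#'
#' @param values Numeric vector of length N (NA where undefined).
#' @param name Measure name, one of `"FM"`, `"Speed"`, `"SD"`, `"RMS"`,
#'   `"CoV"`, `"SDp"`, `"RMSp"`, `"CoVp"`, `"I"`, `"Ip"`, `"kappa"`, `"d"`.
#' @param valid Integer vector `c(lo, hi)`: first and last defined index.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, name, valid = c(1L, length(values))) {
  values <- as.numeric(values)
  lo <- as.integer(valid[1]); hi <- as.integer(valid[2])
  if (lo > hi) stop("empty valid range for series ", name,
                    " (trajectory shorter than the window?)")
  if (lo > 1L) values[seq_len(lo - 1L)] <- NA_real_
  if (hi < length(values)) values[(hi + 1L):length(values)] <- NA_real_
  structure(values, measure = name, valid_range = c(lo, hi),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  vr <- attr(x, "valid_range")
  v <- unclass(x)[vr[1]:vr[2]]
  cat("Feature series ", attr(x, "measure"), ": length ", length(x),
      ", valid indices [", vr[1], ", ", vr[2], "], ",
      sum(!is.na(v)), " defined values\n", sep = "")
  cat("  median ", format(stats::median(v, na.rm = TRUE)),
      ", mean ", format(mean(v, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Defined values of a feature series
#' @param fs A [feature_series].
#' @return Numeric vector of the non-`NA` values inside the valid range.
#' @export
defined_values <- function(fs) {
  vr <- attr(fs, "valid_range")
  v <- unclass(fs)[vr[1]:vr[2]]
  v[!is.na(v)]
}

# window matrix: row k' = samples (k-n)..(k+n) for k = n+1..N-n.
# Explicit two-pass statistics on this matrix keep the arithmetic identical
# to a naive per-window loop (no running-sum cancellation).
roll_matrix <- function(x, n) {
  N <- length(x)
  K <- N - 2L * n
  if (K < 1L) stop("trajectory too short for window half-width n = ", n,
                   " (need at least ", 2L * n + 1L, " samples, got ", N, ")")
  idx <- rep(seq_len(K) + n, times = 2L * n + 1L) +
    rep(seq.int(-n, n), each = K)
  matrix(x[idx], nrow = K)
}

#' Fluctuation from the mean (FM)
#'
#' Per-sample Euclidean distance of the CoP from its whole-trial mean
#' position:
#' \deqn{FM(t_i) = \sqrt{(AP_i - \bar{AP})^2 + (ML_i - \bar{ML})^2}.}
#' Defined at every sample.
#'
#' @param traj A [cop_trajectory].
#' @return A [feature_series] named `"FM"`.
#' @export
fluctuation_from_mean <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  fm <- sqrt((traj$ap - mean(traj$ap))^2 + (traj$ml - mean(traj$ml))^2)
  feature_series(fm, "FM")
}

#' Instantaneous speed
#'
#' Backward-difference Euclidean speed
#' \deqn{v(t_i) = \lVert\gamma(t_i) - \gamma(t_{i-1})\rVert / (t_i - t_{i-1})}
#' for `i = 2, ..., N`, with `v(t_1) = 0` by definition.
#'
#' @param traj A [cop_trajectory].
#' @param eps Smallest admissible time step; a repeated timestamp raises an
#'   error rather than dividing by zero.
#' @return A [feature_series] named `"Speed"` (length units per second).
#' @export
instantaneous_speed <- function(traj, eps = 1e-12) {
  stopifnot(inherits(traj, "cop_trajectory"))
  dt <- diff(traj$t)
  if (any(dt <= eps)) {
    bad <- which(dt <= eps)[1L] + 1L
    stop("repeated timestamp at index ", bad, ": zero time step")
  }
  v <- c(0, sqrt(diff(traj$ml)^2 + diff(traj$ap)^2) / dt)
  feature_series(v, "Speed")
}

#' Windowed dispersion of the fluctuation from the mean
#'
#' For every window of `s = 2n + 1` samples centered at `k`
#' (`k = n+1, ..., N-n`), with local mean \eqn{\bar{FM}_k}:
#' * `SD`: \eqn{\sqrt{\frac{1}{s}\sum (FM_i - \bar{FM}_k)^2}} (population form),
#' * `RMS`: \eqn{\sqrt{\frac{1}{s}\sum FM_i^2}},
#' * `CoV`: \eqn{SD(t_k) / \bar{FM}_k} (undefined where the local mean is
#'   below `eps`).
#'
#' The identity \eqn{RMS^2 = SD^2 + \bar{FM}^2} holds at every valid index.
#'
#' @param fm A [feature_series] `"FM"` from [fluctuation_from_mean()].
#' @param n Window half-width in samples (default 25, i.e. 51 samples =
#'   0.3 s at 170 Hz).
#' @param eps Denominator guard for `CoV`.
#' @return List with components `SD`, `RMS`, `CoV`, each a [feature_series].
#' @export
windowed_dispersion <- function(fm, n = 25L, eps = 1e-12) {
  x <- as.numeric(fm)
  N <- length(x)
  M <- roll_matrix(x, n)
  mu <- rowMeans(M)
  sd_w <- sqrt(rowMeans((M - mu)^2))
  rms_w <- sqrt(rowMeans(M * M))
  cov_w <- ifelse(abs(mu) > eps, sd_w / mu, NA_real_)
  pad <- function(v) {
    out <- rep(NA_real_, N)
    out[(n + 1L):(N - n)] <- v
    out
  }
  valid <- c(n + 1L, N - n)
  list(SD = feature_series(pad(sd_w), "SD", valid),
       RMS = feature_series(pad(rms_w), "RMS", valid),
       CoV = feature_series(pad(cov_w), "CoV", valid))
}

#' Distance travelled within the window
#'
#' Sum of the Euclidean lengths of the trajectory segments lying fully
#' inside the window centered at `k`: segments between samples
#' `k-n, ..., k+n`, i.e. `2n` segment lengths.
#'
#' @param traj A [cop_trajectory].
#' @param n Window half-width in samples.
#' @return A [feature_series] named `"d"` (length units).
#' @export
distance_travelled <- function(traj, n = 25L) {
  stopifnot(inherits(traj, "cop_trajectory"))
  N <- length(traj$t)
  if (N < 2L * n + 1L)
    stop("trajectory too short for window half-width n = ", n)
  seg <- sqrt(diff(traj$ml)^2 + diff(traj$ap)^2)
  cs <- c(0, cumsum(seg))
  k <- (n + 1L):(N - n)
  d <- cs[k + n] - cs[k - n]         # segments (k-n)..(k+n-1)
  out <- rep(NA_real_, N)
  out[k] <- d
  feature_series(out, "d", c(n + 1L, N - n))
}

#' Distance-normalized dispersion variants
#'
#' Divides each windowed dispersion measure by the distance travelled in the
#' same window: `SD' = SD/d`, `RMS' = RMS/d`, `CoV' = CoV/d`. Movers covering
#' more ground within a window are thereby distinguished from slow movers
#' with the same dispersion. Undefined where `d` is below `eps`.
#'
#' @param disp List from [windowed_dispersion()].
#' @param d A [feature_series] `"d"` from [distance_travelled()].
#' @param eps Denominator guard.
#' @return List with components `SDp`, `RMSp`, `CoVp` ([feature_series]).
#' @export
normalized_dispersion <- function(disp, d, eps = 1e-12) {
  vr1 <- attr(disp$SD, "valid_range"); vr2 <- attr(d, "valid_range")
  if (!identical(vr1, vr2))
    stop("dispersion and distance series have mismatched valid ranges")
  dd <- as.numeric(d)
  safe <- !is.na(dd) & dd > eps
  ratio <- function(fs, nm) {
    v <- as.numeric(fs)
    out <- rep(NA_real_, length(v))
    out[safe] <- v[safe] / dd[safe]
    feature_series(out, nm, vr1)
  }
  list(SDp = ratio(disp$SD, "SDp"),
       RMSp = ratio(disp$RMS, "RMSp"),
       CoVp = ratio(disp$CoV, "CoVp"))
}

# shared windowed CoV machinery for speed-based turbulence measures
windowed_sd_over <- function(v, n, denom_fun, eps) {
  N <- length(v)
  M <- roll_matrix(v, n)
  mu <- rowMeans(M)
  sd_w <- sqrt(rowMeans((M - mu)^2))
  den <- denom_fun(M, mu)
  out <- rep(NA_real_, N)
  out[(n + 1L):(N - n)] <- ifelse(abs(den) > eps, sd_w / den, NA_real_)
  list(values = out, valid = c(n + 1L, N - n))
}

#' Turbulence intensity of speed
#'
#' The windowed coefficient of variation of instantaneous speed,
#' \deqn{I(t_k) = \frac{\sqrt{\frac{1}{s}\sum_{i=k-n}^{k+n}(v_i - \mu_k)^2}}{\mu_k},
#'   \quad \mu_k = \frac{1}{s}\sum v_i,}
#' a unitless turbulence measure borrowed from fluid dynamics: the local
#' variability of speed relative to its local level.
#'
#' @param speed A [feature_series] `"Speed"`.
#' @param n Window half-width in samples.
#' @param eps Denominator guard.
#' @return A [feature_series] named `"I"` (unitless).
#' @export
turbulence_intensity <- function(speed, n = 25L, eps = 1e-12) {
  r <- windowed_sd_over(as.numeric(speed), n, function(M, mu) mu, eps)
  feature_series(r$values, "I", r$valid)
}

#' Turbulence intensity variant with mean-square denominator
#'
#' Like [turbulence_intensity()] but normalized by the windowed mean of
#' squared speed, \eqn{\mu'_k = \frac{1}{s}\sum v_i^2}:
#' \deqn{I'(t_k) = SD_w(v) / \mu'_k.}
#' Unlike `I`, this variant is not scale invariant (it has dimension
#' 1/speed), which makes it sensitive to the absolute speed level: faster,
#' smoother movers score lower `I'`.
#'
#' @inheritParams turbulence_intensity
#' @return A [feature_series] named `"Ip"`.
#' @export
turbulence_intensity_prime <- function(speed, n = 25L, eps = 1e-12) {
  r <- windowed_sd_over(as.numeric(speed), n,
                        function(M, mu) rowMeans(M * M), eps)
  feature_series(r$values, "Ip", r$valid)
}

#' Discrete curvature from three consecutive points
#'
#' Curvature of the circle through \eqn{\gamma(t_{i-1}), \gamma(t_i),
#' \gamma(t_{i+1})}, computed from the triangle with side lengths `a`, `b`,
#' `c` via Heron's formula:
#' \deqn{\kappa(t_i) = \frac{4\,\triangle_{abc}}{abc}, \quad
#'   \triangle_{abc} = \sqrt{\hat{s}(\hat{s}-a)(\hat{s}-b)(\hat{s}-c)},
#'   \quad \hat{s} = (a+b+c)/2,}
#' for `i = 2, ..., N-1`. Collinear triples give 0; coincident consecutive
#' points (any side below `eps`) give 0 and are flagged in the
#' `"degenerate"` attribute. A negative Heron radicand arising from
#' floating-point cancellation is clamped to 0.
#'
#' Units are 1/length: doubling the coordinates halves every curvature.
#'
#' @param traj A [cop_trajectory].
#' @param eps Degenerate side-length threshold.
#' @return A [feature_series] named `"kappa"`, valid on `[2, N-1]`, with an
#'   integer attribute `"degenerate"` listing flagged indices.
#' @export
curvature <- function(traj, eps = 1e-12) {
  stopifnot(inherits(traj, "cop_trajectory"))
  N <- length(traj$t)
  ml <- traj$ml; ap <- traj$ap
  seg <- sqrt(diff(ml)^2 + diff(ap)^2)
  a <- seg[1:(N - 2L)]                          # |gamma_i - gamma_{i-1}|
  b <- seg[2:(N - 1L)]                          # |gamma_{i+1} - gamma_i|
  cc <- sqrt((ml[3:N] - ml[1:(N - 2L)])^2 +
             (ap[3:N] - ap[1:(N - 2L)])^2)      # |gamma_{i+1} - gamma_{i-1}|
  sh <- (a + b + cc) / 2
  area <- sqrt(pmax(sh * (sh - a) * (sh - b) * (sh - cc), 0))
  abc <- a * b * cc
  ok <- a > eps & b > eps & cc > eps
  kap <- numeric(N - 2L)
  kap[ok] <- 4 * area[ok] / abc[ok]
  out <- rep(NA_real_, N)
  out[2:(N - 1L)] <- kap
  fs <- feature_series(out, "kappa", c(2L, N - 1L))
  attr(fs, "degenerate") <- which(!ok) + 1L
  fs
}

#' Compute all per-sample balance measures of a trial
#'
#' Runs [fluctuation_from_mean()], [instantaneous_speed()],
#' [windowed_dispersion()], [distance_travelled()],
#' [normalized_dispersion()], [turbulence_intensity()],
#' [turbulence_intensity_prime()] and [curvature()] with one shared window
#' configuration.
#'
#' @param traj A preprocessed [cop_trajectory] on a uniform grid.
#' @param n Window half-width in samples (default 25; 0.3 s at 170 Hz).
#' @param eps Epsilon guard for all denominators.
#' @param max_sway_freq Maximum expected sway frequency in Hz used to check
#'   that the window is shorter than half a sway cycle (default 0.65).
#' @param rate Sampling rate in Hz used for the window-length check; if
#'   `NULL`, inferred from the median time step.
#' @return Named list of [feature_series]: `FM`, `Speed`, `SD`, `RMS`,
#'   `CoV`, `d`, `SDp`, `RMSp`, `CoVp`, `I`, `Ip`, `kappa`.
#' @export
compute_features <- function(traj, n = 25L, eps = 1e-12,
                             max_sway_freq = 0.65, rate = NULL) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (is.null(rate)) rate <- 1 / stats::median(diff(traj$t))
  s <- 2L * n + 1L
  half_cycle <- 1 / (2 * max_sway_freq)
  if (s / rate >= half_cycle)
    warning("window of ", s, " samples (", round(s / rate, 3),
            " s) is not shorter than half a sway cycle at ",
            max_sway_freq, " Hz (", round(half_cycle, 3), " s)")
  fm <- fluctuation_from_mean(traj)
  v <- instantaneous_speed(traj, eps = eps)
  disp <- windowed_dispersion(fm, n = n, eps = eps)
  d <- distance_travelled(traj, n = n)
  prim <- normalized_dispersion(disp, d, eps = eps)
  list(FM = fm, Speed = v,
       SD = disp$SD, RMS = disp$RMS, CoV = disp$CoV, d = d,
       SDp = prim$SDp, RMSp = prim$RMSp, CoVp = prim$CoVp,
       I = turbulence_intensity(v, n = n, eps = eps),
       Ip = turbulence_intensity_prime(v, n = n, eps = eps),
       kappa = curvature(traj, eps = eps))
}

#' Canonical names of the eleven per-trial measures
#' @return Character vector of the measure column names in canonical order.
#' @export
measure_names <- function() {
  c("SD", "RMS", "CoV", "SDp", "RMSp", "CoVp", "I", "Ip", "Speed",
    "kappa_median", "kappa_mean")
}

#' Summarize one trial into its eleven-measure row
#'
#' Collapses each per-sample series to its median over the valid range
#' (undefined samples excluded); curvature additionally keeps the arithmetic
#' mean, which unlike the median is sensitive to rare extreme values - both
#' views are retained deliberately.
#'
#' @param traj A preprocessed [cop_trajectory].
#' @inheritParams compute_features
#' @return One-row data frame: metadata columns `participant`, `group`,
#'   `age`, `trial`, `condition`, then the columns of [measure_names()].
#' @export
summarize_trial <- function(traj, n = 25L, eps = 1e-12,
                            max_sway_freq = 0.65, rate = NULL) {
  f <- compute_features(traj, n = n, eps = eps,
                        max_sway_freq = max_sway_freq, rate = rate)
  med <- function(fs) stats::median(defined_values(fs))
  data.frame(
    participant = traj$participant, group = traj$group, age = traj$age,
    trial = traj$trial, condition = traj$condition,
    SD = med(f$SD), RMS = med(f$RMS), CoV = med(f$CoV),
    SDp = med(f$SDp), RMSp = med(f$RMSp), CoVp = med(f$CoVp),
    I = med(f$I), Ip = med(f$Ip), Speed = med(f$Speed),
    kappa_median = med(f$kappa),
    kappa_mean = mean(defined_values(f$kappa))
  )
}

#' Extract the trial-by-measure feature matrix of a cohort
#'
#' Applies [summarize_trial()] to every trial. With the default study design
#' (2 groups of 20 participants, 10 trials each) this is the 400-row,
#' 11-measure matrix all group statistics operate on. Trials too short for
#' the window are dropped with a warning rather than aborting the run.
#'
#' @param cohort A preprocessed [cop_cohort].
#' @inheritParams compute_features
#' @return Data frame with one row per trial: metadata columns plus the 11
#'   measures of [measure_names()].
#' @export
extract_features <- function(cohort, n = 25L, eps = 1e-12,
                             max_sway_freq = 0.65, rate = NULL) {
  stopifnot(inherits(cohort, "cop_cohort"))
  rows <- vector("list", length(cohort$trajectories))
  for (i in seq_along(rows)) {
    rows[[i]] <- tryCatch(
      summarize_trial(cohort$trajectories[[i]], n = n, eps = eps,
                      max_sway_freq = max_sway_freq, rate = rate),
      error = function(e) {
        warning("trial ", i, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a feature matrix CSV
#'
#' Metadata columns (`participant`, `group`, `age`, `trial`, `condition`)
#' followed by the canonical measure columns of [measure_names()].
#' `read_features_csv` also accepts a bare matrix CSV that has at least a
#' `group` column plus measure columns, so externally computed
#' trial-by-measure tables can enter the statistics stage directly.
#'
#' @param features Data frame from [extract_features()].
#' @param path CSV file path.
#' @return `write_features_csv` returns `path` invisibly;
#'   `read_features_csv` returns the feature data frame.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(df))
    stop("feature CSV lacks required column: group")
  found <- intersect(measure_names(), names(df))
  if (length(found) == 0L)
    stop("feature CSV contains none of the canonical measure columns: ",
         paste(measure_names(), collapse = ", "))
  df
}
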