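#' Group profile for the synthetic sway generator
#'
#' Describes the lateral-sway statistics of one age group. The medial-lateral
#' component is modeled as a smoothed square wave
#' \eqn{ML(t) = A \tanh(\beta \sin(2\pi f t + \phi)) / \tanh(\beta)}:
#' the CoP dwells under one foot, transitions quickly to the other, and the
#' sharpness \eqn{\beta} controls how square (fast and smooth) the
#' transitions are. The anterior-posterior component is a smooth band-limited
#' wander (the stance leg keeps working while the CoP dwells under one foot),
#' and a small broadband measurement/physiological tremor is added to both
#' coordinates.
#'
#' At the sample scale the tremor and wander control the geometry of the
#' discrete path: the smooth wander adds speed without roughness, whereas
#' white tremor bends consecutive chords, raising curvature and the
#' mean-square-normalized turbulence intensity most where motion is slow.
#'
#' @param amplitude_mean,amplitude_sd Half peak-to-peak ML excursion (cm):
#'   per-participant amplitude is drawn once from this distribution.
#' @param sway_frequency_mean,sway_frequency_sd Sway frequency (Hz); must
#'   stay within (0, 0.65], the maximum sway frequency observed in this kind
#'   of lateral weight-shifting exercise.
#' @param transition_sharpness Dimensionless \eqn{\beta > 0}; larger values
#'   give squarer waves, i.e. faster and smoother transitions.
#' @param tremor_noise_sd White jitter SD added to both coordinates (cm);
#'   the main source of sample-scale irregularity (raises curvature and I').
#' @param ap_drift_scale SD of the smooth band-limited AP wander (cm);
#'   livelier wander means higher sustained speed between transitions.
#' @param outlier_prob Per-sample probability of an erroneous measurement
#'   far outside the plate; must be below 5e-4 (rare by design).
#' @return An object of class `group_profile`.
#' @seealso [default_profiles()], [cohort_config()]
#' @export
group_profile <- function(amplitude_mean, amplitude_sd,
                          sway_frequency_mean, sway_frequency_sd,
                          transition_sharpness, tremor_noise_sd,
                          ap_drift_scale, outlier_prob) {
  p <- list(amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
            sway_frequency_mean = sway_frequency_mean,
            sway_frequency_sd = sway_frequency_sd,
            transition_sharpness = transition_sharpness,
            tremor_noise_sd = tremor_noise_sd,
            ap_drift_scale = ap_drift_scale, outlier_prob = outlier_prob)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x), logical(1))]
  if (length(bad))
    stop("group profile parameters must be finite numeric scalars; bad: ",
         paste(bad, collapse = ", "))
  if (amplitude_mean <= 0) stop("amplitude_mean must be > 0")
  if (sway_frequency_mean <= 0 || sway_frequency_mean > 0.65)
    stop("sway_frequency_mean must lie in (0, 0.65] Hz")
  if (transition_sharpness <= 0) stop("transition_sharpness must be > 0")
  if (tremor_noise_sd < 0 || amplitude_sd < 0 || sway_frequency_sd < 0 ||
      ap_drift_scale < 0)
    stop("dispersion parameters must be >= 0")
  if (outlier_prob < 0 || outlier_prob >= 5e-4)
    stop("outlier_prob must lie in [0, 5e-4)")
  structure(p, class = "group_profile")
}

#' Default group profiles: younger vs older movers
#'
#' Younger movers sway with larger amplitude, higher frequency, squarer
#' (faster, smoother) transitions and a livelier smooth wander; older movers
#' are smaller, slower and carry more broadband tremor relative to their
#' speed, making their trajectories more irregular at the sample scale.
#' These defaults define the study conditions the simulator emulates and
#' feed every downstream default.
#'
#' @return Named list with `older` and `younger` [group_profile]s.
#' @export
default_profiles <- function() {
  list(
    older = group_profile(
      amplitude_mean = 8, amplitude_sd = 2.0,
      sway_frequency_mean = 0.30, sway_frequency_sd = 0.06,
      transition_sharpness = 3, tremor_noise_sd = 0.020,
      ap_drift_scale = 0.4, outlier_prob = 2e-4),
    younger = group_profile(
      amplitude_mean = 12, amplitude_sd = 2.5,
      sway_frequency_mean = 0.45, sway_frequency_sd = 0.08,
      transition_sharpness = 8, tremor_noise_sd = 0.008,
      ap_drift_scale = 1.5, outlier_prob = 2e-4)
  )
}

#' Cohort configuration
#'
#' @param n_participants_per_group Participants per group (default 20).
#' @param trials_per_participant Trials per participant (default 10).
#' @param trial_duration Trial length in seconds (default 48; trimming 6 s
#'   from each end leaves 36 s for analysis).
#' @param nominal_rate Nominal sampling rate in Hz (default 170).
#' @param timestamp_jitter_sd SD of the zero-mean timestamp jitter in
#'   seconds, emulating non-uniform sampling (default 5e-4, about 8.5% of
#'   the nominal sampling step).
#' @param profiles Named list of [group_profile]s (default
#'   [default_profiles()]); names become the group labels.
#' @param age_ranges Named list of `c(lo, hi)` age ranges per group used for
#'   metadata and participant ordering.
#' @param seed Integer RNG seed; identical seed and configuration yield a
#'   bit-identical cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants_per_group = 20L,
                          trials_per_participant = 10L,
                          trial_duration = 48,
                          nominal_rate = 170,
                          timestamp_jitter_sd = 5e-4,
                          profiles = default_profiles(),
                          age_ranges = list(older = c(66, 79),
                                            younger = c(20, 60)),
                          seed = 1L) {
  if (n_participants_per_group < 1L) stop("need at least 1 participant per group")
  if (trials_per_participant < 1L) stop("trials_per_participant must be >= 1")
  if (trial_duration <= 0 || nominal_rate <= 0)
    stop("trial_duration and nominal_rate must be positive")
  if (timestamp_jitter_sd < 0) stop("timestamp_jitter_sd must be >= 0")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list (names are the group labels)")
  for (p in profiles)
    if (!inherits(p, "group_profile")) stop("profiles must be group_profile objects")
  structure(list(n_participants_per_group = as.integer(n_participants_per_group),
                 trials_per_participant = as.integer(trials_per_participant),
                 trial_duration = trial_duration,
                 nominal_rate = nominal_rate,
                 timestamp_jitter_sd = timestamp_jitter_sd,
                 profiles = profiles, age_ranges = age_ranges,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# normal draw truncated to [lo, hi]; deterministic given the RNG state
rnorm_trunc <- function(mean, sd, lo, hi) {
  if (sd > 0) {
    for (i in 1:100) {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) return(x)
    }
  }
  min(max(mean, lo), hi)
}

#' Generate one synthetic CoP trial
#'
#' ML is a tanh-smoothed square wave plus tremor; AP is a smooth band-limited
#' wander (a sum of random sinusoids in the 0.5-2.5 Hz band, so it is
#' differentiable and contributes sustained speed without sample-scale
#' roughness) plus tremor; timestamps are a uniform grid at `rate` plus
#' zero-mean jitter kept strictly increasing. With probability
#' `outlier_prob` a sample is replaced by a point far outside the 80 x 60 cm
#' plate area. Uses the current RNG state; seed externally for
#' reproducibility.
#'
#' @param profile A [group_profile].
#' @param duration Trial duration in seconds.
#' @param rate Nominal sampling rate in Hz.
#' @param jitter_sd Timestamp jitter SD in seconds.
#' @param amplitude,frequency Optional per-participant overrides; if `NULL`,
#'   drawn from the profile distributions (amplitude truncated positive,
#'   frequency truncated to (0.05, 0.65]).
#' @param phase Sway phase in radians; if `NULL`, drawn uniformly.
#' @param ... Metadata passed to [cop_trajectory()] (`participant`, `group`,
#'   `age`, `trial`, `condition`).
#' @return A [cop_trajectory] in centimeters.
#' @export
generate_trial <- function(profile, duration = 48, rate = 170,
                           jitter_sd = 5e-4, amplitude = NULL,
                           frequency = NULL, phase = NULL, ...) {
  stopifnot(inherits(profile, "group_profile"))
  if (duration <= 0) stop("duration must be > 0")
  if (rate <= 0) stop("rate must be > 0")
  A <- if (is.null(amplitude))
    rnorm_trunc(profile$amplitude_mean, profile$amplitude_sd,
                0.1 * profile$amplitude_mean, Inf) else amplitude
  f <- if (is.null(frequency))
    rnorm_trunc(profile$sway_frequency_mean, profile$sway_frequency_sd,
                0.05, 0.65) else frequency
  phi <- if (is.null(phase)) stats::runif(1, 0, 2 * pi) else phase
  beta <- profile$transition_sharpness

  N <- floor(duration * rate) + 1L
  tt <- seq.int(0L, N - 1L) / rate
  if (jitter_sd > 0) {
    tt <- tt + stats::rnorm(N, 0, jitter_sd)
    # enforce strict monotonicity without disturbing the near-uniform grid
    tt <- c(tt[1], tt[1] + cumsum(pmax(diff(tt), 1e-6)))
  }

  ml <- A * tanh(beta * sin(2 * pi * f * tt + phi)) / tanh(beta)
  if (profile$tremor_noise_sd > 0)
    ml <- ml + stats::rnorm(N, 0, profile$tremor_noise_sd)

  # AP: smooth band-limited wander - sum of random sinusoids, 0.5-2.5 Hz
  ap <- numeric(N)
  if (profile$ap_drift_scale > 0) {
    K <- 8L
    fw <- stats::runif(K, 0.5, 2.5)
    ph <- stats::runif(K, 0, 2 * pi)
    amp <- profile$ap_drift_scale * sqrt(2 / K)
    for (j in seq_len(K))
      ap <- ap + amp * sin(2 * pi * fw[j] * tt + ph[j])
  }
  if (profile$tremor_noise_sd > 0)
    ap <- ap + stats::rnorm(N, 0, profile$tremor_noise_sd)

  if (profile$outlier_prob > 0) {
    out <- stats::runif(N) < profile$outlier_prob
    n_out <- sum(out)
    if (n_out > 0) {
      # far outside the 80 x 60 cm plate (|ML| <= 40, |AP| <= 30)
      ml[out] <- sample(c(-1, 1), n_out, replace = TRUE) *
        stats::runif(n_out, 60, 120)
      ap[out] <- sample(c(-1, 1), n_out, replace = TRUE) *
        stats::runif(n_out, 45, 90)
    }
  }
  cop_trajectory(tt, ml, ap, ...)
}

#' Generate a synthetic cohort
#'
#' Draws per-participant amplitude and sway frequency once from the group
#' profile and shares them across that participant's trials (each trial gets
#' its own phase and noise). Conditions are emitted as labels cycling 1-5
#' twice across the 10 trials; they carry no distinct dynamics. Participants
#' are assigned ages within the group's range so cohort-level orderings by
#' age are meaningful.
#'
#' @param config A [cohort_config].
#' @return A [cop_cohort] with `n_participants_per_group x groups x
#'   trials_per_participant` trajectories.
#' @examples
#' cfg <- cohort_config(n_participants_per_group = 2,
#'                      trials_per_participant = 2,
#'                      trial_duration = 15, seed = 7)
#' generate_cohort(cfg)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- names(config$profiles)
  trajs <- list()
  meta <- list()
  idx <- 0L
  for (g in groups) {
    prof <- config$profiles[[g]]
    ar <- config$age_ranges[[g]]
    if (is.null(ar)) ar <- c(NA_real_, NA_real_)
    for (p in seq_len(config$n_participants_per_group)) {
      pid <- sprintf("%s%02d", toupper(substr(g, 1, 1)), p)
      A <- rnorm_trunc(prof$amplitude_mean, prof$amplitude_sd,
                       0.1 * prof$amplitude_mean, Inf)
      f <- rnorm_trunc(prof$sway_frequency_mean, prof$sway_frequency_sd,
                       0.05, 0.65)
      age <- if (is.na(ar[1])) NA_real_ else round(stats::runif(1, ar[1], ar[2]))
      for (tr in seq_len(config$trials_per_participant)) {
        idx <- idx + 1L
        cond <- (tr - 1L) %% 5L + 1L
        trajs[[idx]] <- generate_trial(
          prof, duration = config$trial_duration,
          rate = config$nominal_rate,
          jitter_sd = config$timestamp_jitter_sd,
          amplitude = A, frequency = f,
          participant = pid, group = g, age = age,
          trial = tr, condition = cond)
        meta[[idx]] <- data.frame(participant = pid, group = g, age = age,
                                  trial = tr, condition = cond)
      }
    }
  }
  cop_cohort(trajs, do.call(rbind, meta))
}

#' Read / write a cohort configuration as YAML
#'
#' Serializes every scalar of a [cohort_config], including the per-group
#' profiles, so a simulation run is fully reproducible from its config file.
#'
#' @param config A [cohort_config].
#' @param path YAML file path.
#' @return `write_cohort_config` returns `path` invisibly;
#'   `read_cohort_config` returns a [cohort_config].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$profiles <- lapply(x$profiles, unclass)
  x$age_ranges <- lapply(x$age_ranges, as.numeric)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  profiles <- lapply(x$profiles, function(p) do.call(group_profile, p))
  cohort_config(
    n_participants_per_group = x$n_participants_per_group,
    trials_per_participant = x$trials_per_participant,
    trial_duration = x$trial_duration,
    nominal_rate = x$nominal_rate,
    timestamp_jitter_sd = x$timestamp_jitter_sd,
    profiles = profiles,
    age_ranges = lapply(x$age_ranges, as.numeric),
    seed = x$seed)
}
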