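# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately naive (explicit loops, closed forms) so it
# cannot share code paths with the vectorized implementation it checks.

# random smooth-ish trajectory on a uniform grid
random_trajectory <- function(N = 200, rate = 50, scale = 5) {
  tt <- seq.int(0, N - 1) / rate
  ml <- scale * sin(2 * pi * runif(1, 0.2, 0.6) * tt) + rnorm(N, 0, 0.3)
  ap <- scale * 0.3 * cos(2 * pi * runif(1, 0.1, 0.4) * tt) + rnorm(N, 0, 0.3)
  cop_trajectory(tt, ml, ap)
}

# naive per-window loop recomputation of every windowed measure
naive_windowed <- function(traj, n) {
  N <- length(traj$t)
  fm <- sqrt((traj$ap - mean(traj$ap))^2 + (traj$ml - mean(traj$ml))^2)
  v <- c(0, sqrt(diff(traj$ml)^2 + diff(traj$ap)^2) / diff(traj$t))
  ks <- (n + 1):(N - n)
  out <- data.frame(k = ks, SD = NA_real_, RMS = NA_real_, CoV = NA_real_,
                    d = NA_real_, I = NA_real_, Ip = NA_real_)
  for (r in seq_along(ks)) {
    k <- ks[r]
    w <- fm[(k - n):(k + n)]
    mu <- sum(w) / length(w)
    sdw <- sqrt(sum((w - mu)^2) / length(w))
    out$SD[r] <- sdw
    out$RMS[r] <- sqrt(sum(w^2) / length(w))
    out$CoV[r] <- sdw / mu
    dsum <- 0
    for (i in (k - n):(k + n - 1))
      dsum <- dsum + sqrt((traj$ml[i + 1] - traj$ml[i])^2 +
                          (traj$ap[i + 1] - traj$ap[i])^2)
    out$d[r] <- dsum
    vw <- v[(k - n):(k + n)]
    muv <- sum(vw) / length(vw)
    sdv <- sqrt(sum((vw - muv)^2) / length(vw))
    out$I[r] <- sdv / muv
    out$Ip[r] <- sdv / (sum(vw^2) / length(vw))
  }
  out
}

# least-squares circumcircle through >= 3 points (algebraic circle fit);
# independent route to curvature = 1/R
fit_circle_radius <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# small deterministic cohort for pipeline-level tests
tiny_config <- function(seed = 123, n_pp = 3L, trials = 2L, duration = 16) {
  cohort_config(n_participants_per_group = n_pp,
                trials_per_participant = trials,
                trial_duration = duration, seed = seed)
}
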