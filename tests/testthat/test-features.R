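test_that("fluctuation from the mean matches direct substitution", {
  # constant trajectory: every point is the mean
  tr <- cop_trajectory(0:4, ml = rep(2, 5), ap = rep(-1, 5))
  expect_equal(as.numeric(fluctuation_from_mean(tr)), rep(0, 5))

  # symmetric pair about the mean plus a hand-computed triple
  tr2 <- cop_trajectory(0:2, ml = c(-1, 1, 0), ap = c(0, 0, 0))
  expect_equal(as.numeric(fluctuation_from_mean(tr2))[1:2], c(1, 1))

  tr3 <- cop_trajectory(0:2, ml = c(0, 0, 3), ap = c(0, 4, 0))
  # mean = (1, 4/3); FM(t1) = sqrt(1 + 16/9) = 5/3
  expect_equal(as.numeric(fluctuation_from_mean(tr3))[1], 5 / 3)
})

test_that("instantaneous speed is the backward-difference norm with v(t1) = 0", {
  tr <- cop_trajectory(c(0, 1, 2), ml = c(0, 3, 3), ap = c(0, 4, 4))
  v <- instantaneous_speed(tr)
  expect_equal(as.numeric(v)[1], 0)
  expect_equal(as.numeric(v)[2], 5)

  # uniform ML motion at 2 units/s under irregular sampling
  tt <- cumsum(c(0, runif(20, 0.01, 0.3)))
  tr2 <- cop_trajectory(tt, ml = 2 * tt, ap = rep(0, 21))
  expect_equal(as.numeric(instantaneous_speed(tr2))[-1], rep(2, 20))

  tr3 <- cop_trajectory(c(0, 1, 1 + 1e-15, 2), ml = rnorm(4), ap = rnorm(4))
  expect_error(instantaneous_speed(tr3), "repeated timestamp")
})

test_that("windowed dispersion reproduces the three-term hand example", {
  fm <- feature_series(c(1, 2, 3), "FM")
  w <- windowed_dispersion(fm, n = 1L)
  expect_equal(defined_values(w$SD), sqrt(2 / 3))
  expect_equal(defined_values(w$RMS), sqrt(14 / 3))
  expect_equal(defined_values(w$CoV), sqrt(2 / 3) / 2)
  # population identity on the same window: 14/3 = 2/3 + 4
  expect_equal(defined_values(w$RMS)^2,
               defined_values(w$SD)^2 + 2^2)

  # constant window: SD = 0, RMS = c, CoV = 0
  wc <- windowed_dispersion(feature_series(rep(3, 7), "FM"), n = 2L)
  expect_equal(defined_values(wc$SD), rep(0, 3))
  expect_equal(defined_values(wc$RMS), rep(3, 3))
  expect_equal(defined_values(wc$CoV), rep(0, 3))
})

test_that("distance travelled sums exactly the in-window segments", {
  # stationary: zero everywhere
  tr0 <- cop_trajectory(0:9, ml = rep(1, 10), ap = rep(2, 10))
  expect_equal(defined_values(distance_travelled(tr0, n = 2L)), rep(0, 6))

  # collinear equally spaced, n = 1: two segments of length h
  h <- 0.25
  tr1 <- cop_trajectory(0:5, ml = h * (0:5), ap = rep(0, 6))
  expect_equal(defined_values(distance_travelled(tr1, n = 1L)), rep(2 * h, 4))

  # path (0,0) -> (3,4) -> (3,4): segments 5 and 0
  tr2 <- cop_trajectory(0:2, ml = c(0, 3, 3), ap = c(0, 4, 4))
  expect_equal(defined_values(distance_travelled(tr2, n = 1L)), 5)
})

test_that("normalized variants divide by distance and guard degenerate windows", {
  set.seed(4)
  tr <- random_trajectory(60)
  fm <- fluctuation_from_mean(tr)
  disp <- windowed_dispersion(fm, n = 3L)
  d <- distance_travelled(tr, n = 3L)
  pr <- normalized_dispersion(disp, d)
  k <- 10L
  expect_equal(as.numeric(pr$SDp)[k], as.numeric(disp$SD)[k] / as.numeric(d)[k])
  expect_equal(as.numeric(pr$RMSp)[k], as.numeric(disp$RMS)[k] / as.numeric(d)[k])
  expect_equal(as.numeric(pr$CoVp)[k], as.numeric(disp$CoV)[k] / as.numeric(d)[k])

  # a stationary stretch gives d = 0: flagged undefined, never infinite
  ml <- c(rep(0, 20), seq(0, 2, length.out = 20))
  trs <- cop_trajectory(seq_len(40), ml = ml, ap = rep(0, 40))
  ds <- distance_travelled(trs, n = 3L)
  prs <- normalized_dispersion(windowed_dispersion(fluctuation_from_mean(trs),
                                                   n = 3L), ds)
  vals <- as.numeric(prs$SDp)
  expect_false(any(is.infinite(vals)))
  expect_true(anyNA(vals[attr(ds, "valid_range")[1]:attr(ds, "valid_range")[2]]))
})

test_that("turbulence intensities match direct arithmetic and scale laws", {
  v123 <- feature_series(c(1, 2, 3), "Speed")
  expect_equal(defined_values(turbulence_intensity(v123, n = 1L)),
               sqrt(2 / 3) / 2)
  expect_equal(defined_values(turbulence_intensity_prime(v123, n = 1L)),
               sqrt(2 / 3) / (14 / 3))

  # constant speed: both zero
  vc <- feature_series(rep(2.5, 9), "Speed")
  expect_equal(defined_values(turbulence_intensity(vc, n = 2L)), rep(0, 5))
  expect_equal(defined_values(turbulence_intensity_prime(vc, n = 2L)), rep(0, 5))

  # I scale invariant, I' halves when v doubles
  set.seed(9)
  v <- feature_series(runif(31, 0.5, 2), "Speed")
  v2 <- feature_series(2 * as.numeric(v), "Speed")
  expect_equal(defined_values(turbulence_intensity(v2, n = 5L)),
               defined_values(turbulence_intensity(v, n = 5L)))
  expect_equal(defined_values(turbulence_intensity_prime(v2, n = 5L)),
               defined_values(turbulence_intensity_prime(v, n = 5L)) / 2)
})

test_that("three-point curvature agrees with circumcircle geometry", {
  # collinear: zero curvature
  trl <- cop_trajectory(0:2, ml = c(0, 1, 2), ap = c(0, 1, 2))
  expect_equal(defined_values(curvature(trl)), 0)

  # unit equilateral triangle: kappa = sqrt(3) (circumradius 1/sqrt(3))
  tre <- cop_trajectory(0:2, ml = c(0, 1, 0.5), ap = c(0, 0, sqrt(3) / 2))
  expect_equal(defined_values(curvature(tre)), sqrt(3))

  # triples on circles of radius R: kappa = 1/R to 1e-9, cross-checked by a
  # least-squares circle fit
  set.seed(31)
  for (R in c(0.5, 1, 10)) {
    th <- sort(runif(3, 0, 2 * pi))
    tr <- cop_trajectory(0:2, ml = R * cos(th), ap = R * sin(th))
    kap <- defined_values(curvature(tr))
    expect_lt(abs(kap - 1 / R), 1e-9)
    expect_lt(abs(kap - 1 / fit_circle_radius(R * cos(th), R * sin(th))), 1e-8)
  }

  # coincident consecutive points: flagged, kappa = 0, no NaN
  trd <- cop_trajectory(0:3, ml = c(0, 0, 1, 2), ap = c(0, 0, 0, 1))
  kd <- curvature(trd)
  expect_equal(as.numeric(kd)[2], 0)
  expect_true(2L %in% attr(kd, "degenerate"))
})

test_that("vectorized windowed measures equal the naive per-window loop", {
  set.seed(77)
  for (rep in 1:20) {
    N <- sample(60:140, 1)
    n <- sample(2:8, 1)
    tr <- random_trajectory(N)
    f <- compute_features(tr, n = n)
    naive <- naive_windowed(tr, n)
    for (msr in c("SD", "RMS", "CoV", "d", "I", "Ip")) {
      got <- as.numeric(f[[msr]])[naive$k]
      expect_lt(max(rel_err(got, naive[[msr]])), 1e-12)
    }
  }
})

test_that("RMS^2 = SD^2 + local mean^2 at every valid index", {
  set.seed(5)
  tr <- random_trajectory(300)
  fm <- fluctuation_from_mean(tr)
  n <- 10L
  disp <- windowed_dispersion(fm, n = n)
  N <- length(tr$t)
  mu <- rowMeans(matrix(as.numeric(fm)[rep((n + 1):(N - n), 2 * n + 1) +
                                         rep(-n:n, each = N - 2 * n)],
                        ncol = 2 * n + 1))
  expect_equal(defined_values(disp$RMS)^2,
               defined_values(disp$SD)^2 + mu^2, tolerance = 1e-12)
})

test_that("every measure is invariant under translating the trajectory", {
  # FM subtracts the trial-mean position, so translating the whole
  # trajectory moves the mean with it: FM and everything built on it
  # (SD, RMS, CoV and the primes) are translation invariant, as are the
  # purely differential measures (Speed, d, I, I', kappa).
  set.seed(13)
  tr <- random_trajectory(150)
  n <- 5L
  shift <- cop_trajectory(tr$t, tr$ml + 7, tr$ap - 4)
  f0 <- compute_features(tr, n = n)
  f1 <- compute_features(shift, n = n)
  for (msr in c("FM", "SD", "RMS", "CoV", "Speed", "kappa", "I", "Ip", "d"))
    expect_equal(defined_values(f1[[msr]]), defined_values(f0[[msr]]),
                 tolerance = 1e-9)
})

test_that("scaling the coordinates acts with the right power on each measure", {
  set.seed(13)
  tr <- random_trajectory(150)
  n <- 5L
  f0 <- compute_features(tr, n = n)
  # a = 2 scales every coordinate exactly in floating point, so the eight
  # covariance relations must hold to near machine precision; a = 3.7
  # additionally exercises a non-representable factor
  for (spec in list(list(a = 2, tol = 1e-12), list(a = 3.7, tol = 1e-11))) {
    a <- spec$a
    fa <- compute_features(cop_trajectory(tr$t, a * tr$ml, a * tr$ap), n = n)
    # Speed, SD, RMS, d scale with a
    for (msr in c("Speed", "SD", "RMS", "d"))
      expect_lt(max(rel_err(defined_values(fa[[msr]]),
                            a * defined_values(f0[[msr]]))), spec$tol)
    # kappa and I' scale with 1/a
    for (msr in c("kappa", "Ip"))
      expect_lt(max(rel_err(defined_values(fa[[msr]]),
                            defined_values(f0[[msr]]) / a)), spec$tol)
    # CoV, SD', RMS', I are scale invariant
    for (msr in c("CoV", "SDp", "RMSp", "I"))
      expect_lt(max(rel_err(defined_values(fa[[msr]]),
                            defined_values(f0[[msr]]))), spec$tol)
  }
})

test_that("valid-range bookkeeping leaves exactly N - 2n windowed samples", {
  set.seed(2)
  tr <- random_trajectory(101)
  n <- 7L
  f <- compute_features(tr, n = n)
  for (msr in c("SD", "RMS", "d", "I", "Ip")) {
    vr <- attr(f[[msr]], "valid_range")
    expect_identical(vr, c(n + 1L, 101L - n))
    expect_length(defined_values(f[[msr]]), 101L - 2L * n)
    outside <- as.numeric(f[[msr]])[c(seq_len(n), (101L - n + 1L):101L)]
    expect_true(all(is.na(outside)))
  }
  expect_identical(attr(f$kappa, "valid_range"), c(2L, 100L))
})

test_that("trial summaries take medians, plus the mean for curvature", {
  expect_equal(median(c(0, 1, 2, 100)), 1.5)  # the kappa example pair
  expect_equal(mean(c(0, 1, 2, 100)), 25.75)

  set.seed(8)
  tr <- random_trajectory(200, rate = 50)
  row <- summarize_trial(tr, n = 5L)
  f <- compute_features(tr, n = 5L)
  expect_equal(row$SD, median(defined_values(f$SD)))
  expect_equal(row$Speed, median(defined_values(f$Speed)))
  expect_equal(row$kappa_median, median(defined_values(f$kappa)))
  expect_equal(row$kappa_mean, mean(defined_values(f$kappa)))
  expect_true(all(is.finite(as.numeric(row[measure_names()]))))
})

test_that("feature extraction yields one 11-measure row per trial", {
  cfg <- tiny_config(seed = 21)
  coh <- preprocess(generate_cohort(cfg))
  feat <- extract_features(coh)
  expect_identical(nrow(feat), 2L * 3L * 2L)
  expect_true(all(measure_names() %in% names(feat)))
  expect_identical(length(measure_names()), 11L)
  expect_true(all(is.finite(as.matrix(feat[, measure_names()]))))
})

test_that("a trial shorter than the window is skipped with a warning, not fatal", {
  cfg <- tiny_config(seed = 3, n_pp = 1L, trials = 1L)
  coh <- preprocess(generate_cohort(cfg))
  short <- cop_trajectory(seq(0, 0.1, length.out = 10), rnorm(10), rnorm(10))
  mixed <- cop_cohort(c(coh$trajectories, list(short)),
                      rbind(coh$metadata,
                            data.frame(participant = "X", group = "older",
                                       age = 70, trial = 99, condition = 1)))
  expect_warning(feat <- extract_features(mixed), "skipped")
  expect_identical(nrow(feat), length(coh$trajectories))
})
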