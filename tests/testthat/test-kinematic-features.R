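clean_fixture <- function(seed = 5, ...) {
  p <- tapParams(seed = seed, ...)
  gl <- genLandmarkSeries(p)
  list(signal = cleanTappingSignal(gl$series), series = gl$series,
       truth = gl$truth, params = p)
}

test_that("speed and acceleration are forced differencing arithmetic", {
  expect_equal(computeSpeed(c(50, 50, 50), t_frame = 1 / 30), c(0, 0))
  expect_equal(computeSpeed(c(10, 13), t_frame = 1 / 30), 90)
  expect_equal(computeAcceleration(c(90, 90), 1 / 30), 0)
  expect_equal(computeAcceleration(c(90, 0), 1 / 30), 2700)
  expect_error(computeSpeed(c(1), t_frame = 1 / 30), "2 frames")
  expect_error(computeAcceleration(c(1), 1 / 30), "2 speed")
  set.seed(31)
  x <- runif(200, 0, 180)
  tf <- 1 / 30
  s <- computeSpeed(x, t_frame = tf)
  manual <- vapply(2:200, function(i) abs(x[i] - x[i - 1]) / tf, numeric(1))
  expect_equal(s, manual)
  a <- computeAcceleration(s, tf)
  expect_equal(a, vapply(2:length(s),
                         function(i) abs(s[i] - s[i - 1]) / tf, numeric(1)))
})

test_that("tap metrics derive from peak spacing and peak values", {
  x <- 10 + 80 * abs(sin(pi * (0:299) / 30))
  s <- angleSeries(x, 1 / 30)
  cs <- trimFirstLastTap(s, detectPeaks(s))
  tm <- computeTapMetrics(cs)
  expect_equal(tm$periods, rep(1, 7))
  expect_equal(tm$frequencies, rep(1, 7))
  expect_equal(tm$frequencies, 1 / tm$periods)
  expect_equal(length(tm$amplitudes), 8)
  expect_equal(tm$amplitudes, rep(90, 8))
  # zero-jitter 2 Hz generator: median period within one frame of 0.5 s
  fx <- clean_fixture(n_taps = 12, tap_frequency = 2)
  tm2 <- computeTapMetrics(fx$signal)
  expect_lte(abs(median(tm2$periods) - 0.5), 1 / 30)
})

test_that("wrist motion is the 3-4-5 triangle on a hand-made displacement", {
  # wrist at (0.5,0.5) then (0.53,0.46), unit normalizing distance
  fr <- data.frame(frame = 0:1, label = "right", det_score = 1,
                   presence = 1,
                   lm0_x = c(0.50, 0.53), lm0_y = c(0.50, 0.46),
                   lm1_x = c(1.50, 1.53), lm1_y = c(0.50, 0.46),
                   lm4_x = 0.7, lm4_y = 0.3, lm8_x = 0.4, lm8_y = 0.2)
  s <- landmarkSeries(fr, "V", hand = "right", t_frame = 1 / 30)
  wm <- computeWristMotion(s)
  expect_equal(wm$dx, 0.03)
  expect_equal(wm$dy, 0.04)
  expect_equal(wm$d, 0.05)
  expect_equal(wm$d^2, wm$dx^2 + wm$dy^2)
  # stationary wrist: all zeros
  fr0 <- fr; fr0$lm0_x <- 0.5; fr0$lm0_y <- 0.5
  fr0$lm1_x <- 0.6; fr0$lm1_y <- 0.5
  wm0 <- computeWristMotion(landmarkSeries(fr0, "V", hand = "right",
                                           t_frame = 1 / 30))
  expect_equal(wm0$d, 0)
  # seeded random walk matches brute-force recomputation
  set.seed(8)
  n <- 60
  wx <- cumsum(rnorm(n, 0, 0.01)) + 0.5
  wy <- cumsum(rnorm(n, 0, 0.01)) + 0.5
  frn <- data.frame(frame = seq_len(n) - 1L, label = "right",
                    det_score = 1, presence = 1,
                    lm0_x = wx, lm0_y = wy,
                    lm1_x = wx + 0.1, lm1_y = wy,
                    lm4_x = 0.7, lm4_y = 0.3, lm8_x = 0.4, lm8_y = 0.2)
  wmn <- computeWristMotion(landmarkSeries(frn, "V", hand = "right",
                                           t_frame = 1 / 30))
  nx <- wx / 0.1; ny <- wy / 0.1
  expect_equal(wmn$dx, abs(diff(nx)))
  expect_equal(wmn$d, sqrt(diff(nx)^2 + diff(ny)^2))
})

test_that("the seven aggregates match their definitions", {
  ag <- aggregateStats(c(1, 2, 3, 4, 5))
  expect_equal(unname(ag[c("median", "mean", "min", "max")]), c(3, 3, 1, 5))
  expect_equal(unname(ag["std"]), sd(1:5))
  # constant sequence: degenerate distribution
  agc <- aggregateStats(rep(7, 10))
  expect_equal(unname(agc[c("std", "iqr", "entropy")]), c(0, 0, 0))
  expect_error(aggregateStats(numeric(0)), "empty")
  # entropy equals the brute-force histogram computation
  set.seed(12)
  for (rep in 1:5) {
    v <- rnorm(100)
    expect_equal(unname(aggregateStats(v)["entropy"]),
                 oracle_hist_entropy(v))
  }
})

test_that("aperiodicity ranks pure tones below mixtures and matches the DFT oracle", {
  tt <- seq(0, 8 * pi, length.out = 256)
  expect_lt(aperiodicity(sin(tt)), aperiodicity(sin(tt) + sin(2 * tt)))
  # an exact single-bin tone concentrates all spectral mass
  n <- 64
  tone <- sin(2 * pi * 4 * (0:(n - 1)) / n)
  expect_lt(aperiodicity(tone), 1e-9)
  set.seed(77)
  for (rep in 1:5) {
    x <- rnorm(128)
    expect_equal(aperiodicity(x), oracle_spectral_entropy(x),
                 tolerance = 1e-8)
  }
  expect_error(aperiodicity(rnorm(10)), "16 samples")
  expect_equal(suppressMessages(aperiodicity(rep(3, 32))), 0)
})

test_that("interruption and freezing counts follow the duration thresholds", {
  tf <- 0.005  # 5 ms frames so both thresholds are exercised
  sp <- rep(100, 100)
  expect_equal(countInterruptions(sp, tf), 0)
  expect_equal(countFreezing(sp, tf)$count, 0)
  expect_equal(countFreezing(sp, tf)$longest_s, 0)
  # a 15 ms slow run: interruption (>= 10 ms) but not freezing (> 20 ms)
  sp2 <- c(rep(100, 10), rep(30, 3), rep(100, 10))
  expect_equal(countInterruptions(sp2, tf), 1)
  expect_equal(countFreezing(sp2, tf)$count, 0)
  # a 25 ms run is both
  sp3 <- c(rep(100, 10), rep(30, 5), rep(100, 4), rep(20, 5), rep(100, 5))
  expect_equal(countFreezing(sp3, tf)$count, 2)
  expect_equal(countFreezing(sp3, tf)$longest_s, 0.025)
  # exactly at the boundaries: 10 ms counts as interruption, 20 ms is not
  # freezing (strict inequality)
  sp4 <- c(rep(100, 5), rep(10, 2), rep(100, 5), rep(10, 4), rep(100, 5))
  expect_equal(countInterruptions(sp4, tf), 2)
  expect_equal(countFreezing(sp4, tf)$count, 0)
  # random traces match a brute-force run-length scan
  set.seed(21)
  for (rep in 1:10) {
    sp5 <- sample(c(10, 30, 80, 200), 300, replace = TRUE)
    r <- rle(sp5 < 50)
    durs <- r$lengths[r$values] * tf
    expect_equal(countInterruptions(sp5, tf), sum(durs >= 0.010))
    expect_equal(countFreezing(sp5, tf)$count, sum(durs > 0.020))
  }
})

test_that("period linearity and fitting complexity behave on exact shapes", {
  expect_equal(periodLinearity(rep(0.5, 4)), c(r2 = 1, slope = 0))
  expect_equal(periodLinearity(c(0.4, 0.5, 0.6)), c(r2 = 1, slope = 0.1))
  expect_error(periodLinearity(c(0.5, 0.5)), "3 periods")
  expect_equal(periodFitComplexity(c(0.4, 0.5, 0.6, 0.7, 0.8)), 1)
  expect_equal(periodFitComplexity(rep(0.5, 6)), 1)
  # seeded least squares against the closed-form normal equations
  set.seed(14)
  for (rep in 1:5) {
    y <- 0.5 + 0.02 * (1:12) + rnorm(12, 0, 0.05)
    i <- 1:12
    beta <- cov(i, y) / var(i)
    alpha <- mean(y) - beta * mean(i)
    ss_res <- sum((y - alpha - beta * i)^2)
    r2 <- 1 - ss_res / sum((y - mean(y))^2)
    pl <- periodLinearity(y)
    expect_equal(unname(pl["slope"]), beta)
    expect_equal(unname(pl["r2"]), r2)
    # complexity equals a brute-force sweep over degrees
    sweep_degree <- function(y) {
      for (d in 1:10) {
        fit <- lm(y ~ poly(seq_along(y), d, raw = TRUE))
        if (summary(fit)$r.squared >= 0.9) return(d)
      }
      11
    }
    yy <- 0.5 + cumsum(rnorm(15, 0, 0.08))
    expect_equal(periodFitComplexity(yy), sweep_degree(yy))
  }
})

test_that("amplitude decrement measures exact linear fades", {
  expect_equal(unname(amplitudeDecrement(rep(80, 5))), c(0, 0, 0))
  dec <- amplitudeDecrement(c(100, 90, 80, 70))
  expect_equal(unname(dec), c(-15, -30, -10))
  expect_error(amplitudeDecrement(c(1, 2)), "3 amplitudes")
  # planted decrement recovered from the generator within 5%
  fx <- clean_fixture(n_taps = 12, base_amplitude = 95,
                      amplitude_slope = -2, tap_frequency = 2)
  slope <- featurize(fx$signal, fx$series)["amplitude_slope"]
  expect_lt(abs(slope - (-2)) / 2, 0.05)
})

test_that("featurize returns the full 65-feature registry, deterministically", {
  fx <- clean_fixture(n_taps = 10, period_jitter_cv = 0.05,
                      wrist_drift_sd = 2e-4, landmark_noise_sd = 2e-4)
  f <- featurize(fx$signal, fx$series)
  reg <- featureRegistry()
  expect_length(f, 65)
  expect_identical(names(f), as.character(reg))
  expect_length(intersect(names(f), attr(reg, "tapping")), 47)
  expect_length(intersect(names(f), attr(reg, "wrist")), 18)
  expect_true(all(is.finite(f)))
  expect_identical(f, featurize(fx$signal, fx$series))
})

test_that("all features are invariant to translation and uniform scaling", {
  fx <- clean_fixture(n_taps = 10, period_jitter_cv = 0.08,
                      wrist_drift_sd = 3e-4)
  f0 <- featurize(fx$signal, fx$series)
  set.seed(61)
  moved <- transform_series(fx$series, angle = 0, scale = runif(1, 0.3, 3),
                            shift = rnorm(2))
  f1 <- featurize(cleanTappingSignal(moved), moved)
  expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("rotation leaves every rotation-invariant feature unchanged", {
  fx <- clean_fixture(n_taps = 10, wrist_drift_sd = 3e-4)
  f0 <- featurize(fx$signal, fx$series)
  set.seed(62)
  rot <- transform_series(fx$series, angle = runif(1, 0, 2 * pi))
  f1 <- featurize(cleanTappingSignal(rot), rot)
  axis_specific <- grep("^wrist_d[xy]_", names(f0), value = TRUE)
  keep <- setdiff(names(f0), axis_specific)
  expect_equal(f1[keep], f0[keep], tolerance = 1e-9)
})

test_that("matched synthetic pairs move the features in the scored directions", {
  base <- clean_fixture(seed = 9, n_taps = 12, tap_frequency = 2)
  f_base <- featurize(base$signal, base$series)
  # inserting freezes raises the freezing count and drags median speed down
  frozen <- clean_fixture(seed = 9, n_taps = 12, tap_frequency = 2,
                          freeze_events = list(c(0.3, 0.05), c(0.5, 0.05),
                                               c(0.7, 0.05)))
  f_frozen <- featurize(frozen$signal, frozen$series)
  expect_gt(f_frozen["n_freezing"], f_base["n_freezing"])
  # pauses add zero-speed frames: the mean drops, the median cannot rise
  expect_lt(f_frozen["speed_mean"], f_base["speed_mean"])
  expect_lte(f_frozen["speed_median"], f_base["speed_median"])
  # period jitter inflates period IQR and aperiodicity
  jit <- clean_fixture(seed = 9, n_taps = 12, tap_frequency = 2,
                       period_jitter_cv = 0.25)
  f_jit <- featurize(jit$signal, jit$series)
  expect_gt(f_jit["period_iqr"], f_base["period_iqr"])
  expect_gt(f_jit["aperiodicity"], f_base["aperiodicity"])
  # steeper decrement lowers the amplitude slope
  fade <- clean_fixture(seed = 9, n_taps = 12, tap_frequency = 2,
                        base_amplitude = 100, amplitude_slope = -3)
  f_fade <- featurize(fade$signal, fade$series)
  expect_lt(f_fade["amplitude_slope"], f_base["amplitude_slope"])
})

test_that("feature tables round-trip through CSV at full precision", {
  fx <- clean_fixture(n_taps = 10)
  tab <- suppressMessages(featurizeVideos(list(fx$series)))
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, path)
  back <- readFeatureTable(path)
  expect_equal(back[, featureRegistry()], tab[, featureRegistry()],
               tolerance = 0)
  # videos with too few taps are skipped and reported
  short_p <- tapParams(n_taps = 4, seed = 3)
  short <- genLandmarkSeries(short_p)$series
  expect_warning(tab2 <- featurizeVideos(list(fx$series, short)),
                 "skipping")
  expect_equal(nrow(tab2), 1)
  expect_length(attr(tab2, "skipped"), 1)
})
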