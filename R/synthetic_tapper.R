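#' Synthetic tapping parameters
#'
#' Parameters of one simulated hand-video. The angle trace is a sequence of
#' power-of-triangle arches (baseline + amplitude * (1 - |2u - 1|)^gamma over
#' tap phase u), so the direction of motion reverses sharply at both finger
#' contact and maximal aperture and the within-tap angular speed (about
#' 2 * amplitude * frequency degrees/second) stays well above the hesitation
#' floor; hesitations are then planted explicitly as flat pauses at inter-tap
#' valleys. Tap periods are quantized to even frame counts so every tap peak
#' falls exactly on a sampled frame.
#'
#' @param n_taps number of taps (default 10, the task instruction).
#' @param base_amplitude first-tap amplitude above baseline, degrees.
#' @param amplitude_slope amplitude change per tap, degrees/tap.
#' @param tap_frequency taps per second.
#' @param period_jitter_cv coefficient of variation of tap periods.
#' @param freeze_events list of `c(position, duration_s)` pauses with
#'   duration above the freezing threshold; position is a fraction of the
#'   task in (0, 1), realized at the nearest interior inter-tap valley.
#' @param interruption_events like `freeze_events`, for shorter pauses.
#' @param missing_frame_prob per-frame probability of a missing hand.
#' @param landmark_noise_sd coordinate noise, normalized units.
#' @param wrist_drift_sd per-frame wrist random-walk step, normalized units.
#' @param frame_rate frames per second (default 30).
#' @param baseline_angle closed-hand angle, degrees (default 10).
#' @param gamma arch sharpness exponent (default 1, triangular).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return object of class `tap_params`.
#' @export
tapParams <- function(n_taps = 10L, base_amplitude = 90,
                      amplitude_slope = 0, tap_frequency = 2,
                      period_jitter_cv = 0, freeze_events = list(),
                      interruption_events = list(),
                      missing_frame_prob = 0, landmark_noise_sd = 0,
                      wrist_drift_sd = 0, frame_rate = 30,
                      baseline_angle = 10, gamma = 1, seed = NULL) {
  p <- list(n_taps = as.integer(n_taps), base_amplitude = base_amplitude,
            amplitude_slope = amplitude_slope,
            tap_frequency = tap_frequency,
            period_jitter_cv = period_jitter_cv,
            freeze_events = freeze_events,
            interruption_events = interruption_events,
            missing_frame_prob = missing_frame_prob,
            landmark_noise_sd = landmark_noise_sd,
            wrist_drift_sd = wrist_drift_sd, frame_rate = frame_rate,
            baseline_angle = baseline_angle, gamma = gamma, seed = seed)
  if (p$n_taps < 4L) stop("need at least 4 taps", call. = FALSE)
  if (p$tap_frequency <= 0 || p$frame_rate <= 0) {
    stop("frequency and frame rate must be positive", call. = FALSE)
  }
  amps <- p$base_amplitude + p$amplitude_slope * (seq_len(p$n_taps) - 1L)
  if (any(p$baseline_angle + amps >= 180) || any(amps <= 0) ||
      p$baseline_angle < 0) {
    stop("amplitudes must keep the angle inside (0, 180) degrees",
         call. = FALSE)
  }
  if (p$missing_frame_prob < 0 || p$missing_frame_prob > 1) {
    stop("missing_frame_prob must lie in [0, 1]", call. = FALSE)
  }
  for (ev in c(p$freeze_events, p$interruption_events)) {
    if (length(ev) != 2L || ev[1] <= 0 || ev[1] >= 1 || ev[2] <= 0) {
      stop("events must be c(position in (0,1), positive duration)",
           call. = FALSE)
    }
    if (ev[2] >= 1 / p$tap_frequency) {
      stop("pause duration must be shorter than one tap period",
           call. = FALSE)
    }
  }
  structure(p, class = "tap_params")
}

.even_frames <- function(period_s, t_frame) {
  max(4L, 2L * as.integer(round(period_s / t_frame / 2)))
}

#' Generate a synthetic tapping-angle series
#'
#' Builds the quasi-periodic angle trace described by [tapParams()]: `n_taps`
#' arches with the requested amplitude schedule and jittered periods, flat
#' pauses (freezes/interruptions) inserted at interior inter-tap valleys so
#' the trimmed signal retains them, and missing frames as the -1.0 sentinel.
#'
#' @param params a [tapParams()].
#' @param video_id,hand provenance labels.
#' @return list with `series` (an [angleSeries()]) and `truth` — the
#'   realized quantities: per-tap periods (s) and amplitudes (degrees), peak
#'   frame positions, pause durations as realized after frame quantization,
#'   and the counts a correct feature extractor should recover
#'   (`n_freezing`, `n_interruptions` counting every pause at or above the
#'   interruption threshold).
#' @export
genAngleSeries <- function(params, video_id = "synthetic", hand = "right") {
  stopifnot(inherits(params, "tap_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  t_frame <- 1 / params$frame_rate
  n_taps <- params$n_taps
  b <- params$baseline_angle
  amps <- params$base_amplitude +
    params$amplitude_slope * (seq_len(n_taps) - 1L)
  nominal <- 1 / params$tap_frequency
  jitter <- if (params$period_jitter_cv > 0) {
    pmax(-2.5, pmin(2.5, stats::rnorm(n_taps))) * params$period_jitter_cv
  } else rep(0, n_taps)
  n_frames_tap <- vapply(nominal * (1 + jitter), .even_frames,
                         integer(1), t_frame = t_frame)

  # map requested pause positions to distinct interior valleys
  # (boundary after tap j survives the first/last-tap trim for 2<=j<=n-2)
  events <- c(lapply(params$freeze_events, c, type = 1),
              lapply(params$interruption_events, c, type = 2))
  pause_at <- integer(0)
  pause_dur <- numeric(0)
  pause_kind <- character(0)
  lo <- 2L; hi <- n_taps - 2L
  for (ev in events) {
    j <- min(hi, max(lo, as.integer(round(ev[1] * n_taps))))
    while (j %in% pause_at && j < hi) j <- j + 1L
    while (j %in% pause_at && j > lo) j <- j - 1L
    if (j %in% pause_at) {
      stop("too many pause events for the number of interior valleys",
           call. = FALSE)
    }
    pause_at <- c(pause_at, j)
    pause_dur <- c(pause_dur, ev[2])
    pause_kind <- c(pause_kind, if (ev[3] == 1) "freeze" else "interruption")
  }

  values <- numeric(0)
  peak_frames <- integer(0)
  realized_pause <- numeric(0)
  for (i in seq_len(n_taps)) {
    n_i <- n_frames_tap[i]
    u <- (seq_len(n_i) - 1L) / n_i
    arch <- b + amps[i] * (1 - abs(2 * u - 1))^params$gamma
    peak_frames <- c(peak_frames, length(values) + n_i / 2 + 1L)
    values <- c(values, arch)
    hit <- which(pause_at == i)
    if (length(hit)) {
      d <- max(1L, as.integer(round(pause_dur[hit] / t_frame)))
      values <- c(values, rep(b, d))
      realized_pause[hit] <- d * t_frame
    }
  }
  values <- c(values, b)

  missing <- if (params$missing_frame_prob > 0) {
    stats::runif(length(values)) < params$missing_frame_prob
  } else rep(FALSE, length(values))
  out_values <- ifelse(missing, ANGLE_MISSING, values)

  realized_periods <- diff(peak_frames) * t_frame
  interruption_min <- 0.010
  freeze_min <- 0.020
  truth <- list(
    n_taps = n_taps,
    t_frame = t_frame,
    baseline = b,
    amplitudes = b + amps,
    periods = realized_periods,
    peak_frames = peak_frames,
    pause_valley = pause_at,
    pause_duration_s = realized_pause,
    pause_kind = pause_kind,
    n_freezing = sum(realized_pause > freeze_min),
    n_interruptions = sum(realized_pause >= interruption_min),
    longest_freezing_s = if (any(realized_pause > freeze_min))
      max(realized_pause[realized_pause > freeze_min]) else 0,
    clean = values)
  list(series = angleSeries(out_values, t_frame, video_id = video_id,
                            hand = hand),
       truth = truth)
}

#' Generate a synthetic landmark series
#'
#' Places the wrist, thumb base, thumb tip and index fingertip so that the
#' wrist angle between the thumb-tip and index-tip vectors reproduces the
#' angle trace of [genAngleSeries()] exactly, with a constant wrist-to-thumb
#' -base distance. Adds optional wrist random-walk drift and i.i.d.
#' coordinate noise; missing frames carry no detection.
#'
#' @inheritParams genAngleSeries
#' @param participant_id identifier stored on the series.
#' @return list with `series` (a [landmarkSeries()]) and the generator
#'   `truth` record.
#' @export
genLandmarkSeries <- function(params, video_id = "synthetic",
                              participant_id = video_id, hand = "right") {
  ga <- genAngleSeries(params, video_id, hand)
  ang <- ga$series$values
  n <- length(ang)
  t_frame <- ga$series$t_frame
  drift <- if (params$wrist_drift_sd > 0) {
    cbind(cumsum(stats::rnorm(n, 0, params$wrist_drift_sd)),
          cumsum(stats::rnorm(n, 0, params$wrist_drift_sd)))
  } else matrix(0, n, 2)
  theta0 <- -pi / 3
  wx <- 0.5 + drift[, 1]; wy <- 0.55 + drift[, 2]
  cmx <- wx + 0.10; cmy <- wy
  ttx <- wx + 0.25 * cos(theta0); tty <- wy + 0.25 * sin(theta0)
  phi <- theta0 + pmax(ang, 0) * pi / 180
  itx <- wx + 0.30 * cos(phi); ity <- wy + 0.30 * sin(phi)
  if (params$landmark_noise_sd > 0) {
    nz <- function() stats::rnorm(n, 0, params$landmark_noise_sd)
    wx <- wx + nz(); wy <- wy + nz()
    cmx <- cmx + nz(); cmy <- cmy + nz()
    ttx <- ttx + nz(); tty <- tty + nz()
    itx <- itx + nz(); ity <- ity + nz()
  }
  miss <- ang == ANGLE_MISSING
  fr <- data.frame(frame = seq_len(n) - 1L,
                   label = ifelse(miss, NA, hand),
                   det_score = ifelse(miss, NA_real_, 1),
                   presence = ifelse(miss, NA_real_, 1),
                   lm0_x = ifelse(miss, NA_real_, wx),
                   lm0_y = ifelse(miss, NA_real_, wy),
                   lm1_x = ifelse(miss, NA_real_, cmx),
                   lm1_y = ifelse(miss, NA_real_, cmy),
                   lm4_x = ifelse(miss, NA_real_, ttx),
                   lm4_y = ifelse(miss, NA_real_, tty),
                   lm8_x = ifelse(miss, NA_real_, itx),
                   lm8_y = ifelse(miss, NA_real_, ity),
                   stringsAsFactors = FALSE)
  series <- landmarkSeries(fr, video_id = video_id,
                           participant_id = participant_id, hand = hand,
                           t_frame = t_frame)
  list(series = series, truth = ga$truth)
}

#' Severity-dependent kinematic regimes
#'
#' Default mapping from MDS-UPDRS severity 0-4 to generator parameters,
#' constructed monotone in the clinically scored directions: higher severity
#' means smaller and more decrementing amplitude, slower tapping (the median
#' within-tap speed proxy 2 * amplitude * frequency strictly decreases),
#' more period jitter, and more freezing episodes.
#'
#' @return data.frame with one row per severity 0-4.
#' @export
severityRegimes <- function() {
  data.frame(
    severity = 0:4,
    base_amplitude = c(120, 100, 80, 55, 30),
    tap_frequency = c(2.2, 2.0, 1.7, 1.4, 1.1),
    amplitude_slope = c(0, -0.4, -1.0, -1.8, -2.6),
    period_jitter_cv = c(0.02, 0.05, 0.10, 0.18, 0.28),
    n_freezes = c(0L, 0L, 1L, 2L, 4L),
    n_taps = c(12L, 11L, 10L, 9L, 9L),
    wrist_drift_sd = c(5e-5, 1e-4, 3e-4, 6e-4, 1e-3),
    landmark_noise_sd = 5e-4)
}

#' Cohort specification
#'
#' @param n_participants cohort size (default 100).
#' @param class_probs probabilities of severities 0-4 (default mirrors a
#'   skewed clinical distribution dominated by mild scores).
#' @param regimes severity-to-parameter table (default [severityRegimes()]).
#' @param expert_flip_prob probability that one expert deviates by one point
#'   from the true severity (default 0.25).
#' @param nonexpert_flip_prob deviation probability for the two simulated
#'   non-expert raters (default 0.4).
#' @param difficulty_prob probability an expert flags a video as difficult
#'   (default 0.1).
#' @param frame_rate frames per second (default 30).
#' @param seed integer root seed.
#' @return object of class `cohort_spec`.
#' @export
cohortSpec <- function(n_participants = 100L,
                       class_probs = c(0.22, 0.37, 0.29, 0.11, 0.01),
                       regimes = severityRegimes(),
                       expert_flip_prob = 0.25,
                       nonexpert_flip_prob = 0.4,
                       difficulty_prob = 0.1,
                       frame_rate = 30, seed = 1L) {
  if (abs(sum(class_probs) - 1) > 1e-9 || length(class_probs) != 5L) {
    stop("class_probs must be 5 probabilities summing to 1", call. = FALSE)
  }
  speed_proxy <- 2 * regimes$base_amplitude * regimes$tap_frequency
  if (any(diff(speed_proxy) >= 0) || any(diff(regimes$base_amplitude) >= 0)) {
    stop("regimes must be monotone: median speed and amplitude must ",
         "strictly decrease with severity", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 class_probs = class_probs, regimes = regimes,
                 expert_flip_prob = expert_flip_prob,
                 nonexpert_flip_prob = nonexpert_flip_prob,
                 difficulty_prob = difficulty_prob,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

.noisy_rating <- function(truth, flip_prob, n) {
  delta <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                  prob = c(flip_prob / 2, 1 - flip_prob, flip_prob / 2))
  pmin(4L, pmax(0L, truth + delta))
}

#' Generate a synthetic cohort
#'
#' Draws a severity per participant, generates two hand-videos per
#' participant from the participant's severity regime (with mild per-video
#' parameter variation), and simulates three expert and two non-expert
#' raters whose ratings equal the true severity plus seeded discrete noise.
#' Deterministic given the spec seed.
#'
#' @param spec a [cohortSpec()].
#' @return list with `videos` (list of [landmarkSeries()]), `truth`
#'   (data.frame: participant_id, video_id, hand, severity), and `ratings`
#'   (data.frame in the [groundTruthTable()] schema).
#' @export
genCohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  severities <- sample(0:4, n, replace = TRUE, prob = spec$class_probs)
  for (s in which(spec$class_probs > 0)) {
    if (!any(severities == s - 1L)) {
      warning("severity class ", s - 1L,
              " requested with nonzero probability but absent at n = ", n)
    }
  }
  videos <- list()
  truth_rows <- list()
  rating_rows <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    sev <- severities[i]
    reg <- spec$regimes[spec$regimes$severity == sev, ]
    for (hand in c("left", "right")) {
      vid <- sprintf("%s_%s", pid, toupper(substr(hand, 1, 1)))
      amp <- reg$base_amplitude * stats::runif(1, 0.9, 1.1)
      freq <- reg$tap_frequency * stats::runif(1, 0.92, 1.08)
      n_fr <- max(0L, reg$n_freezes +
                    sample(c(-1L, 0L, 1L), 1,
                           prob = c(0.25, 0.5, 0.25)))
      n_fr <- min(n_fr, reg$n_taps - 3L)
      freeze_events <- if (n_fr > 0L) {
        lapply(seq_len(n_fr), function(j) {
          c(j / (n_fr + 1), stats::runif(1, 0.03, 0.12))
        })
      } else list()
      params <- tapParams(
        n_taps = reg$n_taps, base_amplitude = amp,
        amplitude_slope = reg$amplitude_slope, tap_frequency = freq,
        period_jitter_cv = reg$period_jitter_cv,
        freeze_events = freeze_events,
        landmark_noise_sd = reg$landmark_noise_sd,
        wrist_drift_sd = reg$wrist_drift_sd,
        frame_rate = spec$frame_rate, seed = NULL)
      gl <- genLandmarkSeries(params, video_id = vid,
                              participant_id = pid, hand = hand)
      videos[[length(videos) + 1L]] <- gl$series
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        participant_id = pid, video_id = vid, hand = hand, severity = sev,
        stringsAsFactors = FALSE)
      experts <- .noisy_rating(sev, spec$expert_flip_prob, 3L)
      nonexp <- .noisy_rating(sev, spec$nonexpert_flip_prob, 2L)
      flags <- stats::runif(3) < spec$difficulty_prob
      rating_rows[[length(rating_rows) + 1L]] <- data.frame(
        video_id = vid, hand = hand,
        rater_id = c("expert1", "expert2", "expert3",
                     "nonexpert1", "nonexpert2"),
        role = c(rep("expert", 3), rep("non-expert", 2)),
        rating = c(experts, nonexp),
        difficulty_flag = c(flags, FALSE, FALSE),
        stringsAsFactors = FALSE)
    }
  }
  list(videos = videos,
       truth = do.call(rbind, truth_rows),
       ratings = do.call(rbind, rating_rows))
}
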