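#' Per-frame tapping speed
#'
#' Absolute change in tapping angle between consecutive frames divided by the
#' frame duration, in degrees/second. Defined from the second frame on.
#'
#' @param signal a [cleanSignal()], or a numeric angle vector (then `t_frame`
#'   must be given).
#' @param t_frame frame duration in seconds (ignored for clean signals).
#' @return numeric vector of length `n - 1`.
#' @export
computeSpeed <- function(signal, t_frame = NULL) {
  if (inherits(signal, "clean_signal")) {
    x <- signal$angles$values
    t_frame <- signal$angles$t_frame
  } else {
    x <- as.numeric(signal)
  }
  if (length(x) < 2L) stop("need at least 2 frames for speed", call. = FALSE)
  abs(diff(x)) / t_frame
}

#' Per-frame tapping acceleration
#'
#' Absolute change in speed between consecutive frames divided by the frame
#' duration, in degrees/second^2.
#'
#' @param speed numeric speed vector from [computeSpeed()].
#' @param t_frame frame duration in seconds.
#' @return numeric vector of length `length(speed) - 1`.
#' @export
computeAcceleration <- function(speed, t_frame) {
  if (length(speed) < 2L) {
    stop("need at least 2 speed values for acceleration", call. = FALSE)
  }
  abs(diff(speed)) / t_frame
}

#' Per-tap period, frequency and amplitude
#'
#' Period of tap i is the time between peaks i-1 and i; frequency is its
#' inverse; amplitude is the angle at each peak (the maximal aperture of the
#' tap).
#'
#' @param signal a [cleanSignal()] with at least 2 peaks.
#' @return list with `periods` (s), `frequencies` (Hz) — both length k-1 —
#'   and `amplitudes` (degrees, length k).
#' @export
computeTapMetrics <- function(signal) {
  stopifnot(inherits(signal, "clean_signal"))
  pk <- signal$peaks$peaks
  if (length(pk) < 2L) stop("need at least 2 peaks", call. = FALSE)
  periods <- diff(pk) * signal$angles$t_frame
  list(periods = periods, frequencies = 1 / periods,
       amplitudes = signal$peaks$values)
}

#' Per-frame wrist motion
#'
#' Wrist coordinates are first normalized frame-by-frame by the Euclidean
#' wrist-to-thumb-base distance (cancelling camera distance), then the
#' absolute x displacement, absolute y displacement, and Euclidean
#' displacement versus the previous retained frame are computed. Frames with
#' missing wrist landmarks or zero normalizing distance are skipped with a
#' message.
#'
#' @param series a [landmarkSeries()].
#' @param from,to 1-based first and last frame rows of the analyzed segment
#'   (defaults: whole series).
#' @return list of numeric vectors `dx`, `dy`, `d`.
#' @export
computeWristMotion <- function(series, from = 1L, to = nrow(series$frames)) {
  stopifnot(inherits(series, "landmark_series"))
  fr <- series$frames[from:to, , drop = FALSE]
  wx <- fr$lm0_x; wy <- fr$lm0_y
  cx <- fr$lm1_x; cy <- fr$lm1_y
  norm <- sqrt((wx - cx)^2 + (wy - cy)^2)
  ok <- !is.na(wx) & !is.na(cx) & !is.na(norm) & norm > 0
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    message(n_bad, " frame(s) skipped in wrist-motion computation")
  }
  nx <- (wx / norm)[ok]
  ny <- (wy / norm)[ok]
  if (length(nx) < 2L) {
    return(list(dx = numeric(0), dy = numeric(0), d = numeric(0)))
  }
  dx <- abs(diff(nx))
  dy <- abs(diff(ny))
  list(dx = dx, dy = dy, d = sqrt(diff(nx)^2 + diff(ny)^2))
}

.hist_entropy <- function(v, bins) {
  rng <- range(v)
  # a numerically constant sequence is a degenerate (zero-entropy)
  # distribution; without this floor, femto-degree jitter would spread an
  # essentially constant sequence across bins and jump the entropy
  if (rng[2] - rng[1] <= 1e-9 * max(1, abs(rng[1]), abs(rng[2]))) return(0)
  width <- (rng[2] - rng[1]) / bins
  bin <- pmin(bins, floor((v - rng[1]) / width) + 1L)
  p <- tabulate(bin, nbins = bins) / length(v)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Seven statistical aggregates of a measurement sequence
#'
#' Median, interquartile range, mean, minimum, maximum, standard deviation,
#' and Shannon entropy of the empirical distribution (natural log, over an
#' equal-width histogram spanning the observed range).
#'
#' @param values non-empty numeric vector.
#' @param bins histogram bins for the entropy (default 10).
#' @return named numeric vector
#'   `c(median, iqr, mean, min, max, std, entropy)`.
#' @export
aggregateStats <- function(values, bins = 10L) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  c(median = stats::median(values),
    iqr = stats::IQR(values),
    mean = mean(values),
    min = min(values),
    max = max(values),
    std = if (length(values) > 1L) stats::sd(values) else 0,
    entropy = .hist_entropy(values, bins))
}

#' Spectral aperiodicity
#'
#' Shannon entropy of the normalized power spectral density of the
#' mean-removed signal (one-sided spectrum, DC excluded). A signal
#' concentrated on one frequency has near-zero entropy; irregular,
#' arrhythmic tapping spreads power across frequencies and scores high.
#'
#' @param signal a [cleanSignal()] or a numeric vector (at least 16 samples).
#' @return nonnegative scalar; 0 for a constant signal.
#' @export
aperiodicity <- function(signal) {
  x <- if (inherits(signal, "clean_signal")) signal$angles$values else
    as.numeric(signal)
  if (length(x) < 16L) stop("need at least 16 samples", call. = FALSE)
  x <- x - mean(x)
  if (all(abs(x) < 1e-12)) {
    message("constant signal: aperiodicity 0 by convention")
    return(0)
  }
  pw <- Mod(stats::fft(x))^2
  half <- pw[2:(floor(length(x) / 2) + 1L)]
  if (sum(half) == 0) return(0)
  p <- half / sum(half)
  p <- p[p > 0]
  -sum(p * log(p))
}

.slow_runs <- function(speed, t_frame, threshold) {
  r <- rle(speed < threshold)
  r$lengths[r$values] * t_frame
}

#' Count tapping interruptions
#'
#' Maximal runs of tapping speed below the threshold lasting at least
#' `min_dur` seconds.
#'
#' @param speed numeric per-frame speed (degrees/second).
#' @param t_frame frame duration in seconds.
#' @param threshold speed floor, degrees/second (default 50).
#' @param min_dur minimum run duration in seconds (default 0.010).
#' @return integer count.
#' @export
countInterruptions <- function(speed, t_frame, threshold = 50,
                               min_dur = 0.010) {
  durs <- .slow_runs(speed, t_frame, threshold)
  sum(durs >= min_dur)
}

#' Count freezing episodes
#'
#' Maximal sub-threshold speed runs lasting strictly longer than `min_dur`
#' seconds, and the longest such duration.
#'
#' @inheritParams countInterruptions
#' @param min_dur duration that must be exceeded, seconds (default 0.020).
#' @return list with `count` and `longest_s` (0 when none).
#' @export
countFreezing <- function(speed, t_frame, threshold = 50, min_dur = 0.020) {
  durs <- .slow_runs(speed, t_frame, threshold)
  frozen <- durs[durs > min_dur]
  list(count = length(frozen),
       longest_s = if (length(frozen)) max(frozen) else 0)
}

.poly_r2 <- function(y, degree) {
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(list(r2 = 1, slope = 0))
  design <- outer(seq_len(n), 0:degree, `^`)
  fit <- stats::lm.fit(design, y)
  r2 <- 1 - sum(fit$residuals^2) / sst
  list(r2 = r2, slope = unname(fit$coefficients[2]))
}

#' Linearity of tap periods
#'
#' Least-squares line of period versus tap index: a participant tapping at a
#' steady rhythm is well fitted by a flat line. Returns the coefficient of
#' determination (1 by convention when the periods have zero variance) and
#' the slope in seconds per tap.
#'
#' @param periods numeric vector of at least 3 periods.
#' @return named numeric `c(r2, slope)`.
#' @export
periodLinearity <- function(periods) {
  if (length(periods) < 3L) stop("need at least 3 periods", call. = FALSE)
  fit <- .poly_r2(periods, 1L)
  c(r2 = fit$r2, slope = fit$slope)
}

#' Complexity of fitting tap periods
#'
#' Smallest polynomial degree (1..`max_degree`) whose least-squares fit of
#' period versus tap index reaches the R-squared threshold; irregular
#' rhythms need higher degrees. Returns `max_degree + 1` when no degree
#' suffices.
#'
#' @param periods numeric vector of at least 3 periods.
#' @param r2_threshold fit-quality bar (default 0.9).
#' @param max_degree largest degree tried (default 10).
#' @return integer degree.
#' @export
periodFitComplexity <- function(periods, r2_threshold = 0.9,
                                max_degree = 10L) {
  if (length(periods) < 3L) stop("need at least 3 periods", call. = FALSE)
  for (d in seq_len(max_degree)) {
    if (.poly_r2(periods, d)$r2 >= r2_threshold) return(d)
  }
  max_degree + 1L
}

#' Amplitude decrement measures
#'
#' Progressive shrinkage of tap aperture, an MDS-UPDRS scoring criterion:
#' the end amplitude minus the mean amplitude, the end minus the beginning
#' amplitude, and the slope of the least-squares line of amplitude over tap
#' index (degrees/tap). "End" and "beginning" are means of the last/first
#' `end_k` taps (default a single tap).
#'
#' @param amplitudes numeric vector of at least 3 peak amplitudes (degrees).
#' @param end_k taps averaged at each end (default 1).
#' @return named numeric `c(end_minus_mean, end_minus_begin, slope)`.
#' @export
amplitudeDecrement <- function(amplitudes, end_k = 1L) {
  n <- length(amplitudes)
  if (n < 3L) stop("need at least 3 amplitudes", call. = FALSE)
  end_k <- min(end_k, n)
  a_end <- mean(amplitudes[(n - end_k + 1L):n])
  a_begin <- mean(amplitudes[seq_len(end_k)])
  c(end_minus_mean = a_end - mean(amplitudes),
    end_minus_begin = a_end - a_begin,
    slope = .poly_r2(amplitudes, 1L)$slope)
}

#' Assemble the 65-feature vector of one hand-video
#'
#' Computes every registry feature from a cleaned tapping signal and its
#' source landmark series: the seven aggregates of speed, acceleration,
#' period, frequency and amplitude (35 features); aperiodicity,
#' interruption/freezing counts, longest freezing duration, period linearity
#' and fitting complexity, the three amplitude-decrement measures, the period
#' variance normalized by the mean period, and the retained tap count (12
#' features); and six aggregates of the three wrist-motion metrics over the
#' same trimmed segment (18 features).
#'
#' @param signal a [cleanSignal()] with at least 4 retained peaks.
#' @param series the source [landmarkSeries()].
#' @param config a [tapConfig()].
#' @return named numeric vector of length 65 in registry order.
#' @export
featurize <- function(signal, series, config = tapConfig()) {
  stopifnot(inherits(signal, "clean_signal"),
            inherits(series, "landmark_series"))
  if (length(signal$peaks$peaks) < 4L) {
    stop("featurize requires at least 4 retained peaks", call. = FALSE)
  }
  t_frame <- signal$angles$t_frame
  bins <- config$entropy_bins
  speed <- computeSpeed(signal)
  accel <- computeAcceleration(speed, t_frame)
  tm <- computeTapMetrics(signal)
  from <- signal$angles$offset + 1L
  to <- signal$angles$offset + length(signal$angles$values)
  wm <- computeWristMotion(series, from, to)

  out <- numeric(0)
  for (pair in list(c("speed", "speed"), c("acceleration", "accel"),
                    c("period", "periods"), c("frequency", "frequencies"),
                    c("amplitude", "amplitudes"))) {
    vals <- switch(pair[2],
                   speed = speed, accel = accel,
                   periods = tm$periods, frequencies = tm$frequencies,
                   amplitudes = tm$amplitudes)
    ag <- aggregateStats(vals, bins)
    names(ag) <- paste(pair[1], names(ag), sep = "_")
    out <- c(out, ag)
  }
  fr <- countFreezing(speed, t_frame, config$speed_threshold,
                      config$freeze_min_s)
  lin <- periodLinearity(tm$periods)
  dec <- amplitudeDecrement(tm$amplitudes, config$end_taps_k)
  out <- c(out,
           aperiodicity = aperiodicity(signal),
           n_interruptions = countInterruptions(
             speed, t_frame, config$speed_threshold,
             config$interruption_min_s),
           n_freezing = fr$count,
           longest_freezing_s = fr$longest_s,
           period_linearity_r2 = unname(lin["r2"]),
           period_linearity_slope = unname(lin["slope"]),
           period_fit_complexity = periodFitComplexity(
             tm$periods, config$r2_threshold, config$max_fit_degree),
           amplitude_end_minus_mean = unname(dec["end_minus_mean"]),
           amplitude_end_minus_begin = unname(dec["end_minus_begin"]),
           amplitude_slope = unname(dec["slope"]),
           period_var_norm = stats::var(tm$periods) / mean(tm$periods),
           n_taps = length(signal$peaks$peaks))
  for (pair in list(c("wrist_dx", "dx"), c("wrist_dy", "dy"),
                    c("wrist_d", "d"))) {
    vals <- wm[[pair[2]]]
    if (length(vals) == 0L) vals <- 0
    ag <- aggregateStats(vals, bins)
    ag <- ag[setdiff(names(ag), "mean")]
    names(ag) <- paste(pair[1], names(ag), sep = "_")
    out <- c(out, ag)
  }
  reg <- featureRegistry()
  stopifnot(identical(names(out), as.character(reg)))
  out
}

#' Featurize a batch of landmark series
#'
#' Runs the cleaning pipeline and [featurize()] on each series; videos that
#' fail (e.g. fewer than 4 detectable taps) are skipped with a warning and
#' reported in the `skipped` attribute.
#'
#' @param series_list list of [landmarkSeries()] objects.
#' @param config a [tapConfig()].
#' @return data.frame with `participant_id`, `video_id`, `hand`, and the 65
#'   registry feature columns; attribute `skipped` names the failed videos.
#' @export
featurizeVideos <- function(series_list, config = tapConfig()) {
  rows <- list()
  skipped <- character(0)
  for (s in series_list) {
    feats <- tryCatch({
      sig <- cleanTappingSignal(s, config)
      featurize(sig, s, config)
    }, error = function(e) e)
    if (inherits(feats, "error")) {
      warning(sprintf("skipping video %s [%s]: %s", s$video_id, s$hand,
                      conditionMessage(feats)), call. = FALSE)
      skipped <- c(skipped, paste0(s$video_id, ":", s$hand))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = s$participant_id, video_id = s$video_id,
      hand = s$hand, as.list(feats), check.names = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no video could be featurized", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write/read a feature table as CSV at full float precision
#' @param table feature data.frame from [featurizeVideos()].
#' @param path file path.
#' @export
writeFeatureTable <- function(table, path) {
  out <- table
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in intersect(names(df), c(featureRegistry(), "label"))) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  df
}
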