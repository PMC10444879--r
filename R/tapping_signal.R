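#' Finger-tapping angle of one frame
#'
#' Angle at the wrist subtended by the thumb tip and the index fingertip:
#' the arc cosine of the normalized dot product of the wrist-to-thumb-tip and
#' wrist-to-index-tip vectors, in degrees. Being an angle, it is invariant to
#' rotation, translation and uniform scaling of the landmarks, which makes it
#' a camera-distance-invariant proxy for tap aperture.
#'
#' @param wrist,thumb_tip,index_tip numeric (x, y) pairs.
#' @return angle in degrees, in \[0, 180\].
#' @export
#' @examples
#' computeAngle(c(0, 0), c(1, 0), c(0, 1))  # 90
computeAngle <- function(wrist, thumb_tip, index_tip) {
  wt <- as.numeric(thumb_tip) - as.numeric(wrist)
  wi <- as.numeric(index_tip) - as.numeric(wrist)
  nwt <- sqrt(sum(wt^2))
  nwi <- sqrt(sum(wi^2))
  if (nwt == 0 || nwi == 0) {
    stop("degenerate geometry: zero-length wrist vector", call. = FALSE)
  }
  cosv <- sum(wt * wi) / (nwt * nwi)
  acos(min(1, max(-1, cosv))) * 180 / pi
}

ANGLE_MISSING <- -1.0

#' Angle series container
#'
#' Tapping-angle trace in degrees with the -1.0 missing-hand sentinel.
#'
#' @param values numeric vector; each element in \[0,180\] or -1.0.
#' @param t_frame frame duration in seconds.
#' @param offset 0-based offset of the first sample into the source series.
#' @param video_id,hand provenance.
#' @return object of class `angle_series`.
#' @export
angleSeries <- function(values, t_frame, offset = 0L,
                        video_id = NA, hand = NA) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("angle series must be non-empty", call. = FALSE)
  bad <- values != ANGLE_MISSING & (values < 0 | values > 180 | is.na(values))
  if (any(bad)) {
    stop("angle values must lie in [0, 180] or equal the -1.0 sentinel",
         call. = FALSE)
  }
  if (t_frame <= 0) stop("t_frame must be positive", call. = FALSE)
  structure(list(values = values, t_frame = t_frame,
                 offset = as.integer(offset),
                 video_id = video_id, hand = hand),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  n_miss <- sum(x$values == ANGLE_MISSING)
  cat(sprintf("angle_series: %d frames @ %.4g s, %d missing (offset %d)\n",
              length(x$values), x$t_frame, n_miss, x$offset))
  invisible(x)
}

#' Build the tapping-angle series from a landmark series
#'
#' Per frame, the angle of [computeAngle()] over landmarks 0 (wrist),
#' 4 (thumb tip) and 8 (index tip) when the frame holds a selected detection
#' with presence score at or above the threshold; otherwise the -1.0
#' missing-hand sentinel. Frames with degenerate geometry (coincident
#' landmarks) also become sentinels and are counted in a message.
#'
#' @param series a [landmarkSeries()].
#' @param presence_threshold minimum presence score (default 0.90).
#' @return an [angleSeries()].
#' @export
buildAngleSeries <- function(series, presence_threshold = 0.90) {
  stopifnot(inherits(series, "landmark_series"))
  fr <- series$frames
  n <- nrow(fr)
  vals <- rep(ANGLE_MISSING, n)
  degenerate <- 0L
  ok <- !is.na(fr$label) & !is.na(fr$presence) &
    fr$presence >= presence_threshold
  for (i in which(ok)) {
    ang <- tryCatch(
      computeAngle(c(fr$lm0_x[i], fr$lm0_y[i]),
                   c(fr$lm4_x[i], fr$lm4_y[i]),
                   c(fr$lm8_x[i], fr$lm8_y[i])),
      error = function(e) NA_real_)
    if (is.na(ang)) degenerate <- degenerate + 1L else vals[i] <- ang
  }
  if (degenerate > 0L) {
    message(degenerate, " frame(s) with degenerate geometry treated as missing")
  }
  angleSeries(vals, series$t_frame, offset = 0L,
              video_id = series$video_id, hand = series$hand)
}

#' Interpolate isolated missing angles
#'
#' Each -1.0 sentinel whose surrounding neighbourhood (up to `window` frames
#' on each side) holds a strict majority of visible values is replaced by the
#' value of a single polynomial fitted by least squares to all visible
#' samples of the signal, clamped to \[0, 180\]. Sentinels inside long
#' missing runs fail the majority rule and are left untouched.
#'
#' @param series an [angleSeries()].
#' @param window frames inspected on each side (default 5).
#' @param degree degree of the fitted polynomial (default 3).
#' @return an [angleSeries()] with some sentinels filled.
#' @export
interpolateMissing <- function(series, window = 5L, degree = 3L) {
  stopifnot(inherits(series, "angle_series"), window >= 1L)
  x <- series$values
  n <- length(x)
  vis <- x != ANGLE_MISSING
  if (!any(vis)) {
    warning("signal has no visible samples; nothing to interpolate")
    return(series)
  }
  idx <- which(vis)
  deg <- max(1L, min(degree, length(idx) - 1L))
  design <- outer(idx, 0:deg, `^`)
  coefs <- stats::lm.fit(design, x[idx])$coefficients
  coefs[is.na(coefs)] <- 0
  predict_poly <- function(i) sum(coefs * i^(0:deg))
  out <- x
  for (i in which(!vis)) {
    nb <- c(seq(max(1L, i - window), i - 1L),
            seq(i + 1L, min(n, i + window)))
    nb <- nb[nb >= 1L & nb <= n & nb != i]
    if (sum(vis[nb]) * 2L > length(nb)) {
      out[i] <- min(180, max(0, predict_poly(i)))
    }
  }
  angleSeries(out, series$t_frame, series$offset, series$video_id,
              series$hand)
}

#' Longest visible segment
#'
#' The longest run of consecutive visible (non-sentinel) angles; the frames
#' before and after it — typically hand positioning before the task and hand
#' withdrawal after it — are discarded. Equal-length runs keep the earliest.
#'
#' @param series an [angleSeries()].
#' @return an [angleSeries()] with its `offset` advanced to the segment start.
#' @export
longestVisibleSegment <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  vis <- series$values != ANGLE_MISSING
  if (!any(vis)) stop("all frames missing: no visible segment", call. = FALSE)
  r <- rle(vis)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  keep <- starts[best]:ends[best]
  angleSeries(series$values[keep], series$t_frame,
              offset = series$offset + starts[best] - 1L,
              video_id = series$video_id, hand = series$hand)
}

#' Peak set container
#' @param peaks strictly increasing integer positions into an angle series.
#' @param values the angle values at those positions.
#' @return object of class `peak_set`.
#' @export
peakSet <- function(peaks, values) {
  peaks <- as.integer(peaks)
  if (length(peaks) && is.unsorted(peaks, strictly = TRUE)) {
    stop("peak positions must be strictly increasing", call. = FALSE)
  }
  structure(list(peaks = peaks, values = as.numeric(values)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks\n", length(x$peaks)))
  invisible(x)
}

#' Custom tap-peak detection
#'
#' Finds the tap peaks of a cleaned (sentinel-free) angle signal using three
#' task-specific rules: (a) a peak must be followed by a bottom — between two
#' consecutive accepted peaks some sample must drop at least
#' `trough_iqr_fraction` of the signal's interquartile range below the
#' earlier peak; (b) consecutive peaks must be at least `min_gap_s` apart
#' (tapping speed is bounded); and (c) every peak must exceed the
#' `amplitude_floor_quantile` quantile of the signal. Strict local maxima
#' are scanned left to right; when a candidate violates (a) or (b) against
#' the last accepted peak, the larger of the two survives.
#'
#' @param series sentinel-free [angleSeries()].
#' @param min_gap_s minimum inter-peak gap in seconds (default 0.1).
#' @param amplitude_floor_quantile quantile floor (default 0.25).
#' @param trough_iqr_fraction required drop as a fraction of the signal IQR
#'   (default 0.2).
#' @return a [peakSet()]; empty for signals with no qualifying maxima.
#' @export
detectPeaks <- function(series, min_gap_s = 0.1,
                        amplitude_floor_quantile = 0.25,
                        trough_iqr_fraction = 0.2) {
  stopifnot(inherits(series, "angle_series"))
  x <- series$values
  if (any(x == ANGLE_MISSING)) {
    stop("detectPeaks requires a sentinel-free signal", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) return(peakSet(integer(0), numeric(0)))
  floor_val <- stats::quantile(x, amplitude_floor_quantile, names = FALSE)
  drop_req <- trough_iqr_fraction * stats::IQR(x)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] > x[3:n]) + 1L
  cand <- cand[x[cand] > floor_val]
  acc <- integer(0)
  for (c_i in cand) {
    if (!length(acc)) {
      acc <- c_i
      next
    }
    p <- acc[length(acc)]
    gap_ok <- (c_i - p) * series$t_frame >= min_gap_s
    between <- x[(p + 1L):(c_i - 1L)]
    trough_ok <- length(between) > 0 && min(between) < x[p] - drop_req
    if (gap_ok && trough_ok) {
      acc <- c(acc, c_i)
    } else if (x[c_i] > x[p]) {
      acc[length(acc)] <- c_i
    }
  }
  peakSet(acc, x[acc])
}

#' Clean signal: trimmed angle series plus its peaks
#' @param series sentinel-free trimmed [angleSeries()].
#' @param peaks [peakSet()] re-indexed to `series`.
#' @return object of class `clean_signal`.
#' @export
cleanSignal <- function(series, peaks) {
  stopifnot(inherits(series, "angle_series"), inherits(peaks, "peak_set"))
  if (any(series$values == ANGLE_MISSING)) {
    stop("clean signal must contain no sentinels", call. = FALSE)
  }
  structure(list(angles = series, peaks = peaks), class = "clean_signal")
}

#' @export
print.clean_signal <- function(x, ...) {
  cat(sprintf(
    "clean_signal %s [%s]: %d frames @ %.4g s, %d peaks\n",
    x$angles$video_id, x$angles$hand, length(x$angles$values),
    x$angles$t_frame, length(x$peaks$peaks)))
  invisible(x)
}

#' Trim the first and last tap
#'
#' Participants position their hand before tapping and withdraw it after, so
#' the first and last taps are unreliable. The signal is cut to the span from
#' the second peak through the second-to-last peak (inclusive), and the peak
#' set is re-indexed; exactly two peaks are removed.
#'
#' @param series sentinel-free [angleSeries()].
#' @param peaks [peakSet()] from [detectPeaks()]; at least 4 peaks.
#' @return a [cleanSignal()].
#' @export
trimFirstLastTap <- function(series, peaks) {
  stopifnot(inherits(series, "angle_series"), inherits(peaks, "peak_set"))
  k <- length(peaks$peaks)
  if (k < 4L) {
    stop(sprintf("insufficient taps in video %s: %d peaks detected, need 4",
                 series$video_id, k), call. = FALSE)
  }
  from <- peaks$peaks[2L]
  to <- peaks$peaks[k - 1L]
  trimmed <- angleSeries(series$values[from:to], series$t_frame,
                         offset = series$offset + from - 1L,
                         video_id = series$video_id, hand = series$hand)
  new_peaks <- peaks$peaks[2:(k - 1L)] - from + 1L
  cleanSignal(trimmed, peakSet(new_peaks, peaks$values[2:(k - 1L)]))
}

#' Full signal-cleaning pipeline
#'
#' Angle construction, interpolation of isolated missing values, longest
#' visible segment, peak detection, and first/last-tap trimming, in that
#' order.
#'
#' @param series a [landmarkSeries()].
#' @param config a [tapConfig()].
#' @return a [cleanSignal()].
#' @export
cleanTappingSignal <- function(series, config = tapConfig()) {
  ang <- buildAngleSeries(series, config$presence_threshold)
  ang <- interpolateMissing(ang, config$interp_window, config$interp_degree)
  seg <- longestVisibleSegment(ang)
  pk <- detectPeaks(seg, config$min_peak_gap_s,
                    config$amplitude_floor_quantile,
                    config$trough_iqr_fraction)
  trimFirstLastTap(seg, pk)
}

#' Write/read an angle series as CSV
#'
#' Columns `video_id,hand,frame,t_frame,angle_deg` with the -1.0 sentinel.
#' @param series an [angleSeries()].
#' @param path file path.
#' @return `path` invisibly (write); an [angleSeries()] (read).
#' @export
writeAngleSeries <- function(series, path) {
  df <- data.frame(video_id = series$video_id, hand = series$hand,
                   frame = series$offset + seq_along(series$values) - 1L,
                   t_frame = sprintf("%.17g", series$t_frame),
                   angle_deg = sprintf("%.17g", series$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAngleSeries
#' @export
readAngleSeries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  angleSeries(as.numeric(df$angle_deg), as.numeric(df$t_frame[1]),
              offset = as.integer(df$frame[1]),
              video_id = df$video_id[1], hand = df$hand[1])
}
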