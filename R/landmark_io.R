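#' Hand detection record
#'
#' One pose-estimator detection for a single frame: handedness label,
#' classification and presence confidence scores, and the 21 hand key points
#' in normalized image coordinates (origin top-left, x rightwards, y
#' downwards).
#'
#' @param hand_label "left" or "right".
#' @param detection_score handedness classification confidence in \[0,1\].
#' @param presence_score hand presence confidence in \[0,1\].
#' @param keypoints 21 x 2 numeric matrix of (x, y) pairs, row i holding
#'   landmark i-1. Rows other than the wrist (0), thumb base (1), thumb tip
#'   (4) and index tip (8) may be NA.
#' @return object of class `hand_detection`.
#' @export
handDetection <- function(hand_label, detection_score, presence_score,
                          keypoints) {
  hand_label <- match.arg(hand_label, c("left", "right"))
  keypoints <- as.matrix(keypoints)
  if (!is.numeric(keypoints) || nrow(keypoints) != 21L ||
      ncol(keypoints) != 2L) {
    stop("keypoints must be a 21 x 2 numeric matrix", call. = FALSE)
  }
  if (anyNA(keypoints[REQUIRED_LANDMARKS + 1L, ])) {
    stop("required landmarks (0, 1, 4, 8) must be present", call. = FALSE)
  }
  if (detection_score < 0 || detection_score > 1 ||
      presence_score < 0 || presence_score > 1) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  structure(list(hand_label = hand_label,
                 detection_score = detection_score,
                 presence_score = presence_score,
                 keypoints = keypoints),
            class = "hand_detection")
}

#' Select the target hand among multi-hand detections
#'
#' Scans the detections of one frame for the requested hand category. A
#' detection qualifies when its handedness label matches `hand` and its
#' classification score exceeds `score_threshold`. With several qualifying
#' detections (e.g. another person visible in the frame), the subject is
#' assumed to be closest to the camera and therefore to have the largest
#' hand: the detection with the greatest wrist-to-thumb-tip Euclidean
#' distance wins; exact ties keep the earliest-listed detection.
#'
#' @param detections list of [handDetection()] objects (possibly empty).
#' @param hand target hand category, "left" or "right".
#' @param score_threshold handedness score threshold (default 0.9).
#' @param frame optional frame index used in validation error messages.
#' @return the selected `hand_detection`, or `NULL` when no detection
#'   qualifies (missing hand).
#' @export
selectTargetHand <- function(detections, hand,
                             score_threshold = 0.9, frame = NA) {
  hand <- match.arg(hand, c("left", "right"))
  for (d in detections) {
    if (!inherits(d, "hand_detection")) {
      stop(sprintf("malformed detection%s: not a hand_detection record",
                   if (is.na(frame)) "" else sprintf(" at frame %s", frame)),
           call. = FALSE)
    }
  }
  ok <- vapply(detections, function(d) {
    d$hand_label == hand && d$detection_score > score_threshold
  }, logical(1))
  idx <- which(ok)
  if (length(idx) == 0L) return(NULL)
  if (length(idx) == 1L) return(detections[[idx]])
  size <- vapply(detections[idx], function(d) {
    sqrt(sum((d$keypoints[LM_WRIST + 1L, ] -
                d$keypoints[LM_THUMB_TIP + 1L, ])^2))
  }, numeric(1))
  detections[[idx[which.max(size)]]]
}

.lm_cols <- function(ids) {
  as.vector(rbind(sprintf("lm%d_x", ids), sprintf("lm%d_y", ids)))
}

#' Landmark time series for one hand-video
#'
#' @param frames data.frame with one row per frame: columns `frame`
#'   (strictly increasing integer), `label`, `det_score`, `presence`, and
#'   coordinate columns `lm<i>_x`/`lm<i>_y` for at least landmarks 0, 1, 4
#'   and 8. Missing-hand frames carry NA in `label`, scores and coordinates.
#' @param video_id,participant_id identifiers.
#' @param hand hand category of the series, "left" or "right".
#' @param t_frame duration of one frame in seconds (video duration divided by
#'   frame count).
#' @param metadata optional named list (sex, age, PD status, rater difficulty
#'   flags, ...).
#' @return object of class `landmark_series`.
#' @export
landmarkSeries <- function(frames, video_id, participant_id = video_id,
                           hand, t_frame, metadata = list()) {
  hand <- match.arg(hand, c("left", "right"))
  if (!is.data.frame(frames) || nrow(frames) == 0L) {
    stop("frames must be a non-empty data.frame", call. = FALSE)
  }
  need <- c("frame", "label", "det_score", "presence",
            .lm_cols(REQUIRED_LANDMARKS))
  miss <- setdiff(need, names(frames))
  if (length(miss)) {
    stop("frames is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(frames$frame, strictly = TRUE)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(t_frame) || length(t_frame) != 1L || t_frame <= 0) {
    stop("t_frame must be a positive scalar (seconds)", call. = FALSE)
  }
  lab <- frames$label[!is.na(frames$label)]
  if (length(lab) && any(lab != hand)) {
    stop("every selected detection's hand label must equal the series hand",
         call. = FALSE)
  }
  # a frame missing any required coordinate is a missing-hand frame
  req <- .lm_cols(REQUIRED_LANDMARKS)
  incomplete <- !is.na(frames$label) &
    apply(is.na(frames[, req, drop = FALSE]), 1L, any)
  if (any(incomplete)) {
    frames$label[incomplete] <- NA
    frames$det_score[incomplete] <- NA_real_
    frames$presence[incomplete] <- NA_real_
    message(sum(incomplete),
            " frame(s) with incomplete landmarks treated as missing")
  }
  structure(list(video_id = video_id, participant_id = participant_id,
                 hand = hand, t_frame = t_frame, frames = frames,
                 metadata = metadata),
            class = "landmark_series")
}

#' @export
print.landmark_series <- function(x, ...) {
  n_missing <- sum(is.na(x$frames$label))
  cat(sprintf(
    "landmark_series %s [%s hand, participant %s]\n  %d frames @ %.4g s/frame (%.2f s), %d missing-hand\n",
    x$video_id, x$hand, x$participant_id, nrow(x$frames), x$t_frame,
    nrow(x$frames) * x$t_frame, n_missing))
  invisible(x)
}

.missing_frames <- function(series) is.na(series$frames$label)

#' Mean hand presence score of a series
#'
#' Average presence score across frames after dropping the leading and
#' trailing missing-hand runs (the positioning phases before and after the
#' task). Interior missing-hand frames carry no presence score and are
#' excluded from the mean.
#'
#' @param series a [landmarkSeries()].
#' @return fraction in \[0,1\], or `NA` when every frame is missing.
#' @export
meanPresenceScore <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  if (nrow(series$frames) == 0L) stop("empty series", call. = FALSE)
  present <- !.missing_frames(series)
  if (!any(present)) return(NA_real_)
  span <- seq(which(present)[1L], max(which(present)))
  mean(series$frames$presence[span], na.rm = TRUE)
}

#' Adapt a raw video through an external hand-pose estimator
#'
#' Placeholder for the optional video adapter. Turning raw video into a
#' landmark series requires an external 21-landmark hand-pose estimator,
#' which this package does not bundle; analysis starts from landmark series
#' (read from disk or generated synthetically).
#'
#' @param video_path path to a video file.
#' @param hand target hand category.
#' @export
extractFromVideo <- function(video_path, hand) {
  stop("no hand-pose estimator is available in this installation; ",
       "provide landmark series via readLandmarkSeries() or the synthetic ",
       "generator", call. = FALSE)
}

.num_fmt <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a landmark series
#'
#' One row/object per frame; missing-hand frames encode label, scores and
#' coordinates as empty fields (CSV) or nulls (JSONL). Numeric fields are
#' written at full double precision so that write/read round-trips are
#' bit-exact for finite values.
#'
#' @param series a [landmarkSeries()].
#' @param path output file path.
#' @param dialect "csv" (default) or "jsonl".
#' @return `path`, invisibly.
#' @export
writeLandmarkSeries <- function(series, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  fr <- series$frames
  lmcols <- grep("^lm[0-9]+_[xy]$", names(fr), value = TRUE)
  head_df <- data.frame(
    video_id = series$video_id, participant_id = series$participant_id,
    hand = series$hand, frame = fr$frame, t_frame = series$t_frame,
    label = ifelse(is.na(fr$label), "", fr$label),
    stringsAsFactors = FALSE)
  if (dialect == "csv") {
    num <- cbind(det_score = .num_fmt(fr$det_score),
                 presence = .num_fmt(fr$presence))
    for (cl in lmcols) num <- cbind(num, .num_fmt(fr[[cl]]))
    colnames(num) <- c("det_score", "presence", lmcols)
    head_df$t_frame <- sprintf("%.17g", series$t_frame)
    out <- cbind(head_df, as.data.frame(num, stringsAsFactors = FALSE))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    # numeric literals are written with %.17g so doubles survive exactly
    con <- file(path, "w")
    on.exit(close(con))
    jstr <- function(k, v) sprintf("\"%s\":\"%s\"", k, v)
    jnum <- function(k, v) sprintf("\"%s\":%.17g", k, v)
    for (i in seq_len(nrow(fr))) {
      parts <- c(jstr("video_id", series$video_id),
                 jstr("participant_id", series$participant_id),
                 jstr("hand", series$hand),
                 sprintf("\"frame\":%d", fr$frame[i]),
                 jnum("t_frame", series$t_frame))
      if (!is.na(fr$label[i])) parts <- c(parts, jstr("label", fr$label[i]))
      for (cl in c("det_score", "presence", lmcols)) {
        if (!is.na(fr[[cl]][i])) parts <- c(parts, jnum(cl, fr[[cl]][i]))
      }
      writeLines(paste0("{", paste(parts, collapse = ","), "}"), con)
    }
  }
  invisible(path)
}

#' Read a landmark series
#'
#' Inverse of [writeLandmarkSeries()]; validates the schema (required
#' landmark columns, strictly increasing frame indices, positive frame
#' duration) and rejects unknown columns.
#'
#' @param path input file path.
#' @param dialect "csv" (default) or "jsonl".
#' @return a [landmarkSeries()].
#' @export
readLandmarkSeries <- function(path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  } else {
    recs <- lapply(readLines(path), jsonlite::fromJSON)
    cols <- unique(unlist(lapply(recs, names)))
    raw <- as.data.frame(
      stats::setNames(lapply(cols, function(cl) {
        vapply(recs, function(r) {
          v <- r[[cl]]
          if (is.null(v)) NA_character_
          else if (is.numeric(v)) sprintf("%.17g", v)
          else as.character(v)
        }, character(1))
      }), cols), stringsAsFactors = FALSE)
  }
  fixed <- c("video_id", "participant_id", "hand", "frame", "t_frame",
             "label", "det_score", "presence")
  lmcols <- grep("^lm[0-9]+_[xy]$", names(raw), value = TRUE)
  unknown <- setdiff(names(raw), c(fixed, lmcols))
  if (length(unknown)) {
    stop("unknown column(s) in landmark file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(c(fixed, .lm_cols(REQUIRED_LANDMARKS)), names(raw))
  if (length(miss)) {
    stop("landmark file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  blank2na <- function(x) ifelse(is.na(x) | x == "", NA, x)
  fr <- data.frame(frame = as.integer(raw$frame),
                   label = blank2na(raw$label),
                   det_score = as.numeric(blank2na(raw$det_score)),
                   presence = as.numeric(blank2na(raw$presence)),
                   stringsAsFactors = FALSE)
  for (cl in lmcols) fr[[cl]] <- as.numeric(blank2na(raw[[cl]]))
  t_frame <- as.numeric(raw$t_frame[1])
  if (is.na(t_frame) || t_frame <= 0) {
    stop("t_frame must be a positive number of seconds", call. = FALSE)
  }
  landmarkSeries(fr, video_id = raw$video_id[1],
                 participant_id = raw$participant_id[1],
                 hand = raw$hand[1], t_frame = t_frame)
}
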