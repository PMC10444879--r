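#' Derive the ground-truth severity from three expert ratings
#'
#' The label is the modal rating when at least two of the three experts
#' agree (`provenance = "majority"`); otherwise the mean of the three
#' ratings rounded to the nearest integer (`provenance = "averaged"`).
#' With three integer ratings the mean is a multiple of 1/3, so the
#' half-point rounding case cannot arise; rounding is half-up for
#' definiteness.
#'
#' @param ratings integer vector of exactly three expert ratings in 0..4.
#' @return list with `severity` (integer 0-4) and `provenance`.
#' @export
#' @examples
#' deriveGroundTruth(c(2, 2, 3))  # severity 2, majority
#' deriveGroundTruth(c(0, 2, 3))  # severity 2, averaged
deriveGroundTruth <- function(ratings) {
  if (length(ratings) != 3L || anyNA(ratings)) {
    stop("exactly three expert ratings are required", call. = FALSE)
  }
  if (any(ratings != round(ratings)) || any(ratings < 0 | ratings > 4)) {
    stop("ratings must be integers in 0..4", call. = FALSE)
  }
  tab <- table(ratings)
  if (max(tab) >= 2L) {
    list(severity = as.integer(names(tab)[which.max(tab)]),
         provenance = "majority")
  } else {
    list(severity = as.integer(min(4, max(0, floor(mean(ratings) + 0.5)))),
         provenance = "averaged")
  }
}

#' Build the ground-truth table from a ratings table
#'
#' Applies [deriveGroundTruth()] to the three expert ratings of every
#' (video, hand); videos without exactly three expert ratings raise an
#' error. The quality group is "low" when at least one expert flagged the
#' video as difficult to rate, "high" otherwise.
#'
#' @param ratings data.frame with columns `video_id`, `hand`, `rater_id`,
#'   `role` ("expert"/"non-expert"), `rating`, `difficulty_flag`.
#' @return data.frame (video_id, hand, severity, provenance, quality).
#' @export
groundTruthTable <- function(ratings) {
  need <- c("video_id", "hand", "rater_id", "role", "rating",
            "difficulty_flag")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) {
    stop("ratings table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ex <- ratings[ratings$role == "expert", , drop = FALSE]
  keys <- unique(ex[, c("video_id", "hand")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- ex$video_id == keys$video_id[i] & ex$hand == keys$hand[i]
    r <- ex$rating[sel]
    if (length(r) != 3L) {
      stop(sprintf("video %s [%s] has %d expert ratings, need 3",
                   keys$video_id[i], keys$hand[i], length(r)),
           call. = FALSE)
    }
    gt <- deriveGroundTruth(r)
    data.frame(video_id = keys$video_id[i], hand = keys$hand[i],
               severity = gt$severity, provenance = gt$provenance,
               quality = if (any(ex$difficulty_flag[sel])) "low" else "high",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ratings matrix (videos x raters)
#'
#' @param ratings ratings data.frame (see [groundTruthTable()]).
#' @param role restrict to raters of this role (default "expert"; NULL for
#'   all raters).
#' @return numeric matrix, rows = video:hand units, columns = raters, NA for
#'   unrated cells.
#' @export
ratingsMatrix <- function(ratings, role = "expert") {
  if (!is.null(role)) ratings <- ratings[ratings$role == role, , drop = FALSE]
  unit <- paste(ratings$video_id, ratings$hand, sep = ":")
  raters <- sort(unique(ratings$rater_id))
  units <- unique(unit)
  m <- matrix(NA_real_, length(units), length(raters),
              dimnames = list(units, raters))
  m[cbind(match(unit, units), match(ratings$rater_id, raters))] <-
    ratings$rating
  m
}

.icc_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ssr <- k * sum((rowMeans(m) - g)^2)
  ssc <- n * sum((colMeans(m) - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k, msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

#' Intraclass correlation coefficient
#'
#' Two-way random-effects ICC from the rating matrix, with the variant
#' selectable: absolute `"agreement"` (default) or `"consistency"`, for a
#' `"single"` rater (default) or the `"average"` of the k raters. Confidence
#' intervals use the standard F-distribution method (Satterthwaite
#' approximation for the agreement variants). Only complete cases (videos
#' rated by every rater) enter the computation.
#'
#' @param m videos x raters numeric matrix (see [ratingsMatrix()]).
#' @param type "agreement" or "consistency".
#' @param unit "single" or "average".
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci` (length 2), `type`, `unit`, `n`, `k`, and
#'   `degenerate` (TRUE when between-video variance is zero).
#' @export
icc <- function(m, type = c("agreement", "consistency"),
                unit = c("single", "average"), conf = 0.95) {
  type <- match.arg(type)
  unit <- match.arg(unit)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) < 2L || nrow(m) < 5L) {
    stop("need at least 2 raters and 5 complete videos", call. = FALSE)
  }
  ms <- .icc_ms(m)
  n <- ms$n; k <- ms$k
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  alpha <- 1 - conf
  degenerate <- msr <= 1e-12
  if (type == "consistency") {
    est <- if (unit == "single") (msr - mse) / (msr + (k - 1) * mse) else
      (msr - mse) / msr
    fobs <- if (mse == 0) Inf else msr / mse
    df2 <- (n - 1) * (k - 1)
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, n - 1)
    ci <- if (unit == "single") {
      c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else c(1 - 1 / fl, 1 - 1 / fu)
  } else {
    est1 <- (msr - mse) /
      (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (is.nan(est1)) est1 <- 0
    if (mse == 0 && !degenerate) {
      # perfect agreement: no residual variance, the interval collapses
      return(list(icc = 1, ci = c(1, 1), type = type, unit = unit,
                  n = n, k = k, degenerate = FALSE))
    }
    a <- k * est1 / (n * (1 - est1))
    b <- 1 + k * est1 * (n - 1) / (n * (1 - est1))
    v_num <- (a * msc + b * mse)^2
    v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    v <- if (v_den == 0) Inf else v_num / v_den
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    up <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo, up)
    est <- est1
    if (unit == "average") {
      sb <- function(r) k * r / (1 + (k - 1) * r)
      est <- sb(est1)
      ci <- sb(ci)
    }
  }
  if (mse == 0 && !degenerate) {
    est <- 1
    ci <- c(1, 1)
  }
  list(icc = est, ci = ci, type = type, unit = unit, n = n, k = k,
       degenerate = degenerate)
}

#' Krippendorff's alpha
#'
#' Chance-corrected inter-rater agreement from the coincidence matrix,
#' tolerant of missing ratings. The measurement level defaults to ordinal
#' (appropriate for the 0-4 severity scale); interval and nominal metrics
#' are available.
#'
#' @param m videos x raters numeric matrix, NA for unrated cells.
#' @param level "ordinal" (default), "interval" or "nominal".
#' @return scalar alpha (at most 1); 1 when agreement is perfect.
#' @export
krippendorffAlpha <- function(m, level = c("ordinal", "interval",
                                           "nominal")) {
  level <- match.arg(level)
  mu <- rowSums(!is.na(m))
  use <- mu >= 2L
  if (!any(use)) stop("no unit is rated by 2+ raters", call. = FALSE)
  vals <- sort(unique(stats::na.omit(as.vector(m[use, , drop = FALSE]))))
  nv <- length(vals)
  o <- matrix(0, nv, nv)
  for (u in which(use)) {
    r <- stats::na.omit(as.numeric(m[u, ]))
    idx <- match(r, vals)
    mu_u <- length(idx)
    for (a in seq_len(mu_u)) {
      for (b in seq_len(mu_u)) {
        if (a != b) {
          o[idx[a], idx[b]] <- o[idx[a], idx[b]] + 1 / (mu_u - 1)
        }
      }
    }
  }
  nc <- rowSums(o)
  ntot <- sum(nc)
  delta2 <- matrix(0, nv, nv)
  for (ci in seq_len(nv)) {
    for (ki in seq_len(nv)) {
      if (ci == ki) next
      delta2[ci, ki] <- switch(level,
        nominal = 1,
        interval = (vals[ci] - vals[ki])^2,
        ordinal = {
          lo <- min(ci, ki); hi <- max(ci, ki)
          (sum(nc[lo:hi]) - (nc[ci] + nc[ki]) / 2)^2
        })
    }
  }
  d_o <- sum(o * delta2)
  d_e <- sum(outer(nc, nc) * delta2) / (ntot - 1)
  if (d_e == 0) return(1)
  1 - d_o / d_e
}

#' Pairwise rater agreement and per-rater deviation profile
#'
#' For every rater pair: percentage of exact agreement, mean absolute
#' difference, and Pearson correlation, over co-rated videos (pairs with no
#' co-rated videos are NA). Against a supplied ground truth: per-rater MAE
#' and the percentage of ratings within one point of the label.
#'
#' @param m videos x raters numeric matrix.
#' @param ground_truth optional numeric vector of labels aligned with the
#'   rows of `m`.
#' @return list with symmetric matrices `exact_pct`, `mae`, `pcc`, and (when
#'   ground truth is given) data.frame `vs_truth` (rater, mae, within1_pct,
#'   pcc).
#' @export
pairwiseAgreement <- function(m, ground_truth = NULL) {
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 raters", call. = FALSE)
  exact <- mae <- pcc <- matrix(NA_real_, k, k,
                                dimnames = list(colnames(m), colnames(m)))
  diag(exact) <- 100; diag(mae) <- 0; diag(pcc) <- 1
  for (a in 1:(k - 1)) {
    for (b in (a + 1):k) {
      co <- !is.na(m[, a]) & !is.na(m[, b])
      if (!any(co)) next
      exact[a, b] <- exact[b, a] <- 100 * mean(m[co, a] == m[co, b])
      mae[a, b] <- mae[b, a] <- mean(abs(m[co, a] - m[co, b]))
      if (stats::sd(m[co, a]) > 0 && stats::sd(m[co, b]) > 0) {
        pcc[a, b] <- pcc[b, a] <- stats::cor(m[co, a], m[co, b])
      }
    }
  }
  out <- list(exact_pct = exact, mae = mae, pcc = pcc)
  if (!is.null(ground_truth)) {
    stopifnot(length(ground_truth) == nrow(m))
    out$vs_truth <- do.call(rbind, lapply(seq_len(k), function(j) {
      ok <- !is.na(m[, j])
      d <- m[ok, j] - ground_truth[ok]
      data.frame(rater = colnames(m)[j], mae = mean(abs(d)),
                 within1_pct = 100 * mean(abs(d) <= 1),
                 pcc = if (stats::sd(m[ok, j]) > 0)
                   stats::cor(m[ok, j], ground_truth[ok]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Rater agreement stratified by video quality
#'
#' Group-wise ICC (with confidence intervals) for high- and low-quality
#' videos, and a chi-square test of independence between finding a majority
#' agreement and video quality (2x2 table, 1 degree of freedom, no
#' continuity correction).
#'
#' @param m videos x raters expert rating matrix.
#' @param ground_truth data.frame from [groundTruthTable()] aligned with the
#'   rows of `m` (columns `provenance` and `quality`).
#' @param ... passed to [icc()].
#' @return list with `icc_by_quality`, `chisq` (htest), and the 2x2 `counts`.
#' @export
agreementVsQuality <- function(m, ground_truth, ...) {
  stopifnot(nrow(ground_truth) == nrow(m))
  out <- list(icc_by_quality = list())
  for (q in c("high", "low")) {
    sel <- ground_truth$quality == q
    out$icc_by_quality[[q]] <- tryCatch(
      icc(m[sel, , drop = FALSE], ...),
      error = function(e) {
        warning("ICC unavailable for ", q, "-quality group: ",
                conditionMessage(e))
        NULL
      })
  }
  counts <- table(majority = ground_truth$provenance == "majority",
                  quality = ground_truth$quality)
  if (all(dim(counts) == c(2L, 2L))) {
    out$chisq <- stats::chisq.test(counts, correct = FALSE)
  } else {
    warning("quality or provenance group empty; chi-square test skipped")
    out$chisq <- NULL
  }
  out$counts <- counts
  out
}

#' Write/read a ratings table as CSV
#' @param ratings ratings data.frame.
#' @param path file path.
#' @export
writeRatingsTable <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRatingsTable
#' @export
readRatingsTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_id", "hand", "rater_id", "role", "rating",
            "difficulty_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("ratings file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(df$rating %in% 0:4))
  if (length(bad)) {
    stop("invalid rating at row ", bad[1L], " (line ", bad[1L] + 1L, ")",
         call. = FALSE)
  }
  df$difficulty_flag <- as.logical(df$difficulty_flag)
  df
}

#' Load externally released feature/rating tables
#'
#' Maps the column layout of publicly released finger-tapping feature and
#' rating tables onto this package's schemas. The mapping is configurable
#' because released layouts evolve; defaults cover tables with one row per
#' hand-video, rater columns holding 0-4 integers, and boolean difficulty
#' flags.
#'
#' @param ratings_path CSV of per-video rater scores.
#' @param column_map named list mapping schema keys (`video_id`, `hand`,
#'   `rater_prefix`, `difficulty_prefix`) to column names in the file.
#' @return ratings data.frame in the package schema.
#' @export
readReleasedTables <- function(ratings_path,
                               column_map = list(video_id = "video_id",
                                                 hand = "hand",
                                                 rater_prefix = "rater",
                                                 difficulty_prefix =
                                                   "difficulty")) {
  raw <- utils::read.csv(ratings_path, stringsAsFactors = FALSE)
  rater_cols <- grep(paste0("^", column_map$rater_prefix), names(raw),
                     value = TRUE)
  if (!length(rater_cols)) {
    stop("no rater columns matched prefix '", column_map$rater_prefix, "'",
         call. = FALSE)
  }
  rows <- lapply(rater_cols, function(rc) {
    fl_col <- sub(column_map$rater_prefix, column_map$difficulty_prefix, rc)
    data.frame(video_id = raw[[column_map$video_id]],
               hand = raw[[column_map$hand]],
               rater_id = rc,
               role = if (grepl("non", rc)) "non-expert" else "expert",
               rating = raw[[rc]],
               difficulty_flag = if (fl_col %in% names(raw))
                 as.logical(raw[[fl_col]]) else FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$rating), , drop = FALSE]
}
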