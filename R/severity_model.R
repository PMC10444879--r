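.feature_cols <- function(table) {
  intersect(featureRegistry(), names(table))
}

#' Drop redundant features
#'
#' Greedy scan of feature pairs in registry column order: whenever two
#' features correlate with |r| above the threshold, the later column is
#' dropped so simple models can learn the remaining signal. Constant columns
#' have undefined correlation and are treated as uncorrelated but flagged.
#'
#' @param table feature data.frame (rows = hand-videos).
#' @param r_threshold absolute Pearson correlation threshold (default 0.85).
#' @return list with `table` (surviving columns), `dropped` data.frame
#'   (feature, dropped_for, r) and `constant` (flagged feature names).
#' @export
redundancyFilter <- function(table, r_threshold = 0.85) {
  feats <- .feature_cols(table)
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  x <- as.matrix(table[, feats, drop = FALSE])
  constant <- feats[apply(x, 2L, function(v) stats::sd(v) == 0)]
  cm <- suppressWarnings(stats::cor(x))
  kept <- character(0)
  dropped <- list()
  for (j in feats) {
    r_with_kept <- cm[kept, j]
    hit <- which(!is.na(r_with_kept) & abs(r_with_kept) > r_threshold)
    if (length(hit)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        feature = j, dropped_for = kept[hit[1L]],
        r = unname(r_with_kept[hit[1L]]), stringsAsFactors = FALSE)
    } else {
      kept <- c(kept, j)
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(feature = character(0), dropped_for = character(0),
               r = numeric(0))
  keep_cols <- c(setdiff(names(table), feats), kept)
  list(table = table[, keep_cols, drop = FALSE], dropped = dropped,
       constant = constant)
}

#' Per-feature correlation screen against severity
#'
#' Pearson correlation of each feature with the ground-truth severity label
#' and the two-sided correlation-test p-value, flagged at the significance
#' level. No multiplicity correction is applied. The screen is report-only:
#' all features remain candidates for the model regardless of significance,
#' since relevant associations may be non-linear.
#'
#' @param table feature data.frame containing a `label` column (0-4).
#' @param alpha significance level (default 0.01).
#' @return data.frame (feature, r, p, significant, note).
#' @export
significanceScreen <- function(table, alpha = 0.01) {
  stopifnot("label" %in% names(table))
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  y <- table$label
  if (stats::sd(y) == 0) stop("labels are constant", call. = FALSE)
  feats <- .feature_cols(table)
  rows <- lapply(feats, function(f) {
    v <- table[[f]]
    if (stats::sd(v) == 0) {
      return(data.frame(feature = f, r = NA_real_, p = NA_real_,
                        significant = FALSE, note = "constant feature",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(v, y)
    data.frame(feature = f, r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.xgb_params <- function(config, seed, nthread = 1L) {
  m <- config$model
  list(objective = "reg:squarederror", eta = m$eta,
       tree_method = "hist", grow_policy = "lossguide",
       max_depth = 0L, max_leaves = m$max_leaves,
       min_child_weight = m$min_child_weight, subsample = m$subsample,
       colsample_bytree = m$colsample, nthread = nthread, seed = seed)
}

.xgb_fit <- function(x, y, config, seed, nrounds) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  xgboost::xgb.train(params = .xgb_params(config, seed), data = dm,
                     nrounds = nrounds, verbose = 0)
}

#' Recursive feature elimination with a boosted-tree learner
#'
#' Repeatedly fits a gradient-boosted tree regressor, ranks features by gain
#' importance, and drops the weakest feature until `k` remain. Features that
#' never appear in a split have zero gain; ties drop the feature latest in
#' the current column order. Deterministic given the seed.
#'
#' @param table feature data.frame with a `label` column.
#' @param k number of features to keep (default 22).
#' @param config a [tapConfig()].
#' @param seed integer seed for the ranking fits.
#' @return character vector of `k` selected features, ordered by final-fit
#'   importance (most important first).
#' @export
selectFeatures <- function(table, k = 22L, config = tapConfig(), seed = 1L) {
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  feats <- .feature_cols(table)
  if (k > length(feats)) {
    stop("k exceeds the number of candidate features", call. = FALSE)
  }
  y <- table$label
  gain_of <- function(cols) {
    fit <- .xgb_fit(as.matrix(table[, cols, drop = FALSE]), y, config, seed,
                    config$rfe_nrounds)
    imp <- xgboost::xgb.importance(model = fit)
    g <- stats::setNames(rep(0, length(cols)), cols)
    g[imp$Feature] <- imp$Gain
    g
  }
  while (length(feats) > k) {
    g <- gain_of(feats)
    weakest <- max(which(g == min(g)))  # ties: drop latest column
    feats <- feats[-weakest]
  }
  g <- gain_of(feats)
  feats[order(-g)]
}

.fit_scaler <- function(x, method) {
  if (method == "standard") {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
  } else if (method == "minmax") {
    center <- apply(x, 2L, min)
    scale <- apply(x, 2L, max) - center
  } else stop("unknown scaling method: ", method, call. = FALSE)
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale, method = method)
}

.apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$center), 2L, scaler$scale, "/")
}

#' Train the severity regressor
#'
#' Fits the feature scaler on the training rows only, then a gradient-boosted
#' decision-tree ensemble with leaf-wise tree growth on the scaled selected
#' features. The returned model records its feature order, scaler, config and
#' seed; prediction uses exactly that stored order.
#'
#' @param table training feature data.frame with a `label` column.
#' @param features ordered character vector of feature columns to use
#'   (default: all registry columns present).
#' @param config a [tapConfig()].
#' @param seed integer seed.
#' @return object of class `tap_model`.
#' @export
trainSeverityModel <- function(table, features = NULL,
                               config = tapConfig(), seed = 1L) {
  if (is.null(features)) features <- .feature_cols(table)
  missing_f <- setdiff(features, names(table))
  if (length(missing_f)) {
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) < 10L) stop("need at least 10 training rows", call. = FALSE)
  x <- as.matrix(table[, features, drop = FALSE])
  if (!all(is.finite(x))) {
    bad <- features[apply(x, 2L, function(v) any(!is.finite(v)))]
    stop("non-finite values in feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  scaler <- .fit_scaler(x, config$scaling)
  booster <- .xgb_fit(.apply_scaler(x, scaler), table$label, config, seed,
                      config$model$nrounds)
  structure(list(booster = booster, features = features, scaler = scaler,
                 config = config, seed = seed,
                 registry_version = attr(featureRegistry(), "version")),
            class = "tap_model")
}

#' @export
print.tap_model <- function(x, ...) {
  cat(sprintf("tap_model: boosted-tree severity regressor, %d features, seed %d\n",
              length(x$features), x$seed))
  invisible(x)
}

#' Predict continuous severity
#'
#' Raw regressor output clipped to the \[0, 4\] MDS-UPDRS range.
#'
#' @param model a [trainSeverityModel()] fit.
#' @param newdata data.frame (or named vector) holding every model feature.
#' @return numeric predictions in \[0, 4\].
#' @export
predictSeverity <- function(model, newdata) {
  stopifnot(inherits(model, "tap_model"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  missing_f <- setdiff(model$features, names(newdata))
  if (length(missing_f)) {
    stop("missing feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  x <- .apply_scaler(as.matrix(newdata[, model$features, drop = FALSE]),
                     model$scaler)
  raw <- predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1L))
  pmin(4, pmax(0, raw))
}

#' Convert continuous severity to the 0-4 class
#'
#' Nearest integer; exact half-points round half-up.
#' @param pred numeric predictions in \[0, 4\].
#' @return integer classes in 0..4.
#' @export
toSeverityClass <- function(pred) {
  as.integer(pmin(4L, pmax(0L, floor(pred + 0.5))))
}

#' Regression metrics for severity predictions
#'
#' MAE, MSE, classification accuracy (percent, after class conversion),
#' Kendall's tau, MAPE (percent, over rows with nonzero truth; the exclusion
#' count is reported), Pearson and Spearman correlations. Correlation metrics
#' are `NA` when the truth is constant.
#'
#' @param preds continuous predictions.
#' @param truth integer labels 0-4.
#' @return named list of the seven metrics plus `mape_excluded`.
#' @export
computeMetrics <- function(preds, truth) {
  stopifnot(length(preds) == length(truth), length(preds) >= 2L)
  err <- preds - truth
  cls <- toSeverityClass(preds)
  nz <- truth > 0
  const <- stats::sd(truth) == 0 || stats::sd(preds) == 0
  corr <- function(method) {
    if (const) NA_real_ else stats::cor(preds, truth, method = method)
  }
  list(mae = mean(abs(err)),
       mse = mean(err^2),
       accuracy = 100 * mean(cls == truth),
       kendall_tau = corr("kendall"),
       mape = if (any(nz)) 100 * mean(abs(err[nz]) / truth[nz]) else NA_real_,
       pcc = corr("pearson"),
       spearman_rho = corr("spearman"),
       mape_excluded = sum(!nz))
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per participant; all of a participant's rows (both hands) are
#' held out together so the model is always evaluated on unseen people. By
#' default the redundancy filter, recursive feature elimination and scaler
#' are re-fitted inside each training fold (leakage-safe). With
#' `config$paper_mode = TRUE` the filter and selection are computed once on
#' the whole table before cross-validation and only scaling/training are
#' per-fold.
#'
#' @param table feature data.frame with `participant_id`, `video_id`,
#'   `hand`, `label`, and the registry feature columns.
#' @param config a [tapConfig()].
#' @param seed integer root seed for every stochastic component.
#' @return object of class `tap_cv` with `predictions` (one row per input
#'   row: truth, continuous prediction, class), `metrics`, `selected` (per
#'   fold), and the config.
#' @export
lopoCV <- function(table, config = tapConfig(), seed = 1L) {
  stopifnot(all(c("participant_id", "label") %in% names(table)))
  participants <- unique(table$participant_id)
  if (length(participants) < 3L) {
    stop("need at least 3 participants", call. = FALSE)
  }
  global_features <- NULL
  if (isTRUE(config$paper_mode)) {
    filt <- redundancyFilter(table, config$r_threshold)
    k <- min(config$k_features, length(.feature_cols(filt$table)))
    global_features <- selectFeatures(filt$table, k, config, seed)
  }
  preds <- rep(NA_real_, nrow(table))
  selected <- list()
  for (p in participants) {
    test_idx <- which(table$participant_id == p)
    if (!length(test_idx)) {
      warning("participant ", p, " has no rows; skipped")
      next
    }
    train <- table[-test_idx, , drop = FALSE]
    feats <- global_features
    if (is.null(feats)) {
      filt <- redundancyFilter(train, config$r_threshold)
      k <- min(config$k_features, length(.feature_cols(filt$table)))
      feats <- selectFeatures(filt$table, k, config, seed)
    }
    model <- trainSeverityModel(train, feats, config, seed)
    preds[test_idx] <- predictSeverity(model, table[test_idx, , drop = FALSE])
    selected[[as.character(p)]] <- feats
  }
  predictions <- data.frame(
    participant_id = table$participant_id,
    video_id = if ("video_id" %in% names(table)) table$video_id else NA,
    hand = if ("hand" %in% names(table)) table$hand else NA,
    truth = table$label, pred = preds, pred_class = toSeverityClass(preds),
    stringsAsFactors = FALSE)
  structure(list(predictions = predictions,
                 metrics = computeMetrics(preds, table$label),
                 selected = selected, config = config, seed = seed),
            class = "tap_cv")
}

#' @export
print.tap_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "tap_cv: %d rows, %d folds\n  MAE %.4f  MSE %.4f  accuracy %.2f%%  tau %.4f  MAPE %.2f%%  PCC %.4f  rho %.4f\n",
    nrow(x$predictions), length(x$selected), m$mae, m$mse, m$accuracy,
    m$kendall_tau, m$mape, m$pcc, m$spearman_rho))
  invisible(x)
}

#' Additive feature attributions
#'
#' TreeSHAP attributions for a boosted-tree severity model: per row, the
#' per-feature contributions plus the baseline sum exactly to the raw
#' (unclipped) prediction. Global importance is the mean absolute
#' attribution per feature.
#'
#' @param model a [trainSeverityModel()] fit.
#' @param rows data.frame of rows to explain.
#' @return list with `attributions` (rows x features matrix), `baseline`
#'   (expected model output), and `importance` (named, sorted decreasing).
#' @export
explainModel <- function(model, rows) {
  stopifnot(inherits(model, "tap_model"))
  x <- .apply_scaler(as.matrix(rows[, model$features, drop = FALSE]),
                     model$scaler)
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1L),
                     predcontrib = TRUE)
  bias_col <- ncol(contrib)
  attributions <- contrib[, -bias_col, drop = FALSE]
  colnames(attributions) <- model$features
  imp <- sort(colMeans(abs(attributions)), decreasing = TRUE)
  list(attributions = attributions, baseline = contrib[1L, bias_col],
       importance = imp)
}

#' Group-wise error analysis
#'
#' Mean, standard deviation and count of absolute out-of-fold errors per
#' level of a metadata column, plus a two-sided two-sample t-test between two
#' named groups. Groups with fewer than 2 rows are excluded with a warning.
#'
#' @param cv a [lopoCV()] result.
#' @param grouping vector (one value per prediction row) defining the groups.
#' @param compare optional length-2 character vector naming the two groups to
#'   test (default: the two largest).
#' @return list with `groups` data.frame and `test` (htest or NULL).
#' @export
metricsByGroup <- function(cv, grouping, compare = NULL) {
  stopifnot(inherits(cv, "tap_cv"),
            length(grouping) == nrow(cv$predictions))
  abs_err <- abs(cv$predictions$pred - cv$predictions$truth)
  tab <- table(grouping)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("group(s) with < 2 rows excluded: ",
            paste(small, collapse = ", "))
  }
  keep <- !(grouping %in% small)
  groups <- do.call(rbind, lapply(
    sort(unique(grouping[keep])), function(g) {
      e <- abs_err[keep & grouping == g]
      data.frame(group = g, mae = mean(e), std = stats::sd(e),
                 n = length(e), stringsAsFactors = FALSE)
    }))
  test <- NULL
  if (is.null(compare)) {
    big <- groups$group[order(-groups$n)]
    if (length(big) >= 2L) compare <- big[1:2]
  }
  if (!is.null(compare) && all(compare %in% groups$group)) {
    test <- stats::t.test(abs_err[keep & grouping == compare[1]],
                          abs_err[keep & grouping == compare[2]])
  } else if (!is.null(compare)) {
    warning("comparison group(s) absent; reporting groups only")
  }
  list(groups = groups, test = test)
}
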