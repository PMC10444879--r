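# small feature-shaped table with controllable columns
fake_table <- function(n, cols, label = NULL) {
  stopifnot(all(names(cols) %in% featureRegistry()))
  df <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                   video_id = sprintf("V%03d", seq_len(n)),
                   hand = "right", stringsAsFactors = FALSE)
  for (nm in names(cols)) df[[nm]] <- cols[[nm]]
  if (!is.null(label)) df$label <- label
  df
}

test_that("the redundancy filter drops later members of correlated pairs", {
  set.seed(3)
  n <- 500
  a <- rnorm(n)
  tab <- fake_table(n, list(speed_median = a, speed_iqr = a,
                            period_median = rnorm(n),
                            amplitude_median = rnorm(n)))
  out <- redundancyFilter(tab)
  expect_equal(out$dropped$feature, "speed_iqr")
  expect_equal(out$dropped$dropped_for, "speed_median")
  expect_equal(out$dropped$r, 1)
  expect_false("speed_iqr" %in% names(out$table))
  # independent noise columns survive
  tab2 <- fake_table(n, list(speed_median = rnorm(n), speed_iqr = rnorm(n),
                             period_median = rnorm(n)))
  expect_equal(nrow(redundancyFilter(tab2)$dropped), 0)
  # three mutual duplicates: first kept, two dropped
  tab3 <- fake_table(n, list(speed_median = a, speed_iqr = a,
                             speed_mean = a))
  out3 <- redundancyFilter(tab3)
  expect_setequal(out3$dropped$feature, c("speed_iqr", "speed_mean"))
  expect_true("speed_median" %in% names(out3$table))
  # constant columns are flagged, not dropped
  tab4 <- fake_table(n, list(speed_median = rnorm(n), speed_iqr = rep(1, n)))
  out4 <- redundancyFilter(tab4)
  expect_equal(out4$constant, "speed_iqr")
  expect_true("speed_iqr" %in% names(out4$table))
})

test_that("the significance screen reports r and p without dropping anything", {
  set.seed(4)
  n <- 489
  y <- sample(0:4, n, replace = TRUE)
  tab <- fake_table(n, list(speed_median = as.numeric(y),
                            period_median = y + rnorm(n, 0, 0.5),
                            amplitude_median = rnorm(n),
                            speed_iqr = rep(2, n)),
                    label = y)
  rep_tab <- significanceScreen(tab, alpha = 0.01)
  expect_equal(rep_tab$r[rep_tab$feature == "speed_median"], 1)
  expect_true(rep_tab$significant[rep_tab$feature == "speed_median"])
  expect_true(rep_tab$significant[rep_tab$feature == "period_median"])
  expect_false(rep_tab$significant[rep_tab$feature == "speed_iqr"])
  expect_match(rep_tab$note[rep_tab$feature == "speed_iqr"], "constant")
  # r/p match an independent cor.test on the raw columns
  ct <- cor.test(tab$period_median, y)
  expect_equal(rep_tab$p[rep_tab$feature == "period_median"], ct$p.value)
  # label-independent noise is rarely significant at alpha = 0.01
  set.seed(5)
  hits <- vapply(1:40, function(i) {
    t2 <- fake_table(n, list(speed_median = rnorm(n)), label = y)
    significanceScreen(t2, 0.01)$significant[1]
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("recursive feature elimination recovers planted signal and is deterministic", {
  set.seed(6)
  n <- 300
  reg <- featureRegistry()
  informative <- c("speed_median", "amplitude_median", "period_iqr",
                   "aperiodicity", "n_freezing")
  noise_cols <- setdiff(reg[1:40], informative)[1:35]
  y <- sample(0:4, n, replace = TRUE)
  cols <- c(
    setNames(lapply(seq_along(informative), function(i) {
      y * c(-1, 1)[i %% 2 + 1] + rnorm(n, 0, 0.3)
    }), informative),
    setNames(lapply(noise_cols, function(cn) rnorm(n)), noise_cols))
  tab <- fake_table(n, cols, label = y)
  sel <- selectFeatures(tab, k = 5, seed = 11)
  expect_length(sel, 5)
  expect_gte(length(intersect(sel, informative)), 4)
  expect_identical(sel, selectFeatures(tab, k = 5, seed = 11))
  # k = all columns is the identity subset
  all_sel <- selectFeatures(tab, k = 40, seed = 11)
  expect_setequal(all_sel, c(informative, noise_cols))
  expect_error(selectFeatures(tab, k = 0), "positive")
})

test_that("training, prediction, clipping and class conversion contracts hold", {
  set.seed(7)
  n <- 200
  x <- runif(n, 0, 4)
  tab <- fake_table(n, list(speed_median = x,
                            period_median = rnorm(n)),
                    label = round(x))
  m1 <- trainSeverityModel(tab, config = tapConfig(), seed = 2)
  m2 <- trainSeverityModel(tab, config = tapConfig(), seed = 2)
  probe <- tab[1:20, ]
  expect_identical(predictSeverity(m1, probe), predictSeverity(m2, probe))
  # noiseless single-feature rule is learned to small training error
  expect_lt(mean(abs(predictSeverity(m1, tab) - tab$label)), 0.1)
  # constant labels are reproduced
  tabc <- tab; tabc$label <- 2
  mc <- trainSeverityModel(tabc, config = tapConfig(), seed = 2)
  expect_equal(predictSeverity(mc, probe), rep(2, 20), tolerance = 1e-6)
  # predictions are clipped into [0, 4]
  expect_true(all(predictSeverity(m1, tab) >= 0 &
                    predictSeverity(m1, tab) <= 4))
  expect_error(predictSeverity(m1, probe[, setdiff(names(probe),
                                                   "speed_median")]),
               "speed_median")
  expect_error(trainSeverityModel(transform(tab, speed_median = Inf),
                                  config = tapConfig(), seed = 1),
               "speed_median")
  expect_equal(toSeverityClass(c(1.6, 2.5, 0.0, 3.49)), c(2L, 3L, 0L, 3L))
})

test_that("metrics match independent textbook-formula recomputation", {
  t1 <- c(0, 1, 2, 3, 4, 2)
  m_perfect <- computeMetrics(t1, t1)
  expect_equal(m_perfect$mae, 0)
  expect_equal(m_perfect$accuracy, 100)
  expect_equal(m_perfect$pcc, 1)
  expect_equal(m_perfect$kendall_tau, 1)
  expect_equal(m_perfect$spearman_rho, 1)
  m_off <- computeMetrics(t1 + 1, t1)
  expect_equal(m_off$mae, 1)
  expect_equal(m_off$mse, 1)
  set.seed(9)
  preds <- runif(60, 0, 4)
  truth <- sample(0:4, 60, replace = TRUE)
  m <- computeMetrics(preds, truth)
  expect_equal(m$mae, mean(abs(preds - truth)))
  expect_equal(m$mse, mean((preds - truth)^2))
  expect_equal(m$accuracy,
               100 * mean(pmin(4, pmax(0, floor(preds + 0.5))) == truth))
  nz <- truth > 0
  expect_equal(m$mape, 100 * mean(abs(preds - truth)[nz] / truth[nz]))
  expect_equal(m$mape_excluded, sum(truth == 0))
  expect_equal(m$pcc, cov(preds, truth) / (sd(preds) * sd(truth)))
  expect_equal(m$spearman_rho, cor(rank(preds), rank(truth)))
  expect_equal(m$kendall_tau, oracle_kendall(preds, truth))
  expect_gte(sqrt(m$mse), m$mae)  # Jensen
  # constant truth marks correlations undefined but keeps errors
  m_const <- computeMetrics(preds, rep(2L, 60))
  expect_true(is.na(m_const$pcc))
  expect_false(is.na(m_const$mae))
})

test_that("leave-one-patient-out folds hold out whole participants", {
  set.seed(10)
  n_part <- 8
  tab <- do.call(rbind, lapply(seq_len(n_part), function(i) {
    y <- sample(0:4, 1)
    fake_table(2, list(speed_median = y + rnorm(2, 0, 0.2),
                       period_median = rnorm(2),
                       amplitude_median = -y + rnorm(2, 0, 0.2)),
               label = rep(y, 2))
  }))
  tab$participant_id <- rep(sprintf("P%02d", seq_len(n_part)), each = 2)
  cfg <- tapConfig(k_features = 2,
                   model = list(nrounds = 40L))
  cv <- lopoCV(tab, cfg, seed = 3)
  expect_equal(length(cv$selected), n_part)
  expect_false(anyNA(cv$predictions$pred))    # each row predicted once
  expect_true(all(cv$predictions$pred >= 0 & cv$predictions$pred <= 4))
  expect_true(all(cv$predictions$pred_class %in% 0:4))
  expect_identical(cv$predictions$participant_id, tab$participant_id)
  expect_lte(cv$metrics$mae, sqrt(cv$metrics$mse))
  # paper-mode screening selects once, in-fold selection varies per fold
  cvp <- lopoCV(tab, tapConfig(k_features = 2, paper_mode = TRUE,
                               model = list(nrounds = 40L)), seed = 3)
  expect_length(unique(cvp$selected), 1)
  expect_error(lopoCV(tab[tab$participant_id %in% c("P01", "P02"), ],
                      cfg, seed = 1), "3 participants")
})

test_that("scaling statistics come from training rows only", {
  # plant an outlier in one participant: if the scaler saw the held-out
  # fold, the training-fold scaling parameters would shift
  set.seed(11)
  tab <- fake_table(12, list(speed_median = rnorm(12),
                             period_median = rnorm(12)),
                    label = rep(0:3, 3))
  tab$participant_id <- rep(sprintf("P%02d", 1:6), each = 2)
  train_rows <- tab[tab$participant_id != "P01", ]
  m <- trainSeverityModel(train_rows, config = tapConfig(), seed = 1)
  expect_equal(unname(m$scaler$center["speed_median"]),
               mean(train_rows$speed_median))
  expect_equal(unname(m$scaler$scale["speed_median"]),
               sd(train_rows$speed_median))
})

test_that("attributions are additive, stable, and spotlight the planted feature", {
  set.seed(12)
  n <- 250
  y <- sample(0:4, n, replace = TRUE)
  cols <- list(speed_median = y + rnorm(n, 0, 0.2))
  for (cn in c("period_median", "amplitude_median", "speed_iqr",
               "period_iqr", "aperiodicity")) cols[[cn]] <- rnorm(n)
  tab <- fake_table(n, cols, label = y)
  m <- trainSeverityModel(tab, config = tapConfig(), seed = 4)
  ex <- explainModel(m, tab[1:30, ])
  raw <- predict(m$booster,
                 xgboost::xgb.DMatrix(
                   tapscore:::.apply_scaler(
                     as.matrix(tab[1:30, m$features]), m$scaler),
                   nthread = 1L))
  expect_equal(rowSums(ex$attributions) + ex$baseline, raw,
               tolerance = 1e-6)
  expect_equal(names(ex$importance)[1], "speed_median")
  m2 <- trainSeverityModel(tab, config = tapConfig(), seed = 4)
  ex2 <- explainModel(m2, tab[1:30, ])
  expect_identical(ex$attributions, ex2$attributions)
})

test_that("group-wise error analysis reports counts and a null p-value", {
  set.seed(13)
  n <- 400
  tab <- fake_table(n, list(speed_median = rnorm(n)),
                    label = sample(0:4, n, replace = TRUE))
  cv <- structure(list(predictions = data.frame(
    participant_id = tab$participant_id, video_id = tab$video_id,
    hand = "right", truth = tab$label,
    pred = pmin(4, pmax(0, tab$label + rnorm(n, 0, 0.4))),
    pred_class = tab$label)), class = "tap_cv")
  grp <- rep(c("a", "b"), each = n / 2)   # identical error distributions
  out <- metricsByGroup(cv, grp)
  expect_equal(out$groups$n, c(n / 2, n / 2))
  expect_gt(out$test$p.value, 0.05)
  # degenerate group excluded with warning
  grp2 <- c(rep("a", n - 1), "solo")
  expect_warning(out2 <- metricsByGroup(cv, grp2), "excluded")
  expect_equal(out2$groups$group, "a")
})
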