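#' Pipeline configuration
#'
#' Builds the full run configuration with documented defaults. Every tunable
#' threshold of the pipeline lives here; unknown keys are rejected so that a
#' typo in a threshold name fails loudly instead of silently running with a
#' default.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{handedness_threshold (0.9)}{minimum handedness classification score
#'     for a detection to count as the target hand.}
#'   \item{presence_threshold (0.90)}{minimum hand presence score for a frame
#'     to contribute an angle; below it the frame is treated as missing.}
#'   \item{interp_window (5)}{frames inspected on each side of a missing value
#'     when deciding whether to interpolate it.}
#'   \item{interp_degree (3)}{degree of the polynomial fitted to the visible
#'     signal for interpolation.}
#'   \item{min_peak_gap_s (0.1)}{minimum time between consecutive tap peaks,
#'     in seconds; 10 taps/s exceeds any plausible human tapping rate.}
#'   \item{amplitude_floor_quantile (0.25)}{peaks must exceed this quantile of
#'     the analyzed signal.}
#'   \item{trough_iqr_fraction (0.2)}{a peak must be followed by a sample at
#'     least this fraction of the signal IQR below it before the next peak.}
#'   \item{speed_threshold (50)}{degrees/second below which movement counts as
#'     a hesitation.}
#'   \item{interruption_min_s (0.010)}{minimum sub-threshold run duration for
#'     an interruption, seconds.}
#'   \item{freeze_min_s (0.020)}{run duration strictly above this counts as a
#'     freezing event, seconds.}
#'   \item{entropy_bins (10)}{histogram bins for the distribution-entropy
#'     aggregate.}
#'   \item{end_taps_k (1)}{number of taps averaged for the "beginning" and
#'     "end" amplitudes of the decrement features.}
#'   \item{r2_threshold (0.9)}{fit-quality bar for the period fitting
#'     complexity feature.}
#'   \item{max_fit_degree (10)}{largest polynomial degree tried for the period
#'     fitting complexity feature.}
#'   \item{r_threshold (0.85)}{absolute pairwise correlation above which one
#'     of a feature pair is dropped as redundant.}
#'   \item{alpha_level (0.01)}{significance level of the per-feature
#'     correlation screen.}
#'   \item{k_features (22)}{number of features kept by recursive feature
#'     elimination.}
#'   \item{scaling ("standard")}{"standard" (zero mean, unit variance) or
#'     "minmax", always fitted on training rows only.}
#'   \item{paper_mode (FALSE)}{if TRUE, the redundancy filter and feature
#'     selection are computed once on the whole table before cross-validation
#'     (the published-report reading); the default re-runs them inside each
#'     training fold, which is the leakage-safe reading.}
#'   \item{smote (FALSE)}{minority oversampling stub; kept as a documented
#'     config key but not implemented because it degraded performance in the
#'     underlying study. Only FALSE is accepted.}
#'   \item{icc_model, icc_type, icc_unit}{ICC variant: "twoway" random-effects
#'     model, "agreement" or "consistency", "single" or "average" rater.}
#'   \item{krippendorff_level ("ordinal")}{measurement level for alpha;
#'     "interval" is the alternative for the 0-4 scale.}
#'   \item{model}{regressor hyper-parameters: nrounds, eta, max_leaves,
#'     min_child_weight, subsample, colsample; leaf-wise tree growth.}
#'   \item{rfe_nrounds (60)}{boosting rounds used for the ranking fits inside
#'     recursive feature elimination.}
#' }
#'
#' @return a named list of class `tap_config`.
#' @export
#' @examples
#' cfg <- tapConfig(k_features = 10)
#' cfg$k_features
tapConfig <- function(...) {
  defaults <- list(
    handedness_threshold = 0.9,
    presence_threshold = 0.90,
    interp_window = 5L,
    interp_degree = 3L,
    min_peak_gap_s = 0.1,
    amplitude_floor_quantile = 0.25,
    trough_iqr_fraction = 0.2,
    speed_threshold = 50,
    interruption_min_s = 0.010,
    freeze_min_s = 0.020,
    entropy_bins = 10L,
    end_taps_k = 1L,
    r2_threshold = 0.9,
    max_fit_degree = 10L,
    r_threshold = 0.85,
    alpha_level = 0.01,
    k_features = 22L,
    scaling = "standard",
    paper_mode = FALSE,
    smote = FALSE,
    icc_model = "twoway",
    icc_type = "agreement",
    icc_unit = "single",
    krippendorff_level = "ordinal",
    model = list(
      nrounds = 150L, eta = 0.1, max_leaves = 31L,
      min_child_weight = 1, subsample = 1, colsample = 1
    ),
    rfe_nrounds = 60L
  )
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over))))) {
    stop("all configuration overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(over$model)) {
    bad <- setdiff(names(over$model), names(defaults$model))
    if (length(bad)) {
      stop("unknown model hyper-parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    defaults$model[names(over$model)] <- over$model
    over$model <- NULL
  }
  defaults[names(over)] <- over
  if (!identical(defaults$smote, FALSE)) {
    stop("minority oversampling (smote) is not implemented; set smote = FALSE",
         call. = FALSE)
  }
  stopifnot(
    defaults$handedness_threshold > 0, defaults$presence_threshold > 0,
    defaults$min_peak_gap_s > 0, defaults$speed_threshold > 0,
    defaults$interruption_min_s > 0, defaults$freeze_min_s > 0,
    defaults$r_threshold > 0, defaults$alpha_level > 0,
    defaults$k_features > 0
  )
  structure(defaults, class = "tap_config")
}

#' @export
print.tap_config <- function(x, ...) {
  cat("tapscore pipeline configuration\n")
  flat <- x[setdiff(names(x), "model")]
  for (nm in names(flat)) cat(sprintf("  %-26s %s\n", nm, format(flat[[nm]])))
  cat("  model:",
      paste(names(x$model), unlist(x$model), sep = "=", collapse = " "), "\n")
  invisible(x)
}
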