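#' Feature inventory registry
#'
#' The fixed, versioned inventory of the 65 kinematic features extracted per
#' hand-video: 47 tapping-group features (seven statistical aggregates of the
#' five base tap metrics, plus twelve rhythm/hesitation features) and 18
#' wrist-group features (six aggregates of the three wrist-motion metrics).
#' Column order here defines the canonical feature-table order and the scan
#' order of the redundancy filter.
#'
#' @return character vector of 65 feature names, with attributes `version`,
#'   `tapping` and `wrist` giving the group memberships.
#' @export
#' @examples
#' length(featureRegistry())          # 65
#' length(attr(featureRegistry(), "tapping"))  # 47
featureRegistry <- function() {
  aggregates <- c("median", "iqr", "mean", "min", "max", "std", "entropy")
  tap_metrics <- c("speed", "acceleration", "period", "frequency", "amplitude")
  base <- as.vector(t(outer(tap_metrics, aggregates, paste, sep = "_")))
  rhythm <- c(
    "aperiodicity",
    "n_interruptions",
    "n_freezing",
    "longest_freezing_s",
    "period_linearity_r2",
    "period_linearity_slope",
    "period_fit_complexity",
    "amplitude_end_minus_mean",
    "amplitude_end_minus_begin",
    "amplitude_slope",
    "period_var_norm",
    "n_taps"
  )
  wrist_aggr <- setdiff(aggregates, "mean")
  wrist <- as.vector(t(outer(c("wrist_dx", "wrist_dy", "wrist_d"),
                             wrist_aggr, paste, sep = "_")))
  reg <- c(base, rhythm, wrist)
  structure(reg,
            version = "1",
            tapping = c(base, rhythm),
            wrist = wrist)
}

# landmark indices used throughout (pose-estimator convention)
LM_WRIST <- 0L
LM_THUMB_CMC <- 1L
LM_THUMB_TIP <- 4L
LM_INDEX_TIP <- 8L
REQUIRED_LANDMARKS <- c(LM_WRIST, LM_THUMB_CMC, LM_THUMB_TIP, LM_INDEX_TIP)
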