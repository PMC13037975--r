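#' Composite risk score from four outcome probabilities
#'
#' Combines the predicted probabilities of the four proxy outcomes
#' (abnormal primary assessment, lights-and-sirens transport, prehospital
#' intervention, 72 h admission or 30 day mortality) into a single score as
#' their weighted mean, weights normalized to sum to 1. The default 4:2:1:1
#' weighting emphasises the abnormal-assessment outcome. Only the rank
#' ordering of scores matters downstream, so any positive rescaling of the
#' weights yields the same prioritizations.
#'
#' @param preds A data frame or matrix with columns/elements
#'   `p_abnormal`, `p_lights_sirens`, `p_intervention`,
#'   `p_admission_mortality` (each in `[0, 1]`), or a numeric vector of
#'   length 4 for a single patient.
#' @param weights Positive weights of length 4.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
#' @examples
#' composite_score(c(0.2, 0.4, 0.6, 0.8))  # 0.375
composite_score <- function(preds, weights = c(4, 2, 1, 1)) {
  if (length(weights) != 4L || any(weights <= 0)) {
    stop("weights must be 4 positive numbers")
  }
  w <- weights / sum(weights)
  if (is.vector(preds) && is.numeric(preds)) {
    preds <- matrix(preds, ncol = 4, byrow = TRUE)
  } else {
    cols <- c("p_abnormal", "p_lights_sirens", "p_intervention",
              "p_admission_mortality")
    miss <- setdiff(cols, colnames(preds))
    if (length(miss)) stop("missing prediction column(s): ",
                           paste(miss, collapse = ", "))
    preds <- as.matrix(preds[, cols])
  }
  if (any(preds < 0 | preds > 1, na.rm = TRUE)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  as.numeric(preds %*% w)
}

#' Synthetic risk predictions from latent acuity
#'
#' Stands in for a trained risk model: the model's view of each patient is
#' latent acuity plus a patient-level error with SD `config$model_noise_sd`
#' (shared across the four outcomes, so it perturbs the patient's rank) plus
#' a small independent per-outcome wobble. Each predicted probability is a
#' logistic transform of that noisy acuity using the same intercepts and
#' slopes that generate the true proxy outcomes. The noise SD controls how
#' often the composite score ranks the truly sickest patient first; the
#' default is calibrated so the model alone identifies the highest-NEWS
#' member of a pair about 70% of the time.
#'
#' When `months_since_update` is supplied and `config$model_drift_per_month`
#' is nonzero, the effective noise SD grows by that relative amount per
#' month since the last model retraining, emulating covariate drift.
#'
#' @param patients Patient table (needs `latent_acuity`).
#' @param config An [trial_config()] object.
#' @param months_since_update Optional per-patient months since the last
#'   model update (drift clock).
#' @return Data frame with `patient_id`, the four predicted probabilities
#'   and `composite` (the composite risk score).
#' @export
synthetic_predictions <- function(patients, config, months_since_update = NULL) {
  validate_config(config)
  seeds <- stage_seeds(config$seed)
  with_seed(seeds[["predictions"]], {
    n <- nrow(patients)
    sd_eff <- config$model_noise_sd
    if (!is.null(months_since_update)) {
      sd_eff <- sd_eff * (1 + config$model_drift_per_month * months_since_update)
    }
    seen <- patients$latent_acuity + stats::rnorm(n, 0, sd_eff)
    # small per-outcome wobble decorrelates the four probabilities; it
    # scales with the noise SD so the noiseless limit ranks exactly by acuity
    wobble <- function() stats::rnorm(n, 0, 0.05 * sd_eff)
    preds <- data.frame(
      patient_id = patients$patient_id,
      p_abnormal = stats::plogis(-1.1 + 0.8 * (seen + wobble())),
      p_lights_sirens = stats::plogis(-2.4 + 0.9 * (seen + wobble())),
      p_intervention = stats::plogis(-1.5 + 0.7 * (seen + wobble())),
      p_admission_mortality = stats::plogis(-0.6 + 0.8 * (seen + wobble())),
      stringsAsFactors = FALSE)
    preds$composite <- composite_score(preds, config$composite_weights)
    preds
  })
}

#' Calibrate the confidence cutoff from top-two score gaps
#'
#' The confidence statistic of a comparison is the gap between the top and
#' runner-up composite scores within the RCS. The cutoff is the median gap
#' of a calibration set: comparisons with gap >= cutoff are classified
#' high-confidence, so the calibration set itself splits 50/50 to within
#' one element.
#'
#' @param gaps Numeric vector of top-two gaps (length >= 2).
#' @return The cutoff (median gap), with class `"confidence_cutoff"`.
#' @export
#' @examples
#' calibrate_confidence_cutoff(c(0.1, 0.2, 0.3, 0.4))  # 0.25
calibrate_confidence_cutoff <- function(gaps) {
  if (length(gaps) < 2L) stop("need at least 2 calibration gaps")
  if (anyNA(gaps)) stop("gaps must not contain NA")
  cutoff <- stats::median(gaps)
  structure(cutoff, class = "confidence_cutoff")
}

#' Classify comparison confidence from a top-two gap
#'
#' @param gaps Numeric vector of gaps.
#' @param cutoff Cutoff from [calibrate_confidence_cutoff()] (or a number).
#' @return Character vector, `"high"` where `gap >= cutoff`, else `"low"`.
#' @export
classify_confidence <- function(gaps, cutoff) {
  ifelse(gaps >= as.numeric(cutoff), "high", "low")
}

# top-two gap of a score vector (0 when fewer than 2 distinct members)
top_two_gap <- function(scores) {
  s <- sort(scores, decreasing = TRUE)
  if (length(s) < 2L) return(NA_real_)
  s[1] - s[2]
}
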