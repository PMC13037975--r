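#' Configuration for the synthetic dispatch-trial generator
#'
#' Builds a validated configuration object controlling every stage of the
#' simulated trial: cohort structure, the latent-acuity model behind vital
#' signs and risk predictions, dispatcher behaviour, protocol deviations,
#' and missingness.
#'
#' Defaults are calibrated to the operating point of a low-priority
#' dispatch cohort: RCS sizes averaging about 2.2 members, median patient
#' age 77 years, 45% female, a population mean NEWS of about 3, nurse
#' pair-accuracy (probability that the control-arm choice has the highest
#' NEWS, ties correct) of about 0.63, model pair-accuracy of about 0.70,
#' observed intervention-arm agreement with the model of about 0.81,
#' ambulance-stage missingness of 11--14% per component and post-supplement
#' missingness of 3.7--4.8%.
#'
#' @param n_rcs Number of distinct (base) resource constrained situations to
#'   generate. Repeat randomizations add further events on top of these.
#' @param rcs_size_dist Named probability vector over RCS sizes (names are
#'   the sizes, all >= 2); must sum to 1.
#' @param acuity_sd Standard deviation of the latent acuity scale.
#' @param nurse_noise_sd SD of the noise added to latent acuity to form the
#'   dispatch nurse's perception of each patient.
#' @param model_noise_sd SD of the patient-level noise in the risk model's
#'   view of acuity; controls model discrimination.
#' @param compliance_prob Probability that an intervention-arm dispatcher
#'   defers to the model's top-ranked patient; otherwise the nurse choice is
#'   used. Note the observed agreement with the model exceeds this because
#'   nurses sometimes independently agree (see [calibrate_compliance()]).
#' @param optout_prob_per_patient Per-patient probability of retroactively
#'   declining participation; any RCS containing such a patient is excluded.
#' @param repeat_prob_control,repeat_prob_intervention Probability that a
#'   dispatcher, after seeing the arm, re-randomizes the comparison with one
#'   additional patient (modelling attempts to re-roll the allocation; higher
#'   in the control arm).
#' @param miss_rate_ambulance Named per-component probability of the
#'   component being missing in ambulance documentation.
#' @param miss_rate_final Named per-component probability of the component
#'   remaining missing after supplementation with hospital data; must not
#'   exceed the ambulance rate.
#' @param miss_acuity_slope MAR tilt: logit-scale decrease in missingness per
#'   unit latent acuity (sicker patients better documented). 0 gives MCAR.
#' @param news_baseline Target expected NEWS at latent acuity 0 (approximate;
#'   shifts all band cutpoints).
#' @param composite_weights Weights of the four predicted proxy outcomes in
#'   the composite risk score.
#' @param n_months Length of the study period in months (events are spread
#'   uniformly over it).
#' @param model_update_months Months at which the risk model was retrained
#'   (resets the drift clock).
#' @param compliance_drift_per_month Logit-scale change in deferral
#'   probability per study month (0 = stationary).
#' @param model_drift_per_month Relative growth of `model_noise_sd` per month
#'   since the last model update (0 = no drift).
#' @param seed Integer master seed; expanded into independent per-stage
#'   streams.
#' @return An object of class `rcs_config` (a validated list).
#' @seealso [read_trial_config()] to load a configuration from YAML,
#'   [simulate_trial()] to run the generator.
#' @export
trial_config <- function(n_rcs = 1610,
                         rcs_size_dist = c("2" = 0.82, "3" = 0.14, "4" = 0.04),
                         acuity_sd = 1,
                         nurse_noise_sd = 3.5,
                         model_noise_sd = 1.35,
                         compliance_prob = 0.602,
                         optout_prob_per_patient = 0.08,
                         repeat_prob_control = 0.166,
                         repeat_prob_intervention = 0.124,
                         miss_rate_ambulance = c(
                           respiratory_rate = 0.125, spo2 = 0.120,
                           on_oxygen = 0.115, systolic_bp = 0.118,
                           pulse = 0.110, consciousness = 0.112,
                           temperature = 0.142),
                         miss_rate_final = c(
                           respiratory_rate = 0.043, spo2 = 0.042,
                           on_oxygen = 0.040, systolic_bp = 0.041,
                           pulse = 0.039, consciousness = 0.037,
                           temperature = 0.048),
                         miss_acuity_slope = 0.3,
                         news_baseline = 3,
                         composite_weights = c(4, 2, 1, 1),
                         n_months = 46,
                         model_update_months = c(10, 40),
                         compliance_drift_per_month = 0,
                         model_drift_per_month = 0,
                         seed = 1L) {
  cfg <- list(
    n_rcs = n_rcs, rcs_size_dist = rcs_size_dist, acuity_sd = acuity_sd,
    nurse_noise_sd = nurse_noise_sd, model_noise_sd = model_noise_sd,
    compliance_prob = compliance_prob,
    optout_prob_per_patient = optout_prob_per_patient,
    repeat_prob_control = repeat_prob_control,
    repeat_prob_intervention = repeat_prob_intervention,
    miss_rate_ambulance = miss_rate_ambulance,
    miss_rate_final = miss_rate_final,
    miss_acuity_slope = miss_acuity_slope,
    news_baseline = news_baseline,
    composite_weights = composite_weights,
    n_months = n_months, model_update_months = model_update_months,
    compliance_drift_per_month = compliance_drift_per_month,
    model_drift_per_month = model_drift_per_month,
    seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "rcs_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n_rcs), length(cfg$n_rcs) == 1L)
  if (cfg$n_rcs <= 0) stop("n_rcs must be positive")
  d <- cfg$rcs_size_dist
  if (is.null(names(d)) || anyNA(suppressWarnings(as.integer(names(d))))) {
    stop("rcs_size_dist must be named by integer sizes")
  }
  if (any(as.integer(names(d)) < 2)) stop("RCS sizes must be >= 2")
  if (any(d < 0) || abs(sum(d) - 1) > 1e-8) {
    stop("rcs_size_dist must be non-negative and sum to 1")
  }
  probs <- c(cfg$compliance_prob, cfg$optout_prob_per_patient,
             cfg$repeat_prob_control, cfg$repeat_prob_intervention,
             cfg$miss_rate_ambulance, cfg$miss_rate_final)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  comp_names <- c("respiratory_rate", "spo2", "on_oxygen", "systolic_bp",
                  "pulse", "consciousness", "temperature")
  for (fld in c("miss_rate_ambulance", "miss_rate_final")) {
    miss <- setdiff(comp_names, names(cfg[[fld]]))
    if (length(miss)) stop(fld, " lacks component(s): ", paste(miss, collapse = ", "))
  }
  amb <- cfg$miss_rate_ambulance[comp_names]
  fin <- cfg$miss_rate_final[comp_names]
  if (any(fin > amb + 1e-12)) {
    stop("miss_rate_final may not exceed miss_rate_ambulance for any component")
  }
  if (any(cfg$composite_weights <= 0)) stop("composite weights must be positive")
  if (cfg$acuity_sd <= 0) stop("acuity_sd must be positive")
  if (cfg$nurse_noise_sd < 0 || cfg$model_noise_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' Fields absent from the file keep the [trial_config()] defaults; unknown
#' fields raise an error.
#'
#' @param path Path to a YAML file.
#' @return An `rcs_config` object.
#' @export
read_trial_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(trial_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  for (fld in c("rcs_size_dist", "miss_rate_ambulance", "miss_rate_final")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  }
  do.call(trial_config, raw)
}

#' @export
print.rcs_config <- function(x, ...) {
  cat("<rcs_config>\n")
  cat(sprintf("  n_rcs: %d  seed: %d  months: %d\n", x$n_rcs, x$seed, x$n_months))
  cat(sprintf("  RCS sizes: %s\n",
              paste(sprintf("P(%s)=%.2f", names(x$rcs_size_dist), x$rcs_size_dist),
                    collapse = " ")))
  cat(sprintf("  noise: nurse %.2f, model %.2f;  compliance (deferral) %.3f\n",
              x$nurse_noise_sd, x$model_noise_sd, x$compliance_prob))
  invisible(x)
}

# Expand the master seed into independent per-stage seeds so that, e.g.,
# changing the missingness stage cannot perturb the cohort stage.
stage_seeds <- function(seed, stages = c("cohort", "vitals", "predictions",
                                         "events", "decisions", "missingness",
                                         "imputation", "analysis")) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
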