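#' @name synthetic_cohort
#' @title Synthetic dispatch cohort generation
#' @description
#' The generator produces a cohort with the statistical structure the trial
#' analysis assumes. A single latent acuity scalar per patient drives vital
#' signs (hence NEWS), the four binary proxy outcomes, the nurse's perception
#' and the risk model's predictions, so that nurse accuracy, model accuracy
#' and NEWS are mutually coherent and tunable through a handful of noise
#' parameters.
NULL

# Complaint groups: a handful of common dispatch categories followed by
# generic fillers, sampled with Zipf-like weights (41 groups in total).
.call_types <- c(
  "difficulty breathing", "chest pain", "abdominal pain", "general elderly",
  "infection/fever", "fall", "minor trauma", "altered mental status",
  "back pain", "dizziness", "weakness", "nausea/vomiting", "headache",
  "psychiatric", "intoxication", "allergic reaction", "seizure",
  "urinary complaint", "wound", "syncope",
  sprintf("category %02d", 21:41))

#' Generate a synthetic cohort of patients grouped into RCS
#'
#' Draws `n_rcs` resource constrained situations with sizes from
#' `rcs_size_dist`, assigns each a study month uniform over the study period,
#' and fills each RCS with patients: age (median 77), sex (45% female),
#' complaint group, latent acuity `~ N(0, acuity_sd)`, and the four binary
#' proxy outcomes (abnormal primary assessment; lights-and-sirens transport;
#' prehospital intervention; 72 h admission or 30 day mortality), each a
#' Bernoulli draw whose logit is linear in latent acuity.
#'
#' @param config An [trial_config()] object.
#' @return A list with `patients` (one row per patient) and `membership`
#'   (columns `rcs_id`, `patient_id`, `month`). Deterministic given
#'   `config$seed`.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  seeds <- stage_seeds(config$seed)
  with_seed(seeds[["cohort"]], {
    sizes <- as.integer(names(config$rcs_size_dist))
    n_rcs <- as.integer(config$n_rcs)
    rcs_size <- sizes[sample.int(length(sizes), n_rcs, replace = TRUE,
                                 prob = config$rcs_size_dist)]
    n_pat <- sum(rcs_size)
    rcs_id <- sprintf("RCS%05d", seq_len(n_rcs))
    month <- sample.int(config$n_months, n_rcs, replace = TRUE)

    patients <- draw_patients(n_pat, config)
    patients$rcs_id <- rep(rcs_id, rcs_size)
    patients$month <- rep(month, rcs_size)
    patients <- patients[, c("patient_id", "rcs_id", "month",
                             setdiff(names(patients), c("patient_id", "rcs_id", "month")))]
    membership <- patients[, c("rcs_id", "patient_id", "month")]
    list(patients = patients, membership = membership)
  })
}

# Draw n patients with the cohort's marginals (uses the current RNG stream).
# Also used by the trial engine to recruit the extra patient of a grown
# repeat randomization. Proxy-outcome intercepts give base rates of roughly
# 25% (abnormal assessment), 8% (lights and sirens), 18% (intervention) and
# 35% (admission/mortality).
draw_patients <- function(n, config, id_offset = 0L) {
  acuity <- stats::rnorm(n, 0, config$acuity_sd)
  draw <- function(a, b) stats::rbinom(n, 1L, stats::plogis(a + b * acuity))
  ct_w <- 1 / seq_along(.call_types)
  data.frame(
    patient_id = sprintf("P%06d", id_offset + seq_len(n)),
    rcs_id = NA_character_,
    month = NA_integer_,
    age = pmin(103, pmax(18, round(stats::rnorm(n, mean = 77, sd = 15)))),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.45, 0.55)),
    call_type = sample(.call_types, n, replace = TRUE, prob = ct_w / sum(ct_w)),
    latent_acuity = acuity,
    outcome_abnormal = draw(-1.1, 0.8),
    outcome_lights_sirens = draw(-2.4, 0.9),
    outcome_intervention = draw(-1.5, 0.7),
    outcome_admission_mortality = draw(-0.6, 0.8),
    optout = FALSE,
    stringsAsFactors = FALSE)
}

# Band machinery for ordinal vital-sign sampling. Each component has four
# severity levels ordered by NEWS points; a proportional-odds draw shifted
# by latent acuity selects the level, then a measurement value is sampled
# uniformly within a band carrying those points.
.vital_bands <- list(
  respiratory_rate = list(points = c(0, 1, 2, 3),
    ranges = list(list(c(12, 20)), list(c(9, 11)), list(c(21, 24)),
                  list(c(25, 40), c(4, 8))),
    range_probs = list(1, 1, 1, c(0.8, 0.2)), digits = 0),
  spo2 = list(points = c(0, 1, 2, 3),
    ranges = list(list(c(96, 100)), list(c(94, 95)), list(c(92, 93)),
                  list(c(75, 91))),
    range_probs = list(1, 1, 1, 1), digits = 0),
  systolic_bp = list(points = c(0, 1, 2, 3),
    ranges = list(list(c(111, 180)), list(c(101, 110)), list(c(91, 100)),
                  list(c(60, 90), c(220, 260))),
    range_probs = list(1, 1, 1, c(0.9, 0.1)), digits = 0),
  pulse = list(points = c(0, 1, 2, 3),
    ranges = list(list(c(51, 90)), list(c(91, 110), c(41, 50)),
                  list(c(111, 130)), list(c(131, 180), c(25, 40))),
    range_probs = list(1, c(0.85, 0.15), 1, c(0.85, 0.15)), digits = 0),
  temperature = list(points = c(0, 1, 2, 3),
    ranges = list(list(c(36.1, 38.0)), list(c(38.1, 39.0), c(35.1, 36.0)),
                  list(c(39.1, 41.0)), list(c(33.0, 35.0))),
    range_probs = list(1, c(0.7, 0.3), 1, 1), digits = 1)
)

# Probability of reaching each severity level at acuity 0, and the logit
# slope on acuity. These constants were calibrated once (see the methods
# vignette) so that the population mean NEWS is about 3 and the rank
# correlation between acuity and NEWS is strong enough to support the
# targeted nurse and model pair-accuracies.
.vital_calib <- list(
  p_ge = c(0.30, 0.105, 0.035),   # P(severity >= 1, >= 2, >= 3) at acuity 0
  slope = 1.1,
  p_not_alert = 0.055,            # consciousness: any of C/V/P/U
  p_oxygen = 0.07,
  oxygen_slope = 0.9,
  acvpu_probs = c(Confusion = 0.55, Voice = 0.25, Pain = 0.12,
                  Unresponsive = 0.08)
)

# severity level 0..3 for n patients via proportional odds on acuity
.draw_severity <- function(acuity, baseline_shift) {
  n <- length(acuity)
  cuts <- -stats::qlogis(.vital_calib$p_ge) - baseline_shift
  p_ge <- vapply(cuts, function(ck) {
    stats::plogis(.vital_calib$slope * acuity - ck)
  }, numeric(n))
  p_ge <- matrix(p_ge, nrow = n)
  u <- stats::runif(n)
  rowSums(u < p_ge)
}

.sample_in_band <- function(sev, spec) {
  n <- length(sev)
  out <- numeric(n)
  for (lev in 0:3) {
    idx <- which(sev == lev)
    if (!length(idx)) next
    ranges <- spec$ranges[[lev + 1L]]
    rp <- spec$range_probs[[lev + 1L]]
    pick <- if (length(ranges) == 1L) rep(1L, length(idx)) else
      sample(seq_along(ranges), length(idx), replace = TRUE, prob = rp)
    for (j in seq_along(ranges)) {
      jj <- idx[pick == j]
      if (!length(jj)) next
      r <- ranges[[j]]
      out[jj] <- round(stats::runif(length(jj), r[1], r[2]), spec$digits)
    }
  }
  out
}

#' Generate vital signs from latent acuity
#'
#' For each patient each NEWS component is drawn by ordinal band sampling:
#' a proportional-odds model on latent acuity selects a severity level
#' (0--3 NEWS points), then a measurement is sampled uniformly within a
#' chart band carrying those points. Abnormality probabilities therefore
#' increase monotonically with acuity, and the expected NEWS at acuity 0 is
#' governed by `config$news_baseline`.
#'
#' @param patients Patient table from [generate_cohort()] (needs
#'   `patient_id` and `latent_acuity`).
#' @param config An [trial_config()] object.
#' @return A data frame with `patient_id` and the seven component columns
#'   (complete; see [apply_missingness()]).
#' @export
generate_vitals <- function(patients, config) {
  validate_config(config)
  stopifnot(all(is.finite(patients$latent_acuity)))
  seeds <- stage_seeds(config$seed)
  with_seed(seeds[["vitals"]], {
    a <- patients$latent_acuity
    n <- length(a)
    shift <- log(config$news_baseline / 3)
    vit <- data.frame(patient_id = patients$patient_id,
                      stringsAsFactors = FALSE)
    for (nm in names(.vital_bands)) {
      sev <- .draw_severity(a, shift)
      vit[[nm]] <- .sample_in_band(sev, .vital_bands[[nm]])
    }
    p_ox <- stats::plogis(stats::qlogis(.vital_calib$p_oxygen) + shift +
                            .vital_calib$oxygen_slope * a)
    vit$on_oxygen <- stats::runif(n) < p_ox
    p_na <- stats::plogis(stats::qlogis(.vital_calib$p_not_alert) + shift +
                            .vital_calib$slope * a)
    not_alert <- stats::runif(n) < p_na
    cons <- rep("Alert", n)
    if (any(not_alert)) {
      cons[not_alert] <- sample(names(.vital_calib$acvpu_probs),
                                sum(not_alert), replace = TRUE,
                                prob = .vital_calib$acvpu_probs)
    }
    vit$consciousness <- cons
    vit[, c("patient_id", "respiratory_rate", "spo2", "on_oxygen",
            "systolic_bp", "pulse", "consciousness", "temperature")]
  })
}

#' Apply two-stage missingness to a complete vitals table
#'
#' Emulates the trial's data collection: components are first missing from
#' ambulance documentation at per-component rates
#' (`config$miss_rate_ambulance`), then hospital records supplement a
#' fraction of the missing cells so that the final per-component rates equal
#' `config$miss_rate_final`. A mild missing-at-random tilt on latent acuity
#' (sicker patients better documented, `miss_acuity_slope`) is applied on
#' the logit scale; set the slope to 0 for MCAR.
#'
#' @param vitals Complete vitals table from [generate_vitals()].
#' @param patients Patient table (supplies `latent_acuity` for the MAR tilt).
#' @param config An [trial_config()] object.
#' @return A list with `ambulance` (stage-1 table), `final` (post-supplement
#'   table used for analysis) and `source` (per-cell provenance:
#'   `"ambulance"`, `"hospital"` or `"missing"`).
#' @export
apply_missingness <- function(vitals, patients, config) {
  validate_config(config)
  a <- patients$latent_acuity[match(vitals$patient_id, patients$patient_id)]
  seeds <- stage_seeds(config$seed)
  with_seed(seeds[["missingness"]], {
    n <- nrow(vitals)
    comps <- c("respiratory_rate", "spo2", "on_oxygen", "systolic_bp",
               "pulse", "consciousness", "temperature")
    ambulance <- final <- vitals
    src <- matrix("ambulance", n, length(comps), dimnames = list(NULL, comps))
    for (nm in comps) {
      r_amb <- config$miss_rate_ambulance[[nm]]
      r_fin <- config$miss_rate_final[[nm]]
      p_amb <- if (r_amb %in% c(0, 1)) rep(r_amb, n) else
        stats::plogis(stats::qlogis(r_amb) - config$miss_acuity_slope * a)
      miss1 <- stats::runif(n) < p_amb
      # supplementation keeps a cell missing with prob r_fin / r_amb so the
      # marginal final rate matches the configured value
      keep_missing <- if (r_amb > 0) r_fin / r_amb else 0
      miss2 <- miss1 & (stats::runif(n) < keep_missing)
      ambulance[[nm]][miss1] <- NA
      final[[nm]][miss2] <- NA
      src[miss1 & !miss2, nm] <- "hospital"
      src[miss2, nm] <- "missing"
    }
    list(ambulance = ambulance, final = final,
         source = as.data.frame(src, stringsAsFactors = FALSE))
  })
}

#' Flag patients who retroactively opt out of the study
#'
#' Draws independent per-patient opt-out flags; downstream, any RCS that
#' contains at least one opted-out patient is excluded from analysis.
#'
#' @param patients Patient table.
#' @param config An [trial_config()] object (`optout_prob_per_patient`).
#' @return The patient table with its `optout` column filled in.
#' @export
assign_optouts <- function(patients, config) {
  validate_config(config)
  seeds <- stage_seeds(config$seed)
  with_seed(seeds[["cohort"]] + 1L, {
    patients$optout <- stats::runif(nrow(patients)) < config$optout_prob_per_patient
    patients
  })
}
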