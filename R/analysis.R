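#' @name analysis
#' @title RCS-level outcome construction and pooled analyses
#' @description
#' Functions that turn the simulated event, dispatch and (imputed) vitals
#' tables into RCS-level outcomes and run the trial's pre-specified and
#' post-hoc analyses: pooled logistic regression of correct prioritization
#' on arm, pooled rank-sum tests of the NEWS difference, compliance and
#' confidence subgroup rates, time trends, drift monitoring, model
#' calibration, the random-prioritization baseline, and the
#' full-compliance and confidence-blended counterfactual strategies.
NULL

#' Build the RCS-level outcome table for one completed dataset
#'
#' One row per analyzable RCS. The prioritized patient is the first to be
#' assigned an ambulance post-randomization per the dispatch log. An
#' assessment is correct when the prioritized patient belongs to the
#' NEWS winner set ([rcs_winner_set()]), so ties count as correct; the same
#' rule applied to the composite *outcome* score (the 4:2:1:1-weighted
#' combination of the four observed proxy outcomes) gives
#' `correct_composite`. `news_diff` is the prioritized patient's NEWS minus
#' the mean NEWS of the delayed members.
#'
#' @param decisions Decision table from [simulate_decisions()].
#' @param dispatch_log Dispatch log from [simulate_decisions()].
#' @param vitals One completed vitals table (no missing cells).
#' @param patients Patient table (for the proxy outcomes).
#' @param config An [trial_config()] object (composite weights).
#' @return Data frame with one row per RCS: `rcs_id`, `arm`, `month`,
#'   `prioritized_id`, `correct_news`, `correct_composite`, `news_diff`,
#'   `model_agreement`, `confidence`, `n_members`, `n_winners`.
#' @export
build_rcs_outcomes <- function(decisions, dispatch_log, vitals, patients,
                               config = trial_config()) {
  news <- stats::setNames(compute_news(vitals), vitals$patient_id)
  oc <- as.matrix(patients[, c("outcome_abnormal", "outcome_lights_sirens",
                               "outcome_intervention",
                               "outcome_admission_mortality")])
  w <- config$composite_weights / sum(config$composite_weights)
  comp_out <- stats::setNames(as.numeric(oc %*% w), patients$patient_id)

  first_assigned <- dispatch_log$patient_id[dispatch_log$dispatch_order == 1L]
  names(first_assigned) <- dispatch_log$event_id[dispatch_log$dispatch_order == 1L]

  mem_list <- split_members(decisions$members)
  no_dispatch <- !(decisions$event_id %in% names(first_assigned))
  if (any(no_dispatch)) {
    message(sum(no_dispatch), " RCS without any dispatched ambulance excluded")
  }
  keep <- which(!no_dispatch)
  pri <- unname(first_assigned[decisions$event_id[keep]])
  stats_mat <- vapply(seq_along(keep), function(j) {
    mem <- mem_list[[keep[j]]]
    nv <- news[mem]
    mx <- max(nv)
    p_news <- news[[pri[j]]]
    c(correct_news = as.numeric(p_news == mx),
      correct_composite = as.numeric(
        comp_out[[pri[j]]] == max(comp_out[mem])),
      news_diff = p_news - (sum(nv) - p_news) / (length(mem) - 1),
      n_members = length(mem),
      n_winners = sum(nv == mx))
  }, numeric(5))
  data.frame(
    rcs_id = decisions$rcs_id[keep], event_id = decisions$event_id[keep],
    arm = decisions$arm[keep], month = decisions$month[keep],
    prioritized_id = pri,
    correct_news = as.integer(stats_mat["correct_news", ]),
    correct_composite = as.integer(stats_mat["correct_composite", ]),
    news_diff = stats_mat["news_diff", ],
    model_agreement = as.integer(pri == decisions$model_top_id[keep]),
    confidence = decisions$confidence[keep],
    n_members = as.integer(stats_mat["n_members", ]),
    n_winners = as.integer(stats_mat["n_winners", ]),
    stringsAsFactors = FALSE)
}

#' Build one RCS outcome table per imputation
#'
#' @param decisions,dispatch_log,patients,config As in
#'   [build_rcs_outcomes()].
#' @param imp An `rcs_imputation` object (or a list of completed vitals
#'   tables).
#' @return List of outcome tables, one per completed dataset.
#' @export
build_outcome_sets <- function(decisions, dispatch_log, imp, patients,
                               config = trial_config()) {
  completed <- if (inherits(imp, "rcs_imputation")) imp$completed else imp
  lapply(completed, function(v) {
    build_rcs_outcomes(decisions, dispatch_log, v, patients, config)
  })
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(centre - half, centre + half)
}

#' Dispatcher agreement with the model, by arm and confidence class
#'
#' The model's top-ranked patient is recorded in both arms (scores are
#' computed but hidden in the control arm), so agreement proportions are
#' available for both: the control-arm rate measures chance agreement of
#' independent nurse choices with the model, the intervention-arm rate the
#' observed compliance. Wilson 95% CIs; two-sample test for the arm
#' difference, and within the intervention arm for the high-vs-low
#' confidence difference.
#'
#' @param outcomes An RCS outcome table from [build_rcs_outcomes()] (model
#'   agreement does not depend on the imputation, so any one table works).
#' @return A list with `by_arm`, `by_confidence` (intervention only) data
#'   frames and the `arm_diff_p` / `confidence_diff_p` test p values.
#' @export
compliance_rates <- function(outcomes) {
  rate_row <- function(d, label) {
    n <- nrow(d)
    if (n == 0) {
      warning("empty stratum: ", label)
      return(data.frame(stratum = label, n = 0L, agree = NA_integer_,
                        rate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    x <- sum(d$model_agreement)
    ci <- wilson_ci(x, n)
    data.frame(stratum = label, n = n, agree = x, rate = x / n,
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  }
  ctrl <- outcomes[outcomes$arm == "control", ]
  intv <- outcomes[outcomes$arm == "intervention", ]
  by_arm <- rbind(rate_row(ctrl, "control"), rate_row(intv, "intervention"))
  hi <- intv[intv$confidence == "high", ]
  lo <- intv[intv$confidence == "low", ]
  by_conf <- rbind(rate_row(hi, "high"), rate_row(lo, "low"))
  test_p <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
    suppressWarnings(stats::prop.test(
      c(sum(a$model_agreement), sum(b$model_agreement)),
      c(nrow(a), nrow(b))))$p.value
  }
  list(by_arm = by_arm, by_confidence = by_conf,
       arm_diff_p = test_p(ctrl, intv),
       confidence_diff_p = test_p(hi, lo))
}

# Re-derive correctness columns after substituting prioritized ids.
# Used by the counterfactual strategies; only NEWS-dependent columns are
# recomputed per imputation.
recompute_with_prioritized <- function(decisions, new_prioritized, imp,
                                       patients, config) {
  completed <- if (inherits(imp, "rcs_imputation")) imp$completed else imp
  mem_list <- split_members(decisions$members)
  lapply(completed, function(v) {
    news <- stats::setNames(compute_news(v), v$patient_id)
    stats_mat <- vapply(seq_len(nrow(decisions)), function(i) {
      mem <- mem_list[[i]]
      nv <- news[mem]
      p_news <- news[[new_prioritized[i]]]
      c(correct_news = as.numeric(p_news == max(nv)),
        news_diff = p_news - (sum(nv) - p_news) / (length(mem) - 1))
    }, numeric(2))
    data.frame(
      rcs_id = decisions$rcs_id, arm = decisions$arm,
      month = decisions$month,
      correct_news = as.integer(stats_mat["correct_news", ]),
      news_diff = stats_mat["news_diff", ],
      confidence = decisions$confidence,
      stringsAsFactors = FALSE)
  })
}

#' Intervention effect under 100% compliance
#'
#' Re-runs the primary analysis after replacing the prioritized patient of
#' every intervention-arm RCS with the model's top-ranked patient; the
#' control arm is untouched. In a run that was already fully compliant the
#' result is identical to the observed analysis.
#'
#' @param decisions Decision table restricted to the analysis set.
#' @param imp `rcs_imputation` (or list of completed vitals tables).
#' @param patients Patient table.
#' @param config An [trial_config()] object.
#' @return List with `accuracy` (per-arm proportions, averaged over
#'   imputations) and `pooled` (pooled logistic estimate of the arm
#'   effect).
#' @export
full_compliance_counterfactual <- function(decisions, imp, patients,
                                           config = trial_config()) {
  pri <- ifelse(decisions$arm == "intervention",
                decisions$model_top_id, decisions$prioritized_id)
  sets <- recompute_with_prioritized(decisions, pri, imp, patients, config)
  summarize_strategy(sets)
}

#' Intervention effect under confidence-blended prioritization
#'
#' Post-hoc strategy: in the intervention arm, follow the model where its
#' confidence was high and keep the observed dispatcher choice where it was
#' low; the control arm is untouched. With all comparisons high-confidence
#' this equals the full-compliance counterfactual; with all low-confidence
#' it equals the observed analysis.
#'
#' @inheritParams full_compliance_counterfactual
#' @return As [full_compliance_counterfactual()].
#' @export
blended_strategy <- function(decisions, imp, patients,
                             config = trial_config()) {
  pri <- ifelse(decisions$arm == "intervention" & decisions$confidence == "high",
                decisions$model_top_id, decisions$prioritized_id)
  sets <- recompute_with_prioritized(decisions, pri, imp, patients, config)
  summarize_strategy(sets)
}

summarize_strategy <- function(outcome_sets) {
  acc <- sapply(outcome_sets, function(o) {
    tapply(o$correct_news, o$arm, mean)
  })
  pooled <- pooled_logistic(outcome_sets, correct_news ~ arm,
                            term = "armintervention")
  list(accuracy = rowMeans(acc), pooled = pooled)
}

#' Expected accuracy of random prioritization
#'
#' If the immediate ambulance were assigned uniformly at random within each
#' RCS, the probability that the prioritized patient attains the highest
#' NEWS equals the winner-set size divided by the RCS size; the cohort-level
#' expectation is the mean of this ratio over RCS (and, with multiply
#' imputed NEWS, over imputations).
#'
#' @param n_winners Integer vector of winner-set sizes (or an outcome table
#'   list from [build_outcome_sets()], in which case `rcs_sizes` is ignored).
#' @param rcs_sizes Integer vector of RCS sizes.
#' @return Expected accuracy in `[0, 1]`.
#' @export
#' @examples
#' random_baseline(1, 2)            # pair without tie: 0.5
#' random_baseline(2, 2)            # pair with tie: 1
#' random_baseline(1, 3)            # members {2,2,3}: 1/3
random_baseline <- function(n_winners, rcs_sizes = NULL) {
  if (is.list(n_winners)) {
    return(mean(vapply(n_winners, function(o) {
      mean(o$n_winners / o$n_members)
    }, numeric(1))))
  }
  mean(n_winners / rcs_sizes)
}

#' Time-trend analyses of compliance and control-arm accuracy
#'
#' Logistic regressions with study month as the independent variable:
#' compliance (model agreement) on month in the intervention arm, and
#' correct prioritization on month in the control arm (spillover). Slopes
#' are reported as odds ratios per month with 95% CIs.
#'
#' @param outcomes An RCS outcome table.
#' @return List with `compliance_trend` and `spillover_trend`, each a list
#'   with `or_per_month`, `ci_low`, `ci_high`, `p_value`.
#' @export
time_trends <- function(outcomes) {
  slope <- function(d, yname) {
    if (length(unique(d$month)) < 3L) {
      stop("time-trend analysis needs >= 3 distinct months")
    }
    if (length(unique(d[[yname]])) < 2L) {
      stop("outcome '", yname, "' has no variance; slope undefined")
    }
    fit <- stats::glm(stats::reformulate("month", yname),
                      family = stats::binomial(), data = d)
    est <- stats::coef(fit)["month"]
    se <- sqrt(diag(stats::vcov(fit)))["month"]
    list(or_per_month = unname(exp(est)),
         ci_low = unname(exp(est - 1.96 * se)),
         ci_high = unname(exp(est + 1.96 * se)),
         p_value = unname(summary(fit)$coefficients["month", 4]))
  }
  list(
    compliance_trend = slope(outcomes[outcomes$arm == "intervention", ],
                             "model_agreement"),
    spillover_trend = slope(outcomes[outcomes$arm == "control", ],
                            "correct_news"))
}

#' Months elapsed since the most recent model update
#'
#' @param month Integer study months.
#' @param update_months Months at which the model was retrained; the drift
#'   clock resets at each.
#' @return Integer vector of months since the last update (study start
#'   counts as month 0 when no update has occurred yet).
#' @export
months_since_update <- function(month, update_months = c(10, 40)) {
  vapply(month, function(t) {
    past <- update_months[update_months <= t]
    t - if (length(past)) max(past) else 0
  }, numeric(1))
}

#' Monitor drift of the risk score's association with NEWS
#'
#' Computes the Spearman correlation between the composite risk score and
#' NEWS within each study month (months with fewer than `min_n` patients
#' are excluded), then regresses the monthly coefficients on months since
#' the most recent model update, the clock resetting at each update.
#'
#' @param scored Patient-level data frame with `composite`, `news_total`
#'   and `month` columns.
#' @param update_months Model retraining months.
#' @param min_n Minimum patients per month (default 10).
#' @return List with `monthly` (month, months_since_update, n, spearman)
#'   and `slope` (`estimate`, `ci_low`, `ci_high`, `p_value` per month).
#' @export
drift_monitor <- function(scored, update_months = c(10, 40), min_n = 10) {
  by_month <- split(scored, scored$month)
  rows <- lapply(by_month, function(d) {
    if (nrow(d) < min_n) {
      message("month ", d$month[1], " excluded (", nrow(d), " patients)")
      return(NULL)
    }
    data.frame(month = d$month[1], n = nrow(d),
               spearman = suppressWarnings(
                 stats::cor(d$composite, d$news_total, method = "spearman")))
  })
  monthly <- do.call(rbind, rows)
  if (is.null(monthly) || nrow(monthly) < 3L) {
    stop("drift monitoring needs >= 3 months with sufficient data")
  }
  monthly$months_since_update <- months_since_update(monthly$month, update_months)
  fit <- stats::lm(spearman ~ months_since_update, data = monthly)
  est <- stats::coef(fit)["months_since_update"]
  se <- sqrt(diag(stats::vcov(fit)))["months_since_update"]
  list(monthly = monthly,
       slope = list(estimate = unname(est),
                    ci_low = unname(est - 1.96 * se),
                    ci_high = unname(est + 1.96 * se),
                    p_value = unname(summary(fit)$coefficients[
                      "months_since_update", 4])))
}

#' Residual calibration of the risk score against patient characteristics
#'
#' Fits, in each completed dataset, the linear model
#' `NEWS ~ composite score + age + sex + complaint-category indicators` and
#' pools each coefficient with Rubin's rules. A well-calibrated score
#' leaves no residual predictive value in age or sex; category indicators
#' that remain significant flag complaint groups where the score is
#' mis-calibrated. Aliased (rank-deficient) indicators are dropped with a
#' message.
#'
#' @param datasets List of patient-level data frames (one per imputation)
#'   with `news_total`, `composite`, `age`, `sex`, `call_type`.
#' @return Data frame of pooled coefficients with `term`, `estimate`, `se`,
#'   `p_value`, `significant` (p < 0.05, score and intercept excluded from
#'   flagging).
#' @export
calibration_check <- function(datasets) {
  fits <- lapply(datasets, function(d) {
    d$call_type <- factor(d$call_type)
    stats::lm(news_total ~ composite + age + sex + call_type, data = d)
  })
  co <- stats::coef(fits[[1]])
  aliased <- names(co)[is.na(co)]
  if (length(aliased)) {
    message("dropping aliased indicator(s): ", paste(aliased, collapse = ", "))
  }
  terms <- names(co)[!is.na(co)]
  rows <- lapply(terms, function(tm) {
    Q <- vapply(fits, function(f) stats::coef(f)[tm], numeric(1))
    U <- vapply(fits, function(f) {
      s <- summary(f)$coefficients
      s[tm, "Std. Error"]^2
    }, numeric(1))
    p <- pool_rubin(Q, U, df_com = fits[[1]]$df.residual)
    data.frame(term = tm, estimate = p$point, se = p$se, p_value = p$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < 0.05 &
    !out$term %in% c("(Intercept)", "composite")
  out
}

#' Sample size for a two-sided test of two proportions
#'
#' Closed-form normal-approximation sample size per group,
#' `n = (z_{1-alpha/2} + z_{power})^2 * (p1 q1 + p2 q2) / (p1 - p2)^2`
#' (unpooled variance), with the pooled-variance variant reported
#' alongside. Equal proportions give an infinite requirement, reported
#' explicitly.
#'
#' @param p1,p2 The two proportions (in (0, 1)).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return List with `n_per_group`, `n_total` (unpooled), `n_per_group_pooled`,
#'   `n_total_pooled`, the inputs, and `formula` describing the computation;
#'   `n_per_group` is `Inf` with an explanatory `note` when `p1 == p2`.
#' @export
#' @examples
#' power_proportions(0.653, 0.703)  # ~1,367 per group
power_proportions <- function(p1, p2, alpha = 0.05, power = 0.8) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  if (p1 == p2) {
    return(list(n_per_group = Inf, n_total = Inf,
                p1 = p1, p2 = p2, alpha = alpha, power = power,
                note = "p1 equals p2: no finite sample size detects a null effect"))
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  delta2 <- (p1 - p2)^2
  n_unpooled <- (za + zb)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / delta2
  pbar <- (p1 + p2) / 2
  n_pooled <- (za * sqrt(2 * pbar * (1 - pbar)) +
                 zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / delta2
  list(n_per_group = ceiling(n_unpooled), n_total = 2 * ceiling(n_unpooled),
       n_per_group_pooled = ceiling(n_pooled),
       n_total_pooled = 2 * ceiling(n_pooled),
       p1 = p1, p2 = p2, alpha = alpha, power = power,
       formula = "n = (z_{1-a/2} + z_power)^2 (p1 q1 + p2 q2) / (p1 - p2)^2 per group")
}

#' Deferral probability reproducing a target observed agreement
#'
#' Observed intervention-arm agreement with the model mixes true deferral
#' with chance agreement of independent nurse choices:
#' `observed = c + (1 - c) * chance`. Given a target observed agreement and
#' the chance-agreement rate (measurable in the control arm, where scores
#' are computed but hidden), this solves for the deferral probability `c`.
#'
#' @param target_observed Target observed agreement proportion.
#' @param chance_agreement Chance agreement proportion.
#' @return The deferral probability.
#' @export
#' @examples
#' calibrate_compliance(0.809, 0.540)  # ~0.585
calibrate_compliance <- function(target_observed, chance_agreement) {
  stopifnot(chance_agreement >= 0, chance_agreement < 1)
  c_hat <- (target_observed - chance_agreement) / (1 - chance_agreement)
  if (c_hat < 0 || c_hat > 1) {
    stop("target agreement unreachable for the given chance-agreement rate")
  }
  c_hat
}
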