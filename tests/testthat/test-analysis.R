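# hand-built two-RCS fixture: known NEWS, known dispatch order
tiny_trial <- function(news_a = 5, news_b = 3, pri = "A") {
  decisions <- data.frame(
    event_id = "E1", rcs_id = "R1", members = "A;B", arm = "control",
    month = 1L, prioritized_id = pri, model_top_id = "A",
    nurse_top_id = pri, deferred = FALSE, gap = 0.1, confidence = "high",
    stringsAsFactors = FALSE)
  dispatch_log <- data.frame(
    event_id = "E1", rcs_id = "R1", patient_id = c(pri, setdiff(c("A", "B"), pri)),
    dispatch_order = 1:2, dispatch_minutes = c(30, 60),
    stringsAsFactors = FALSE)
  vit <- normal_vitals(2)
  vit$patient_id <- c("A", "B")
  # respiratory-rate bands used to realize the requested NEWS totals
  rr_for <- function(total) switch(as.character(total),
    "0" = 16, "1" = 10, "2" = 22, "3" = 8, "5" = 8, stop("unsupported"))
  if (news_a %in% c(0:3)) vit$respiratory_rate[1] <- rr_for(news_a)
  if (news_b %in% c(0:3)) vit$respiratory_rate[2] <- rr_for(news_b)
  if (news_a == 5) { vit$respiratory_rate[1] <- 8; vit$spo2[1] <- 92 }
  if (news_b == 5) { vit$respiratory_rate[2] <- 8; vit$spo2[2] <- 92 }
  patients <- data.frame(
    patient_id = c("A", "B"), outcome_abnormal = c(1, 0),
    outcome_lights_sirens = c(0, 0), outcome_intervention = c(0, 0),
    outcome_admission_mortality = c(1, 0), stringsAsFactors = FALSE)
  list(decisions = decisions, dispatch_log = dispatch_log, vitals = vit,
       patients = patients)
}

test_that("RCS outcomes encode correctness, ties and the NEWS difference", {
  f <- tiny_trial(news_a = 5, news_b = 3, pri = "A")
  oc <- build_rcs_outcomes(f$decisions, f$dispatch_log, f$vitals, f$patients)
  expect_equal(oc$correct_news, 1L)
  expect_equal(oc$news_diff, 2)

  f <- tiny_trial(news_a = 3, news_b = 5, pri = "A")
  oc <- build_rcs_outcomes(f$decisions, f$dispatch_log, f$vitals, f$patients)
  expect_equal(oc$correct_news, 0L)
  expect_equal(oc$news_diff, -2)

  # tie on NEWS counts as a correct assessment
  f <- tiny_trial(news_a = 2, news_b = 2, pri = "A")
  oc <- build_rcs_outcomes(f$decisions, f$dispatch_log, f$vitals, f$patients)
  expect_equal(oc$correct_news, 1L)
  expect_equal(oc$news_diff, 0)
  expect_equal(oc$n_winners, 2L)

  # composite outcome winner: A carries the outcome flags
  expect_equal(oc$correct_composite, 1L)
})

test_that("correctness is 1 whenever all members tie, regardless of choice", {
  for (pri in c("A", "B")) {
    f <- tiny_trial(news_a = 1, news_b = 1, pri = pri)
    oc <- build_rcs_outcomes(f$decisions, f$dispatch_log, f$vitals, f$patients)
    expect_equal(oc$correct_news, 1L)
  }
})

test_that("random baseline equals the exact enumeration over uniform choices", {
  expect_equal(random_baseline(1, 2), 0.5)
  expect_equal(random_baseline(2, 2), 1)
  expect_equal(random_baseline(1, 3), 1 / 3)  # members {2,2,3}

  # enumeration oracle: average over each member being prioritized
  enumerate <- function(scores) {
    mean(vapply(seq_along(scores), function(i) {
      scores[i] == max(scores)
    }, logical(1)))
  }
  set.seed(6)
  for (size in 2:4) {
    for (rep in 1:30) {
      scores <- sample(0:3, size, replace = TRUE)
      expect_equal(random_baseline(sum(scores == max(scores)), size),
                   enumerate(scores))
    }
  }
})

test_that("compliance rates stratify by arm and confidence with Wilson CIs", {
  oc <- data.frame(
    arm = rep(c("control", "intervention"), c(40, 60)),
    model_agreement = c(rep(c(1, 0), 20), rep(c(1, 1, 1, 1, 0), 12)),
    confidence = c(rep("low", 40), rep(c("high", "low"), 30)),
    stringsAsFactors = FALSE)
  cr <- compliance_rates(oc)
  expect_equal(cr$by_arm$rate[cr$by_arm$stratum == "control"], 0.5)
  expect_equal(cr$by_arm$rate[cr$by_arm$stratum == "intervention"], 0.8)
  expect_true(all(cr$by_arm$ci_low < cr$by_arm$rate &
                    cr$by_arm$rate < cr$by_arm$ci_high))
  # Wilson interval oracle for 20/40
  z <- qnorm(0.975)
  p <- 0.5; n <- 40
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(cr$by_arm$ci_low[cr$by_arm$stratum == "control"], lo)
})

test_that("decisions independent of the model agree about half the time in pairs", {
  cfg <- trial_config(n_rcs = 3000, seed = 15, rcs_size_dist = c("2" = 1),
                      compliance_prob = 0, optout_prob_per_patient = 0,
                      repeat_prob_control = 0, repeat_prob_intervention = 0,
                      nurse_noise_sd = 60, model_noise_sd = 60)
  sim <- simulate_trial(cfg)
  agree <- mean(sim$decisions$prioritized_id == sim$decisions$model_top_id)
  expect_gt(agree, 0.46)
  expect_lt(agree, 0.54)
})

test_that("counterfactual strategies honour their degenerate limits", {
  cfg <- small_config(seed = 33, compliance_prob = 1)
  sim <- simulate_trial(cfg)
  imp <- impute_components(sim$vitals_observed, m = 2, maxit = 2,
                           engine = "pmm", seed = 7)
  dec <- sim$analysis_decisions
  oc <- build_outcome_sets(dec, sim$dispatch_log, imp, sim$patients, cfg)
  observed <- rcstrial:::summarize_strategy(
    rcstrial:::recompute_with_prioritized(dec, dec$prioritized_id, imp,
                                          sim$patients, cfg))
  cf <- full_compliance_counterfactual(dec, imp, sim$patients, cfg)
  # fully compliant run: counterfactual identical to observed analysis
  expect_equal(cf$accuracy, observed$accuracy)
  expect_equal(cf$pooled$point, observed$pooled$point)

  # all-low confidence: blended equals observed
  dec_low <- dec
  dec_low$confidence <- "low"
  bl <- blended_strategy(dec_low, imp, sim$patients, cfg)
  expect_equal(bl$accuracy, observed$accuracy)
  expect_equal(bl$pooled$point, observed$pooled$point)

  # all-high confidence: blended equals the full-compliance counterfactual
  dec_high <- dec
  dec_high$confidence <- "high"
  bh <- blended_strategy(dec_high, imp, sim$patients, cfg)
  expect_equal(bh$accuracy, cf$accuracy)
  expect_equal(bh$pooled$point, cf$pooled$point)
})

test_that("full-compliance accuracy beats observed when the model outperforms nurses", {
  cfg <- small_config(seed = 44, compliance_prob = 0.5)
  sim <- simulate_trial(cfg)
  imp <- impute_components(sim$vitals_observed, m = 2, maxit = 2,
                           engine = "pmm", seed = 8)
  dec <- sim$analysis_decisions
  observed <- rcstrial:::summarize_strategy(
    rcstrial:::recompute_with_prioritized(dec, dec$prioritized_id, imp,
                                          sim$patients, cfg))
  cf <- full_compliance_counterfactual(dec, imp, sim$patients, cfg)
  expect_gte(cf$accuracy[["intervention"]],
             observed$accuracy[["intervention"]] - 0.02)
  expect_equal(cf$accuracy[["control"]], observed$accuracy[["control"]])
})

test_that("time trends recover stationarity and reject degenerate input", {
  res <- quick_analysis(seed = 51)
  tr <- res$time_trends
  expect_true(tr$compliance_trend$ci_low < 1 & 1 < tr$compliance_trend$ci_high ||
                abs(log(tr$compliance_trend$or_per_month)) < 0.05)

  oc <- res$outcome_sets[[1]]
  oc$month <- 1L
  expect_error(time_trends(oc), "3 distinct months")
  oc2 <- res$outcome_sets[[1]]
  oc2$correct_news <- 1L
  expect_error(time_trends(oc2), "no variance")
})

test_that("injected compliance drift is recovered with the right sign", {
  cfg <- trial_config(n_rcs = 1200, seed = 61, compliance_drift_per_month = -0.06,
                      optout_prob_per_patient = 0,
                      repeat_prob_control = 0, repeat_prob_intervention = 0)
  sim <- simulate_trial(cfg)
  dec <- sim$decisions
  set.seed(62)
  oc <- data.frame(arm = dec$arm, month = dec$month,
                   model_agreement = as.integer(dec$prioritized_id == dec$model_top_id),
                   correct_news = rbinom(nrow(dec), 1, 0.6))
  tr <- time_trends(oc)
  expect_lt(tr$compliance_trend$or_per_month, 1)
  expect_lt(tr$compliance_trend$p_value, 0.05)
})

test_that("drift monitor handles the update clock and recovers decay", {
  expect_equal(months_since_update(c(1, 9, 10, 12, 39, 40, 45), c(10, 40)),
               c(1, 9, 0, 2, 29, 0, 5))

  # stationary generator: slope CI covers 0
  res <- quick_analysis(seed = 71, n_rcs = 800)
  expect_true(res$drift$slope$ci_low <= 0 && 0 <= res$drift$slope$ci_high)

  # decaying score-NEWS association: negative slope recovered
  cfg <- trial_config(n_rcs = 2500, seed = 72, model_drift_per_month = 0.25,
                      model_update_months = integer(0),
                      optout_prob_per_patient = 0,
                      repeat_prob_control = 0, repeat_prob_intervention = 0)
  sim <- simulate_trial(cfg)
  scored <- sim$patients[, c("patient_id", "month")]
  scored$composite <- sim$predictions$composite
  scored$news_total <- compute_news(sim$vitals_complete)
  dr <- drift_monitor(scored, update_months = integer(0))
  expect_lt(dr$slope$estimate, 0)
  expect_lt(dr$slope$p_value, 0.05)

  # months below the size threshold are dropped with a message
  scored_small <- scored[scored$month <= 3 | seq_len(nrow(scored)) %% 50 == 0, ]
  expect_message(drift_monitor(scored_small), "excluded")
})

test_that("calibration check finds no residual signal under the null and flags injected shifts", {
  cfg <- trial_config(n_rcs = 1500, seed = 81, optout_prob_per_patient = 0,
                      repeat_prob_control = 0, repeat_prob_intervention = 0)
  sim <- simulate_trial(cfg)
  d <- sim$patients[, c("patient_id", "age", "sex", "call_type")]
  d$composite <- sim$predictions$composite
  d$news_total <- compute_news(sim$vitals_complete)
  cal <- calibration_check(list(d))
  age_sex <- cal[cal$term %in% c("age", "sexmale"), ]
  expect_true(all(age_sex$p_value > 0.001))

  # inject a category-specific NEWS shift and expect that category flagged
  d2 <- d
  shift_rows <- d2$call_type == "chest pain"
  d2$news_total <- d2$news_total + ifelse(shift_rows, 4L, 0L)
  cal2 <- calibration_check(list(d2))
  flagged <- cal2$term[cal2$significant]
  expect_true(any(grepl("chest pain", flagged)))
})

test_that("sample-size utility matches the closed form and flags degenerate input", {
  pw <- power_proportions(0.653, 0.703)
  expect_equal(pw$n_per_group, 1367)  # (1.96 + 0.8416)^2 (p1q1 + p2q2) / d^2
  expect_equal(pw$n_total, 2734)

  # halving the effect roughly quadruples the requirement
  pw2 <- power_proportions(0.653, 0.678)
  expect_gt(pw2$n_per_group / pw$n_per_group, 3.6)
  expect_lt(pw2$n_per_group / pw$n_per_group, 4.4)

  eq <- power_proportions(0.5, 0.5)
  expect_true(is.infinite(eq$n_per_group))
  expect_match(eq$note, "no finite")
})

test_that("compliance calibration inverts the observed-agreement mixture", {
  expect_equal(calibrate_compliance(0.809, 0.540), (0.809 - 0.54) / 0.46)
  expect_error(calibrate_compliance(0.3, 0.5), "unreachable")
  # round trip: deferral c and chance g give observed c + (1-c) g
  c0 <- 0.6; g <- 0.52
  expect_equal(calibrate_compliance(c0 + (1 - c0) * g, g), c0)
})
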