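#' Simulate a complete dispatch trial
#'
#' Runs the whole generator: cohort and RCS structure, randomization events
#' with repeat re-rolls, opt-outs, vital signs, risk predictions (with the
#' drift clock), protocol resolution, dispatcher decisions and dispatch
#' log, participant flow, and two-stage missingness. Deterministic given
#' `config$seed`.
#'
#' @param config An [trial_config()] object.
#' @return A list of class `rcs_trial` with elements `config`, `patients`,
#'   `events`, `resolved`, `decisions`, `analysis_decisions` (decisions
#'   minus opt-out RCS), `dispatch_log`, `predictions`, `vitals_complete`,
#'   `vitals_observed` (post-supplement table with missing cells),
#'   `vitals_source`, `flow` and `cutoff`.
#' @export
simulate_trial <- function(config = trial_config()) {
  cohort <- generate_cohort(config)
  ev <- simulate_events(cohort, config)
  patients <- assign_optouts(ev$patients, config)
  vitals <- generate_vitals(patients, config)
  msu <- months_since_update(patients$month, config$model_update_months)
  preds <- synthetic_predictions(patients, config, months_since_update = msu)
  resolved <- resolve_repeats(ev$events)
  dec <- simulate_decisions(resolved, patients, preds, config)
  flow <- consort_flow(resolved, patients)
  miss <- apply_missingness(vitals, patients, config)

  optout_ids <- patients$patient_id[patients$optout]
  has_optout <- vapply(split_members(dec$decisions$members),
                       function(m) any(m %in% optout_ids), logical(1))
  structure(list(
    config = config, patients = patients, events = ev$events,
    resolved = resolved, decisions = dec$decisions,
    analysis_decisions = dec$decisions[!has_optout, , drop = FALSE],
    dispatch_log = dec$dispatch_log, predictions = preds,
    vitals_complete = vitals, vitals_observed = miss$final,
    vitals_ambulance = miss$ambulance, vitals_source = miss$source,
    flow = flow, cutoff = dec$cutoff), class = "rcs_trial")
}

#' @export
print.rcs_trial <- function(x, ...) {
  cat("<rcs_trial>\n")
  print(x$flow)
  invisible(x)
}

#' Analyse a simulated trial
#'
#' Multiply imputes the observed vitals, builds per-imputation RCS outcome
#' tables, and runs the full analysis suite: the primary pooled logistic
#' regression (correct prioritization by NEWS on arm), the secondary
#' pooled logistic on the composite outcome score, the pooled rank-sum
#' test on the NEWS difference, compliance and confidence subgroup rates,
#' the random-prioritization baseline, the full-compliance and
#' confidence-blended counterfactuals, time trends, drift monitoring and
#' the calibration check.
#'
#' @param sim An `rcs_trial` from [simulate_trial()].
#' @param m Number of imputations (default 10).
#' @param maxit Chained-equation iterations per chain (default 10).
#' @param engine Imputation engine, `"rf"` or `"pmm"`.
#' @param imp Optionally, a precomputed `rcs_imputation` for
#'   `sim$vitals_observed` (skips the imputation step).
#' @return A list of class `rcs_results` with the analysis blocks.
#' @export
analyze_trial <- function(sim, m = 10, maxit = 10, engine = c("rf", "pmm"),
                          imp = NULL) {
  stopifnot(inherits(sim, "rcs_trial"))
  engine <- match.arg(engine)
  config <- sim$config
  seeds <- stage_seeds(config$seed)
  if (is.null(imp)) {
    aux <- sim$patients[, c("patient_id", "age", "sex")]
    imp <- impute_components(sim$vitals_observed, predictors = aux, m = m,
                             maxit = maxit, engine = engine,
                             seed = seeds[["imputation"]])
  }
  dec <- sim$analysis_decisions
  outcome_sets <- build_outcome_sets(dec, sim$dispatch_log, imp,
                                     sim$patients, config)

  primary <- pooled_logistic(outcome_sets, correct_news ~ arm,
                             term = "armintervention")
  secondary_composite <- pooled_logistic(outcome_sets, correct_composite ~ arm,
                                         term = "armintervention")
  secondary_news_diff <- pooled_wilcoxon(datasets = outcome_sets)

  acc <- sapply(outcome_sets, function(o) tapply(o$correct_news, o$arm, mean))
  accuracy_by_arm <- rowMeans(acc)
  news_diff_by_arm <- rowMeans(sapply(outcome_sets, function(o) {
    tapply(o$news_diff, o$arm, mean)
  }))

  compliance <- compliance_rates(outcome_sets[[1]])
  baseline <- random_baseline(outcome_sets)
  counterfactual <- full_compliance_counterfactual(dec, imp, sim$patients, config)
  blended <- blended_strategy(dec, imp, sim$patients, config)
  trends <- time_trends(outcome_sets[[1]])

  # drift and calibration are patient-level: attach per-imputation NEWS
  scored_sets <- lapply(imp$completed, function(v) {
    d <- sim$patients[, c("patient_id", "age", "sex", "call_type", "month")]
    d$composite <- sim$predictions$composite[
      match(d$patient_id, sim$predictions$patient_id)]
    d$news_total <- compute_news(v)[match(d$patient_id, v$patient_id)]
    d
  })
  # drift and calibration need a reasonable number of patients per month;
  # on very small runs they are skipped with a message rather than failing
  drift <- tryCatch(
    drift_monitor(average_monthly(scored_sets),
                  update_months = config$model_update_months),
    error = function(e) { message("drift monitor skipped: ", e$message); NULL })
  calibration <- tryCatch(
    calibration_check(scored_sets),
    error = function(e) { message("calibration check skipped: ", e$message); NULL })

  structure(list(
    flow = sim$flow,
    imputation = imp,
    diagnostics = if (imp$m >= 2 && imp$maxit >= 2 && length(imp$targets))
      diagnose_imputation(imp) else NULL,
    accuracy_by_arm = accuracy_by_arm,
    news_diff_by_arm = news_diff_by_arm,
    primary = primary,
    secondary_composite = secondary_composite,
    secondary_news_diff = secondary_news_diff,
    compliance = compliance,
    random_baseline = baseline,
    counterfactual_full_compliance = counterfactual,
    blended_strategy = blended,
    time_trends = trends,
    drift = drift,
    calibration = calibration,
    outcome_sets = outcome_sets), class = "rcs_results")
}

# average patient-level NEWS over imputations for the drift monitor (the
# score-NEWS association is monitored without reference to arm; using the
# across-imputation mean NEWS per patient keeps one series per month)
average_monthly <- function(scored_sets) {
  base <- scored_sets[[1]]
  news_mat <- sapply(scored_sets, function(d) d$news_total)
  base$news_total <- if (is.matrix(news_mat)) rowMeans(news_mat) else news_mat
  base
}

#' @export
print.rcs_results <- function(x, ...) {
  cat("Trial analysis\n")
  cat(sprintf("  accuracy: control %.3f, intervention %.3f (random baseline %.3f)\n",
              x$accuracy_by_arm[["control"]], x$accuracy_by_arm[["intervention"]],
              x$random_baseline))
  cat(sprintf("  primary OR %.2f [%.2f, %.2f], p = %.3g\n",
              x$primary$or, x$primary$or_ci_low, x$primary$or_ci_high,
              x$primary$p_value))
  cat(sprintf("  composite OR %.2f [%.2f, %.2f], p = %.3g\n",
              x$secondary_composite$or, x$secondary_composite$or_ci_low,
              x$secondary_composite$or_ci_high, x$secondary_composite$p_value))
  if (!is.na(x$secondary_news_diff$z)) {
    cat(sprintf("  NEWS difference rank-sum z = %.3f, p = %.3g\n",
                x$secondary_news_diff$z, x$secondary_news_diff$p_value))
  }
  inv <- x$compliance$by_arm
  cat(sprintf("  model agreement: control %.1f%%, intervention %.1f%%\n",
              100 * inv$rate[inv$stratum == "control"],
              100 * inv$rate[inv$stratum == "intervention"]))
  cat(sprintf("  100%%-compliance accuracy %.3f (OR %.2f); blended %.3f (OR %.2f)\n",
              x$counterfactual_full_compliance$accuracy[["intervention"]],
              x$counterfactual_full_compliance$pooled$or,
              x$blended_strategy$accuracy[["intervention"]],
              x$blended_strategy$pooled$or))
  invisible(x)
}

#' Run the full pipeline and write its artifacts
#'
#' Simulate, impute, analyse and report from a single configuration,
#' writing the patient, vitals, event, decision and dispatch tables, the
#' long-format imputation table, a results JSON, the rendered report
#' tables, and a run manifest (config hash, per-stage seeds, package
#' version, stage timings). Re-running with an identical configuration
#' reproduces identical tables.
#'
#' @param config An [trial_config()] object, or the path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param m,maxit,engine Imputation settings passed to [analyze_trial()].
#' @param format `"csv"` or `"parquet"` (the latter requires the `arrow`
#'   package).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, m = 10, maxit = 10,
                         engine = c("rf", "pmm"), format = c("csv", "parquet")) {
  if (is.character(config)) config <- read_trial_config(config)
  engine <- match.arg(engine)
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tick <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[label]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    r
  }
  sim <- tick("simulate", simulate_trial(config))
  res <- tick("analyze", analyze_trial(sim, m = m, maxit = maxit, engine = engine))

  write_tbl <- function(d, name) {
    if (format == "parquet") {
      arrow::write_parquet(d, file.path(out_dir, paste0(name, ".parquet")))
    } else {
      utils::write.csv(d, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  tick("write", {
    write_tbl(sim$patients, "patients")
    write_tbl(sim$vitals_observed, "vitals_observed")
    write_tbl(sim$events, "events")
    write_tbl(sim$resolved, "events_resolved")
    write_tbl(sim$decisions, "decisions")
    write_tbl(sim$dispatch_log, "dispatch_log")
    write_tbl(sim$predictions, "predictions")
    write_tbl(imputation_long(res$imputation), "imputations_long")
    write_tbl(render_report(res)$hypotheses, "table2_hypotheses")
    write_tbl(render_report(res)$cohort, "table1_cohort")
    jsonlite::write_json(results_json(res), file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("rcstrial")),
    config = unclass(config),
    config_hash = config_hash(config),
    stage_seeds = as.list(stage_seeds(config$seed)),
    imputation = list(m = m, maxit = maxit, engine = engine),
    timings_sec = as.list(timings),
    outputs = list(dir = out_dir, format = format))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# stable polynomial hash of the configuration's deparsed form (avoids a
# digest dependency; collision resistance is irrelevant here)
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# flatten the headline numbers for JSON export
results_json <- function(res) {
  list(
    flow = unclass(res$flow)[c("randomized_rcs", "protocol_violation_rcs",
                               "optout_excluded_rcs", "analyzed_rcs",
                               "analyzed_patients")],
    accuracy = as.list(res$accuracy_by_arm),
    random_baseline = res$random_baseline,
    primary = res$primary[c("or", "or_ci_low", "or_ci_high", "p_value")],
    secondary_composite = res$secondary_composite[
      c("or", "or_ci_low", "or_ci_high", "p_value")],
    secondary_news_diff = res$secondary_news_diff[c("z", "p_value")],
    news_diff_by_arm = as.list(res$news_diff_by_arm),
    compliance = list(
      control = res$compliance$by_arm$rate[1],
      intervention = res$compliance$by_arm$rate[2],
      high_confidence = res$compliance$by_confidence$rate[1],
      low_confidence = res$compliance$by_confidence$rate[2]),
    counterfactual_full_compliance = list(
      accuracy = res$counterfactual_full_compliance$accuracy[["intervention"]],
      or = res$counterfactual_full_compliance$pooled$or,
      p_value = res$counterfactual_full_compliance$pooled$p_value),
    blended = list(
      accuracy = res$blended_strategy$accuracy[["intervention"]],
      or = res$blended_strategy$pooled$or),
    time_trends = res$time_trends,
    drift_slope = res$drift$slope)
}

#' Render human-readable summary tables from an analysis
#'
#' Produces a cohort-description table (counts, medians with bootstrap
#' percentile CIs by arm) and a hypothesis-summary table (the primary and
#' two secondary hypotheses with ORs/z, CIs and p values), as plain data
#' frames suitable for delimited-text export.
#'
#' @param res An `rcs_results` object from [analyze_trial()].
#' @param n_boot Bootstrap resamples for the cohort-table CIs.
#' @param boot_seed Seed for the bootstrap resampling (fixed so the rendered
#'   report is reproducible).
#' @return List with data frames `cohort` and `hypotheses`.
#' @export
render_report <- function(res, n_boot = 1000, boot_seed = 191) {
  stopifnot(inherits(res, "rcs_results"))
  oc <- res$outcome_sets[[1]]
  flow <- res$flow
  boot_ci <- function(x, stat, n_boot) {
    if (!length(x)) return(c(NA, NA))
    s <- with_seed(boot_seed,
                   replicate(n_boot, stat(sample(x, replace = TRUE))))
    stats::quantile(s, c(0.025, 0.975), names = FALSE)
  }
  fmt <- function(v, ci, d = 2) {
    sprintf(paste0("%.", d, "f [%.", d, "f, %.", d, "f]"), v, ci[1], ci[2])
  }
  cohort <- data.frame(
    characteristic = c("Number of RCS included", "Number of patients included"),
    control = c(flow$analyzed_rcs_by_arm[["control"]],
                flow$analyzed_patients_by_arm[["control"]]),
    intervention = c(flow$analyzed_rcs_by_arm[["intervention"]],
                     flow$analyzed_patients_by_arm[["intervention"]]),
    stringsAsFactors = FALSE)
  acc <- res$accuracy_by_arm
  cohort <- rbind(cohort, data.frame(
    characteristic = "Correct prioritization (proportion)",
    control = round(acc[["control"]], 3),
    intervention = round(acc[["intervention"]], 3)))
  # median NEWS difference by arm with bootstrap percentile CIs
  med_row <- vapply(c("control", "intervention"), function(a) {
    x <- oc$news_diff[oc$arm == a]
    fmt(stats::median(x), boot_ci(x, stats::median, n_boot))
  }, character(1))
  cohort <- rbind(cohort, data.frame(
    characteristic = "Median NEWS difference (prioritized - delayed)",
    control = med_row[["control"]], intervention = med_row[["intervention"]]))

  hyp <- data.frame(
    hypothesis = c(
      "Primary: prioritized patient has highest NEWS (pooled logistic)",
      "Secondary: prioritized patient has highest composite outcome score (pooled logistic)",
      "Secondary: larger NEWS difference in intervention arm (pooled rank-sum)"),
    result = c(
      sprintf("OR %.2f (95%% CI [%.2f, %.2f], p = %.3f)", res$primary$or,
              res$primary$or_ci_low, res$primary$or_ci_high, res$primary$p_value),
      sprintf("OR %.2f (95%% CI [%.2f, %.2f], p = %.3f)",
              res$secondary_composite$or, res$secondary_composite$or_ci_low,
              res$secondary_composite$or_ci_high, res$secondary_composite$p_value),
      if (is.na(res$secondary_news_diff$z)) "z undefined (all tied)" else
        sprintf("z = %.3f, p = %.3f", res$secondary_news_diff$z,
                res$secondary_news_diff$p_value)),
    stringsAsFactors = FALSE)
  list(cohort = cohort, hypotheses = hyp)
}
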