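# build a small vitals table with controllable MCAR missingness
make_missing_vitals <- function(n = 300, rate = 0.15, seed = 5,
                                components = c("respiratory_rate", "spo2",
                                               "systolic_bp", "pulse",
                                               "temperature", "on_oxygen",
                                               "consciousness")) {
  cfg <- trial_config(n_rcs = ceiling(n / 2), rcs_size_dist = c("2" = 1),
                      seed = seed)
  pats <- generate_cohort(cfg)$patients[seq_len(n), ]
  vit <- generate_vitals(pats, cfg)[seq_len(n), ]
  set.seed(seed + 1)
  for (comp in components) {
    vit[[comp]][runif(n) < rate] <- NA
  }
  list(vitals = vit, patients = pats, config = cfg)
}

test_that("a complete table yields m identical copies of the input", {
  f <- make_missing_vitals(n = 60, rate = 0)
  imp <- impute_components(f$vitals, m = 3, maxit = 2, engine = "pmm", seed = 1)
  for (k in 1:3) expect_identical(imp$completed[[k]], f$vitals)
})

test_that("observed cells are never altered and draws stay in observed range", {
  f <- make_missing_vitals(n = 250, rate = 0.12, seed = 9)
  for (eng in c("pmm", "rf")) {
    imp <- impute_components(f$vitals, predictors = f$patients[, c("patient_id", "age", "sex")],
                             m = 2, maxit = 3, engine = eng, seed = 4)
    for (k in seq_len(imp$m)) {
      comp_tab <- imp$completed[[k]]
      expect_false(anyNA(comp_tab[-1]))
      for (comp in imp$targets) {
        obs <- !is.na(f$vitals[[comp]])
        expect_identical(comp_tab[[comp]][obs], f$vitals[[comp]][obs])
        if (is.numeric(f$vitals[[comp]])) {
          expect_gte(min(comp_tab[[comp]]), min(f$vitals[[comp]], na.rm = TRUE))
          expect_lte(max(comp_tab[[comp]]), max(f$vitals[[comp]], na.rm = TRUE))
        }
      }
      # imputed categorical values are valid levels
      expect_true(all(comp_tab$consciousness %in%
                        c("Alert", "Confusion", "Voice", "Pain", "Unresponsive")))
      expect_type(comp_tab$on_oxygen, "logical")
    }
  }
})

test_that("a single missing cell is filled from within the observed range", {
  f <- make_missing_vitals(n = 500, rate = 0)
  f$vitals$temperature[77] <- NA
  imp <- impute_components(f$vitals, m = 4, maxit = 2, engine = "pmm", seed = 2)
  for (k in 1:4) {
    v <- imp$completed[[k]]$temperature[77]
    expect_gte(v, min(f$vitals$temperature, na.rm = TRUE))
    expect_lte(v, max(f$vitals$temperature, na.rm = TRUE))
  }
})

test_that("MCAR imputation reproduces the complete-data mean NEWS", {
  # complete-data oracle: NEWS before masking any cells
  cfg <- trial_config(n_rcs = 400, rcs_size_dist = c("2" = 1), seed = 23)
  pats <- generate_cohort(cfg)$patients
  vit_full <- generate_vitals(pats, cfg)
  truth <- mean(compute_news(vit_full))

  vit <- vit_full
  set.seed(24)
  n <- nrow(vit)
  for (comp in c("respiratory_rate", "spo2", "systolic_bp", "pulse",
                 "temperature")) {
    vit[[comp]][runif(n) < 0.15] <- NA
  }
  imp <- impute_components(vit, predictors = pats[, c("patient_id", "age", "sex")],
                           m = 10, maxit = 5, engine = "pmm", seed = 25)
  pooled_means <- vapply(imp$completed, function(v) mean(compute_news(v)),
                         numeric(1))
  mc_se <- stats::sd(compute_news(vit_full)) / sqrt(n)
  expect_lt(abs(mean(pooled_means) - truth), 2 * mc_se + 0.05)
})

test_that("an all-missing column is refused", {
  f <- make_missing_vitals(n = 50, rate = 0)
  f$vitals$pulse <- NA_real_
  expect_error(impute_components(f$vitals, m = 2, engine = "pmm"),
               "no observed values")
})

test_that("mixing diagnostics are 1 for identical chains and flag divergence", {
  imp <- structure(list(
    m = 3, maxit = 6, engine = "pmm", targets = "pulse",
    chain_mean = list(pulse = matrix(rep(c(70, 71, 72, 71, 70, 71), 3),
                                     ncol = 3)),
    chain_var = list(pulse = matrix(1, 6, 3))), class = "rcs_imputation")
  d <- diagnose_imputation(imp)
  expect_equal(d$ratio, 1)
  expect_false(d$flagged)

  # chains stuck at different levels must be flagged
  imp$chain_mean$pulse <- cbind(rep(60, 6) + rnorm(6, 0, 0.1),
                                rep(80, 6) + rnorm(6, 0, 0.1),
                                rep(100, 6) + rnorm(6, 0, 0.1))
  d2 <- diagnose_imputation(imp)
  expect_true(d2$flagged)
  expect_error(diagnose_imputation(structure(list(m = 1, maxit = 5),
                                             class = "rcs_imputation")),
               "2 chains")
})

test_that("a default-style run on synthetic data shows good mixing", {
  cfg <- trial_config(n_rcs = 900, seed = 29)  # ~2,000 patients
  pats <- generate_cohort(cfg)$patients
  vit <- generate_vitals(pats, cfg)
  mm <- apply_missingness(vit, pats, cfg)
  imp <- impute_components(mm$final, predictors = pats[, c("patient_id", "age", "sex")],
                           m = 5, maxit = 10, engine = "pmm", seed = 30)
  d <- diagnose_imputation(imp)
  expect_false(any(d$flagged))
})

test_that("median NEWS across imputations matches a direct computation", {
  f <- make_missing_vitals(n = 80, rate = 0.2, seed = 13)
  imp <- impute_components(f$vitals, m = 5, maxit = 2, engine = "pmm", seed = 14)
  med <- median_news(imp)
  totals <- sapply(imp$completed, compute_news)
  expect_equal(med$news_median, apply(totals, 1, median))
  # complete rows have identical totals in every imputation
  complete_rows <- stats::complete.cases(f$vitals)
  expect_true(all(apply(totals[complete_rows, , drop = FALSE], 1,
                        function(x) length(unique(x)) == 1)))
})

test_that("long-format serialization stacks all imputations", {
  f <- make_missing_vitals(n = 40, rate = 0.1, seed = 3)
  imp <- impute_components(f$vitals, m = 3, maxit = 2, engine = "pmm", seed = 6)
  long <- imputation_long(imp)
  expect_equal(nrow(long), 3 * 40)
  expect_equal(unique(long$.imp), 1:3)
})
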