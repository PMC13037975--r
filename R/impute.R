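#' Multiple imputation of NEWS components by chained equations
#'
#' Imputes missing vital-sign components with multivariate imputation by
#' chained equations (MICE). Each chain initializes missing cells by
#' sampling observed values, then cycles through the incomplete components,
#' refitting a conditional model of each on all other components plus the
#' auxiliary predictors and drawing fresh imputations, for `maxit`
#' iterations. `m` independent chains yield `m` completed tables. NEWS
#' totals are never imputed directly: score completed tables with
#' [compute_news()] afterwards.
#'
#' Two engines are provided. `"rf"` (the default) draws each imputation
#' from the terminal-node donors of a random forest: a tree is picked at
#' random, the missing row is dropped down it, and an observed response is
#' sampled from the co-members of its leaf. `"pmm"` is predictive mean
#' matching on a linear model (5 donors); the ordinal components
#' (consciousness on the ACVPU scale, supplemental oxygen) are matched on
#' their ordered integer codes, so draws are always valid levels. Both
#' engines are donor-based, so imputed values always lie within the
#' observed range.
#'
#' @param vitals Vitals table with missing cells (`patient_id` plus the
#'   seven component columns).
#' @param predictors Optional data frame of auxiliary, fully observed
#'   covariates keyed by `patient_id` (e.g. age and sex); used as
#'   predictors in every conditional model but never imputed.
#' @param m Number of imputations (chains). Default 10.
#' @param maxit Iterations per chain. Default 10.
#' @param engine `"rf"` or `"pmm"`.
#' @param seed Integer seed governing all chains.
#' @param num_trees Trees per random forest (`"rf"` engine).
#' @return An object of class `rcs_imputation`: a list with `completed`
#'   (list of `m` completed tables), `chains` (per-component chain-mean and
#'   chain-variance trajectories for [diagnose_imputation()]), and the call
#'   parameters.
#' @export
impute_components <- function(vitals, predictors = NULL, m = 10, maxit = 10,
                              engine = c("rf", "pmm"), seed = 1L,
                              num_trees = 30L) {
  engine <- match.arg(engine)
  comps <- c("respiratory_rate", "spo2", "on_oxygen", "systolic_bp",
             "pulse", "consciousness", "temperature")
  miss_cols <- setdiff(comps, names(vitals))
  if (length(miss_cols)) stop("vitals lacks column(s): ",
                              paste(miss_cols, collapse = ", "))
  if (m < 1) stop("m must be >= 1")

  # working copy on ordered integer codes for the categorical components
  work <- vitals[comps]
  work$on_oxygen <- as.integer(vitals$on_oxygen)
  work$consciousness <- as.integer(factor(vitals$consciousness,
                                          levels = .acvpu_levels))
  bad_cons <- !is.na(vitals$consciousness) & is.na(work$consciousness)
  if (any(bad_cons)) stop("invalid ACVPU level(s) in consciousness")
  aux <- NULL
  if (!is.null(predictors)) {
    stopifnot("patient_id" %in% names(predictors))
    aux <- predictors[match(vitals$patient_id, predictors$patient_id),
                      setdiff(names(predictors), "patient_id"), drop = FALSE]
    if (anyNA(aux)) stop("auxiliary predictors must be fully observed")
  }

  targets <- comps[vapply(work, anyNA, logical(1))]
  all_missing <- comps[vapply(work, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    stop("component(s) with no observed values cannot be imputed: ",
         paste(all_missing, collapse = ", "))
  }

  chain_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, m))
  completed <- vector("list", m)
  # chains[[component]] : maxit x m matrices of imputed-cell means and vars
  chain_mean <- chain_var <- lapply(targets, function(x)
    matrix(NA_real_, nrow = maxit, ncol = m))
  names(chain_mean) <- names(chain_var) <- targets

  for (k in seq_len(m)) {
    filled <- with_seed(chain_seeds[k], {
      cur <- work
      for (nm in targets) {
        na <- is.na(cur[[nm]])
        cur[[nm]][na] <- sample(cur[[nm]][!na], sum(na), replace = TRUE)
      }
      if (length(targets)) {
        for (it in seq_len(maxit)) {
          for (nm in targets) {
            na <- is.na(work[[nm]])
            x <- cur[setdiff(comps, nm)]
            if (!is.null(aux)) x <- cbind(x, aux)
            drawn <- if (engine == "rf") {
              draw_rf(cur[[nm]], x, na, num_trees)
            } else {
              draw_pmm(cur[[nm]], x, na)
            }
            cur[[nm]][na] <- drawn
            chain_mean[[nm]][it, k] <- mean(drawn)
            chain_var[[nm]][it, k] <- stats::var(drawn)
          }
        }
      }
      cur
    })
    out <- vitals
    for (nm in setdiff(targets, c("on_oxygen", "consciousness"))) {
      out[[nm]] <- filled[[nm]]
    }
    if ("on_oxygen" %in% targets) out$on_oxygen <- filled$on_oxygen == 1L
    if ("consciousness" %in% targets) {
      out$consciousness <- .acvpu_levels[filled$consciousness]
    }
    completed[[k]] <- out
  }
  structure(list(m = m, maxit = maxit, engine = engine, seed = seed,
                 targets = targets, completed = completed,
                 chain_mean = chain_mean, chain_var = chain_var),
            class = "rcs_imputation")
}

# random-forest conditional draw: sample an observed response from the
# terminal-node co-members of a randomly chosen tree
draw_rf <- function(y, x, na, num_trees) {
  obs <- which(!na); mis <- which(na)
  fit <- ranger::ranger(y = y[obs], x = x[obs, , drop = FALSE],
                        num.trees = num_trees, min.node.size = 5,
                        num.threads = 1)
  nodes <- stats::predict(fit, data = x, type = "terminalNodes",
                          num.threads = 1)$predictions
  tree <- sample.int(num_trees, length(mis), replace = TRUE)
  vapply(seq_along(mis), function(i) {
    donors <- obs[nodes[obs, tree[i]] == nodes[mis[i], tree[i]]]
    if (!length(donors)) donors <- obs
    y[donors[sample.int(length(donors), 1L)]]
  }, numeric(1))
}

# predictive mean matching, type 0, 5 donors
draw_pmm <- function(y, x, na, donors = 5L) {
  obs <- which(!na); mis <- which(na)
  mm <- stats::model.matrix(~ ., data = as.data.frame(x))
  fit <- stats::lm.fit(mm[obs, , drop = FALSE], y[obs])
  keep <- !is.na(fit$coefficients)
  yhat <- mm[, keep, drop = FALSE] %*% fit$coefficients[keep]
  vapply(mis, function(i) {
    d <- abs(yhat[obs] - yhat[i])
    cand <- obs[order(d)[seq_len(min(donors, length(obs)))]]
    y[cand[sample.int(length(cand), 1L)]]
  }, numeric(1))
}

#' Convergence diagnostics for a chained-equations run
#'
#' Computes, for each imputed component, a between/within-chain variance
#' ratio on the chain means of the imputed cells, discarding the first two
#' iterations as burn-in: `sqrt(1 + max(0, B - W/I) / W)`, where `B` is the
#' variance of the per-chain means, `W` the mean within-chain variance
#' across the `I` retained iterations, and the `W/I` term removes the
#' sampling noise a well-mixed chain mean carries, so the statistic centres
#' on 1 at stationarity. Chains with identical trajectories give exactly 1;
#' chains stuck at different levels inflate `B` far beyond `W` and exceed
#' `threshold`.
#'
#' @param imp An `rcs_imputation` object with at least 2 chains and 2
#'   iterations.
#' @param threshold Flagging threshold (default 1.2).
#' @return Data frame with `component`, `ratio`, `flagged`.
#' @export
diagnose_imputation <- function(imp, threshold = 1.2) {
  stopifnot(inherits(imp, "rcs_imputation"))
  if (imp$m < 2L) stop("diagnostics require at least 2 chains")
  if (imp$maxit < 2L) stop("diagnostics require at least 2 iterations")
  burn <- min(2L, imp$maxit - 2L)
  half <- seq.int(max(1L, burn + 1L), imp$maxit)
  out <- lapply(imp$targets, function(nm) {
    tr <- imp$chain_mean[[nm]][half, , drop = FALSE]
    W <- mean(apply(tr, 2, stats::var))
    B <- stats::var(colMeans(tr))
    excess <- max(0, B - W / length(half))
    ratio <- if (isTRUE(all.equal(B, 0))) 1 else if (W == 0) Inf else
      sqrt(1 + excess / W)
    data.frame(component = nm, ratio = ratio, flagged = ratio > threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.rcs_imputation <- function(x, ...) {
  cat(sprintf("<rcs_imputation> m = %d, maxit = %d, engine = %s\n",
              x$m, x$maxit, x$engine))
  cat(sprintf("  imputed components: %s\n",
              if (length(x$targets)) paste(x$targets, collapse = ", ")
              else "none (input complete)"))
  invisible(x)
}

#' Median NEWS across imputations (sensitivity analysis)
#'
#' Returns each patient's median NEWS total across the `m` completed
#' datasets. This realizes the simpler single-dataset evaluation rule
#' (analyse the median of the imputations) kept as a sensitivity analysis;
#' the primary analyses pool per-imputation estimates with Rubin's rules
#' instead, which propagates between-imputation uncertainty rather than
#' discarding it.
#'
#' @param imp An `rcs_imputation` object.
#' @return Data frame with `patient_id` and `news_median`.
#' @export
median_news <- function(imp) {
  stopifnot(inherits(imp, "rcs_imputation"))
  totals <- vapply(imp$completed, compute_news, integer(nrow(imp$completed[[1]])))
  data.frame(patient_id = imp$completed[[1]]$patient_id,
             news_median = apply(as.matrix(totals), 1, stats::median),
             stringsAsFactors = FALSE)
}

#' Serialize an imputation set to long format
#'
#' Stacks the `m` completed tables with an imputation-index column,
#' matching the one-table-per-row layout used for export.
#'
#' @param imp An `rcs_imputation` object.
#' @return A data frame with an `.imp` column in `1:m`.
#' @export
imputation_long <- function(imp) {
  stopifnot(inherits(imp, "rcs_imputation"))
  do.call(rbind, lapply(seq_len(imp$m), function(k) {
    cbind(.imp = k, imp$completed[[k]])
  }))
}
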