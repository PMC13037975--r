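#' Pool estimates across imputations with Rubin's rules
#'
#' Combines per-imputation point estimates `Q` and within-imputation
#' variances `U`: pooled point `Qbar = mean(Q)`, between-imputation
#' variance `B = var(Q)`, total variance `T = Ubar + (1 + 1/m) B`, with
#' Barnard--Rubin small-sample degrees of freedom when the complete-data
#' degrees of freedom `df_com` are supplied (otherwise the older
#' large-sample formula `(m - 1) / lambda^2` is used).
#'
#' @param Q Numeric vector of per-imputation estimates.
#' @param U Numeric vector of per-imputation variances (same length).
#' @param df_com Complete-data degrees of freedom (e.g. `n - p`), or `NULL`.
#' @return A list of class `pooled_estimate` with `point`, `within_var`,
#'   `between_var`, `total_var`, `df`, `se`, `statistic`, `p_value`,
#'   `ci_low`, `ci_high`, `m`.
#' @export
#' @examples
#' pool_rubin(Q = c(1, 2, 3), U = c(1, 1, 1))  # point 2, B 1, T 7/3
pool_rubin <- function(Q, U, df_com = NULL) {
  m <- length(Q)
  if (length(U) != m) stop("Q and U must have equal length")
  if (m < 1) stop("no estimates to pool")
  qbar <- mean(Q)
  ubar <- mean(U)
  B <- if (m > 1) stats::var(Q) else 0
  Tvar <- ubar + (1 + 1 / m) * B
  lambda <- if (Tvar > 0) (1 + 1 / m) * B / Tvar else 0
  df <- if (m == 1 || lambda < .Machine$double.eps) {
    if (!is.null(df_com)) df_com else Inf
  } else {
    df_old <- (m - 1) / lambda^2
    if (is.null(df_com)) {
      df_old
    } else {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    }
  }
  se <- sqrt(Tvar)
  stat <- if (se > 0) qbar / se else sign(qbar) * Inf
  p <- 2 * stats::pt(-abs(stat), df = df)
  crit <- stats::qt(0.975, df = df)
  structure(list(point = qbar, within_var = ubar, between_var = B,
                 total_var = Tvar, df = df, se = se, statistic = stat,
                 p_value = p, ci_low = qbar - crit * se,
                 ci_high = qbar + crit * se, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$point, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  within var %.4g, between var %.4g, total %.4g, df %.1f, p = %.4g\n",
              x$within_var, x$between_var, x$total_var, x$df, x$p_value))
  invisible(x)
}

# Firth-penalized logistic regression (Jeffreys prior) used as a fallback
# under perfect separation: IRLS on the modified score with hat-value
# correction.
firth_logistic <- function(X, y, maxit = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    XtWX <- crossprod(X, XW)
    inv <- solve(XtWX)
    h <- rowSums((X %*% inv) * XW)  # hat diagonal
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- inv %*% U
    beta <- beta + as.numeric(delta)
    if (max(abs(delta)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  vcov <- solve(crossprod(X, X * w))
  list(coefficients = beta, vcov = vcov)
}

#' Pooled logistic regression over multiply imputed datasets
#'
#' Fits the same logistic regression to each completed dataset by maximum
#' likelihood and pools the coefficient of interest on the log-odds scale
#' with [pool_rubin()], using Barnard--Rubin degrees of freedom with
#' complete-data df `n - p`. Results are reported as an odds ratio with a
#' 95% CI. If any fit shows signs of perfect separation (non-convergence
#' or an absurd standard error), that imputation is refitted with
#' Firth-penalized likelihood and the output is flagged.
#'
#' @param datasets List of data frames (one per imputation).
#' @param formula Model formula whose response is binary (0/1 or logical).
#' @param term Name of the coefficient to pool (default: first non-intercept
#'   term of the fitted model).
#' @return A `pooled_estimate` with extra fields `or`, `or_ci_low`,
#'   `or_ci_high`, `term` and `penalized` (which imputations fell back to
#'   the Firth fit).
#' @export
pooled_logistic <- function(datasets, formula, term = NULL) {
  if (length(datasets) < 1L) stop("need at least one dataset")
  Q <- U <- numeric(length(datasets))
  penalized <- logical(length(datasets))
  df_com <- NULL
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    fit <- suppressWarnings(stats::glm(formula, family = stats::binomial(), data = d))
    if (is.null(term)) {
      term <- names(stats::coef(fit))[2L]
    }
    se <- sqrt(diag(stats::vcov(fit)))[term]
    separated <- !fit$converged || is.na(se) || se > 50 ||
      abs(stats::coef(fit)[term]) > 20
    if (separated) {
      mf <- stats::model.frame(formula, data = d)
      X <- stats::model.matrix(attr(mf, "terms"), mf)
      y <- as.numeric(stats::model.response(mf))
      ff <- firth_logistic(X, y)
      j <- match(term, colnames(X))
      Q[k] <- ff$coefficients[j]
      U[k] <- ff$vcov[j, j]
      penalized[k] <- TRUE
      df_com <- nrow(X) - ncol(X)
    } else {
      Q[k] <- stats::coef(fit)[term]
      U[k] <- se^2
      df_com <- fit$df.residual
    }
  }
  pooled <- pool_rubin(Q, U, df_com = df_com)
  pooled$term <- term
  pooled$or <- exp(pooled$point)
  pooled$or_ci_low <- exp(pooled$ci_low)
  pooled$or_ci_high <- exp(pooled$ci_high)
  pooled$penalized <- which(penalized)
  pooled
}

# Wilcoxon rank-sum z statistic with normal approximation and tie
# correction (no continuity correction); positive z means group 2 tends
# to exceed group 1.
wilcoxon_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  ties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(NA_real_)
  -(W - mu) / sqrt(sigma2)  # sign flipped so larger y => positive z
}

#' Pooled Wilcoxon rank-sum test over multiply imputed datasets
#'
#' Computes the rank-sum z statistic in each completed dataset and pools
#' the z values treating them as estimates with unit within-imputation
#' variance: pooled `z = mean(z) / sqrt(1 + (1 + 1/m) var(z))`, with a
#' two-sided normal p value. If the data are entirely tied in any
#' imputation the z statistic is undefined and reported as such.
#'
#' @param values_by_arm List of `m` lists, each holding numeric vectors
#'   `control` and `intervention`; or a function applied to
#'   `datasets[[k]]`. For convenience you may instead pass `datasets`
#'   together with `value` and `arm` column names.
#' @param datasets,value,arm Alternative interface: list of completed data
#'   frames plus the names of the value and arm columns (arm levels
#'   `control`/`intervention`).
#' @return A list of class `pooled_z` with `z`, `p_value`, `z_values`,
#'   `between_var`, `m`.
#' @export
#' @examples
#' pooled_wilcoxon(list(
#'   list(control = c(1, 2, 3), intervention = c(2, 3, 4)),
#'   list(control = c(1, 2, 2), intervention = c(3, 3, 4))))
pooled_wilcoxon <- function(values_by_arm = NULL, datasets = NULL,
                            value = "news_diff", arm = "arm") {
  if (is.null(values_by_arm)) {
    values_by_arm <- lapply(datasets, function(d) {
      list(control = d[[value]][d[[arm]] == "control"],
           intervention = d[[value]][d[[arm]] == "intervention"])
    })
  }
  z <- vapply(values_by_arm, function(v) {
    wilcoxon_z(v$control, v$intervention)
  }, numeric(1))
  if (anyNA(z)) {
    return(structure(list(z = NA_real_, p_value = NA_real_, z_values = z,
                          between_var = NA_real_, m = length(z),
                          note = "z undefined: all values tied in >=1 imputation"),
                     class = "pooled_z"))
  }
  m <- length(z)
  B <- if (m > 1) stats::var(z) else 0
  zp <- mean(z) / sqrt(1 + (1 + 1 / m) * B)
  structure(list(z = zp, p_value = 2 * stats::pnorm(-abs(zp)),
                 z_values = z, between_var = B, m = m),
            class = "pooled_z")
}

#' @export
print.pooled_z <- function(x, ...) {
  if (is.na(x$z)) {
    cat("pooled rank-sum z undefined (all values tied)\n")
  } else {
    cat(sprintf("pooled rank-sum z = %.3f, p = %.4g (m = %d, between var %.3g)\n",
                x$z, x$p_value, x$m, x$between_var))
  }
  invisible(x)
}
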