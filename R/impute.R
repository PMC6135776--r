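#' Multiple imputation of missing cohort values
#'
#' Produces `m` completed copies of the table. Continuous variables are
#' imputed by predictive mean matching: a linear model of the variable on
#' the complete covariates is fitted to the observed rows, coefficients
#' are drawn from their approximate posterior (so imputations vary across
#' copies), and each missing row receives the observed value of one of the
#' `donors` nearest cases by predicted value. Categorical variables are
#' imputed by a fitted categorical draw: a logistic model (two levels) or
#' the observed class proportions, sampled per missing row.
#'
#' Defaults follow the analysis protocol of 100 imputations; smaller `m`
#' is appropriate for quick runs.
#'
#' @param data Data frame; columns named in `exclude` (default
#'   `"case_id"`) are never imputed or used as predictors.
#' @param m Number of imputed copies (default 100).
#' @param seed Integer seed.
#' @param donors Donor-pool size for predictive mean matching (default 5).
#' @param exclude Columns to leave untouched.
#' @return List of `m` completed data frames. A column that is entirely
#'   missing is an error. With no missing values, `m` identical copies
#'   are returned.
#' @export
impute_missing <- function(data, m = 100, seed = NULL, donors = 5,
                           exclude = "case_id") {
  stopifnot(is.data.frame(data), m >= 1)
  cols <- setdiff(names(data), exclude)
  all_missing <- cols[vapply(cols, function(cc) all(is.na(data[[cc]])),
                             logical(1L))]
  if (length(all_missing) > 0L) {
    stop("column(s) entirely missing cannot be imputed: ",
         paste(all_missing, collapse = ", "))
  }
  incomplete <- cols[vapply(cols, function(cc) anyNA(data[[cc]]),
                            logical(1L))]
  if (length(incomplete) == 0L) {
    return(replicate(m, data, simplify = FALSE))
  }
  complete_cols <- setdiff(cols, incomplete)
  rng <- local_rng(seed)
  lapply(seq_len(m), function(i) {
    out <- data
    for (cc in incomplete) {
      miss <- is.na(out[[cc]])
      out[[cc]][miss] <- if (is.numeric(out[[cc]])) {
        impute_pmm(out, cc, complete_cols, miss, donors, rng)
      } else {
        impute_categorical(out, cc, complete_cols, miss, rng)
      }
    }
    out
  })
}

# predictive mean matching with a posterior draw of the coefficients
impute_pmm <- function(data, target, predictors, miss, donors, rng) {
  y <- data[[target]]
  X <- impute_design(data, predictors)
  obs <- which(!miss)
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  keep <- !is.na(fit$coefficients)
  Xk <- X[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xk[obs, , drop = FALSE], y[obs])
  beta <- fit$coefficients
  res <- fit$residuals
  df <- max(length(obs) - length(beta), 1L)
  sigma2 <- sum(res^2) / df
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(Xk[obs, , drop = FALSE]))),
                      error = function(e) NULL)
  beta_star <- if (is.null(XtX_inv)) beta else {
    sigma2_star <- sigma2 * df /
      rng$draw(function() stats::rchisq(1L, df))
    rng$draw(function() {
      beta + drop(chol(sigma2_star * XtX_inv + diag(1e-12, length(beta))) %*%
                    stats::rnorm(length(beta)))
    })
  }
  pred_obs <- drop(Xk[obs, , drop = FALSE] %*% beta)
  pred_mis <- drop(Xk[miss, , drop = FALSE] %*% beta_star)
  vapply(pred_mis, function(p) {
    nearest <- order(abs(pred_obs - p))[seq_len(min(donors, length(obs)))]
    donor <- rng$draw(function() nearest[sample.int(length(nearest), 1L)])
    y[obs[donor]]
  }, numeric(1L))
}

# fitted categorical draw: logistic model for two levels, observed
# proportions otherwise
impute_categorical <- function(data, target, predictors, miss, rng) {
  y <- factor(data[[target]])
  obs <- which(!miss)
  lev <- levels(droplevels(y[obs]))
  if (length(lev) == 2L && length(predictors) > 0L) {
    X <- impute_design(data, predictors)
    fit <- suppressWarnings(stats::glm.fit(X[obs, , drop = FALSE],
                                           as.integer(y[obs] == lev[2L]),
                                           family = stats::binomial()))
    eta <- drop(X[miss, , drop = FALSE] %*% ifelse(is.na(fit$coefficients),
                                                   0, fit$coefficients))
    pr <- stats::plogis(eta)
    draw <- rng$draw(function() stats::rbinom(length(pr), 1L, pr))
    as.character(factor(lev[draw + 1L], levels = levels(y)))
  } else {
    prop <- table(y[obs])
    rng$draw(function() {
      sample(names(prop), sum(miss), replace = TRUE,
             prob = as.numeric(prop))
    })
  }
}

impute_design <- function(data, predictors) {
  if (length(predictors) == 0L) {
    return(matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(
    stats::as.formula(paste("~", paste(predictors, collapse = " + "))),
    data = data)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and variances: the pooled
#' estimate is the mean, the total variance is
#' `W + (1 + 1/m) * B` (within-imputation mean variance plus inflated
#' between-imputation variance), and inference uses the t reference with
#' Rubin's degrees of freedom
#' `(m - 1) * (1 + W / ((1 + 1/m) * B))^2`.
#'
#' @param estimates Numeric vector of per-imputation estimates (on the
#'   coefficient scale).
#' @param variances Per-imputation squared standard errors, same length.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `within`, `between`, `total_variance`,
#'   `se`, `df`, `ci_low`, `ci_high`, `p_value` (two-sided test of zero).
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (length(variances) != m) stop("estimates and variances differ in length")
  stopifnot(m >= 1)
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  total <- w + (1 + 1 / m) * b
  df <- if (b > 0 && m > 1) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  se <- sqrt(total)
  alpha <- 1 - conf_level
  tq <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else
    stats::qnorm(1 - alpha / 2)
  p <- if (se > 0) {
    2 * stats::pt(-abs(qbar / se), df)
  } else as.numeric(qbar == 0)
  list(estimate = qbar, within = w, between = b, total_variance = total,
       se = se, df = df, ci_low = qbar - tq * se, ci_high = qbar + tq * se,
       p_value = p)
}

#' Pooled report of rank-test results across imputations
#'
#' For Mann-Whitney association tests run on every imputed dataset, the
#' pooled report is the median p-value and median `r^2` across
#' imputations.
#'
#' @param results List of [mann_whitney_assoc()] results.
#' @return List with `p_value` and `r_squared` (medians).
#' @export
pool_rank_tests <- function(results) {
  list(p_value = stats::median(vapply(results, `[[`, 0, "p_value")),
       r_squared = stats::median(vapply(results, `[[`, 0, "r_squared")))
}
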