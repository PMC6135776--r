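#' Mann-Whitney association between a feature and a binary grouping
#'
#' Two-sided rank-sum test of a continuous feature against a two-level
#' grouping, with the strength of association summarised by the
#' coefficient of determination `r^2 = Z^2 / N`, where `Z` is the
#' tie-corrected normal-approximation statistic of the test and `N` the
#' total sample size.
#'
#' @param x Numeric feature values.
#' @param g Binary grouping (two-level factor, or any vector with exactly
#'   two distinct non-missing values).
#' @return List with `p_value` (exact where `stats::wilcox.test` computes
#'   it, otherwise normal approximation), `r_squared`, `z` and `n`.
#' @export
mann_whitney_assoc <- function(x, g) {
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- factor(g[keep])
  if (nlevels(g) != 2L) stop("grouping must have exactly two levels")
  x1 <- x[g == levels(g)[1L]]
  x2 <- x[g == levels(g)[2L]]
  if (length(x1) == 0L || length(x2) == 0L) {
    stop("both groups must be non-empty")
  }
  n1 <- length(x1)
  n2 <- length(x2)
  n <- n1 + n2
  r <- rank(c(x1, x2))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of group 1
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  # continuity-corrected, tie-corrected normal approximation
  z <- if (sigma2 > 0) (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2) else 0
  p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
  list(p_value = p, r_squared = z^2 / n, z = z, n = n)
}

# rank (Mann-Whitney) AUC of a score against a binary outcome
rank_auc <- function(score, outcome) {
  keep <- !is.na(score) & !is.na(outcome)
  score <- score[keep]
  outcome <- outcome[keep]
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

new_effect_estimate <- function(...) {
  structure(list(...), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s (%s -> %s): %s factor %.3f (95%% CI %.3f-%.3f), %s p = %.4g",
              x$feature, format(x$baseline_value, digits = 3),
              format(x$changed_value, digits = 3), x$model,
              x$ratio_factor, x$ci_low, x$ci_high, x$p_type, x$p_value))
  if (!is.na(x$auc)) cat(sprintf(", AUC = %.3f", x$auc))
  cat("\n")
  invisible(x)
}

# quartile contrast of a covariate: Q1 -> Q3 for a continuous feature,
# first -> second level for a two-level categorical one
feature_contrast <- function(values) {
  if (is.numeric(values)) {
    q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    list(continuous = TRUE, baseline = q[1L], changed = q[2L],
         scale = q[2L] - q[1L])
  } else {
    lev <- levels(factor(values))
    if (length(lev) != 2L) {
      stop("categorical features must have exactly two levels")
    }
    list(continuous = FALSE, baseline = lev[1L], changed = lev[2L],
         scale = 1)
  }
}

#' Interquartile-scaled logistic effect of a feature on metastasis
#'
#' Fits a maximum-likelihood logistic regression of the binary 5-year
#' metastasis outcome on the feature (plus any adjusters) and reports the
#' factor of change in odds when the feature moves from its 1st to its 3rd
#' quartile: `exp(beta * (Q3 - Q1))`, with a 95% Wald confidence interval
#' on the same scale. For a two-level categorical feature, the contrast is
#' the change between levels. The p-value is from the likelihood-ratio
#' test dropping the feature. The AUC is the rank AUC of the feature
#' itself in univariate analysis, and the AUC of the fitted model in
#' multivariate (adjusted) analysis.
#'
#' @param data Cohort data frame.
#' @param feature Feature column name.
#' @param adjusters Character vector of adjustment covariate names
#'   (default none).
#' @param outcome Binary outcome column (default `"metastasis_5yr"`).
#' @return An `effect_estimate` with `p_type = "likelihood_ratio"`.
#'   Non-convergence or separation gives `status = "failed"` with `NA`
#'   estimates, never silent numbers.
#' @export
logistic_iqr_effect <- function(data, feature, adjusters = character(0),
                                outcome = "metastasis_5yr") {
  vars <- c(outcome, feature, adjusters)
  stopifnot(all(vars %in% names(data)))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y)) != 2L) {
    stop("outcome must be binary and non-degenerate")
  }
  ctr <- feature_contrast(d[[feature]])
  rhs <- paste(c(feature, adjusters), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste(outcome, "~", rhs)),
                    family = stats::binomial(), data = d)
  fit0 <- stats::glm(
    stats::as.formula(paste(outcome, "~",
                            if (length(adjusters)) paste(adjusters,
                                                         collapse = " + ")
                            else "1")),
    family = stats::binomial(), data = d)
  co <- summary(fit)$coefficients
  feat_row <- grep(paste0("^", feature), rownames(co))[1L]
  beta <- co[feat_row, "Estimate"]
  se <- co[feat_row, "Std. Error"]
  failed <- !fit$converged || !is.finite(se) || se > 100
  p_lr <- stats::pchisq(2 * as.numeric(stats::logLik(fit) - stats::logLik(fit0)),
                        df = 1, lower.tail = FALSE)
  auc <- if (length(adjusters) == 0L && ctr$continuous) {
    rank_auc(d[[feature]], y)
  } else {
    rank_auc(stats::fitted(fit), y)
  }
  zc <- stats::qnorm(0.975)
  new_effect_estimate(
    feature = feature, model = "odds ratio",
    baseline_value = ctr$baseline, changed_value = ctr$changed,
    ratio_factor = if (failed) NA_real_ else exp(beta * ctr$scale),
    ci_low = if (failed) NA_real_ else exp((beta - zc * se) * ctr$scale),
    ci_high = if (failed) NA_real_ else exp((beta + zc * se) * ctr$scale),
    p_value = p_lr, p_type = "likelihood_ratio",
    auc = auc, adjusted = length(adjusters) > 0L, adjusters = adjusters,
    n = nrow(d),
    status = if (failed) "failed" else "ok")
}

#' Interquartile-scaled Cox proportional-hazards effect of a feature
#'
#' Fits a Cox partial-likelihood model of distant-metastasis-free survival
#' on the feature (plus adjusters) and reports the hazard-ratio factor for
#' an interquartile change, `exp(beta * (Q3 - Q1))`, with its 95% CI. The
#' reported p-value is Rao's score test in univariate analysis (which
#' equals the log-rank test for a single two-level categorical feature)
#' and the Wald test of the feature's coefficient in multivariate
#' analysis. The AUC, when requested (`n_boot > 0`), is the
#' optimism-corrected bootstrap AUC of the fitted model
#' ([bootstrap_auc()]).
#'
#' @param data Cohort data frame.
#' @param feature Feature column name.
#' @param adjusters Adjustment covariates (default none).
#' @param time,event Survival columns (defaults `"dmfs_time_years"`,
#'   `"dmfs_event"`).
#' @param n_boot Bootstrap replicates for the AUC; 0 skips it.
#' @param seed Seed for the bootstrap.
#' @return An `effect_estimate` with `p_type` `"score"` or `"wald"`.
#' @export
cox_iqr_effect <- function(data, feature, adjusters = character(0),
                           time = "dmfs_time_years", event = "dmfs_event",
                           n_boot = 0, seed = NULL) {
  vars <- c(time, event, feature, adjusters)
  stopifnot(all(vars %in% names(data)))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  if (sum(d[[event]]) < 1) {
    stop("survival analysis requires at least one event ",
         "(all observations are censored)")
  }
  if (any(d[[time]] <= 0)) {
    stop("survival times must be positive")
  }
  ctr <- feature_contrast(d[[feature]])
  rhs <- paste(c(feature, adjusters), collapse = " + ")
  fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                  ") ~ ", rhs))
  fit <- survival::coxph(fml, data = d)
  s <- summary(fit)
  feat_row <- grep(paste0("^", feature), rownames(s$coefficients))[1L]
  beta <- s$coefficients[feat_row, "coef"]
  se <- s$coefficients[feat_row, "se(coef)"]
  failed <- !is.finite(se) || se > 100
  if (length(adjusters) == 0L) {
    p <- s$sctest[["pvalue"]]
    p_type <- "score"
  } else {
    p <- s$coefficients[feat_row, "Pr(>|z|)"]
    p_type <- "wald"
  }
  auc <- if (n_boot > 0) {
    bootstrap_auc(fml, d, n_boot = n_boot, seed = seed)$auc_corrected
  } else NA_real_
  zc <- stats::qnorm(0.975)
  new_effect_estimate(
    feature = feature, model = "hazard ratio",
    baseline_value = ctr$baseline, changed_value = ctr$changed,
    ratio_factor = if (failed) NA_real_ else exp(beta * ctr$scale),
    ci_low = if (failed) NA_real_ else exp((beta - zc * se) * ctr$scale),
    ci_high = if (failed) NA_real_ else exp((beta + zc * se) * ctr$scale),
    p_value = p, p_type = p_type,
    auc = auc, adjusted = length(adjusters) > 0L, adjusters = adjusters,
    n = nrow(d),
    status = if (failed) "failed" else "ok")
}

#' Optimism-corrected bootstrap AUC of a survival model
#'
#' Internal validation of a Cox model's discrimination by the bootstrap
#' optimism correction: the apparent Somers' `Dxy` of the model fitted to
#' the full data is reduced by the mean optimism over resamples (each
#' resample refits the model, and its `Dxy` on the resample minus its
#' `Dxy` on the original data estimates the over-fit), and mapped to the
#' AUC scale by `AUC = (Dxy + 1) / 2`.
#'
#' @param formula Cox model formula (`survival::Surv(...) ~ ...`).
#' @param data Data frame the model is fitted to.
#' @param n_boot Number of resampling replicates (default 100).
#' @param seed Integer seed.
#' @return List with `auc_apparent`, `auc_corrected`, `dxy_apparent`,
#'   `optimism`, and `n_failed` (replicates whose refit failed; more than
#'   half failing is an error).
#' @export
bootstrap_auc <- function(formula, data, n_boot = 100, seed = NULL) {
  fit <- survival::coxph(formula, data = data)
  conc <- survival::concordance(fit)$concordance
  dxy_app <- 2 * conc - 1
  rng <- local_rng(seed)
  opt <- rep(NA_real_, n_boot)
  resp <- fit$y
  for (b in seq_len(n_boot)) {
    idx <- rng$draw(function() sample.int(nrow(data), nrow(data),
                                          replace = TRUE))
    db <- data[idx, , drop = FALSE]
    fit_b <- tryCatch(survival::coxph(formula, data = db),
                      error = function(e) NULL, warning = function(w) {
                        tryCatch(suppressWarnings(
                          survival::coxph(formula, data = db)),
                          error = function(e) NULL)
                      })
    if (is.null(fit_b)) next
    c_train <- survival::concordance(fit_b)$concordance
    lp_test <- tryCatch(stats::predict(fit_b, newdata = data, type = "lp"),
                        error = function(e) NULL)
    if (is.null(lp_test)) next
    c_test <- survival::concordance(resp ~ lp_test, reverse = TRUE)$concordance
    opt[b] <- (2 * c_train - 1) - (2 * c_test - 1)
  }
  n_failed <- sum(is.na(opt))
  if (n_failed > n_boot / 2) {
    stop("bootstrap AUC failed: ", n_failed, " of ", n_boot,
         " refits did not converge")
  }
  if (n_failed > 0) {
    message("bootstrap AUC: ", n_failed, " failed refit(s) skipped")
  }
  dxy_corr <- dxy_app - mean(opt, na.rm = TRUE)
  list(auc_apparent = (dxy_app + 1) / 2,
       auc_corrected = (dxy_corr + 1) / 2,
       dxy_apparent = dxy_app,
       optimism = mean(opt, na.rm = TRUE),
       n_failed = n_failed)
}

#' Altman's correction of a minimum p-value
#'
#' When a survival cutoff is chosen by scanning for the minimum log-rank
#' p-value, the minimum is over-optimistic; the corrected p-value is
#' `P_cor = -1.63 * P_min * (1 + 2.35 * ln(P_min))`, valid for
#' `P_min < 0.1`, and clipped to `[P_min, 1]`.
#'
#' @param p_min Minimum p-value(s) from the cutoff scan.
#' @return Corrected p-value(s); `NA` (with a warning) where
#'   `p_min >= 0.1`, outside the correction's validity.
#' @export
altman_correction <- function(p_min) {
  out <- rep(NA_real_, length(p_min))
  ok <- !is.na(p_min) & p_min > 0 & p_min < 0.1
  out[ok] <- pmin(1, pmax(p_min[ok],
                          -1.63 * p_min[ok] * (1 + 2.35 * log(p_min[ok]))))
  if (any(!ok & !is.na(p_min))) {
    warning("Altman's correction is only valid for p_min < 0.1; NA returned")
  }
  out
}

#' Minimum-p-value survival cutoff with corrected significance
#'
#' Scans candidate cutoffs of a continuous feature (the observed values
#' within the inner quantile window, default 10-90%), stratifies cases at
#' each cutoff, and computes the two-group log-rank p-value. The cutoff
#' with the minimum p-value is returned together with Altman's corrected
#' p-value ([altman_correction()]) and the Kaplan-Meier curves of the two
#' groups.
#'
#' @param x Feature values.
#' @param time,event Survival outcome vectors.
#' @param quantile_window Inner quantile range of admissible cutoffs.
#' @return Object of class `cutoff_result`: `cutoff`, `group_sizes`
#'   (low = `x <= cutoff`, high), `p_min`, `p_corrected`, `scan` (the
#'   candidate table) and `km` (a `survfit` object for plotting/export).
#'   No admissible cutoff is an error.
#' @export
minp_cutoff <- function(x, time, event, quantile_window = c(0.1, 0.9)) {
  keep <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[keep]
  time <- time[keep]
  event <- event[keep]
  qs <- stats::quantile(x, quantile_window, names = FALSE)
  cand <- sort(unique(x[x >= qs[1L] & x <= qs[2L]]))
  cand <- cand[vapply(cand, function(cc) any(x <= cc) && any(x > cc),
                      logical(1L))]
  if (length(cand) == 0L) {
    stop("no admissible cutoff: feature has too few distinct values in ",
         "the quantile window")
  }
  ps <- vapply(cand, function(cc) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ I(x <= cc))
    stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }, numeric(1L))
  best <- which.min(ps)
  cutoff <- cand[best]
  grp <- factor(ifelse(x <= cutoff, "low", "high"), levels = c("low", "high"))
  km <- survival::survfit(survival::Surv(time, event) ~ grp)
  structure(list(
    cutoff = cutoff,
    group_sizes = table(grp),
    p_min = ps[best],
    p_corrected = suppressWarnings(altman_correction(ps[best])),
    scan = data.frame(cutoff = cand, p = ps),
    km = km
  ), class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("min-p cutoff %.4g (n = %d low / %d high): p_min = %.4g, ",
              x$cutoff, x$group_sizes[["low"]], x$group_sizes[["high"]],
              x$p_min))
  if (is.na(x$p_corrected)) {
    cat("corrected p not applicable (p_min >= 0.1)\n")
  } else {
    cat(sprintf("corrected p = %.4g\n", x$p_corrected))
  }
  invisible(x)
}

#' Export Kaplan-Meier curve coordinates
#'
#' @param km A `survfit` object (e.g. from [minp_cutoff()]`$km`).
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, `lower`, `upper` — plottable with any graphics system.
#' @export
km_coordinates <- function(km) {
  s <- summary(km, censored = TRUE)
  grp <- if (is.null(s$strata)) "all" else sub("^.*=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, survival = s$surv,
             lower = s$lower, upper = s$upper,
             stringsAsFactors = FALSE)
}
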