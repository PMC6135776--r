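test_that("cohort filter applies the exclusion rules with logged counts", {
  manifest <- example_manifest()
  expect_equal(nrow(manifest), 130L)
  expect_equal(as.vector(table(manifest$cohort)[c("site_A", "site_B")]),
               c(90L, 40L))
  expect_message(kept <- filter_cohort(manifest), "28 of 130")
  expect_equal(nrow(kept), 102L)
  expect_equal(as.vector(table(kept$cohort)[c("site_A", "site_B")]),
               c(72L, 30L))
  log <- attr(kept, "exclusion_log")
  expect_equal(sum(log$n_excluded), 28)

  suppressMessages({
    expect_equal(nrow(filter_cohort(manifest[0, ])), 0L)
    clean <- manifest
    clean[, 3:5] <- FALSE
    expect_equal(nrow(filter_cohort(clean)), 130L)
  })
})

test_that("Mann-Whitney association matches exact and permutation oracles", {
  # identical multisets: no association
  same <- mann_whitney_assoc(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))
  expect_lt(same$r_squared, 1e-12)
  expect_equal(same$p_value, 1)

  # fully separated triples: exact two-sided p = 0.1
  sep <- mann_whitney_assoc(c(1, 2, 3, 4, 5, 6),
                            rep(c("a", "b"), each = 3))
  expect_equal(sep$p_value, 0.1)

  # normal approximation agrees with exhaustive permutation: untied
  # samples of 8 per group stay within 0.02
  set.seed(77)
  for (rep in 1:10) {
    x1 <- rnorm(8)
    x2 <- rnorm(8, 0.5)
    res <- mann_whitney_assoc(c(x1, x2), rep(c("a", "b"), each = 8))
    z_p <- 2 * stats::pnorm(-abs(res$z))
    expect_lt(abs(z_p - oracle_permutation_p(x1, x2)), 0.02)
  }
  # heavily tied tiny samples: the tie-corrected approximation stays a
  # usable surrogate (enumeration shows deviations up to ~0.13 there)
  set.seed(78)
  for (rep in 1:10) {
    x1 <- sample(1:4, sample(4:7, 1), replace = TRUE)
    x2 <- sample(2:6, sample(4:7, 1), replace = TRUE)
    res <- mann_whitney_assoc(c(x1, x2),
                              rep(c("a", "b"), c(length(x1), length(x2))))
    z_p <- 2 * stats::pnorm(-abs(res$z))
    expect_lt(abs(z_p - oracle_permutation_p(x1, x2)), 0.15)
  }

  expect_error(mann_whitney_assoc(1:5, rep("a", 5)), "two levels")
})

test_that("null Mann-Whitney p-values are uniform", {
  set.seed(101)
  ps <- replicate(300, {
    mann_whitney_assoc(rnorm(24), rep(c("a", "b"), 12))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("logistic IQR effect reproduces the scaling formula", {
  co <- generate_cohort(cohort_config(400, beta = c(f = 1), seed = 13))
  est <- logistic_iqr_effect(co, "f")
  fit <- stats::glm(metastasis_5yr ~ f, binomial(), co)
  q <- unname(stats::quantile(co$f, c(0.25, 0.75)))
  expect_equal(est$ratio_factor, exp(coef(fit)[["f"]] * (q[2] - q[1])))
  expect_equal(est$baseline_value, q[1])
  expect_equal(est$changed_value, q[2])
  expect_true(est$ci_low <= est$ratio_factor &
                est$ratio_factor <= est$ci_high)
  expect_equal(est$p_type, "likelihood_ratio")
  expect_true(est$auc >= 0 && est$auc <= 1)
  # likelihood-ratio p recomputed directly
  fit0 <- stats::glm(metastasis_5yr ~ 1, binomial(), co)
  expect_equal(est$p_value,
               pchisq(2 * (logLik(fit)[1] - logLik(fit0)[1]), 1,
                      lower.tail = FALSE))

  # adjusted analysis keeps the feature contrast but reports model AUC
  adj <- logistic_iqr_effect(co, "f", adjusters = c("t_stage", "cohort"))
  expect_true(adj$adjusted)
  expect_equal(adj$p_type, "likelihood_ratio")

  # complete separation is flagged, never silent
  sep_data <- data.frame(metastasis_5yr = rep(0:1, each = 20),
                         f = rep(c(0, 10), each = 20) + runif(40, 0, 0.1))
  suppressWarnings(sep_est <- logistic_iqr_effect(sep_data, "f"))
  expect_equal(sep_est$status, "failed")
  expect_true(is.na(sep_est$ratio_factor))
})

test_that("Cox IQR effect uses score/Wald tests and positive times", {
  co <- generate_cohort(cohort_config(600, log_hazard = c(f = log(2)),
                                      seed = 23))
  est <- cox_iqr_effect(co, "f")
  expect_equal(est$p_type, "score")
  fit <- survival::coxph(survival::Surv(dmfs_time_years, dmfs_event) ~ f,
                         co)
  q <- unname(stats::quantile(co$f, c(0.25, 0.75)))
  expect_equal(est$ratio_factor, exp(coef(fit)[["f"]] * (q[2] - q[1])))

  adj <- cox_iqr_effect(co, "f", adjusters = "t_stage")
  expect_equal(adj$p_type, "wald")

  # a null covariate has a hazard-ratio factor near 1
  co$noise <- runif(nrow(co))
  null_est <- cox_iqr_effect(co, "noise")
  expect_gt(null_est$ci_high, 1)
  expect_lt(null_est$ci_low, 1)
})

test_that("univariate score test equals the log-rank test on a binary factor", {
  co <- generate_cohort(cohort_config(300, log_hazard = c(f = 0.8),
                                      seed = 31))
  co$grp <- factor(ifelse(co$f > stats::median(co$f), "high", "low"))
  est <- cox_iqr_effect(co, "grp")
  lr <- survival::survdiff(
    survival::Surv(dmfs_time_years, dmfs_event) ~ grp, co)
  p_logrank <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  expect_equal(est$p_value, p_logrank, tolerance = 1e-6)
})

test_that("bootstrap AUC corrects optimism and respects bounds", {
  co <- generate_cohort(cohort_config(150, log_hazard = c(f = log(2)),
                                      seed = 47))
  fml <- survival::Surv(dmfs_time_years, dmfs_event) ~ f
  ba <- bootstrap_auc(fml, co, n_boot = 40, seed = 3)
  # optimism can be slightly negative by chance at modest n
  expect_lte(ba$auc_corrected, ba$auc_apparent + 0.02)
  expect_gt(ba$auc_corrected, 0.5)
  expect_identical(ba, bootstrap_auc(fml, co, n_boot = 40, seed = 3))

  # no signal: corrected AUC near 1/2
  co$noise <- runif(nrow(co))
  ba0 <- bootstrap_auc(survival::Surv(dmfs_time_years, dmfs_event) ~ noise,
                       generate_cohort(cohort_config(
                         800, log_hazard = c(noise = 0), seed = 9)),
                       n_boot = 30, seed = 5)
  expect_lt(abs(ba0$auc_corrected - 0.5), 0.05)

  # perfectly rank-predictive feature without censoring
  perfect <- data.frame(t = sort(rexp(60)) , e = 1)
  perfect$x <- -perfect$t
  bap <- bootstrap_auc(survival::Surv(t, e) ~ x, perfect, n_boot = 20,
                       seed = 11)
  expect_equal(bap$auc_apparent, 1)
  expect_lte(bap$auc_corrected, 1)
})

test_that("Altman's correction matches the formula and is monotone", {
  expect_equal(altman_correction(0.05),
               -1.63 * 0.05 * (1 + 2.35 * log(0.05)))
  grid <- seq(0.001, 0.099, by = 0.001)
  corr <- altman_correction(grid)
  expect_true(all(diff(corr) > 0))
  expect_true(all(corr >= grid))
  expect_true(all(corr <= 1))
  expect_warning(out <- altman_correction(0.5), "only valid")
  expect_true(is.na(out))
})

test_that("minimum-p cutoff recovers a planted survival split", {
  set.seed(61)
  n <- 150
  x <- runif(n)
  rate <- ifelse(x > 0.5, 0.6, 0.15)
  t <- rexp(n, rate)
  event <- as.integer(t <= 5)
  time <- pmin(t, 5)
  res <- minp_cutoff(x, time, event)
  expect_gt(res$cutoff, 0.3)
  expect_lt(res$cutoff, 0.7)
  expect_true(all(res$group_sizes > 0))
  expect_gte(res$p_corrected, res$p_min)
  km <- km_coordinates(res$km)
  expect_setequal(unique(km$group), c("low", "high"))
  expect_true(all(km$survival >= 0 & km$survival <= 1))

  expect_error(minp_cutoff(rep(1, n), time, event), "no admissible cutoff")
})

test_that("multiple imputation completes tables and preserves marginals", {
  co <- generate_cohort(cohort_config(500, beta = c(f = 0.5),
                                      missing_rate = 0.2, seed = 71))
  imp <- impute_missing(co, m = 5, seed = 8)
  expect_length(imp, 5L)
  for (d in imp) expect_false(anyNA(d$f))
  # PMM keeps the marginal mean near the observed-data mean
  obs_mean <- mean(co$f, na.rm = TRUE)
  imp_means <- vapply(imp, function(d) mean(d$f), numeric(1L))
  expect_lt(max(abs(imp_means - obs_mean)), 0.05)
  # imputed values are observed donor values
  expect_true(all(imp[[1]]$f %in% c(co$f[!is.na(co$f)])))

  # no missing data: m identical copies
  full <- generate_cohort(cohort_config(50, beta = c(f = 0.5), seed = 3))
  copies <- impute_missing(full, m = 3, seed = 1)
  expect_identical(copies[[1]], full)
  expect_identical(copies[[2]], full)

  expect_identical(impute_missing(co, m = 1, seed = 2)[[1]],
                   impute_missing(co, m = 1, seed = 2)[[1]])

  broken <- co
  broken$f <- NA_real_
  expect_error(impute_missing(broken, m = 2), "entirely missing")
})

test_that("categorical imputation draws plausible classes", {
  co <- generate_cohort(cohort_config(400, beta = c(f = 0.5), seed = 5))
  co$differentiation[sample(400, 80)] <- NA
  imp <- impute_missing(co, m = 3, seed = 4)
  for (d in imp) {
    expect_false(anyNA(d$differentiation))
    expect_true(all(d$differentiation %in% c("WD/MD", "PD")))
  }
  # imputed class frequency close to the observed frequency
  p_obs <- mean(co$differentiation == "PD", na.rm = TRUE)
  p_imp <- mean(imp[[1]]$differentiation == "PD")
  expect_lt(abs(p_imp - p_obs), 0.1)
})

test_that("Rubin pooling matches the hand-evaluated formulas", {
  # identical estimates: between-variance 0, pooled = the estimate
  same <- rubin_pool(c(2, 2), c(0.5, 0.5))
  expect_equal(same$estimate, 2)
  expect_equal(same$between, 0)
  expect_equal(same$total_variance, 0.5)

  # m = 3 estimates {1,2,3}, equal within-variance w
  w <- 0.25
  pooled <- rubin_pool(c(1, 2, 3), rep(w, 3))
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$between, 1)
  expect_equal(pooled$total_variance, w + (1 + 1 / 3) * 1)
  expect_equal(pooled$df, 2 * (1 + w / (4 / 3))^2)
  expect_true(pooled$ci_low < 2 && pooled$ci_high > 2)

  m1 <- rubin_pool(1.5, 0.04)
  expect_equal(m1$estimate, 1.5)
  expect_equal(m1$total_variance, 0.04)

  expect_error(rubin_pool(1:3, 1:2), "differ in length")

  meds <- pool_rank_tests(list(list(p_value = 0.2, r_squared = 0.01),
                               list(p_value = 0.4, r_squared = 0.05),
                               list(p_value = 0.3, r_squared = 0.03)))
  expect_equal(meds$p_value, 0.3)
  expect_equal(meds$r_squared, 0.03)
})

test_that("pooled logistic analysis across imputations is coherent", {
  co <- generate_cohort(cohort_config(600, beta = c(f = 1),
                                      missing_rate = 0.15, seed = 91))
  imp <- impute_missing(co, m = 5, seed = 10)
  fits <- lapply(imp, function(d) {
    fit <- stats::glm(metastasis_5yr ~ f, binomial(), d)
    s <- summary(fit)$coefficients["f", ]
    c(est = s[["Estimate"]], var = s[["Std. Error"]]^2)
  })
  pooled <- rubin_pool(vapply(fits, `[[`, 0, "est"),
                       vapply(fits, `[[`, 0, "var"))
  q <- stats::quantile(co$f, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  or_iqr <- exp(pooled$estimate * (q[2] - q[1]))
  expect_gt(or_iqr, 1.5)
  expect_lt(or_iqr, 5)
})
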