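test_that("quartile assignment follows order statistics with lower-tie rule", {
  rec <- tibble::tibble(id = 1:8, cmin_1 = 1:8,
                        response = rep(c("PR", "SD"), 4))
  qs <- quartile_summary(rec, "cmin_1")
  expect_equal(qs$n, rep(2L, 4))
  expect_equal(qs$exposure_lo, c(1, 3, 5, 7))
  expect_equal(qs$exposure_hi, c(2, 4, 6, 8))
  # all responders: ORR 100% everywhere; ORR <= DCR always
  rec2 <- tibble::tibble(id = 1:8, cmin_1 = 1:8, response = rep("CR", 8))
  qs2 <- quartile_summary(rec2, "cmin_1")
  expect_equal(qs2$orr_pct, rep(100, 4))
  expect_true(all(qs$orr_pct <= qs$dcr_pct))
  expect_error(quartile_summary(rec[1:3, ], "cmin_1"), ">= 4")
  expect_error(quartile_summary(rec, "nope"), "not found")
})

test_that("quartile category counts sum to quartile n and ORR is flat on
          flat synthetic outcomes", {
  set.seed(8)
  exposures <- tibble::tibble(id = 1:1e4,
                              cmin_1 = exp(rnorm(1e4, 3, 0.4)))
  out <- generate_outcomes(exposures, outcome_model_spec(), seed = 31)
  qs <- quartile_summary(out$records, "cmin_1")
  expect_equal(qs$cr + qs$pr + qs$sd_n + qs$pd + qs$ne, qs$n)
  expect_lt(max(qs$orr_pct) - min(qs$orr_pct), 5)
})

test_that("logistic regression matches the 2x2 closed form and flags
          separation", {
  y <- c(rep(1, 3), rep(0, 7), rep(1, 6), rep(0, 4))
  x <- c(rep(0, 10), rep(1, 10))
  fit <- logistic_regression(y, x, log_exposure = FALSE)
  expect_equal(fit$slope, log((6 / 4) / (3 / 7)), tolerance = 1e-6)
  expect_equal(fit$intercept, log(3 / 7), tolerance = 1e-6)
  expect_error(logistic_regression(rep(1, 10), rnorm(10)), "separation")
  # calibration: slope CI covers 0 under a flat generator
  set.seed(12)
  cover <- vapply(1:40, function(i) {
    xx <- exp(rnorm(400, 3, 0.5))
    yy <- rbinom(400, 1, 0.3)
    ci <- logistic_regression(yy, xx)
    ci$slope_lo <= 0 && ci$slope_hi >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("Kaplan-Meier estimator reproduces the product-limit arithmetic", {
  km <- km_estimator(c(5, 7, 10), censored = c(FALSE, TRUE, FALSE))
  s5 <- km$curve$surv[km$curve$time == 5]
  s10 <- km$curve$surv[km$curve$time == 10]
  expect_equal(s5, 2 / 3)
  expect_equal(s10, 0)
  # censoring between events leaves the estimate unchanged
  expect_true(all(km$curve$surv[km$curve$time > 5 & km$curve$time < 10] ==
                    2 / 3))
  # all censored: flat at 1 with undefined median
  km2 <- km_estimator(c(3, 6, 9), censored = rep(TRUE, 3))
  expect_true(all(km2$curve$surv == 1))
  expect_true(is.na(km2$median))
  expect_error(km_estimator(numeric(0), logical(0)), "empty")
  # exponential sanity: median ~ ln 2 / rate
  set.seed(4)
  tt <- rexp(1e4, 1 / 50)
  km3 <- km_estimator(tt, censored = rep(FALSE, 1e4))
  expect_equal(unname(km3$median), 50 * log(2), tolerance = 0.05)
  # no censoring: KM equals 1 - empirical CDF
  km4 <- km_estimator(c(2, 4, 6, 8), censored = rep(FALSE, 4))
  expect_equal(km4$curve$surv, c(0.75, 0.5, 0.25, 0))
})

test_that("AECI filtering applies the three qualification rules", {
  mk <- function(n_with, name, grade = 1, related = TRUE, serious = FALSE,
                 aesi = TRUE) {
    tibble::tibble(id = seq_len(n_with), name = name, grade = grade,
                   drug_related = related, serious = serious, aesi = aesi)
  }
  n_pop <- 1000
  # AESI rule straddles the 2.5% boundary
  below <- aeci_filter(mk(24, "a"), n_pop)   # 2.4%
  above <- aeci_filter(mk(26, "b"), n_pop)   # 2.6%
  expect_equal(nrow(below), 0)
  expect_equal(nrow(above), 26)
  expect_true(all(above$criterion == "aesi>2.5%"))
  # severity rule ignores incidence
  sev <- aeci_filter(mk(5, "c", grade = 3, aesi = FALSE), n_pop)
  expect_equal(nrow(sev), 5)
  expect_true(all(sev$criterion == "grade>=3"))
  # serious rule
  ser <- aeci_filter(mk(2, "d", serious = TRUE, aesi = FALSE), n_pop)
  expect_equal(nrow(ser), 2)
  # non-drug-related events never qualify
  expect_equal(nrow(aeci_filter(mk(50, "e", grade = 4, related = FALSE),
                                n_pop)), 0)
  expect_equal(nrow(aeci_filter(mk(0, "f")[0, ], n_pop)), 0)
  expect_error(aeci_filter(mk(5, "g"), 0), "population_n")
})

test_that("the exposure-response report is flat on null data and detects an
          injected slope", {
  set.seed(17)
  exposures <- tibble::tibble(
    id = 1:800,
    cmin_1 = exp(rnorm(800, 3, 0.5)),
    cavg_1 = exp(rnorm(800, 3.5, 0.5))
  )
  flat <- generate_outcomes(exposures, outcome_model_spec(), seed = 41)
  rep_flat <- er_report(flat$records, flat$aes,
                        metrics = c("cmin_1", "cavg_1"))
  expect_true(all(rep_flat$verdicts$verdict == "flat"))
  # a strong AE-exposure slope flips the verdict for the driving metric
  steep <- generate_outcomes(
    exposures, outcome_model_spec(ae_exposure_slope = 2), seed = 42)
  rep_steep <- er_report(steep$records, steep$aes, metrics = "cmin_1")
  expect_equal(rep_steep$verdicts$verdict, "non-flat")
  # metrics missing for all subjects are reported as skipped
  rep_missing <- er_report(flat$records, flat$aes,
                           metrics = c("cmin_1", "auc_inf_1"))
  expect_true("auc_inf_1" %in% rep_missing$skipped)
})
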