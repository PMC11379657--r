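test_that("sampled covariates follow the specified distributions", {
  p <- final_model_parameters()
  spec <- population_spec(1e4, country_mix = c(chinese = 1, american = 0,
                                               japanese = 0))
  pop <- sample_population(spec, p, seed = 11)
  expect_equal(median(pop$crcl), 95.14, tolerance = 0.02)
  expect_true(all(pop$country == "chinese"))
  expect_equal(sd(pop$eta_cl), p$omega_cl, tolerance = 0.05)
  # renal categories derive from CRCL by the standard cut-offs
  expect_true(all(pop$renal_category[pop$crcl > 90] == "normal"))
  expect_true(all(pop$renal_category[pop$crcl <= 90 & pop$crcl > 60] ==
                    "mild"))
  # zero variability pins the random effects at zero
  p0 <- final_model_parameters(omega_cl = 0, omega_v = 0, omega_ka = 0)
  pop0 <- sample_population(population_spec(50), p0, seed = 2)
  expect_true(all(pop0$eta_cl == 0 & pop0$eta_v == 0 & pop0$eta_ka == 0))
  expect_error(population_spec(10, country_mix = c(chinese = 0.5,
                                                   american = 0.2,
                                                   japanese = 0.1)),
               "sum to 1")
})

test_that("study dataset matches the design arithmetic and is reproducible", {
  p <- final_model_parameters()
  ds <- generate_study_dataset(p, n_rich = 30, n_sparse = 152, seed = 99)
  # 20 rich x 20 + 10 rich Q4W x 16 + 152 sparse x 8 troughs
  expect_equal(sum(ds$EVID == 0), 20 * 20 + 10 * 16 + 152 * 8)
  expect_equal(length(unique(ds$ID)), 182)
  # same seed reproduces the dataset bit for bit
  ds2 <- generate_study_dataset(p, n_rich = 30, n_sparse = 152, seed = 99)
  expect_identical(dplyr::as_tibble(ds), dplyr::as_tibble(ds2))
  # every subject doses before observing; covariates constant
  expect_silent(validate_pk_dataset(ds))
  # truth block covers all subjects
  expect_equal(nrow(attr(ds, "truth")$population), 182)
})

test_that("zero-variability datasets equal the typical profile", {
  p <- final_model_parameters(omega_cl = 0, omega_v = 0, omega_ka = 0,
                              sigma_prop = 0)
  spec <- population_spec(1, country_mix = c(chinese = 1, american = 0,
                                             japanese = 0))
  pop <- sample_population(spec, p, seed = 5)
  des <- default_study_designs()$rich
  ds <- generate_pk_dataset(pop, des, p, seed = 5)
  obs <- ds$DV[ds$EVID == 0]
  pred <- solve_profile(p, covariate_profile(wt = pop$wt, crcl = pop$crcl),
                        doses = des$doses, times = des$sampling_times)
  expect_equal(obs, pred)
})

test_that("synthetic outcomes converge to their configured frequencies", {
  set.seed(3)
  exposures <- tibble::tibble(id = 1:1e4,
                              cmin_1 = exp(rnorm(1e4, log(20), 0.5)))
  out <- generate_outcomes(exposures, outcome_model_spec(), seed = 21)
  rec <- out$records
  # flat exposure-response: ORR close to 30% in every exposure quartile
  q <- cut(rec$cmin_1, quantile(rec$cmin_1, 0:4 / 4), include.lowest = TRUE)
  orr_q <- tapply(rec$response %in% c("CR", "PR"), q, mean)
  expect_true(all(abs(orr_q - 0.30) < 0.03))
  # marginal AE incidence close to catalog values (binomial error)
  ast <- out$aes[out$aes$name == "increased AST", ]
  expect_equal(length(unique(ast$id)) / 1e4, 0.162, tolerance = 0.08)
  # responders only carry DOR; exponential median with no censoring
  out2 <- generate_outcomes(exposures,
                            outcome_model_spec(censoring_rate = 0,
                                               dor_event_rate = 1 / 100),
                            seed = 22)
  dor <- out2$records$dor_days[out2$records$response %in% c("CR", "PR")]
  expect_true(all(is.na(out2$records$dor_days[
    !out2$records$response %in% c("CR", "PR")])))
  expect_equal(median(dor), 100 * log(2), tolerance = 0.06)
})
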