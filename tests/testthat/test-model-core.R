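test_that("clearance time multiplier matches its closed form and limits", {
  # no change at the first dose
  expect_equal(clearance_time_multiplier(0, emax = -0.439, t50 = 34), 1.0)
  # half the asymptotic log-change at t = T50
  expect_equal(clearance_time_multiplier(34 * 24, emax = -0.439, t50 = 34),
               exp(-0.439 / 2), tolerance = 1e-12)
  # asymptote exp(emax)
  expect_equal(clearance_time_multiplier(1e12, emax = -0.439, t50 = 34),
               exp(-0.439), tolerance = 1e-6)
  # monotone decreasing and bounded for emax < 0
  tt <- seq(0, 5000, by = 10)
  mult <- clearance_time_multiplier(tt, emax = -0.439, t50 = 34)
  expect_true(all(diff(mult) < 0))
  expect_true(all(mult <= 1 & mult >= exp(-0.439)))
  expect_error(clearance_time_multiplier(-1, -0.4, 34), "t must")
  expect_error(clearance_time_multiplier(1, -0.4, 0), "t50")
})

test_that("individual clearance reproduces the published covariate model", {
  p <- final_model_parameters()
  ref <- covariate_profile(crcl = 95.14, country = "chinese")
  # typical subject at t = 0 returns the typical value exactly
  expect_equal(individual_clearance(p, ref), 0.0478)
  # country multipliers
  expect_equal(
    individual_clearance(p, covariate_profile(crcl = 95.14,
                                              country = "japanese")),
    0.0478 * 0.740)
  expect_equal(
    individual_clearance(p, covariate_profile(crcl = 95.14,
                                              country = "american")),
    0.0478 * 0.891)
  # weight-incorporated CRCL power term: 10th-percentile renal function
  pw <- weight_model_parameters()
  r <- individual_clearance(pw, covariate_profile(crcl = 62.2)) /
    individual_clearance(pw, covariate_profile(crcl = 95.1))
  expect_equal(r, (62.2 / 95.1)^0.412, tolerance = 1e-12)
  expect_equal(100 * (r - 1), -16.1, tolerance = 0.5)
  # random effect acts multiplicatively on the log scale
  expect_equal(
    individual_clearance(p, ref, random_effects(eta_cl = 0.3)),
    0.0478 * exp(0.3))
})

test_that("individual volume follows the weight power model", {
  p <- final_model_parameters()
  expect_equal(individual_volume(p, covariate_profile()), 15.5)
  pw <- weight_model_parameters()
  expect_equal(individual_volume(pw, covariate_profile(wt = 63)),
               pw$v_pop)
  expect_equal(individual_volume(pw, covariate_profile(wt = 126)),
               pw$v_pop * 2^0.623)
})

test_that("covariate power terms and country multipliers commute", {
  pw <- weight_model_parameters()
  cov <- covariate_profile(wt = 85, crcl = 70, country = "american")
  direct <- individual_clearance(pw, cov)
  by_hand <- pw$cl_pop *
    0.842 *
    (70 / 95.14)^0.412 *
    (85 / 63)^0.155
  expect_equal(direct, by_hand, tolerance = 1e-12)
})

test_that("proportional residual error has the stated moments", {
  expect_equal(apply_residual_error(c(1, 5, 10), 0), c(1, 5, 10))
  expect_equal(apply_residual_error(rep(0, 100), 0.3, seed = 1), rep(0, 100))
  y <- apply_residual_error(rep(10, 1e5), 0.224, seed = 7)
  expect_equal(sd(y) / mean(y), 0.224, tolerance = 0.01)
  expect_true(all(y >= 0))
  # resampling variant avoids the floor without changing the scale much
  y2 <- apply_residual_error(rep(10, 1e4), 0.224, resample = TRUE, seed = 7)
  expect_true(all(y2 > 0))
  expect_error(apply_residual_error(1, -0.1), "sigma")
})

test_that("parameter containers validate and serialize", {
  expect_error(pk_parameters(cl_pop = -1, v_pop = 15, ka_pop = 0.01))
  expect_error(pk_parameters(cl_pop = 0.05, v_pop = 15, ka_pop = 0.01,
                             beta_crcl = 0.3, variant = "base"),
               "base")
  # epsilon interpreted as variance by default, as SD on request
  expect_equal(final_model_parameters()$sigma_prop, sqrt(0.0501))
  expect_equal(final_model_parameters(epsilon_is_variance = FALSE)$sigma_prop,
               0.0501)
  p <- weight_model_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pk_parameters(p, path)
  expect_equal(read_pk_parameters(path), p)
  pj <- withr::local_tempfile(fileext = ".json")
  write_pk_parameters(p, pj)
  expect_equal(read_pk_parameters(pj), p)
  expect_error(params_from_list(list(cl_pop = 1, nope = 2)), "unknown")
})
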