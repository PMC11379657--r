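test_that("OFV reduces to the analytic fixed-effects likelihood without
          random effects", {
  # constant clearance, no IIV: predictions have a closed form, so the
  # -2 log likelihood can be computed independently of the estimation code
  p <- params_constant_cl(sigma_prop = 0.2)
  ds <- single_subject_dataset(p, sigma = 0.2, seed = 3)
  obs <- ds[ds$EVID == 0, ]
  f <- bateman_profile(ds$TIME[ds$EVID == 1], ds$AMT[ds$EVID == 1],
                       obs$TIME, ka = p$ka_pop, v = p$v_pop, cl = p$cl_pop)
  ll <- sum(log(2 * pi * 0.2^2 * f^2) + (obs$DV - f)^2 / (0.2^2 * f^2))
  expect_equal(objective_function(p, ds, method = "foce", hmax = 0.5), ll,
               tolerance = 1e-6)
  expect_equal(objective_function(p, ds, method = "laplace", hmax = 0.5), ll,
               tolerance = 1e-6)
})

test_that("OFV is additive over independent subjects", {
  p <- final_model_parameters()
  ds <- small_study(p, n_rich = 2, n_sparse = 3, seed = 13)
  dup <- ds
  dup$ID <- dup$ID + max(ds$ID)
  both <- dplyr::bind_rows(ds, dup)
  expect_equal(objective_function(p, both), 2 * objective_function(p, ds),
               tolerance = 1e-9)
})

test_that("OFV is invariant to subject order and prefers the generating
          parameters on a large dataset", {
  p <- final_model_parameters()
  ds <- small_study(p, n_rich = 6, n_sparse = 24, seed = 17)
  shuffled <- ds[order(rev(seq_len(nrow(ds)))), ] |>
    dplyr::arrange(dplyr::desc(ID), TIME, dplyr::desc(EVID))
  expect_equal(objective_function(p, shuffled), objective_function(p, ds),
               tolerance = 1e-9)
  worse <- final_model_parameters(cl_pop = 0.08, v_pop = 10)
  expect_lt(objective_function(p, ds), objective_function(worse, ds))
})

test_that("empirical-Bayes estimates invert rich noise-free data and shrink
          to the prior without data", {
  p <- final_model_parameters(sigma_prop = 0.005)
  eta_true <- random_effects(eta_cl = 0.25, eta_v = -0.3, eta_ka = 0.4)
  ds <- single_subject_dataset(p, eta = eta_true, sigma = 0)
  eb <- empirical_bayes(p, ds)
  expect_equal(eb$eta_cl, 0.25, tolerance = 1e-3)
  expect_equal(eb$eta_v, -0.3, tolerance = 1e-3)
  expect_equal(eb$eta_ka, 0.4, tolerance = 1e-3)
  # no observations: prior mode (all zero)
  ds_no_obs <- ds[ds$EVID == 1, ]
  eb0 <- empirical_bayes(p, ds_no_obs)
  expect_equal(unlist(eb0[, -1]), c(eta_cl = 0, eta_v = 0, eta_ka = 0))
  # vanishing omega pins the EBE at zero regardless of data
  p_tiny <- final_model_parameters(sigma_prop = 0.005, omega_cl = 1e-6,
                                   omega_v = 1e-6, omega_ka = 1e-6)
  eb_tiny <- empirical_bayes(p_tiny, ds)
  expect_lt(max(abs(unlist(eb_tiny[, -1]))), 1e-4)
})

test_that("a noise-free deterministic inverse problem is recovered by the
          fixed-effects fit", {
  truth <- params_constant_cl(sigma_prop = 0.01)
  ds <- single_subject_dataset(truth, sigma = 0)
  init <- params_constant_cl(cl_pop = 0.08, v_pop = 10, ka_pop = 0.02,
                             sigma_prop = 0.05)
  fit <- fit_population(ds, init, fixed = c("emax", "t50"))
  expect_equal(fit$estimates$cl_pop, truth$cl_pop, tolerance = 1e-3)
  expect_equal(fit$estimates$v_pop, truth$v_pop, tolerance = 1e-3)
  expect_equal(fit$estimates$ka_pop, truth$ka_pop, tolerance = 1e-3)
})

test_that("EBE shrinkage rises as per-subject information vanishes", {
  p <- final_model_parameters()
  rich <- small_study(p, n_rich = 12, n_sparse = 0, seed = 23)
  poor <- rich[rich$EVID == 1 | rich$TIME == 336, ] # one sample each
  eb_rich <- empirical_bayes(p, rich)
  eb_poor <- empirical_bayes(p, poor)
  shr <- function(eb) 1 - sd(eb$eta_v) / p$omega_v
  expect_gt(shr(eb_poor), shr(eb_rich))
})

test_that("bootstrap is reproducible and recovers the original fit when the
          resample equals the original", {
  p <- params_constant_cl(sigma_prop = 0.15)
  ds <- small_study(p, n_rich = 0, n_sparse = 8, seed = 29)
  fixed <- c("ka_pop", "emax", "t50")
  b1 <- bootstrap(ds, p, n_resamples = 3, fixed = fixed, seed = 77,
                  control = list(iter_max = 60))
  b2 <- bootstrap(ds, p, n_resamples = 3, fixed = fixed, seed = 77,
                  control = list(iter_max = 60))
  expect_identical(b1$summary, b2$summary)
  expect_true(all(b1$summary$q05 <= b1$summary$median &
                    b1$summary$median <= b1$summary$q95))
  expect_true(b1$convergence_rate_pct >= 0 &&
                b1$convergence_rate_pct <= 100)
})
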