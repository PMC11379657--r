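test_that("integrator matches the Bateman closed form at constant clearance", {
  p <- params_constant_cl()
  cov <- covariate_profile()
  doses <- dose_events(time = 0, amount = 150)
  times <- c(1, 6, 24, 72, 168, 336, 840, 1680, 3360)
  num <- solve_profile(p, cov, doses = doses, times = times)
  ref <- bateman_profile(0, 150, times, ka = p$ka_pop, v = p$v_pop,
                         cl = p$cl_pop)
  expect_equal(num, ref, tolerance = 1e-6)
  # AUC0-inf equals dose/CL within 0.1% (integrate far into the tail)
  grid <- seq(0, 40000, by = 4)
  cc <- solve_profile(p, cov, doses = doses, times = grid, hmax = 4)
  auc <- sum(diff(grid) * (cc[-1] + cc[-length(cc)]) / 2)
  expect_equal(auc, 150 / p$cl_pop, tolerance = 1e-3)
})

test_that("profiles are linear in dose and superpose over events", {
  p <- final_model_parameters(omega_cl = 0, omega_v = 0, omega_ka = 0,
                              sigma_prop = 0)
  cov <- covariate_profile()
  times <- seq(12, 2000, by = 36)
  set.seed(42)
  for (rep in 1:5) {
    eta <- random_effects(rnorm(1, 0, 0.3), rnorm(1, 0, 0.3),
                          rnorm(1, 0, 0.3))
    t1 <- runif(1, 0, 300)
    t2 <- t1 + runif(1, 100, 500)
    a1 <- runif(1, 50, 400)
    a2 <- runif(1, 50, 400)
    both <- solve_profile(p, cov, eta, dose_events(c(t1, t2), c(a1, a2)),
                          times)
    one <- solve_profile(p, cov, eta, dose_events(t1, a1), times)
    two <- solve_profile(p, cov, eta, dose_events(t2, a2), times)
    expect_equal(both, one + two, tolerance = 1e-6)
    # dose scaling
    lam <- runif(1, 0.2, 4)
    scaled <- solve_profile(p, cov, eta,
                            dose_events(c(t1, t2), lam * c(a1, a2)), times)
    expect_equal(scaled, lam * both, tolerance = 1e-8)
  }
})

test_that("profile edge cases behave", {
  p <- final_model_parameters()
  cov <- covariate_profile()
  # no doses: identically zero
  expect_equal(
    solve_profile(p, cov, doses = dose_events(numeric(0), numeric(0)),
                  times = c(0, 10, 100)),
    c(0, 0, 0))
  # output exactly at a dose time is the pre-dose trough
  doses <- regimen_qw(150, weeks = 4)
  at_dose <- solve_profile(p, cov, doses = doses, times = 168)
  just_before <- solve_profile(p, cov, doses = doses, times = 168 - 1e-6)
  expect_equal(at_dose, just_before, tolerance = 1e-6)
  expect_error(solve_profile(p, cov, doses = doses, times = c(10, 5)),
               "sorted")
  # per-kg dosing uses the subject's weight
  pk <- solve_profile(p, covariate_profile(wt = 60),
                      doses = regimen_qw(2.5, weeks = 4, per_kg = TRUE),
                      times = c(100, 300))
  fixed <- solve_profile(p, covariate_profile(wt = 60),
                         doses = regimen_qw(150, weeks = 4),
                         times = c(100, 300))
  expect_equal(pk, fixed)
})

test_that("grid refinement is converged at the default step", {
  p <- final_model_parameters()
  cov <- covariate_profile()
  doses <- regimen_qw(150, weeks = 8)
  times <- seq(24, 8 * 168, by = 24)
  c1 <- solve_profile(p, cov, doses = doses, times = times, hmax = 1)
  c2 <- solve_profile(p, cov, doses = doses, times = times, hmax = 0.25)
  expect_equal(c1, c2, tolerance = 1e-8)
})
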