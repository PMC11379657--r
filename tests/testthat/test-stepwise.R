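# stepwise tests run on reduced designs: trough-only sampling, IIV restricted
# to clearance (the parameter carrying the candidate effects), and absorption
# and time-dependence parameters held at their generating values, so each
# candidate fit is a small, fast optimization

sparse_crcl_dataset <- function(params, n = 50, seed = 1) {
  spec <- population_spec(n, country_mix = c(chinese = 1, american = 0,
                                             japanese = 0))
  pop <- sample_population(spec, params, seed = seed)
  des <- study_design("troughs", regimen_qw(150, weeks = 12),
                      c(2, 4, 6, 8, 10, 12) * 168, 12)
  generate_pk_dataset(pop, des, params, seed = seed + 1)
}

test_that("an injected creatinine-clearance effect on clearance is selected
          in the forward step", {
  truth <- final_model_parameters(beta_crcl = 0.475, frac_american = 1,
                                  frac_japanese = 1,
                                  omega_cl = 0.2, omega_v = 0, omega_ka = 0,
                                  sigma_prop = 0.15)
  ds <- sparse_crcl_dataset(truth, n = 50, seed = 301)
  fixedpars <- c("ka_pop", "emax", "t50")
  sw <- stepwise_covariate_search(
    ds, truth, candidates = c("cl~crcl", "cl~wt"), fixed = fixedpars,
    control = list(iter_max = 60), prescreen = TRUE)
  expect_true("cl~crcl" %in% sw$selected)
  added <- sw$trace[sw$trace$action == "added", ]
  expect_true(all(added$dofv >= 6.63))
  # the selected model's coefficient is near the generating exponent
  expect_equal(sw$final_fit$estimates$beta_crcl, 0.475, tolerance = 0.5)
})

test_that("the forward step false-selects a null covariate at roughly the
          nominal 1% rate", {
  # no-IIV generating model: each replicate fit is a plain fixed-effects
  # likelihood optimization, keeping the replicate loop fast
  truth <- params_constant_cl(sigma_prop = 0.15,
                              emax = -0.439, t50 = 34)
  fixedpars <- c("ka_pop", "emax", "t50")
  n_rep <- 30
  hits <- 0
  for (r in seq_len(n_rep)) {
    ds <- sparse_crcl_dataset(truth, n = 30, seed = 400 + r)
    base_list <- params_to_list(truth)
    f0 <- fit_population(ds, truth, fixed = fixedpars,
                         control = list(iter_max = 50))
    skel <- params_to_list(truth)
    skel$variant <- "final"
    skel$beta_crcl <- 0.1
    f1 <- fit_population(ds, params_from_list(skel),
                         fixed = c(fixedpars, "frac_american",
                                   "frac_japanese"),
                         control = list(iter_max = 50))
    if (f0$ofv - f1$ofv >= 6.63) hits <- hits + 1
  }
  # Binomial(30, 0.01): P(X > 3) < 1e-4
  expect_lte(hits, 3)
})

test_that("an empty candidate list returns the base fit unchanged", {
  truth <- params_constant_cl(sigma_prop = 0.15)
  ds <- sparse_crcl_dataset(truth, n = 8, seed = 500)
  sw <- stepwise_covariate_search(ds, truth, candidates = character(),
                                  fixed = c("ka_pop", "emax", "t50"),
                                  control = list(iter_max = 40))
  expect_equal(sw$selected, character())
  expect_equal(sw$final_fit$ofv, sw$base_fit$ofv)
  expect_equal(nrow(sw$trace), 0)
})
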