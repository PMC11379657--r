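test_that("per-kg and equivalent fixed dosing coincide; zero dose is inert", {
  p <- final_model_parameters()
  cov <- covariate_profile(wt = 60)
  per_kg <- simulate_typical(cov, regimen_qw(2.5, per_kg = TRUE), p)
  fixed <- simulate_typical(cov, regimen_qw(150), p)
  expect_equal(per_kg$cmin_ss, fixed$cmin_ss)
  expect_equal(per_kg$auc_tau_ss, fixed$auc_tau_ss)
  zero <- simulate_typical(cov, regimen(0, 168, 20), p)
  expect_equal(zero$cmax_ss, 0)
  expect_equal(zero$auc_tau_ss, 0)
})

test_that("accumulation ratios are invariant to dose scaling", {
  p <- final_model_parameters()
  cov <- covariate_profile()
  lo <- simulate_typical(cov, regimen_qw(75), p)
  hi <- simulate_typical(cov, regimen_qw(300), p)
  expect_equal(lo$r_auc, hi$r_auc, tolerance = 1e-8)
  expect_equal(lo$r_cmax, hi$r_cmax, tolerance = 1e-8)
})

test_that("covariate impact table reports percent changes vs reference", {
  pw <- weight_model_parameters()
  scen <- list(
    normal = covariate_profile(wt = 60, crcl = 95),
    mild = covariate_profile(wt = 60, crcl = 75),
    same = covariate_profile(wt = 60, crcl = 95)
  )
  tab <- covariate_impact_table(pw, scen, reference = "normal")
  expect_equal(nrow(tab), 2)
  same <- tab[tab$scenario == "same", ]
  expect_equal(same$auc_ss_pct, 0)
  expect_equal(same$cmax_ss_pct, 0)
  expect_equal(same$cmin_ss_pct, 0)
  mild <- tab[tab$scenario == "mild", ]
  expect_true(mild$cmin_ss_pct > 0) # lower CRCL, lower CL, higher trough
  expect_true(attr(tab, "clinically_limited"))
  expect_error(covariate_impact_table(pw, scen, reference = "missing"),
               "reference")
})

test_that("regimen comparison is symmetric and null for identical regimens", {
  p <- final_model_parameters()
  pop <- tibble::tibble(id = 1L, country = "chinese", wt = 60, crcl = 95.14,
                        eta_cl = 0, eta_v = 0, eta_ka = 0)
  cmp <- compare_regimens(list(a = regimen_qw(150), b = regimen_qw(150)),
                          pop, p)
  expect_equal(cmp$max_rel_diff_pct, 0, tolerance = 1e-10)
  expect_error(compare_regimens(list(a = regimen_qw(150)), pop, p),
               ">= 2 regimens")
})
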