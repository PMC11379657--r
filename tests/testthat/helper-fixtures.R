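# shared fixtures: small parameter sets and datasets built in code

# constant-clearance parameters with no variability (closed-form regime)
params_constant_cl <- function(sigma_prop = 0, emax = 0, t50 = 1,
                               omega_cl = 0, omega_v = 0, omega_ka = 0, ...) {
  base_model_parameters(emax = emax, t50 = t50,
                        omega_cl = omega_cl, omega_v = omega_v,
                        omega_ka = omega_ka, sigma_prop = sigma_prop, ...)
}

# a small mixed-design dataset for estimation tests
small_study <- function(params, n_rich = 4, n_sparse = 8, seed = 101) {
  generate_study_dataset(params, n_rich = n_rich, n_sparse = n_sparse,
                         seed = seed)
}

# single-subject rich dataset with known etas
single_subject_dataset <- function(params, eta = random_effects(),
                                   cov = covariate_profile(),
                                   doses = regimen_qw(150, weeks = 8),
                                   times = c(4, 8, 24, 48, 96, 168, 336,
                                             504, 672, 840, 1008, 1176,
                                             1344),
                                   sigma = params$sigma_prop, seed = 1) {
  pred <- solve_profile(params, cov, eta, doses, times)
  dv <- apply_residual_error(pred, sigma, seed = seed)
  dplyr::bind_rows(
    tibble::tibble(ID = 1L, TIME = doses$time, AMT = doses$amount,
                   DV = NA_real_, EVID = 1L, MDV = 1L),
    tibble::tibble(ID = 1L, TIME = times, AMT = NA_real_, DV = dv,
                   EVID = 0L, MDV = 0L)
  ) |>
    dplyr::arrange(TIME, dplyr::desc(EVID)) |>
    dplyr::mutate(WT = cov$wt, CRCL = cov$crcl, COUNTRY = cov$country)
}
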