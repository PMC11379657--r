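#' Virtual population specification
#'
#' Describes the joint covariate distribution of a virtual oncology
#' population: country mix, per-country log-normal body-weight distributions,
#' and a log-normal creatinine-clearance distribution. Defaults emulate a
#' mixed Chinese/American/Japanese solid-tumor program: typical weight 60 kg
#' (CN/JP) and 80 kg (US), CRCL median about 95 mL/min with 34.8%
#' between-subject spread.
#'
#' @param n_subjects Number of subjects.
#' @param country_mix Named proportions over chinese/american/japanese;
#'   must sum to 1.
#' @param wt_median Named per-country median weights, kg.
#' @param wt_cv Named per-country weight CVs (fractions).
#' @param wt_range Truncation bounds for weight, kg (the supported dosing
#'   weight range).
#' @param crcl_median Median creatinine clearance, mL/min.
#' @param crcl_cv CRCL coefficient of variation (fraction).
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_subjects,
                            country_mix = c(chinese = 0.7, american = 0.2,
                                            japanese = 0.1),
                            wt_median = c(chinese = 60, american = 80,
                                          japanese = 60),
                            wt_cv = c(chinese = 0.20, american = 0.25,
                                      japanese = 0.20),
                            wt_range = c(39.5, 120),
                            crcl_median = 95.14,
                            crcl_cv = 0.348) {
  stopifnot(n_subjects >= 1, crcl_median > 0, crcl_cv > 0,
            all(wt_median > 0), all(wt_cv > 0))
  if (abs(sum(country_mix) - 1) > 1e-8 || any(country_mix < 0)) {
    stop("country_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 country_mix = country_mix,
                 wt_median = wt_median, wt_cv = wt_cv, wt_range = wt_range,
                 crcl_median = crcl_median, crcl_cv = crcl_cv),
            class = "population_spec")
}

# sdlog of a log-normal with the given CV
.sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Sample a virtual population
#'
#' Draws covariates from the distributions in `spec` and log-scale random
#' effects from N(0, omega^2) per parameter. Reproducible under `seed`.
#'
#' @param spec A [population_spec()].
#' @param params A [pk_parameters()] supplying the omegas for the random
#'   effects.
#' @param seed Optional integer seed (applied locally).
#' @return A tibble with columns `id`, `country`, `wt`, `crcl`,
#'   `renal_category`, `eta_cl`, `eta_v`, `eta_ka`.
#' @export
sample_population <- function(spec, params, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(params, "pk_parameters"))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- spec$n_subjects
  country <- sample(names(spec$country_mix), n, replace = TRUE,
                    prob = spec$country_mix)
  wt <- spec$wt_median[country] *
    exp(stats::rnorm(n, 0, .sdlog(spec$wt_cv[country])))
  wt <- pmin(pmax(wt, spec$wt_range[1]), spec$wt_range[2])
  crcl <- spec$crcl_median * exp(stats::rnorm(n, 0, .sdlog(spec$crcl_cv)))
  tibble::tibble(
    id = seq_len(n),
    country = country,
    wt = unname(wt),
    crcl = crcl,
    renal_category = renal_category(crcl),
    eta_cl = stats::rnorm(n, 0, params$omega_cl),
    eta_v = stats::rnorm(n, 0, params$omega_v),
    eta_ka = stats::rnorm(n, 0, params$omega_ka)
  )
}

# row -> S3 helpers used throughout
.row_cov <- function(row) {
  covariate_profile(wt = row$wt, crcl = row$crcl, country = row$country)
}
.row_eta <- function(row) {
  random_effects(eta_cl = row$eta_cl, eta_v = row$eta_v, eta_ka = row$eta_ka)
}
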