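#' Time-dependent clearance multiplier
#'
#' Fractional change of apparent clearance with treatment time,
#' \eqn{e^{E_{max} \, t / (24 \, T_{50} + t)}}. The multiplier is 1 at
#' \eqn{t = 0}, approaches \eqn{e^{E_{max}}} as \eqn{t \to \infty}, and is
#' strictly monotone (decreasing when `emax < 0`). Time is measured from the
#' first dose.
#'
#' @param t Time since first dose, hours (vectorized).
#' @param emax Maximum fractional log-clearance change, unitless.
#' @param t50 Time to half the maximal change, days.
#' @return Unitless multiplier, same length as `t`.
#' @export
clearance_time_multiplier <- function(t, emax, t50) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (t50 <= 0) stop("t50 must be > 0", call. = FALSE)
  exp(emax * t / (24 * t50 + t))
}

# country multiplier lookup
.country_mult <- function(params, country) {
  switch(country,
         chinese = 1,
         american = params$frac_american,
         japanese = params$frac_japanese,
         stop("unknown country: ", country, call. = FALSE))
}

#' Individual apparent clearance at time t
#'
#' Combines the typical clearance with the covariate model implied by
#' `params$variant`, the time-dependence multiplier, and the subject's random
#' effect:
#' \deqn{CL/F(t) = \theta_{CL} (CRCL/ref)^{\beta} (WT/ref)^{\beta_{WT}}
#'   \cdot f_{country} \cdot e^{E_{max} t/(24 T_{50}+t)} \cdot e^{\eta_{CL}}}
#' With reference covariates, zero random effects, and `t = 0` the typical
#' value is returned exactly. The power terms and multipliers commute.
#'
#' @param params [pk_parameters()].
#' @param cov [covariate_profile()].
#' @param eta [random_effects()].
#' @param t Time since first dose, hours (vectorized).
#' @return Apparent clearance, L/h.
#' @export
individual_clearance <- function(params, cov, eta = random_effects(), t = 0) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(cov, "covariate_profile"))
  cl <- params$cl_pop
  if (params$variant != "base") {
    cl <- cl * (cov$crcl / params$crcl_ref)^params$beta_crcl *
      .country_mult(params, cov$country)
  }
  if (params$variant == "weight_incorporated") {
    cl <- cl * (cov$wt / params$wt_ref)^params$beta_wt_cl
  }
  cl * clearance_time_multiplier(t, params$emax, params$t50) * exp(eta$eta_cl)
}

#' Individual apparent volume of distribution
#'
#' `V/F = theta_V * exp(eta_V)`, with a `(WT/ref)^beta` power term under the
#' weight-incorporated variant.
#'
#' @inheritParams individual_clearance
#' @return Apparent volume, L.
#' @export
individual_volume <- function(params, cov, eta = random_effects()) {
  stopifnot(inherits(params, "pk_parameters"),
            inherits(cov, "covariate_profile"))
  v <- params$v_pop
  if (params$variant == "weight_incorporated") {
    v <- v * (cov$wt / params$wt_ref)^params$beta_wt_v
  }
  v * exp(eta$eta_v)
}

#' Individual absorption rate constant
#'
#' No covariates act on absorption; only the random effect applies.
#'
#' @inheritParams individual_clearance
#' @return Absorption rate constant, 1/h.
#' @export
individual_ka <- function(params, eta = random_effects()) {
  params$ka_pop * exp(eta$eta_ka)
}

# baseline (t = 0) structural parameters of one subject; used by the solver,
# the simulator, and the estimation machinery
.subject_structural <- function(params, cov, eta) {
  c(ka = individual_ka(params, eta),
    v = individual_volume(params, cov, eta),
    cl0 = individual_clearance(params, cov, eta, t = 0))
}

#' Apply proportional residual error
#'
#' Observation model `Y_obs = Y_pred * (1 + eps)`, `eps ~ N(0, sigma^2)`.
#' Draws that would yield a negative observation (`eps < -1`) are floored at
#' `floor` by default; `resample = TRUE` redraws them instead, preserving
#' positivity without a point mass at the floor.
#'
#' @param pred Predicted concentrations, mg/L (non-negative).
#' @param sigma_prop Proportional residual SD (>= 0).
#' @param floor Lower truncation bound for the observation, default 0.
#' @param resample Redraw instead of flooring negative observations.
#' @param seed Optional integer seed applied locally for reproducibility.
#' @return Observed concentrations, mg/L.
#' @export
apply_residual_error <- function(pred, sigma_prop, floor = 0,
                                 resample = FALSE, seed = NULL) {
  if (sigma_prop < 0) stop("sigma_prop must be >= 0", call. = FALSE)
  if (any(pred < 0)) stop("pred must be >= 0", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  eps <- stats::rnorm(length(pred), 0, sigma_prop)
  if (resample && sigma_prop > 0) {
    bad <- which(eps < -1 & pred > 0)
    while (length(bad)) {
      eps[bad] <- stats::rnorm(length(bad), 0, sigma_prop)
      bad <- bad[eps[bad] < -1]
    }
  }
  pmax(pred * (1 + eps), floor)
}
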