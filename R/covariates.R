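#' Subject covariates
#'
#' @param wt Body weight, kg.
#' @param crcl Creatinine clearance (Cockcroft-Gault), mL/min.
#' @param country One of `"chinese"`, `"american"`, `"japanese"`.
#' @return A `covariate_profile` object.
#' @export
covariate_profile <- function(wt = 60, crcl = 95.14,
                              country = c("chinese", "american", "japanese")) {
  country <- match.arg(country)
  stopifnot(wt > 0, crcl > 0)
  structure(list(wt = wt, crcl = crcl, country = country),
            class = "covariate_profile")
}

#' Subject-level random effects (log-scale deviations)
#'
#' All-zero random effects describe the typical subject.
#'
#' @param eta_cl,eta_v,eta_ka Log-scale deviations of clearance, volume, and
#'   absorption rate; unitless, finite.
#' @return A `random_effects` object.
#' @export
random_effects <- function(eta_cl = 0, eta_v = 0, eta_ka = 0) {
  stopifnot(is.finite(eta_cl), is.finite(eta_v), is.finite(eta_ka))
  structure(list(eta_cl = eta_cl, eta_v = eta_v, eta_ka = eta_ka),
            class = "random_effects")
}

#' Renal-function category from creatinine clearance
#'
#' Categories follow the usual cut-offs: normal (> 90 mL/min), mild
#' impairment (60-90], moderate (30-60], severe (<= 30).
#'
#' @param crcl Creatinine clearance values, mL/min.
#' @return A factor with levels normal, mild, moderate, severe.
#' @export
renal_category <- function(crcl) {
  stopifnot(all(crcl > 0))
  cut(crcl, breaks = c(0, 30, 60, 90, Inf),
      labels = c("severe", "moderate", "mild", "normal"),
      right = TRUE) |>
    factor(levels = c("normal", "mild", "moderate", "severe"))
}
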