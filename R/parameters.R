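#' Population pharmacokinetic parameter set
#'
#' Container for the fixed effects, random-effect standard deviations, and
#' residual-error magnitude of a one-compartment subcutaneous-absorption model
#' with Emax-type time-dependent clearance:
#' \deqn{CL/F(t) = \theta_{CL} \cdot g(\mathrm{cov}) \cdot
#'   e^{E_{max} t / (T_{50} + t)} \cdot e^{\eta_{CL}}}
#' All parameters are apparent (CL/F, V/F); bioavailability is not separable
#' for a purely subcutaneous program and no F parameter exists in the model.
#'
#' Three covariate `variant`s are supported:
#' * `"base"`: no covariates; all exponents 0, all multipliers 1.
#' * `"final"`: a power term on creatinine clearance (reference
#'   `crcl_ref` mL/min) and country multipliers on clearance.
#' * `"weight_incorporated"`: additionally power terms of body weight
#'   (reference `wt_ref` kg) on clearance and volume.
#'
#' @param cl_pop Typical apparent clearance, L/h.
#' @param v_pop Typical apparent central volume, L.
#' @param ka_pop First-order absorption rate constant, 1/h.
#' @param emax Maximum fractional change of log clearance with treatment time
#'   (negative for a clearance that falls over time); unitless.
#' @param t50 Time at which half the maximal clearance change is reached,
#'   days. Converted to hours (x 24) when the model is evaluated.
#' @param beta_crcl Power exponent of creatinine clearance on CL/F.
#' @param frac_american,frac_japanese Country multipliers on CL/F
#'   (Chinese = reference, multiplier 1).
#' @param beta_wt_cl,beta_wt_v Power exponents of body weight on CL/F and V/F
#'   (weight-incorporated variant only).
#' @param omega_cl,omega_v,omega_ka Standard deviations of the log-normal
#'   inter-individual random effects (approximate CVs).
#' @param sigma_prop Proportional residual-error standard deviation.
#' @param variant Covariate model variant, see Details.
#' @param crcl_ref,wt_ref Reference covariate values used by the power terms.
#'
#' @return An object of class `pk_parameters` (a named list).
#' @seealso [final_model_parameters()], [weight_model_parameters()],
#'   [base_model_parameters()] for published defaults.
#' @export
pk_parameters <- function(cl_pop, v_pop, ka_pop,
                          emax = 0, t50 = 1,
                          beta_crcl = 0,
                          frac_american = 1, frac_japanese = 1,
                          beta_wt_cl = 0, beta_wt_v = 0,
                          omega_cl = 0, omega_v = 0, omega_ka = 0,
                          sigma_prop = 0,
                          variant = c("base", "final", "weight_incorporated"),
                          crcl_ref = 95.14, wt_ref = 63) {
  variant <- match.arg(variant)
  stopifnot(
    cl_pop > 0, v_pop > 0, ka_pop > 0, t50 > 0, sigma_prop >= 0,
    omega_cl >= 0, omega_v >= 0, omega_ka >= 0,
    crcl_ref > 0, wt_ref > 0,
    is.finite(emax)
  )
  if (variant == "base" &&
      (beta_crcl != 0 || frac_american != 1 || frac_japanese != 1 ||
       beta_wt_cl != 0 || beta_wt_v != 0)) {
    stop("variant = \"base\" forbids non-neutral covariate coefficients",
         call. = FALSE)
  }
  if (variant == "final" && (beta_wt_cl != 0 || beta_wt_v != 0)) {
    stop("weight exponents require variant = \"weight_incorporated\"",
         call. = FALSE)
  }
  structure(
    list(
      cl_pop = cl_pop, v_pop = v_pop, ka_pop = ka_pop,
      emax = emax, t50 = t50,
      beta_crcl = beta_crcl,
      frac_american = frac_american, frac_japanese = frac_japanese,
      beta_wt_cl = beta_wt_cl, beta_wt_v = beta_wt_v,
      omega_cl = omega_cl, omega_v = omega_v, omega_ka = omega_ka,
      sigma_prop = sigma_prop,
      variant = variant,
      crcl_ref = crcl_ref, wt_ref = wt_ref
    ),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters> variant:", x$variant, "\n")
  cat(sprintf("  CL/F %.4g L/h | V/F %.4g L | Ka %.4g 1/h | Emax %.4g | T50 %.4g d\n",
              x$cl_pop, x$v_pop, x$ka_pop, x$emax, x$t50))
  if (x$variant != "base") {
    cat(sprintf("  CRCL^%.3g (ref %.4g) | US x%.3g | JP x%.3g",
                x$beta_crcl, x$crcl_ref, x$frac_american, x$frac_japanese))
    if (x$variant == "weight_incorporated") {
      cat(sprintf(" | WT^%.3g on CL, WT^%.3g on V (ref %.3g kg)",
                  x$beta_wt_cl, x$beta_wt_v, x$wt_ref))
    }
    cat("\n")
  }
  cat(sprintf("  omega (CL, V, Ka): %.3g, %.3g, %.3g | sigma_prop %.3g\n",
              x$omega_cl, x$omega_v, x$omega_ka, x$sigma_prop))
  invisible(x)
}

# Published typical values for envafolimab, a subcutaneously dosed anti-PD-L1
# single-domain antibody-Fc fusion, in patients with advanced solid tumors.
# The residual-error magnitude is reported as "epsilon" 0.0501; the dominant
# convention for a proportional-error model reports the variance sigma^2, so
# the default interprets it as a variance (SD ~0.224). Set
# `epsilon_is_variance = FALSE` for the SD reading.
.default_theta <- list(cl = 0.0478, v = 15.5, ka = 0.0147,
                       emax = -0.439, t50 = 34.0,
                       omega_cl = 0.306, omega_v = 0.558, omega_ka = 0.609,
                       epsilon = 0.0501)

.sigma_from_epsilon <- function(epsilon, epsilon_is_variance) {
  if (epsilon_is_variance) sqrt(epsilon) else epsilon
}

#' Published parameter sets for a subcutaneous anti-PD-L1 antibody
#'
#' Convenience constructors pre-filled with the reported population estimates
#' for envafolimab: `base_model_parameters()` (structural model only),
#' `final_model_parameters()` (creatinine-clearance power term and country
#' multipliers on clearance), and `weight_model_parameters()` (body-weight
#' power terms added to clearance and volume).
#'
#' @param epsilon_is_variance Interpret the reported residual "epsilon"
#'   (0.0501) as the variance sigma^2 (default) rather than the SD.
#' @param ... Overrides passed on to [pk_parameters()].
#' @return A [pk_parameters()] object.
#' @export
final_model_parameters <- function(epsilon_is_variance = TRUE, ...) {
  d <- .default_theta
  args <- list(
    cl_pop = d$cl, v_pop = d$v, ka_pop = d$ka, emax = d$emax, t50 = d$t50,
    beta_crcl = 0.475, frac_american = 0.891, frac_japanese = 0.740,
    omega_cl = d$omega_cl, omega_v = d$omega_v, omega_ka = d$omega_ka,
    sigma_prop = .sigma_from_epsilon(d$epsilon, epsilon_is_variance),
    variant = "final"
  )
  do.call(pk_parameters, utils::modifyList(args, list(...)))
}

#' @rdname final_model_parameters
#' @export
weight_model_parameters <- function(epsilon_is_variance = TRUE, ...) {
  d <- .default_theta
  args <- list(
    cl_pop = d$cl, v_pop = d$v, ka_pop = d$ka, emax = d$emax, t50 = d$t50,
    beta_crcl = 0.412, frac_american = 0.842, frac_japanese = 0.73,
    beta_wt_cl = 0.155, beta_wt_v = 0.623,
    omega_cl = d$omega_cl, omega_v = d$omega_v, omega_ka = d$omega_ka,
    sigma_prop = .sigma_from_epsilon(d$epsilon, epsilon_is_variance),
    variant = "weight_incorporated"
  )
  do.call(pk_parameters, utils::modifyList(args, list(...)))
}

#' @rdname final_model_parameters
#' @export
base_model_parameters <- function(epsilon_is_variance = TRUE, ...) {
  d <- .default_theta
  args <- list(
    cl_pop = d$cl, v_pop = d$v, ka_pop = d$ka, emax = d$emax, t50 = d$t50,
    omega_cl = d$omega_cl, omega_v = d$omega_v, omega_ka = d$omega_ka,
    sigma_prop = .sigma_from_epsilon(d$epsilon, epsilon_is_variance),
    variant = "base"
  )
  do.call(pk_parameters, utils::modifyList(args, list(...)))
}

#' Serialize parameters to / from flat key-value configuration
#'
#' Parameters round-trip through a flat named list whose keys match the
#' field names of [pk_parameters()], suitable for YAML or JSON configs.
#'
#' @param params A `pk_parameters` object.
#' @param path Optional file path; extension `.yaml`/`.yml` or `.json`
#'   chooses the dialect.
#' @return `params_to_list()` returns a named list; `params_from_list()` and
#'   `read_pk_parameters()` return a `pk_parameters` object;
#'   `write_pk_parameters()` returns `path` invisibly.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "pk_parameters"))
  unclass(params)
}

#' @rdname params_to_list
#' @param x A named list with `pk_parameters` fields.
#' @export
params_from_list <- function(x) {
  known <- names(formals(pk_parameters))
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("unknown parameter keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(pk_parameters, x)
}

#' @rdname params_to_list
#' @export
write_pk_parameters <- function(params, path) {
  x <- params_to_list(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 12)
  }
  invisible(path)
}

#' @rdname params_to_list
#' @export
read_pk_parameters <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(x)
}
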