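#' Default adverse-event catalog
#'
#' Marginal incidences of the adverse events of clinical interest reported
#' for a subcutaneous anti-PD-L1 antibody program (increased AST 16.2%,
#' increased ALT 14.6%, increased blood bilirubin 12.2%, rash 11.7%, ...).
#' Grade probabilities default to mostly grade 1-2 with a small grade >= 3
#' tail; all catalog entries are drug-related AESIs.
#'
#' @return A tibble with columns `name`, `incidence`, `grade_probs`
#'   (list-column over grades 1-5), `drug_related`, `serious_prob`, `aesi`.
#' @export
default_ae_catalog <- function() {
  nm <- c("increased AST", "increased ALT", "increased blood bilirubin",
          "rash", "hypothyroidism", "anemia", "hyperthyroidism", "fever",
          "diarrhea", "injection site reactions", "proteinuria",
          "abnormal hepatic function",
          "increased blood thyroid-stimulating hormone", "hyponatremia",
          "pruritus")
  inc <- c(0.162, 0.146, 0.122, 0.117, 0.104, 0.084, 0.055, 0.044, 0.040,
           0.040, 0.040, 0.033, 0.031, 0.027, 0.027)
  tibble::tibble(
    name = nm,
    incidence = inc,
    grade_probs = rep(list(c(0.55, 0.33, 0.10, 0.02, 0)), length(nm)),
    drug_related = TRUE,
    serious_prob = 0.03,
    aesi = TRUE
  )
}

#' Outcome model specification for synthetic efficacy/safety data
#'
#' Defines how per-subject exposures map to outcomes. Defaults encode flat
#' exposure-response relationships (zero slopes), the behavior expected for
#' a target-saturating checkpoint inhibitor at therapeutic doses, so that
#' the exposure-response stage should return a "flat" verdict on data
#' generated with the defaults.
#'
#' @param response_intercept Logit-scale intercept of the objective-response
#'   probability.
#' @param response_slope Logit-scale slope on centered log exposure.
#' @param p_cr_given_response Probability a responder is a complete
#'   response.
#' @param p_sd_given_nonresponse Probability a non-responder is stable
#'   disease (the rest split PD/NE 9:1).
#' @param lesion_change_mean,lesion_change_sd Mean/SD of percent change in
#'   target lesion size for non-responders; responders are shifted by
#'   `lesion_change_response_shift`.
#' @param lesion_change_response_shift Additive shift (%) for responders.
#' @param lesion_change_slope Slope of lesion change on centered log
#'   exposure.
#' @param dor_event_rate Exponential hazard of response ending, 1/day.
#' @param dor_exposure_effect Log-hazard slope on centered log exposure.
#' @param censoring_rate Exponential censoring hazard for DOR, 1/day.
#' @param ae_catalog Adverse-event catalog, see [default_ae_catalog()].
#' @param ae_exposure_slope Logit-scale slope of AE occurrence on centered
#'   log exposure (applies to every catalog entry).
#' @return An `outcome_model_spec` object.
#' @export
outcome_model_spec <- function(response_intercept = stats::qlogis(0.30),
                               response_slope = 0,
                               p_cr_given_response = 0.10,
                               p_sd_given_nonresponse = 0.45,
                               lesion_change_mean = 5,
                               lesion_change_sd = 30,
                               lesion_change_response_shift = -45,
                               lesion_change_slope = 0,
                               dor_event_rate = log(2) / 304,
                               dor_exposure_effect = 0,
                               censoring_rate = 1 / 600,
                               ae_catalog = default_ae_catalog(),
                               ae_exposure_slope = 0) {
  stopifnot(dor_event_rate > 0, censoring_rate >= 0,
            all(ae_catalog$incidence >= 0 & ae_catalog$incidence <= 1))
  structure(as.list(environment()), class = "outcome_model_spec")
}

#' Generate synthetic efficacy and safety outcomes
#'
#' Draws one outcome record per exposure row: best overall response from a
#' logistic model on centered log exposure, percent lesion change from a
#' Gaussian, duration of response (responders only) from an exponential with
#' optional exposure effect and independent exponential censoring, and
#' adverse events as independent Bernoulli draws per catalog entry with
#' grade sampled from the entry's grade distribution.
#'
#' @param exposures Tibble with `id` and an exposure column named by
#'   `exposure_metric` (e.g. from [simulate_regimen()]`$metrics`).
#' @param spec An [outcome_model_spec()].
#' @param exposure_metric Name of the exposure column driving the outcome
#'   models.
#' @param seed Integer seed (applied locally).
#' @return A list with `records` (tibble: `id`, exposure columns, `response`
#'   in CR/PR/SD/PD/NE, `lesion_change`, `dor_days`, `dor_censored`) and
#'   `aes` (tibble: `id`, `name`, `grade`, `drug_related`, `serious`,
#'   `aesi`). Rows with a missing exposure are skipped with a warning.
#' @export
generate_outcomes <- function(exposures, spec = outcome_model_spec(),
                              exposure_metric = "cmin_1", seed = NULL) {
  stopifnot(inherits(spec, "outcome_model_spec"))
  if (!exposure_metric %in% names(exposures)) {
    stop("exposure metric not found: ", exposure_metric, call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  x <- exposures[[exposure_metric]]
  miss <- !is.finite(x) | x <= 0
  if (any(miss)) {
    warning(sum(miss), " subjects skipped: missing exposure", call. = FALSE)
    exposures <- exposures[!miss, ]
    x <- x[!miss]
  }
  n <- nrow(exposures)
  lx <- log(x) - mean(log(x))
  p_resp <- stats::plogis(spec$response_intercept + spec$response_slope * lx)
  responder <- stats::runif(n) < p_resp
  response <- character(n)
  response[responder] <- ifelse(
    stats::runif(sum(responder)) < spec$p_cr_given_response, "CR", "PR")
  nr <- !responder
  u <- stats::runif(sum(nr))
  response[nr] <- ifelse(u < spec$p_sd_given_nonresponse, "SD",
                         ifelse(u < spec$p_sd_given_nonresponse +
                                  0.9 * (1 - spec$p_sd_given_nonresponse),
                                "PD", "NE"))
  lesion <- stats::rnorm(n, spec$lesion_change_mean +
                           spec$lesion_change_slope * lx +
                           ifelse(responder,
                                  spec$lesion_change_response_shift, 0),
                         spec$lesion_change_sd)
  dor_days <- rep(NA_real_, n)
  dor_cens <- rep(NA, n)
  if (any(responder)) {
    rate <- spec$dor_event_rate * exp(spec$dor_exposure_effect * lx[responder])
    t_event <- stats::rexp(sum(responder), rate)
    t_cens <- if (spec$censoring_rate > 0) {
      stats::rexp(sum(responder), spec$censoring_rate)
    } else {
      rep(Inf, sum(responder))
    }
    dor_days[responder] <- pmin(t_event, t_cens)
    dor_cens[responder] <- t_cens < t_event
  }
  aes <- lapply(seq_len(nrow(spec$ae_catalog)), function(k) {
    entry <- spec$ae_catalog[k, ]
    p <- stats::plogis(stats::qlogis(entry$incidence) +
                         spec$ae_exposure_slope * lx)
    hit <- which(stats::runif(n) < p)
    if (!length(hit)) return(NULL)
    tibble::tibble(
      id = exposures$id[hit],
      name = entry$name,
      grade = sample(1:5, length(hit), replace = TRUE,
                     prob = entry$grade_probs[[1]]),
      drug_related = entry$drug_related,
      serious = stats::runif(length(hit)) < entry$serious_prob,
      aesi = entry$aesi
    )
  })
  list(
    records = dplyr::bind_cols(
      exposures,
      tibble::tibble(response = response, lesion_change = lesion,
                     dor_days = dor_days, dor_censored = dor_cens)),
    aes = dplyr::bind_rows(aes)
  )
}
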