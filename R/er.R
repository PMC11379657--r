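#' Quartile summary of efficacy and safety by exposure
#'
#' Splits subjects into exposure quartiles (cut points at the 25th/50th/75th
#' percentiles; values tied with a cut point fall in the lower quartile) and
#' tabulates response categories, objective response rate
#' (ORR = (CR+PR)/n), disease control rate (DCR = (CR+PR+SD)/n), and, when
#' an AE table is supplied, the incidence of subjects with at least one
#' qualifying adverse event. Not-evaluable (NE) subjects are excluded from
#' the ORR/DCR denominators but counted in the quartile totals.
#'
#' @param records Tibble with `id`, an exposure column, and optionally
#'   `response`.
#' @param exposure_metric Name of the exposure column.
#' @param aes Optional AE tibble (`id`, `name`, `grade`, ...).
#' @return A `quartile_summary` tibble: one row per quartile with `n`,
#'   response-category counts, `orr_pct`, `dcr_pct`, and AE incidence.
#' @export
quartile_summary <- function(records, exposure_metric, aes = NULL) {
  x <- records[[exposure_metric]]
  if (is.null(x)) stop("exposure metric not found: ", exposure_metric,
                       call. = FALSE)
  ok <- is.finite(x)
  if (sum(ok) < 4) stop("need >= 4 non-missing values of ", exposure_metric,
                        call. = FALSE)
  records <- records[ok, ]
  x <- x[ok]
  cuts <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7)
  # ties with a cut point belong to the lower quartile
  qt <- 1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])
  records$quartile <- qt
  per_q <- lapply(1:4, function(k) {
    d <- records[records$quartile == k, ]
    n <- nrow(d)
    out <- tibble::tibble(quartile = k, n = n,
                          exposure_lo = if (n) min(d[[exposure_metric]]) else NA_real_,
                          exposure_hi = if (n) max(d[[exposure_metric]]) else NA_real_)
    if ("response" %in% names(d)) {
      cnt <- table(factor(d$response, levels = c("CR", "PR", "SD", "PD", "NE")))
      denom <- n - cnt[["NE"]]
      out$cr <- cnt[["CR"]]; out$pr <- cnt[["PR"]]; out$sd_n <- cnt[["SD"]]
      out$pd <- cnt[["PD"]]; out$ne <- cnt[["NE"]]
      out$orr_pct <- if (denom > 0) 100 * (cnt[["CR"]] + cnt[["PR"]]) / denom else NA_real_
      out$dcr_pct <- if (denom > 0) {
        100 * (cnt[["CR"]] + cnt[["PR"]] + cnt[["SD"]]) / denom
      } else {
        NA_real_
      }
    }
    if (!is.null(aes)) {
      out$ae_incidence_pct <- if (n) {
        100 * mean(d$id %in% aes$id)
      } else {
        NA_real_
      }
      out$ae_grade3plus_pct <- if (n) {
        100 * mean(d$id %in% aes$id[aes$grade >= 3])
      } else {
        NA_real_
      }
    }
    out
  })
  out <- dplyr::bind_rows(per_q)
  class(out) <- c("quartile_summary", class(out))
  out
}

#' Logistic exposure-response regression
#'
#' Maximum-likelihood logistic regression of a binary outcome on (log)
#' exposure via iteratively reweighted least squares (coefficient
#' convergence tolerance 1e-8), reporting the slope, Wald confidence
#' interval, p-value, and odds ratio per unit of the exposure scale.
#' Complete separation is flagged as an error rather than returning
#' divergent estimates.
#'
#' @param y Binary outcomes (0/1 or logical).
#' @param x Exposure values; log-transformed when `log_exposure = TRUE`
#'   (the standard choice for log-normally distributed exposures).
#' @param log_exposure Regress on `log(x)`.
#' @param conf_level Confidence level for the Wald interval.
#' @return A tibble with `intercept`, `slope`, `slope_se`, `slope_lo`,
#'   `slope_hi`, `p_value`, `odds_ratio`.
#' @export
logistic_regression <- function(y, x, log_exposure = TRUE,
                                conf_level = 0.95) {
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1), length(y) == length(x))
  if (length(unique(y)) < 2) {
    stop("complete separation: only one outcome class present",
         call. = FALSE)
  }
  xr <- if (log_exposure) log(x) else x
  fit <- suppressWarnings(
    stats::glm(y ~ xr, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  if (max(abs(stats::coef(fit))) > 1e2) {
    stop("complete separation detected; no stable estimates", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    intercept = co[1, 1], slope = co[2, 1], slope_se = co[2, 2],
    slope_lo = co[2, 1] - z * co[2, 2], slope_hi = co[2, 1] + z * co[2, 2],
    p_value = co[2, 4], odds_ratio = exp(co[2, 1])
  )
}

#' Kaplan-Meier estimate of duration of response
#'
#' Product-limit estimator wrapped from the survival package, returned as a
#' tidy curve with at-risk counts and the median (the earliest time at which
#' the survival estimate drops to 0.5 or below; `NA` when never reached).
#' With a grouping factor, a log-rank test compares the groups.
#'
#' @param times Positive event/censoring times.
#' @param censored Logical: `TRUE` when the subject was censored (no event).
#' @param group Optional grouping factor (e.g. above/below median exposure).
#' @return A `km_curve` object: list with `curve` (tibble: `time`,
#'   `n_risk`, `n_event`, `surv`, `group`), `median` (per group), and
#'   `logrank_p` (when grouped).
#' @export
km_estimator <- function(times, censored, group = NULL) {
  if (!length(times)) stop("empty input", call. = FALSE)
  stopifnot(all(times > 0), length(censored) == length(times))
  event <- as.integer(!censored)
  if (is.null(group)) {
    sf <- survival::survfit(survival::Surv(times, event) ~ 1)
    curve <- tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                            n_event = sf$n.event, surv = sf$surv,
                            group = "all")
    med <- unname(summary(sf)$table["median"])
    lr <- NA_real_
  } else {
    group <- as.factor(group)
    sf <- survival::survfit(survival::Surv(times, event) ~ group)
    strata <- rep(names(sf$strata), sf$strata)
    curve <- tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                            n_event = sf$n.event, surv = sf$surv,
                            group = sub("^group=", "", strata))
    tab <- summary(sf)$table
    med <- stats::setNames(tab[, "median"], sub("^group=", "", rownames(tab)))
    lr <- tryCatch({
      sd <- survival::survdiff(survival::Surv(times, event) ~ group)
      stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
    }, error = function(e) NA_real_)
  }
  structure(list(curve = curve, median = med, logrank_p = lr),
            class = "km_curve")
}

#' Filter adverse events of clinical interest (AECI)
#'
#' An AE qualifies as an AECI when it is drug-related and (a) grade 3 or
#' higher, or (b) serious, or (c) an AE of special interest whose incidence
#' exceeds 2.5% of the analysis population.
#'
#' @param ae_records AE tibble (`id`, `name`, `grade`, `drug_related`,
#'   `serious`, `aesi`).
#' @param population_n Size of the analysis population (> 0).
#' @param aesi_incidence_threshold Incidence threshold for the AESI
#'   criterion (fraction; default 0.025).
#' @return The qualifying AE rows with a `criterion` column.
#' @export
aeci_filter <- function(ae_records, population_n,
                        aesi_incidence_threshold = 0.025) {
  if (population_n <= 0) stop("population_n must be > 0", call. = FALSE)
  if (!nrow(ae_records)) return(ae_records)
  inc <- ae_records |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(incidence = dplyr::n_distinct(.data$id) / population_n,
                     .groups = "drop")
  ae <- dplyr::left_join(ae_records, inc, by = "name")
  sev <- ae$drug_related & ae$grade >= 3
  ser <- ae$drug_related & ae$serious
  asi <- ae$drug_related & ae$aesi & ae$incidence > aesi_incidence_threshold
  keep <- sev | ser | asi
  out <- ae[keep, ]
  out$criterion <- dplyr::case_when(
    sev[keep] ~ "grade>=3",
    ser[keep] ~ "serious",
    TRUE ~ "aesi>2.5%"
  )
  out
}

#' Exposure-response report
#'
#' Runs the full exposure-response stage for each requested exposure metric:
#' quartile summaries of best response and AECI incidence, logistic
#' regressions of objective response and AECI occurrence on log exposure,
#' and a Kaplan-Meier comparison of duration of response stratified at the
#' metric's median among responders. The per-metric flatness verdict is
#' `"flat"` when none of the metric's component tests (regression slopes,
#' log-rank) is significant at `alpha` after Holm adjustment, which controls
#' the family-wise error of the verdict.
#'
#' @param records Outcome tibble from [generate_outcomes()]`$records` (or
#'   equivalent real data).
#' @param aes AE tibble.
#' @param metrics Character vector of exposure-metric column names.
#' @param alpha Significance level for the flatness verdict.
#' @return An `er_report`: named list per metric with `quartiles`,
#'   `logistic_orr`, `logistic_aeci`, `km`, `verdict`; plus a `verdicts`
#'   tibble at the top level. Metrics missing for all subjects are skipped
#'   with a note.
#' @export
er_report <- function(records, aes,
                      metrics = c("cmin_1", "cavg_1", "auc_inf_1",
                                  "cmin_overall"),
                      alpha = 0.05) {
  population_n <- nrow(records)
  aeci <- aeci_filter(aes, population_n)
  out <- list()
  skipped <- character()
  for (m in metrics) {
    if (!m %in% names(records) || !any(is.finite(records[[m]]))) {
      skipped <- c(skipped, m)
      next
    }
    d <- records[is.finite(records[[m]]), ]
    res <- list()
    res$quartiles <- quartile_summary(d, m, aes = aeci)
    responder <- d$response %in% c("CR", "PR")
    eval_mask <- d$response != "NE"
    res$logistic_orr <- tryCatch(
      logistic_regression(responder[eval_mask], d[[m]][eval_mask]),
      error = function(e) NULL)
    has_aeci <- d$id %in% aeci$id
    res$logistic_aeci <- tryCatch(
      logistic_regression(has_aeci, d[[m]]),
      error = function(e) NULL)
    dor <- d[responder & is.finite(d$dor_days), ]
    res$km <- if (nrow(dor) >= 4) {
      med_exp <- stats::median(dor[[m]])
      km_estimator(dor$dor_days, dor$dor_censored,
                   group = ifelse(dor[[m]] > med_exp, "high", "low"))
    } else {
      NULL
    }
    pvals <- c(
      if (!is.null(res$logistic_orr)) res$logistic_orr$p_value,
      if (!is.null(res$logistic_aeci)) res$logistic_aeci$p_value,
      if (!is.null(res$km)) res$km$logrank_p
    )
    pvals <- pvals[is.finite(pvals)]
    # Holm adjustment controls the family-wise error of the per-metric
    # verdict across its component tests
    padj <- stats::p.adjust(pvals, method = "holm")
    res$p_values <- pvals
    res$verdict <- if (length(padj) && all(padj > alpha)) "flat" else "non-flat"
    out[[m]] <- res
  }
  verdicts <- tibble::tibble(
    metric = names(out),
    verdict = unname(vapply(out, `[[`, character(1), "verdict"))
  )
  structure(list(metrics = out, verdicts = verdicts, skipped = skipped,
                 aeci = aeci),
            class = "er_report")
}

#' @export
print.er_report <- function(x, ...) {
  cat("<er_report>\n")
  print(x$verdicts)
  if (length(x$skipped)) {
    cat("skipped metrics (all missing):", paste(x$skipped, collapse = ", "),
        "\n")
  }
  invisible(x)
}
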