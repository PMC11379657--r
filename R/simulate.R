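#' Simulate a dosing regimen across a population
#'
#' Simulates true (residual-error-free) concentration profiles for every
#' subject in `population` on a dense grid, derives per-subject
#' [exposure_metrics()] and accumulation ratios, and summarizes the
#' concentration-time bands (median and 90% interval across subjects).
#'
#' @param population Tibble from [sample_population()] (or any tibble with
#'   `id`, `country`, `wt`, `crcl`, `eta_cl`, `eta_v`, `eta_ka`).
#' @param doses Dose-event table, e.g. [regimen_qw()].
#' @param params A [pk_parameters()].
#' @param duration_weeks Simulated duration, weeks; must cover at least two
#'   dosing intervals.
#' @param grid_h Output grid step, h (1 h is sufficient by grid-halving
#'   convergence; see the methods vignette).
#' @return A list with `metrics` (one row per subject: first-cycle and
#'   steady-state metrics, accumulation ratios), `bands` (grid time, median,
#'   5th and 95th percentile concentration), `grid`, and `doses`.
#' @export
simulate_regimen <- function(population, doses, params, duration_weeks = 20,
                             grid_h = 1) {
  tau <- if (nrow(doses) > 1) doses$time[2] - doses$time[1] else Inf
  if (duration_weeks * 168 < 2 * tau) {
    stop("duration must cover at least two dosing intervals", call. = FALSE)
  }
  grid <- seq(0, duration_weeks * 168, by = grid_h)
  conc <- matrix(NA_real_, length(grid), nrow(population))
  met <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    row <- population[i, ]
    cov <- .row_cov(row)
    eta <- .row_eta(row)
    ci <- solve_profile(params, cov, eta, doses, grid, hmax = grid_h)
    conc[, i] <- ci
    m <- exposure_metrics(grid, ci, doses,
                          baseline_cl = individual_clearance(params, cov, eta,
                                                             t = 0),
                          wt = cov$wt)
    rr <- accumulation_ratios(m)
    met[[i]] <- tibble::tibble(
      id = row$id,
      cmax_1 = m$cmax_1, cmin_1 = m$cmin_1, cavg_1 = m$cavg_1,
      auc_tau_1 = m$auc_tau_1, auc_inf_1 = m$auc_inf_1,
      cmax_ss = m$cmax_ss, cmin_ss = m$cmin_ss, cavg_ss = m$cavg_ss,
      auc_tau_ss = m$auc_tau_ss, cmin_overall = m$cmin_overall,
      r_cmax = rr[["r_cmax"]], r_auc = rr[["r_auc"]]
    )
  }
  bands <- tibble::tibble(
    time = grid,
    median = apply(conc, 1, stats::median),
    p5 = apply(conc, 1, stats::quantile, probs = 0.05),
    p95 = apply(conc, 1, stats::quantile, probs = 0.95)
  )
  list(metrics = dplyr::bind_rows(met), bands = bands, grid = grid,
       doses = doses)
}

#' Virtual population for regimen-comparison simulations
#'
#' Builds the default simulation population for accumulation-ratio and
#' threshold-attainment tables. Three modes control where between-subject
#' variability comes from:
#' * `"covariate"` (default): study-like covariate distributions (CRCL
#'   log-normal, per-country weights), random effects at zero. The
#'   between-subject spread of accumulation ratios then reflects covariate
#'   differences only, matching the modest CVs (14-18%) reported for such
#'   tables; full random-effect variability produces far wider, right-skewed
#'   ratio distributions.
#' * `"iiv"`: typical covariates, random effects drawn from the omegas.
#' * `"both"`: covariates and random effects both vary.
#'
#' @param n Number of virtual subjects.
#' @param params A [pk_parameters()] supplying omegas for the iiv modes.
#' @param mode Variability mode, see Details.
#' @param country Country of the virtual population (default Chinese).
#' @param seed Integer seed (applied locally).
#' @return A population tibble suitable for [simulate_regimen()].
#' @export
simulation_population <- function(n, params,
                                  mode = c("covariate", "iiv", "both"),
                                  country = "chinese", seed = NULL) {
  mode <- match.arg(mode)
  p <- params
  if (mode == "covariate") {
    p <- params_from_list(utils::modifyList(
      params_to_list(params), list(omega_cl = 0, omega_v = 0, omega_ka = 0)))
  }
  mix <- c(chinese = 0, american = 0, japanese = 0)
  mix[country] <- 1
  spec <- population_spec(n, country_mix = mix)
  pop <- sample_population(spec, p, seed = seed)
  if (mode == "iiv") {
    pop$crcl <- spec$crcl_median
    pop$wt <- unname(spec$wt_median[country])
    pop$renal_category <- renal_category(pop$crcl)
  }
  pop
}

# single typical subject (etas 0) helper
.typical_population <- function(cov) {
  tibble::tibble(id = 1L, country = cov$country, wt = cov$wt,
                 crcl = cov$crcl, eta_cl = 0, eta_v = 0, eta_ka = 0)
}

#' Simulate a typical subject on a regimen
#'
#' Convenience wrapper around [simulate_regimen()] for a single subject with
#' zero random effects and no residual error.
#'
#' @param cov A [covariate_profile()].
#' @inheritParams simulate_regimen
#' @return One-row metrics tibble (see [simulate_regimen()]).
#' @export
simulate_typical <- function(cov, doses, params, duration_weeks = 20,
                             grid_h = 1) {
  simulate_regimen(.typical_population(cov), doses, params,
                   duration_weeks, grid_h)$metrics
}

#' Covariate impact on steady-state exposure
#'
#' Simulates typical subjects (zero random effects, no residual error) at
#' each covariate scenario and reports the percent change of steady-state
#' exposure (`auc_tau_ss`, `cmax_ss`, `cmin_ss`) against the reference
#' scenario. The `clinically_limited` attribute is `TRUE` when no scenario
#' changes any metric by 50% or more, the conventional relevance bound.
#'
#' @param params A [pk_parameters()] (typically the weight-incorporated
#'   variant).
#' @param scenarios Named list of [covariate_profile()] objects.
#' @param reference Name of the reference scenario in `scenarios`.
#' @param doses Dose-event table (default 150 mg weekly).
#' @param duration_weeks Simulated duration, weeks.
#' @return A tibble with one row per non-reference scenario and percent
#'   changes per metric; attribute `clinically_limited`.
#' @export
covariate_impact_table <- function(params, scenarios, reference,
                                   doses = regimen_qw(150),
                                   duration_weeks = 20) {
  if (!reference %in% names(scenarios)) {
    stop("reference scenario not found among scenarios", call. = FALSE)
  }
  met <- lapply(scenarios, simulate_typical, doses = doses, params = params,
                duration_weeks = duration_weeks)
  ref <- met[[reference]]
  rows <- lapply(names(scenarios), function(nm) {
    m <- met[[nm]]
    tibble::tibble(
      scenario = nm,
      auc_ss_pct = 100 * (m$auc_tau_ss / ref$auc_tau_ss - 1),
      cmax_ss_pct = 100 * (m$cmax_ss / ref$cmax_ss - 1),
      cmin_ss_pct = 100 * (m$cmin_ss / ref$cmin_ss - 1)
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::filter(.data$scenario != reference)
  attr(out, "clinically_limited") <-
    all(abs(c(out$auc_ss_pct, out$cmax_ss_pct, out$cmin_ss_pct)) < 50)
  out
}

#' Compare dosing regimens
#'
#' Simulates each regimen over the same population and duration and
#' summarizes steady-state exposure. Because regimens may differ in dosing
#' interval, "steady state" metrics are computed over the final common
#' window (the largest dosing interval among the regimens): the average
#' concentration and the peak over that window. Pairwise relative
#' differences use the pair mean as denominator.
#'
#' @param regimens Named list of dose-event tables.
#' @param population Population tibble (a single typical subject for a
#'   typical-value comparison).
#' @param params A [pk_parameters()].
#' @param duration_weeks Simulated duration, weeks.
#' @return A list with `summary` (per regimen: population mean/SD/CV of
#'   window Cavg and Cmax plus accumulation ratios), `pairwise` (per metric
#'   and regimen pair: relative difference %), and `max_rel_diff_pct`.
#' @export
compare_regimens <- function(regimens, population, params,
                             duration_weeks = 20) {
  if (length(regimens) < 2) stop(">= 2 regimens required", call. = FALSE)
  if (is.null(names(regimens))) names(regimens) <- paste0("regimen", seq_along(regimens))
  window <- max(vapply(regimens, function(d) {
    if (nrow(d) > 1) d$time[2] - d$time[1] else duration_weeks * 168
  }, numeric(1)))
  t_end <- duration_weeks * 168
  sims <- lapply(regimens, function(d) {
    simulate_regimen(population, d, params, duration_weeks)
  })
  per_subject <- lapply(names(sims), function(nm) {
    s <- sims[[nm]]
    idx <- which(s$grid >= t_end - window)
    tt <- s$grid[idx]
    # window metrics per subject from the band grid requires per-subject
    # profiles; recompute cheaply from metrics when intervals match, else
    # from stored bands. Here we resimulate the window per subject.
    mets <- s$metrics
    win <- vapply(seq_len(nrow(population)), function(i) {
      row <- population[i, ]
      ci <- solve_profile(params, .row_cov(row), .row_eta(row),
                          regimens[[nm]], tt)
      c(.trapz(tt, ci) / window, max(ci))
    }, numeric(2))
    tibble::tibble(
      regimen = nm, id = mets$id,
      cavg_window = win[1, ], cmax_window = win[2, ],
      r_cmax = mets$r_cmax, r_auc = mets$r_auc, cmin_ss = mets$cmin_ss
    )
  })
  per_subject <- dplyr::bind_rows(per_subject)
  summary <- per_subject |>
    dplyr::group_by(.data$regimen) |>
    dplyr::summarise(dplyr::across(
      c("cavg_window", "cmax_window", "r_cmax", "r_auc", "cmin_ss"),
      list(mean = mean, sd = stats::sd,
           cv = ~ 100 * stats::sd(.x) / mean(.x))
    ), .groups = "drop")
  pop_means <- per_subject |>
    dplyr::group_by(.data$regimen) |>
    dplyr::summarise(cavg = mean(.data$cavg_window),
                     cmax = mean(.data$cmax_window), .groups = "drop")
  pairs <- utils::combn(pop_means$regimen, 2, simplify = FALSE)
  pairwise <- dplyr::bind_rows(lapply(pairs, function(pr) {
    a <- pop_means[pop_means$regimen == pr[1], ]
    b <- pop_means[pop_means$regimen == pr[2], ]
    tibble::tibble(
      regimen_a = pr[1], regimen_b = pr[2],
      metric = c("cavg_window", "cmax_window"),
      rel_diff_pct = c(
        200 * abs(a$cavg - b$cavg) / (a$cavg + b$cavg),
        200 * abs(a$cmax - b$cmax) / (a$cmax + b$cmax)
      )
    )
  }))
  list(summary = summary, pairwise = pairwise,
       max_rel_diff_pct = max(pairwise$rel_diff_pct))
}
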