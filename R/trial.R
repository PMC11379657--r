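#' Study design: regimen plus sampling schedule
#'
#' @param label Design label.
#' @param doses Dose-event table ([regimen()] etc.).
#' @param sampling_times PK sampling times, h; must fall within the study
#'   duration.
#' @param duration_weeks Study duration, weeks.
#' @return A `study_design` object.
#' @export
study_design <- function(label, doses, sampling_times, duration_weeks) {
  stopifnot(all(sampling_times >= 0))
  if (any(sampling_times > duration_weeks * 168)) {
    stop("sampling times must lie within the study duration", call. = FALSE)
  }
  structure(list(label = label, doses = doses,
                 sampling_times = sort(sampling_times),
                 duration_weeks = duration_weeks),
            class = "study_design")
}

#' Default study designs of the synthetic program
#'
#' Three templates mirroring a pooled phase I/II antibody program:
#' * `rich`: the phase-I weight-based arm — a single 2.5 mg/kg dose with
#'   intensive washout sampling over 4 weeks (the single-dose PK window of
#'   an escalation cohort, which observes the elimination phase directly
#'   and anchors baseline clearance against the time-dependence
#'   parameters), followed by 2.5 mg/kg QW from week 4 with troughs every
#'   2 weeks; 20 samples over 20 weeks.
#' * `rich_q4w`: 300 mg every 4 weeks (the phase-I monthly cohort), 12
#'   samples across the 4-week first interval plus pre-dose troughs.
#' * `sparse`: 150 mg weekly with pre-dose troughs at weeks 2, 4, 6, 8,
#'   10, 12, 16, and 20 (phase-II-like trough-only sampling).
#'
#' With 20 + 10 rich and 152 sparse subjects these designs yield
#' 20 x 20 + 10 x 16 + 152 x 8 = 1776 concentration records, matching the
#' scale of a 182-subject, ~1810-record program.
#'
#' @param weeks Study duration, weeks.
#' @return A named list of three [study_design()] objects.
#' @export
default_study_designs <- function(weeks = 20) {
  washout <- c(1, 4, 8, 24, 48, 96, 120, 168, 240, 336, 504, 672)
  esc_doses <- dose_events(time = c(0, seq(672, (weeks - 1) * 168, by = 168)),
                           amount = 2.5, per_kg = TRUE)
  esc_troughs <- seq(1008, weeks * 168, by = 336)
  q4w_cycle1 <- c(1, 4, 8, 24, 48, 96, 168, 240, 336, 432, 504, 672)
  q4w_troughs <- seq(2 * 672, floor(weeks / 4) * 672, by = 672)
  sparse_troughs <- c(2, 4, 6, 8, 10, 12, 16, 20) * 168
  list(
    rich = study_design("rich_perkg2.5",
                        esc_doses, c(washout, esc_troughs), weeks),
    rich_q4w = study_design("rich_q4w300",
                            regimen(300, 672,
                                    n_doses = floor(weeks * 168 / 672)),
                            c(q4w_cycle1, q4w_troughs), weeks),
    sparse = study_design("sparse_qw150",
                          regimen_qw(150, weeks = weeks),
                          sparse_troughs, weeks)
  )
}

#' Generate a synthetic PK trial dataset
#'
#' Simulates event records for one design: true concentrations from
#' [solve_profile()] at each subject's covariates and random effects, with
#' proportional residual error applied. Per-kg regimens use each subject's
#' weight. The returned table is in the pharmacometric event-record dialect
#' (`ID, TIME, AMT, DV, EVID, MDV, WT, CRCL, COUNTRY`); the generating truth
#' (random effects and parameters) is attached as `attr(x, "truth")` for
#' recovery testing.
#'
#' @param population Tibble from [sample_population()].
#' @param design A [study_design()].
#' @param params A [pk_parameters()].
#' @param seed Optional integer seed (applied locally) for the residual
#'   error draws.
#' @return A tibble of event records with a `truth` attribute.
#' @export
generate_pk_dataset <- function(population, design, params, seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "pk_parameters"))
  if (!is.null(seed)) withr::local_seed(seed)
  recs <- lapply(seq_len(nrow(population)), function(i) {
    row <- population[i, ]
    cov <- .row_cov(row)
    eta <- .row_eta(row)
    pred <- solve_profile(params, cov, eta, design$doses,
                          design$sampling_times)
    dv <- apply_residual_error(pred, params$sigma_prop)
    amt <- .dose_amounts_mg(design$doses, cov$wt)
    dose_rows <- tibble::tibble(ID = row$id, TIME = design$doses$time,
                                AMT = amt, DV = NA_real_, EVID = 1L, MDV = 1L)
    obs_rows <- tibble::tibble(ID = row$id, TIME = design$sampling_times,
                               AMT = NA_real_, DV = dv, EVID = 0L, MDV = 0L)
    dplyr::bind_rows(dose_rows, obs_rows) |>
      dplyr::arrange(.data$TIME, dplyr::desc(.data$EVID)) |>
      dplyr::mutate(WT = row$wt, CRCL = row$crcl, COUNTRY = row$country)
  })
  out <- dplyr::bind_rows(recs)
  attr(out, "truth") <- list(population = population, params = params,
                             design_label = design$label)
  out
}

#' Generate the default two-design study dataset
#'
#' Composes the rich and sparse templates of [default_study_designs()] into a
#' single dataset of `n_rich + n_sparse` subjects with globally unique IDs,
#' emulating a pooled phase I/II analysis population (default 182 subjects,
#' about 1810 concentration records). One third of the rich subjects
#' (rounded) are allocated to the monthly (Q4W) cohort, the rest to the
#' biweekly cohort.
#'
#' @param params A [pk_parameters()].
#' @param n_rich,n_sparse Subjects on the rich and sparse designs.
#' @param spec Optional [population_spec()] shared by both designs (its
#'   `n_subjects` is ignored); the default is an all-Chinese population so
#'   that country multipliers drop out of the typical-value scale.
#' @param weeks Study duration, weeks.
#' @param seed Integer seed controlling covariates, random effects, and
#'   residual error.
#' @return A tibble of event records with a `truth` attribute covering both
#'   arms.
#' @export
generate_study_dataset <- function(params, n_rich = 30, n_sparse = 152,
                                   spec = NULL, weeks = 20, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  designs <- default_study_designs(weeks)
  if (is.null(spec)) {
    spec <- population_spec(n_rich + n_sparse,
                            country_mix = c(chinese = 1, american = 0,
                                            japanese = 0))
  }
  spec$n_subjects <- as.integer(n_rich + n_sparse)
  pop <- sample_population(spec, params)
  n_q4w <- round(n_rich / 3)
  n_q2w <- n_rich - n_q4w
  pop_q2w <- pop[seq_len(n_q2w), ]
  pop_q4w <- pop[n_q2w + seq_len(n_q4w), ]
  pop_sparse <- pop[n_rich + seq_len(n_sparse), ]
  out <- dplyr::bind_rows(
    generate_pk_dataset(pop_q2w, designs$rich, params),
    generate_pk_dataset(pop_q4w, designs$rich_q4w, params),
    generate_pk_dataset(pop_sparse, designs$sparse, params)
  )
  pop$design <- rep(c("rich", "rich_q4w", "sparse"),
                    c(n_q2w, n_q4w, n_sparse))
  attr(out, "truth") <- list(population = pop, params = params,
                             design_label = "rich+sparse")
  out
}
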