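# covariate coefficient names behind each candidate term
.candidate_coefs <- function(cand) {
  switch(cand,
         "cl~crcl" = "beta_crcl",
         "cl~wt" = "beta_wt_cl",
         "cl~country" = c("frac_american", "frac_japanese"),
         "v~wt" = "beta_wt_v",
         stop("unknown candidate: ", cand, call. = FALSE))
}
.all_cov_coefs <- c("beta_crcl", "beta_wt_cl", "frac_american",
                    "frac_japanese", "beta_wt_v")

# continuous candidates prescreened by correlating clearance EBEs with the
# log covariate
.prescreen_keep <- function(cand, ebes, dataset, alpha = 0.01) {
  covname <- switch(cand, "cl~crcl" = "CRCL", "cl~wt" = "WT", NULL)
  if (is.null(covname)) return(TRUE)   # categorical: always tested
  if (!"eta_cl" %in% names(ebes)) return(TRUE)
  covs <- dataset |>
    dplyr::distinct(.data$ID, .keep_all = TRUE)
  x <- log(covs[[covname]][match(ebes$id, covs$ID)])
  ct <- stats::cor.test(ebes$eta_cl, x)
  ct$p.value < alpha
}

# fit the model containing exactly the covariate terms in `selected`
.fit_with_terms <- function(dataset, initial, selected, fixed, method, control) {
  skel <- params_to_list(initial)
  skel$variant <- "weight_incorporated"
  est_coefs <- unlist(lapply(selected, .candidate_coefs))
  # neutral starting values for newly added coefficients
  for (cf in .all_cov_coefs) {
    if (!cf %in% est_coefs) {
      skel[[cf]] <- if (grepl("^frac", cf)) 1 else 0
    } else if ((grepl("^frac", cf) && skel[[cf]] == 1) ||
               (!grepl("^frac", cf) && skel[[cf]] == 0)) {
      skel[[cf]] <- if (grepl("^frac", cf)) 1 else 0.1
    }
  }
  init <- params_from_list(skel)
  fit_population(dataset, init,
                 fixed = union(fixed, setdiff(.all_cov_coefs, est_coefs)),
                 method = method, control = control)
}

#' Stepwise covariate selection by forward addition and backward deletion
#'
#' Starting from a covariate-free fit, candidate covariate-parameter terms
#' are screened (continuous candidates by correlating base-model clearance
#' EBEs with the log covariate at `P < 0.01`), then added greedily: at each
#' forward step the candidate with the largest drop in OFV is added if the
#' drop is at least `forward_dofv` (default 6.63, chi-squared `P < .01` with
#' 1 df). Backward deletion then removes any retained term whose deletion
#' raises the OFV by less than `backward_dofv` (default 10.83, `P < .001`).
#'
#' Supported candidate terms: `"cl~crcl"` and `"cl~wt"` (power terms on
#' clearance), `"cl~country"` (country multipliers), `"v~wt"` (power term on
#' volume).
#'
#' @param dataset Event-record tibble.
#' @param base_initial A [pk_parameters()] used to fit the covariate-free
#'   base model (its covariate coefficients are ignored).
#' @param candidates Character vector of candidate terms.
#' @param fixed Parameters held fixed in every fit.
#' @param method Likelihood approximation (see [fit_population()]).
#' @param control Passed to [fit_population()].
#' @param forward_dofv,backward_dofv OFV thresholds for addition/retention.
#' @param prescreen Apply the correlation prescreen to continuous
#'   candidates.
#' @return A list with `selected` (character), `trace` (tibble of every
#'   tested step), `base_fit`, and `final_fit`.
#' @export
stepwise_covariate_search <- function(dataset, base_initial,
                                      candidates = c("cl~crcl", "cl~wt",
                                                     "cl~country"),
                                      fixed = character(),
                                      method = "laplace", control = list(),
                                      forward_dofv = 6.63,
                                      backward_dofv = 10.83,
                                      prescreen = TRUE) {
  base_list <- params_to_list(base_initial)
  base_list$variant <- "base"
  base_list[.all_cov_coefs] <- list(0, 0, 1, 1, 0)
  base_fit <- fit_population(dataset, params_from_list(base_list),
                             fixed = fixed, method = method,
                             control = control)
  if (!length(candidates)) {
    return(list(selected = character(), trace = tibble::tibble(),
                base_fit = base_fit, final_fit = base_fit))
  }
  if (prescreen) {
    keep <- vapply(candidates, .prescreen_keep, logical(1),
                   ebes = base_fit$ebes, dataset = dataset)
    dropped <- candidates[!keep]
    candidates <- candidates[keep]
  } else {
    dropped <- character()
  }
  trace <- list()
  selected <- character()
  current_fit <- base_fit
  # forward addition
  repeat {
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    trial <- lapply(pool, function(cand) {
      .fit_with_terms(dataset, current_fit$estimates,
                      c(selected, cand), fixed, method, control)
    })
    dofv <- current_fit$ofv - vapply(trial, function(f) f$ofv, numeric(1))
    for (k in seq_along(pool)) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        phase = "forward", candidate = pool[k],
        ofv_ref = current_fit$ofv, ofv_alt = trial[[k]]$ofv,
        dofv = dofv[k], action = "tested")
    }
    best <- which.max(dofv)
    if (dofv[best] >= forward_dofv) {
      selected <- c(selected, pool[best])
      current_fit <- trial[[best]]
      trace[[length(trace)]] <- NULL
      trace[[length(trace) + 1]] <- tibble::tibble(
        phase = "forward", candidate = pool[best],
        ofv_ref = NA_real_, ofv_alt = current_fit$ofv,
        dofv = dofv[best], action = "added")
    } else {
      break
    }
  }
  # backward deletion
  repeat {
    if (length(selected) < 1) break
    trial <- lapply(selected, function(cand) {
      rest <- setdiff(selected, cand)
      if (length(rest)) {
        .fit_with_terms(dataset, current_fit$estimates, rest, fixed,
                        method, control)
      } else {
        base_fit
      }
    })
    dofv <- vapply(trial, function(f) f$ofv, numeric(1)) - current_fit$ofv
    for (k in seq_along(selected)) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        phase = "backward", candidate = selected[k],
        ofv_ref = current_fit$ofv, ofv_alt = trial[[k]]$ofv,
        dofv = dofv[k], action = "tested")
    }
    worst <- which.min(dofv)
    if (dofv[worst] < backward_dofv) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        phase = "backward", candidate = selected[worst],
        ofv_ref = current_fit$ofv, ofv_alt = trial[[worst]]$ofv,
        dofv = dofv[worst], action = "deleted")
      current_fit <- trial[[worst]]
      selected <- setdiff(selected, selected[worst])
    } else {
      break
    }
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else tibble::tibble()
  if (length(dropped)) {
    trace <- dplyr::bind_rows(
      tibble::tibble(phase = "prescreen", candidate = dropped,
                     ofv_ref = NA_real_, ofv_alt = NA_real_,
                     dofv = NA_real_, action = "screened_out"),
      trace)
  }
  list(selected = selected, trace = trace,
       base_fit = base_fit, final_fit = current_fit)
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement, refits each resample starting from
#' the original estimates, and summarizes the estimated parameters by their
#' median and 90% percentile interval, together with the refit convergence
#' rate.
#'
#' @param dataset Event-record tibble.
#' @param final_params A [pk_parameters()]: the original fit's estimates,
#'   used as refit initials.
#' @param n_resamples Number of bootstrap resamples.
#' @param fixed,method,control Passed to [fit_population()].
#' @param seed Integer seed (applied locally).
#' @return A `pk_bootstrap` object: list with `n_resamples`,
#'   `convergence_rate_pct`, `summary` (per parameter: median, 5th and 95th
#'   percentiles), and `draws` (per-resample estimates).
#' @export
bootstrap <- function(dataset, final_params, n_resamples = 500,
                      fixed = character(), method = "laplace",
                      control = list(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  ids <- unique(dataset$ID)
  est_names <- .default_est_names(final_params, fixed)
  draws <- matrix(NA_real_, n_resamples, length(est_names),
                  dimnames = list(NULL, est_names))
  conv <- logical(n_resamples)
  by_id <- split(dataset, dataset$ID)
  for (b in seq_len(n_resamples)) {
    take <- sample(ids, length(ids), replace = TRUE)
    resample <- dplyr::bind_rows(lapply(seq_along(take), function(k) {
      d <- by_id[[as.character(take[k])]]
      d$ID <- k
      d
    }))
    fit <- tryCatch(
      fit_population(resample, final_params, fixed = fixed, method = method,
                     control = control),
      error = function(e) NULL)
    if (!is.null(fit)) {
      conv[b] <- fit$converged
      draws[b, ] <- vapply(est_names, function(nm) fit$estimates[[nm]],
                           numeric(1))
    }
  }
  ok <- stats::complete.cases(draws)
  if (!any(ok)) stop("all bootstrap refits failed", call. = FALSE)
  summary <- tibble::tibble(
    parameter = est_names,
    median = apply(draws[ok, , drop = FALSE], 2, stats::median),
    q05 = apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = 0.05),
    q95 = apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = 0.95)
  )
  structure(list(n_resamples = n_resamples,
                 convergence_rate_pct = 100 * mean(conv),
                 summary = summary,
                 draws = tibble::as_tibble(draws)),
            class = "pk_bootstrap")
}
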