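# time after most recent dose for each observation
.time_after_dose <- function(obs_times, dose_times) {
  vapply(obs_times, function(t) {
    prior <- dose_times[dose_times <= t]
    if (!length(prior)) t else t - max(prior)
  }, numeric(1))
}

# most recent dose amount for each observation (dose correction)
.last_dose_amt <- function(obs_times, dose_times, dose_amt) {
  vapply(obs_times, function(t) {
    prior <- which(dose_times <= t)
    if (!length(prior)) NA_real_ else dose_amt[max(prior)]
  }, numeric(1))
}

#' Goodness-of-fit table with conditional weighted residuals
#'
#' For every non-missing observation, returns the observed value, the
#' population prediction (zero random effects), the individual prediction
#' (at the empirical-Bayes mode), time after dose, and the conditional
#' weighted residual (CWRES). CWRES decorrelates the residual vector
#' `y - f(eta_hat) + J eta_hat` by the model-implied observation covariance
#' from the first-order expansion about the EBEs,
#' `V = J Omega J' + diag(sigma^2 f(eta_hat)^2)`; under a correct model
#' CWRES are approximately standard normal. With no random effects CWRES
#' reduce to `(y - f) / (sigma f)`. A subject whose covariance cannot be
#' factorized falls back to `residual / SD` with a warning.
#'
#' @param fit A `pk_fit` (or a [pk_parameters()] object, in which case EBEs
#'   are computed on the fly).
#' @param dataset Event-record tibble.
#' @param hmax Integration step bound, h.
#' @return A tibble: `id`, `time`, `tad`, `dv`, `pred`, `ipred`, `cwres`.
#' @export
cwres <- function(fit, dataset, hmax = 4) {
  params <- if (inherits(fit, "pk_fit")) fit$estimates else fit
  subjects <- .prep_subjects(dataset)
  om <- .active_etas(params)
  q <- length(om)
  sigma2 <- params$sigma_prop^2
  out <- lapply(subjects, function(sub) {
    if (!length(sub$y)) return(NULL)
    base <- .subject_base(params, sub$cov)
    map <- .map_eta(sub, base, params, numeric(q), hmax)
    f0 <- drop(.predict_etas(sub, base, params, matrix(0, 1, max(q, 1)),
                             hmax))
    fs <- pmax(map$f, 1e-12)
    if (q == 0) {
      cw <- (sub$y - fs) / (params$sigma_prop * fs)
    } else {
      V <- map$J %*% diag(om^2, q) %*% t(map$J) +
        diag(sigma2 * fs^2, length(sub$y))
      res <- sub$y - map$f + drop(map$J %*% map$eta)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) {
        warning("singular covariance for subject ", sub$id,
                "; falling back to residual/SD", call. = FALSE)
        cw <- res / sqrt(diag(V))
      } else {
        cw <- backsolve(ch, res, transpose = TRUE)
      }
    }
    tibble::tibble(id = sub$id, time = sub$times,
                   tad = .time_after_dose(sub$times, sub$dose_time),
                   dv = sub$y, pred = f0, ipred = map$f, cwres = cw)
  })
  dplyr::bind_rows(out)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the model with the original
#' design (each subject's doses, sampling times, and covariates; new random
#' effects and residual errors), then compares the observed 5th/50th/95th
#' concentration percentiles per time bin with the 95% confidence bands of
#' the same percentiles across the simulated replicates. With
#' `dose_correct = TRUE`, every concentration (observed and simulated) is
#' divided by the subject's most recent dose amount, which makes the bands
#' invariant to dose-group composition under dose linearity.
#'
#' Default bins are deciles of time since first dose; empty bins are merged
#' with their left neighbour.
#'
#' @param fit A `pk_fit` or [pk_parameters()] object.
#' @param dataset Event-record tibble.
#' @param n_sim Number of simulation replicates.
#' @param bins Optional numeric vector of bin edges (h).
#' @param dose_correct Divide concentrations by the most recent dose amount.
#' @param seed Integer seed (applied locally).
#' @param hmax Integration step bound, h.
#' @return A `vpc_result`: tibble with one row per bin (edges, n, observed
#'   percentiles, simulated 95% CI of each percentile) plus attributes.
#' @export
vpc <- function(fit, dataset, n_sim = 1000, bins = NULL,
                dose_correct = FALSE, seed = NULL, hmax = 4) {
  params <- if (inherits(fit, "pk_fit")) fit$estimates else fit
  if (!is.null(seed)) withr::local_seed(seed)
  subjects <- .prep_subjects(dataset)
  om <- .active_etas(params)
  q <- length(om)

  obs_time <- unlist(lapply(subjects, `[[`, "times"))
  obs_dv <- unlist(lapply(subjects, `[[`, "y"))
  scale <- unlist(lapply(subjects, function(s) {
    if (dose_correct) .last_dose_amt(s$times, s$dose_time, s$dose_amt)
    else rep(1, length(s$times))
  }))

  if (is.null(bins)) {
    edges <- unique(stats::quantile(obs_time, probs = seq(0, 1, by = 0.1)))
  } else {
    edges <- sort(unique(bins))
  }
  bin_of <- function(t) {
    findInterval(t, edges, rightmost.closed = TRUE, all.inside = TRUE)
  }
  obs_bin <- bin_of(obs_time)
  # merge empty bins leftward
  counts <- tabulate(obs_bin, nbins = length(edges) - 1)
  if (any(counts == 0)) {
    edges <- edges[-(which(counts == 0) + 1)]
    obs_bin <- bin_of(obs_time)
  }
  n_bins <- length(edges) - 1

  # simulate: per subject one batched solve over n_sim eta draws
  sim_dv <- matrix(NA_real_, length(obs_time), n_sim)
  pos <- 0
  for (sub in subjects) {
    n_t <- length(sub$times)
    if (!n_t) next
    base <- .subject_base(params, sub$cov)
    etas <- matrix(stats::rnorm(n_sim * q, 0, rep(om, each = n_sim)),
                   n_sim, q)
    f <- .predict_etas(sub, base, params, etas, hmax)
    eps <- matrix(stats::rnorm(n_t * n_sim, 0, params$sigma_prop), n_t, n_sim)
    sim_dv[pos + seq_len(n_t), ] <- pmax(f * (1 + eps), 0)
    pos <- pos + n_t
  }

  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(seq_len(n_bins), function(b) {
    stats::quantile((obs_dv / scale)[obs_bin == b], probs = probs)
  }, numeric(3)))
  sim_pct <- array(NA_real_, c(n_bins, 3, n_sim))
  for (s in seq_len(n_sim)) {
    v <- sim_dv[, s] / scale
    for (b in seq_len(n_bins)) {
      sim_pct[b, , s] <- stats::quantile(v[obs_bin == b], probs = probs)
    }
  }
  ci <- apply(sim_pct, c(1, 2), stats::quantile, probs = c(0.025, 0.975))
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    t_lo = edges[-length(edges)], t_hi = edges[-1],
    n_obs = tabulate(obs_bin, nbins = n_bins),
    obs_p5 = obs_pct[, 1], obs_p50 = obs_pct[, 2], obs_p95 = obs_pct[, 3],
    sim_p5_lo = ci[1, , 1], sim_p5_hi = ci[2, , 1],
    sim_p50_lo = ci[1, , 2], sim_p50_hi = ci[2, , 2],
    sim_p95_lo = ci[1, , 3], sim_p95_hi = ci[2, , 3]
  )
  structure(out, class = c("vpc_result", class(out)),
            n_sim = n_sim, dose_correct = dose_correct)
}

#' Plot a visual predictive check
#'
#' @param x A `vpc_result` from [vpc()].
#' @return A ggplot object.
#' @export
plot_vpc <- function(x) {
  mid <- (x$t_lo + x$t_hi) / 2
  df <- tibble::as_tibble(x)
  df$mid <- mid
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p50_lo,
                                      ymax = .data$sim_p50_hi),
                         fill = "red", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p5_lo,
                                      ymax = .data$sim_p5_hi),
                         fill = "blue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_p95_lo,
                                      ymax = .data$sim_p95_hi),
                         fill = "blue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), color = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), color = "blue",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), color = "blue",
                       linetype = 2) +
    ggplot2::labs(x = "time since first dose (h)",
                  y = if (isTRUE(attr(x, "dose_correct"))) {
                    "dose-corrected concentration (mg/L per mg)"
                  } else {
                    "concentration (mg/L)"
                  }) +
    ggplot2::theme_bw()
}

#' Goodness-of-fit plots
#'
#' Standard four-panel data: observed vs population/individual predictions
#' and CWRES vs population prediction / time after dose. Returns a list of
#' ggplot objects.
#'
#' @param gof A tibble from [cwres()].
#' @return Named list of ggplots.
#' @export
plot_gof <- function(gof) {
  p1 <- ggplot2::ggplot(gof, ggplot2::aes(.data$ipred, .data$dv)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "red") +
    ggplot2::labs(x = "individual prediction (mg/L)",
                  y = "observed (mg/L)") +
    ggplot2::theme_bw()
  p2 <- p1 + ggplot2::aes(.data$pred, .data$dv) +
    ggplot2::labs(x = "population prediction (mg/L)")
  p3 <- ggplot2::ggplot(gof, ggplot2::aes(.data$pred, .data$cwres)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, color = "red") +
    ggplot2::labs(x = "population prediction (mg/L)", y = "CWRES") +
    ggplot2::theme_bw()
  p4 <- p3 + ggplot2::aes(.data$tad, .data$cwres) +
    ggplot2::labs(x = "time after dose (h)")
  list(dv_ipred = p1, dv_pred = p2, cwres_pred = p3, cwres_tad = p4)
}
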