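# ---- dataset preparation --------------------------------------------------

# split an event-record table into per-subject structures used by the
# likelihood machinery
.prep_subjects <- function(dataset) {
  ids <- unique(dataset$ID)
  lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, ]
    obs <- d[d$EVID == 0 & d$MDV == 0, ]
    dos <- d[d$EVID == 1, ]
    if (!nrow(dos)) stop("subject ", id, " has no dose records", call. = FALSE)
    list(id = id,
         y = obs$DV, times = obs$TIME,
         dose_time = dos$TIME, dose_amt = dos$AMT,
         cov = covariate_profile(wt = d$WT[1], crcl = d$CRCL[1],
                                 country = d$COUNTRY[1]))
  })
}

# covariate-scaled baseline structural parameters (eta = 0) for a subject
.subject_base <- function(params, cov) {
  c(ka = params$ka_pop,
    v = individual_volume(params, cov),
    cl0 = individual_clearance(params, cov, t = 0))
}

# ---- parameter packing ----------------------------------------------------

# transform table: estimation happens on the log scale for positive
# parameters; emax and power exponents are unconstrained. T50 has a lower
# bound of 0.1 day (the profile is flat in T50 near zero).
.par_spec <- function() {
  tibble::tibble(
    name = c("cl_pop", "v_pop", "ka_pop", "emax", "t50",
             "beta_crcl", "frac_american", "frac_japanese",
             "beta_wt_cl", "beta_wt_v",
             "omega_cl", "omega_v", "omega_ka", "sigma_prop"),
    trans = c("log", "log", "log", "id", "log",
              "id", "log", "log", "id", "id",
              "log", "log", "log", "log"),
    lower = c(rep(-Inf, 3), -10, log(0.1),
              -5, -5, -5, -5, -5,
              rep(log(1e-3), 3), log(1e-3)),
    upper = c(rep(Inf, 3), 10, log(1e4),
              5, 5, 5, 5, 5,
              rep(log(5), 3), log(5))
  )
}

.pack_par <- function(params, est_names) {
  spec <- .par_spec()
  vapply(est_names, function(nm) {
    v <- params[[nm]]
    if (spec$trans[spec$name == nm] == "log") log(v) else v
  }, numeric(1))
}

.unpack_par <- function(vec, est_names, skeleton) {
  spec <- .par_spec()
  for (i in seq_along(est_names)) {
    nm <- est_names[i]
    skeleton[[nm]] <- if (spec$trans[spec$name == nm] == "log") {
      exp(unname(vec[i]))
    } else {
      unname(vec[i])
    }
  }
  skeleton
}

# default estimated-parameter set for a variant
.default_est_names <- function(params, fixed) {
  nm <- c("cl_pop", "v_pop", "ka_pop", "emax", "t50")
  if (params$variant != "base") {
    nm <- c(nm, "beta_crcl", "frac_american", "frac_japanese")
  }
  if (params$variant == "weight_incorporated") {
    nm <- c(nm, "beta_wt_cl", "beta_wt_v")
  }
  om <- c("omega_cl", "omega_v", "omega_ka")
  nm <- c(nm, om[vapply(om, function(o) params[[o]] > 0, logical(1))],
          "sigma_prop")
  setdiff(nm, fixed)
}

# ---- per-subject likelihood -----------------------------------------------

# active eta dimensions and their variances for the current parameters
.active_etas <- function(params) {
  om <- c(cl = params$omega_cl, v = params$omega_v, ka = params$omega_ka)
  om[om > 0]
}

# -2 log joint density of (y, eta) for one subject; f floored to avoid a
# degenerate proportional-error variance at zero prediction
.m_joint <- function(f, y, eta, om2, sigma2) {
  f <- pmax(f, 1e-12)
  m <- sum(log(2 * pi * sigma2 * f^2) + (y - f)^2 / (sigma2 * f^2))
  if (length(eta)) {
    m <- m + length(eta) * log(2 * pi) + sum(log(om2)) + sum(eta^2 / om2)
  }
  m
}

# predictions for one subject at a set of eta vectors (rows of `etas`);
# returns a length(times) x nrow(etas) matrix
.predict_etas <- function(sub, base, params, etas, hmax) {
  which_eta <- names(.active_etas(params))
  theta <- matrix(rep(c(base[["ka"]], base[["v"]], base[["cl0"]]),
                      each = nrow(etas)), ncol = 3)
  colnames(theta) <- c("ka", "v", "cl0")
  for (j in seq_along(which_eta)) {
    idx <- match(which_eta[j], c("ka", "v", "cl"))
    theta[, c("ka", "v", "cl0")[idx]] <-
      theta[, c("ka", "v", "cl0")[idx]] * exp(etas[, j])
  }
  .solve_onecomp_multi_cpp(sub$dose_time, sub$dose_amt, sub$times,
                           cbind(theta[, "ka"], theta[, "v"], theta[, "cl0"],
                                 params$emax, 24 * params$t50),
                           hmax)
}

# MAP estimate of one subject's etas by damped Gauss-Newton on the penalized
# proportional-error least-squares surface. Returns the mode together with
# the prediction and finite-difference eta-Jacobian at the mode (reused by
# the FOCE objective and CWRES).
.map_eta <- function(sub, base, params, eta0, hmax,
                     max_iter = 25, tol = 1e-5, m_tol = 1e-9) {
  om <- .active_etas(params)
  q <- length(om)
  sigma2 <- params$sigma_prop^2
  if (q == 0 || !length(sub$y)) {
    f <- drop(.predict_etas(sub, base, params,
                            matrix(0, 1, max(q, 1)), hmax))
    return(list(eta = numeric(q), f = f,
                J = matrix(0, length(sub$y), q),
                m = .m_joint(f, sub$y, numeric(0), numeric(0), sigma2)))
  }
  om2 <- om^2
  eta <- eta0
  h <- 1e-4
  f0 <- NULL; J <- NULL
  m_cur <- NULL
  # a warm start is only a hint: discard it when the prior mode is better,
  # so a stale cache entry from another parameter region cannot poison the
  # mode search
  if (any(eta0 != 0)) {
    f_w <- drop(.predict_etas(sub, base, params, matrix(eta0, 1), hmax))
    m_w <- .m_joint(f_w, sub$y, eta0, om2, sigma2)
    f_z <- drop(.predict_etas(sub, base, params,
                              matrix(numeric(q), 1), hmax))
    m_z <- .m_joint(f_z, sub$y, numeric(q), om2, sigma2)
    if (!is.finite(m_w) || m_z < m_w) eta <- numeric(q)
    m_cur <- min(m_w, m_z, na.rm = TRUE)
  }
  for (it in seq_len(max_iter)) {
    etas <- matrix(rep(eta, q + 1), nrow = q + 1, byrow = TRUE)
    for (j in seq_len(q)) etas[j + 1, j] <- etas[j + 1, j] + h
    fm <- .predict_etas(sub, base, params, etas, hmax)
    f0 <- fm[, 1]
    J <- (fm[, -1, drop = FALSE] - f0) / h
    if (is.null(m_cur)) m_cur <- .m_joint(f0, sub$y, eta, om2, sigma2)
    fs <- pmax(f0, 1e-12)
    r <- sub$y - f0
    w <- 1 / (sigma2 * fs^2)
    grad <- drop(2 * crossprod(J, 1 / fs - r * w - r^2 * w / fs)) +
      2 * eta / om2
    H <- 2 * crossprod(J * sqrt(w)) + 2 * diag(1 / om2, q)
    step <- tryCatch(-solve(H, grad), error = function(e) -grad / max(diag(H)))
    if (max(abs(step)) < tol) break
    alpha <- 1
    improved <- FALSE
    m_prev <- m_cur
    for (ls in 1:10) {
      eta_try <- eta + alpha * step
      f_try <- drop(.predict_etas(sub, base, params, matrix(eta_try, 1), hmax))
      m_try <- .m_joint(f_try, sub$y, eta_try, om2, sigma2)
      if (is.finite(m_try) && m_try < m_cur) {
        eta <- eta_try
        m_cur <- m_try
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
    if (max(abs(alpha * step)) < tol) break
    # stop once the joint density stops improving beyond the FD noise floor
    if (m_prev - m_cur < m_tol * (1 + abs(m_cur))) break
  }
  # refresh f and J at the accepted mode
  etas <- matrix(rep(eta, q + 1), nrow = q + 1, byrow = TRUE)
  for (j in seq_len(q)) etas[j + 1, j] <- etas[j + 1, j] + h
  fm <- .predict_etas(sub, base, params, etas, hmax)
  f0 <- fm[, 1]
  J <- (fm[, -1, drop = FALSE] - f0) / h
  list(eta = eta, f = f0, J = J,
       m = .m_joint(f0, sub$y, eta, om2, sigma2))
}

# exact Hessian of the joint -2 log density at the mode (for the Laplace
# objective). First and second derivatives of the prediction vector come
# from one batched central-difference solve (13 parameter sets for q = 3);
# the Hessian is then assembled analytically from f, J, and f_ab.
.m_hessian <- function(sub, base, params, eta, hmax, h = 1e-3) {
  om <- .active_etas(params)
  q <- length(om)
  om2 <- om^2
  sigma2 <- params$sigma_prop^2
  pairs <- if (q > 1) utils::combn(q, 2) else matrix(numeric(0), 2, 0)
  n_pts <- 1 + 2 * q + 2 * ncol(pairs)
  etas <- matrix(rep(eta, n_pts), nrow = n_pts, byrow = TRUE)
  for (j in seq_len(q)) {
    etas[1 + j, j] <- eta[j] + h
    etas[1 + q + j, j] <- eta[j] - h
  }
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    etas[1 + 2 * q + 2 * k - 1, c(a, b)] <- eta[c(a, b)] + h
    etas[1 + 2 * q + 2 * k, c(a, b)] <- eta[c(a, b)] - h
  }
  fm <- .predict_etas(sub, base, params, etas, hmax)
  f0 <- fm[, 1]
  fp <- fm[, 1 + seq_len(q), drop = FALSE]
  fn <- fm[, 1 + q + seq_len(q), drop = FALSE]
  J <- (fp - fn) / (2 * h)
  n <- length(sub$y)
  Fab <- array(0, c(n, q, q))
  for (j in seq_len(q)) Fab[, j, j] <- (fp[, j] - 2 * f0 + fn[, j]) / h^2
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    fpp <- fm[, 1 + 2 * q + 2 * k - 1]
    fnn <- fm[, 1 + 2 * q + 2 * k]
    Fab[, a, b] <- Fab[, b, a] <-
      (fpp + fnn - fp[, a] - fn[, a] - fp[, b] - fn[, b] + 2 * f0) /
      (2 * h^2)
  }
  fs <- pmax(f0, 1e-12)
  r <- sub$y - f0
  # per-observation coefficients of J_a J_b and f_ab in d2m/deta_a deta_b
  c_jj <- -2 / fs^2 + 2 / (sigma2 * fs^2) + 8 * r / (sigma2 * fs^3) +
    6 * r^2 / (sigma2 * fs^4)
  c_ab <- 2 / fs - 2 * r / (sigma2 * fs^2) - 2 * r^2 / (sigma2 * fs^3)
  H <- matrix(0, q, q)
  for (a in seq_len(q)) {
    for (b in seq_len(q)) {
      H[a, b] <- sum(c_jj * J[, a] * J[, b] + c_ab * Fab[, a, b])
    }
  }
  H + 2 * diag(1 / om2, q)
}

# one subject's contribution to the approximate -2 log marginal likelihood
.ofv_subject <- function(sub, base, params, eta0, method, hmax) {
  map <- .map_eta(sub, base, params, eta0, hmax)
  om <- .active_etas(params)
  q <- length(om)
  n <- length(sub$y)
  sigma2 <- params$sigma_prop^2
  if (q == 0) {
    return(list(ofv = map$m, eta = map$eta))
  }
  if (method == "laplace") {
    H <- .m_hessian(sub, base, params, map$eta, hmax)
    detH <- det(H / 2)
    if (!is.finite(detH) || detH <= 0) {
      # fall back to the Gauss-Newton curvature when the exact one is not
      # positive definite at a flat mode
      fs <- pmax(map$f, 1e-12)
      w <- 1 / (sigma2 * fs^2)
      H <- 2 * crossprod(map$J * sqrt(w)) + 2 * diag(1 / om^2, q)
      detH <- det(H / 2)
    }
    ofv <- map$m - q * log(2 * pi) + log(detH)
  } else {
    fs <- pmax(map$f, 1e-12)
    V <- map$J %*% diag(om^2, q) %*% t(map$J) + diag(sigma2 * fs^2, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      stop("non-finite likelihood for subject ", sub$id, call. = FALSE)
    }
    res <- sub$y - map$f + drop(map$J %*% map$eta)
    z <- backsolve(ch, res, transpose = TRUE)
    ofv <- n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2)
  }
  if (!is.finite(ofv)) {
    stop("non-finite likelihood for subject ", sub$id, call. = FALSE)
  }
  list(ofv = ofv, eta = map$eta)
}

# ---- exported operations --------------------------------------------------

#' Approximate marginal-likelihood objective function
#'
#' Computes the population objective function value (OFV), minus twice the
#' approximate marginal log likelihood summed over subjects, for an
#' event-record dataset under the model in `params`. Two approximations are
#' available: `"foce"` (first-order conditional estimation with interaction:
#' linearization of the subject model about the empirical-Bayes modes, with
#' the residual variance evaluated at the conditional prediction) and
#' `"laplace"` (second-order curvature correction at the modes). Differences
#' in OFV between nested models are asymptotically chi-squared under the
#' null.
#'
#' @param params A [pk_parameters()].
#' @param dataset Event-record tibble (see [generate_pk_dataset()] or
#'   [read_pk_dataset()]).
#' @param method `"foce"` or `"laplace"`.
#' @param hmax Integration step bound, h.
#' @return The OFV (scalar).
#' @export
objective_function <- function(params, dataset,
                               method = c("laplace", "foce"), hmax = 4) {
  method <- match.arg(method)
  subjects <- .prep_subjects(dataset)
  q <- length(.active_etas(params))
  tot <- 0
  for (sub in subjects) {
    base <- .subject_base(params, sub$cov)
    tot <- tot + .ofv_subject(sub, base, params, numeric(q), method, hmax)$ofv
  }
  tot
}

#' Fit the population model by approximate maximum marginal likelihood
#'
#' Estimates the fixed effects, random-effect SDs, and residual SD of the
#' model in `initial` by minimizing [objective_function()]. Positive
#' parameters are estimated on the log scale; T50 is bounded below at 0.1
#' day. Random effects exist for every `omega_*` that is positive in
#' `initial`; set an omega to 0 (and list it in `fixed`) to drop its eta,
#' e.g. the time-dependence parameters Emax and T50 conventionally carry no
#' inter-individual variability. Per-subject empirical-Bayes estimates and
#' their shrinkage (1 - SD(EBE)/omega, %) are returned with the fit.
#'
#' @param dataset Event-record tibble.
#' @param initial A [pk_parameters()] with starting values; its `variant`
#'   decides which covariate coefficients are estimated.
#' @param fixed Character vector of parameter names held at their initial
#'   values.
#' @param method Likelihood approximation, `"foce"` (default) or
#'   `"laplace"`.
#' @param control List: `hmax` (integration step, default 2), `iter_max`
#'   (default 200), `n_starts` (default 1; additional starts perturb the
#'   initial log-scale values by up to +/-50%), `start_seed` (seed for the
#'   perturbations), `trace` (print optimizer progress).
#' @return A `pk_fit` object: list with `estimates` ([pk_parameters()]),
#'   `ofv`, `converged`, `ebes` (tibble of per-subject modes), `shrinkage`
#'   (named %, per eta), `method`, `est_names`, `n_subjects`, `n_obs`, and
#'   the raw optimizer result.
#' @export
fit_population <- function(dataset, initial, fixed = character(),
                           method = c("laplace", "foce"), control = list()) {
  method <- match.arg(method)
  stopifnot(inherits(initial, "pk_parameters"))
  ctl <- utils::modifyList(
    list(hmax = 4, iter_max = 80, n_starts = 1, start_seed = 1,
         trace = FALSE),
    control)
  subjects <- .prep_subjects(dataset)
  est_names <- .default_est_names(initial, fixed)
  spec <- .par_spec()
  idx <- match(est_names, spec$name)
  start <- .pack_par(initial, est_names)
  q <- length(.active_etas(initial))
  # warm-start cache of per-subject eta modes across objective evaluations
  eta_cache <- matrix(0, length(subjects), q)

  obj <- function(p) {
    params <- .unpack_par(p, est_names, initial)
    tot <- 0
    for (i in seq_along(subjects)) {
      sub <- subjects[[i]]
      base <- .subject_base(params, sub$cov)
      r <- tryCatch(
        .ofv_subject(sub, base, params, eta_cache[i, ], method, ctl$hmax),
        error = function(e) NULL)
      if (is.null(r)) {
        eta_cache[i, ] <<- 0
        return(1e10)
      }
      eta_cache[i, ] <<- r$eta
      tot <- tot + r$ofv
    }
    if (ctl$trace) message(sprintf("OFV %.4f", tot))
    tot
  }

  starts <- list(start)
  if (ctl$n_starts > 1) {
    withr::local_seed(ctl$start_seed)
    for (k in seq_len(ctl$n_starts - 1)) {
      starts[[k + 1]] <- start + stats::runif(length(start), -0.5, 0.5)
    }
  }
  best <- NULL
  for (s in starts) {
    # L-BFGS-B with moderately sized finite-difference steps: the objective
    # carries tiny inner-optimization noise that very small steps would
    # amplify into spurious gradients
    res <- stats::optim(s, obj, method = "L-BFGS-B",
                        lower = spec$lower[idx], upper = spec$upper[idx],
                        control = list(maxit = ctl$iter_max, factr = 1e8,
                                       ndeps = rep(1e-4, length(s))))
    if (is.null(best) || res$value < best$value) best <- res
  }
  best$objective <- best$value
  estimates <- .unpack_par(best$par, est_names, initial)
  eb <- empirical_bayes(estimates, dataset, hmax = ctl$hmax)
  om <- .active_etas(estimates)
  shrink <- vapply(seq_along(om), function(j) {
    100 * max(0, min(1, 1 - stats::sd(eb[[paste0("eta_", names(om)[j])]]) /
                       om[j]))
  }, numeric(1))
  names(shrink) <- names(om)
  structure(list(
    estimates = estimates, ofv = best$objective,
    converged = best$convergence == 0, ebes = eb, shrinkage = shrink,
    method = method, est_names = est_names,
    n_subjects = length(subjects),
    n_obs = sum(vapply(subjects, function(s) length(s$y), numeric(1))),
    optimizer = best, control = ctl
  ), class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit>", x$method, "| OFV", format(x$ofv, digits = 8),
      "| converged:", x$converged, "\n")
  cat("  subjects:", x$n_subjects, "| observations:", x$n_obs, "\n")
  print(x$estimates)
  if (length(x$shrinkage)) {
    cat("  eta shrinkage (%):",
        paste(names(x$shrinkage), round(x$shrinkage, 1), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Empirical-Bayes (MAP) estimates of individual random effects
#'
#' Per-subject posterior modes of the eta vector given the population
#' parameters. A subject with no observations returns zero etas (the prior
#' mode); as an omega tends to zero its eta is pinned at zero by the prior.
#'
#' @param params A [pk_parameters()].
#' @param dataset Event-record tibble.
#' @param hmax Integration step bound, h.
#' @return A tibble with `id` and one `eta_*` column per active random
#'   effect.
#' @export
empirical_bayes <- function(params, dataset, hmax = 4) {
  subjects <- .prep_subjects(dataset)
  om <- .active_etas(params)
  q <- length(om)
  out <- lapply(subjects, function(sub) {
    base <- .subject_base(params, sub$cov)
    eta <- if (!length(sub$y)) {
      numeric(q)
    } else {
      .map_eta(sub, base, params, numeric(q), hmax)$eta
    }
    row <- tibble::tibble(id = sub$id)
    for (j in seq_len(q)) row[[paste0("eta_", names(om)[j])]] <- eta[j]
    row
  })
  dplyr::bind_rows(out)
}
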