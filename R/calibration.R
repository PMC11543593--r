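# Map from observable name to the model quantity it measures. Cell counts are
# total cells (flow cytometry cannot separate the guilds) reported per ml.
observable_from_state <- function(traj, observable) {
  switch(observable,
    Fe2_mM       = traj$c_fe,
    NO3_mM       = traj$c_no3,
    cells_per_ml = (traj$x_sw2 + traj$x_ks) * 1e-3,
    pNO_Pa       = traj$p_no,
    pN2O_Pa      = traj$p_n2o,
    stop("unknown observable: ", observable))
}

#' Define a calibration problem
#'
#' Couples an observation table to a scenario, a full starting parameter set,
#' the subset of parameters to be estimated, and box bounds in log10 space.
#' The loss is the sum of squared scaled residuals; each observable is divided
#' by a characteristic scale (initial Fe(II) and nitrate, maximum observed
#' cell count and partial pressures) so that millimolar and Pascal data
#' contribute comparably.
#'
#' @param observations Data frame with columns `replicate`, `time`,
#'   `observable`, `value` (see [generate_observations()]).
#' @param config A [reactor_config()] for the scenario being fitted.
#' @param params Full parameter list supplying fixed values and the fit
#'   starting point.
#' @param free Character vector of flat parameter names to estimate (see
#'   [read_params()] for the key set).
#' @param bounds_decades Half-width of the log10 box around the starting
#'   values (default 3 decades each way).
#' @param rtol Integration tolerance used inside the fit (looser than the
#'   final-simulation default for speed; refit-insensitive at 1e-6).
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(observations, config, params, free,
                        bounds_decades = 3, rtol = 1e-6) {
  if (!nrow(observations)) stop("fit_problem: empty observation set")
  need <- c("replicate", "time", "observable", "value")
  if (!all(need %in% names(observations)))
    stop("fit_problem: observations need columns ",
         paste(need, collapse = ", "))
  flat <- flatten_params(params)
  unknown <- setdiff(free, names(flat))
  if (length(unknown))
    stop("fit_problem: unknown parameter name(s): ",
         paste(unknown, collapse = ", "))
  obs_names <- unique(observations$observable)
  scales <- vapply(obs_names, function(ob) {
    s <- switch(ob,
      Fe2_mM  = config$init[["c_fe"]],
      NO3_mM  = config$init[["c_no3"]],
      cells_per_ml = max(observations$value[observations$observable == ob]),
      max(observations$value[observations$observable == ob]))
    if (!is.finite(s) || s <= 0) 1 else s
  }, numeric(1))
  center <- log10(flat[free])
  structure(list(observations = observations, config = config,
                 params = params, free = free, scales = scales,
                 center = center,
                 lower = center - bounds_decades,
                 upper = center + bounds_decades,
                 rtol = rtol),
            class = "fit_problem")
}

params_with <- function(params, flat_updates) {
  flat <- flatten_params(params)
  flat[names(flat_updates)] <- flat_updates
  unflatten_params(flat)
}

#' Scaled residual vector at a point in log10 parameter space
#'
#' Simulates the problem's scenario at the proposed parameters, interpolates
#' the trajectory at the observation times, and returns
#' `(observed - simulated) / scale` per row. Integration failures yield a
#' large finite penalty vector so the optimizer can retreat.
#'
#' @param log_params Named numeric vector of log10 values for the problem's
#'   free parameters.
#' @param problem A [fit_problem()].
#' @return Numeric residual vector, one entry per observation row.
#' @export
fit_residuals <- function(log_params, problem) {
  theta <- 10^log_params
  names(theta) <- problem$free
  obs <- problem$observations
  # pathological parameter proposals can stall the integrator; silence the
  # solver chatter and hand the optimizer a finite penalty instead
  sim <- suppressWarnings(try(simulate_reactor(
    problem$config, params_with(problem$params, theta),
    times = sort(unique(c(0, obs$time))),
    rtol = problem$rtol, atol = 1e-12), silent = TRUE))
  if (inherits(sim, "try-error") || any(!is.finite(as.matrix(sim))))
    return(rep(1e4, nrow(obs)))
  res <- numeric(nrow(obs))
  for (ob in unique(obs$observable)) {
    idx <- which(obs$observable == ob)
    simvals <- observable_from_state(sim, ob)
    at <- match(obs$time[idx], sim$time)
    res[idx] <- (obs$value[idx] - simvals[at]) / problem$scales[[ob]]
  }
  res
}

fit_loss <- function(log_params, problem) sum(fit_residuals(log_params, problem)^2)

# Core bounded least-squares driver: Levenberg-Marquardt with box bounds on
# log10 parameters, multi-started from log-uniform draws around the center.
fit_core <- function(problem, n_starts = 3, start_spread = 0.5, seed = 1,
                     maxiter = 100) {
  starts <- list(problem$center)
  if (n_starts > 1) {
    rs <- local_rng(seed)
    on.exit(restore_rng(rs))
    for (i in seq_len(n_starts - 1)) {
      s <- problem$center +
        stats::runif(length(problem$center), -start_spread, start_spread)
      starts[[i + 1]] <- pmin(pmax(s, problem$lower), problem$upper)
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = problem$lower, upper = problem$upper,
      fn = fit_residuals, problem = problem,
      # epsfcn keeps finite-difference steps (~1e-3 in log10 space) well
      # above the ODE integration noise, which would otherwise stall the
      # Jacobian estimate
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           epsfcn = 1e-6)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("fit_core: no start converged")
  loss0 <- fit_loss(problem$center, problem)
  if (best$deviance > loss0) {
    # optimizer never worsens the declared starting point
    best$par <- problem$center
    best$deviance <- loss0
    best$info <- -1L
  }
  best
}

finish_fit <- function(fit, problem) {
  est_log <- fit$par
  est <- 10^est_log
  names(est) <- problem$free
  converged <- fit$info %in% 1:4
  # Gauss-Newton standard errors on log10 scale from the residual covariance
  se <- rep(NA_real_, length(est))
  flags <- rep(FALSE, length(est))
  jt <- try({
    r <- fit_residuals(est_log, problem)
    J <- numjac(function(lp) fit_residuals(lp, problem), est_log)
    dof <- max(length(r) - length(est_log), 1)
    s2 <- sum(r^2) / dof
    JtJ <- crossprod(J)
    sv <- svd(JtJ)$d
    flags <- sv < max(sv) * 1e-10
    cova <- s2 * tryCatch(solve(JtJ), error = function(e) {
      matrix(NA_real_, length(est_log), length(est_log))
    })
    sqrt(pmax(diag(cova), 0))
  }, silent = TRUE)
  if (!inherits(jt, "try-error")) se <- jt
  structure(list(estimates = est, log10_estimates = est_log,
                 loss = fit$deviance, converged = converged,
                 se_log10 = stats::setNames(se, problem$free),
                 non_identifiable = stats::setNames(flags, problem$free),
                 problem = problem, fit = fit),
            class = "fit_result")
}

numjac <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Calibration fit (", length(x$estimates), " free parameters)\n", sep = "")
  cat("  loss:", format(x$loss, digits = 6),
      " converged:", x$converged, "\n")
  print(data.frame(estimate = x$estimates, se_log10 = x$se_log10,
                   flagged = x$non_identifiable))
  invisible(x)
}

#' Calibrate the photoferrotroph model to SW2-only observations
#'
#' Frees the three photoferrotrophy parameters (`mu_max_ph`, `K_Fe_ph`,
#' `Y_sw2`) and fits the SW2-only scenario to the observations by bounded
#' nonlinear least squares over log10-transformed parameters, the log
#' transform removing the orders-of-magnitude disparity between rate
#' constants and cell yields.
#'
#' @param observations Observation table (Fe(II) and cell counts at minimum).
#' @param config SW2-only [reactor_config()]; defaults to the standard
#'   incubation (10 mM Fe(II), 1 mM nitrate, 30 days).
#' @param params Starting/fixed parameter set (default [default_params()]).
#' @param n_starts Number of multi-start optimizations (first start is the
#'   supplied center; the rest are log-uniform perturbations).
#' @param seed Seed for the multi-start draws.
#' @param ... Passed to [fit_problem()] (e.g. `bounds_decades`, `rtol`).
#' @return A `fit_result`.
#' @export
fit_sw2 <- function(observations,
                    config = reactor_config("SW2_ONLY",
                      reactor_state(x_sw2 = 2e9), t_end = 30),
                    params = default_params(),
                    n_starts = 3, seed = 1, ...) {
  problem <- fit_problem(observations, config, params,
                         free = c("mu_max_ph", "K_Fe_ph", "Y_sw2"), ...)
  finish_fit(fit_core(problem, n_starts = n_starts, seed = seed), problem)
}

#' Calibrate the two-step denitrification model to KS-only observations
#'
#' Frees the eight parameters of the nitrate-reducing guild and the gas
#' exchange coefficient (`mu_max_1`, `mu_max_2`, `K_Fe_ndfo`, `K_NO3`,
#' `K_NO`, `Y_ks1`, `Y_ks2`, `k_tr`).
#'
#' @inheritParams fit_sw2
#' @param config KS-only [reactor_config()].
#' @return A `fit_result`.
#' @export
fit_ks <- function(observations,
                   config = reactor_config("KS_ONLY",
                     reactor_state(x_ks = 1e9), t_end = 30),
                   params = default_params(),
                   n_starts = 3, seed = 1, ...) {
  problem <- fit_problem(observations, config, params,
                         free = c("mu_max_1", "mu_max_2", "K_Fe_ndfo",
                                  "K_NO3", "K_NO", "Y_ks1", "Y_ks2", "k_tr"),
                         ...)
  finish_fit(fit_core(problem, n_starts = n_starts, seed = seed), problem)
}

#' Fit the toxicity parameters of the assembled mixed model
#'
#' Combines the individually calibrated photoferrotroph and denitrifier
#' parameter sets into the mixed model and estimates only the toxicity
#' free parameters `k_d` (decay rate) and `p_tox` (steepness). The toxic
#' inhibition concentration `K_I_NO` is held fixed at its experimentally
#' determined value of 12 nM (1.2e-5 mM) and is never estimated.
#'
#' @param observations Mixed-incubation observation table.
#' @param sw2_fit,ks_fit `fit_result`s from [fit_sw2()] and [fit_ks()].
#' @inheritParams fit_sw2
#' @param config Mixed [reactor_config()].
#' @return A `fit_result`; `estimates` carries only `k_d` and `p_tox`, the
#'   assembled full parameter list is in `$params_full`.
#' @export
fit_mixed_toxicity <- function(observations, sw2_fit, ks_fit,
                               config = reactor_config("MIXED",
                                 reactor_state(x_sw2 = 2e9, x_ks = 1e9),
                                 t_end = 30),
                               params = default_params(),
                               n_starts = 3, seed = 1, ...) {
  flat <- flatten_params(params)
  flat[names(sw2_fit$estimates)] <- sw2_fit$estimates
  flat[names(ks_fit$estimates)] <- ks_fit$estimates
  flat["K_I_NO"] <- 1.2e-5
  assembled <- unflatten_params(flat)
  problem <- fit_problem(observations, config, assembled,
                         free = c("k_d", "p_tox"), ...)
  out <- finish_fit(fit_core(problem, n_starts = n_starts, seed = seed),
                    problem)
  out$params_full <- params_with(assembled, out$estimates)
  out
}

#' Local sensitivity and identifiability summary of a fit
#'
#' Computes, for each free parameter at the optimum: the central
#' finite-difference gradient of the loss with respect to log10 of the
#' parameter, the root-mean-square normalized residual sensitivity (the
#' corresponding column of the residual Jacobian), the Gauss-Newton standard
#' error on the log10 scale, and a non-identifiability flag raised when the
#' parameter's Jacobian column is numerically negligible or the information
#' matrix is singular along it.
#'
#' @param fit_result A `fit_result`.
#' @param h Finite-difference step in log10 units.
#' @return A data.frame with one row per free parameter.
#' @export
local_sensitivity <- function(fit_result, h = 1e-4) {
  problem <- fit_result$problem
  lp <- fit_result$log10_estimates
  grad <- vapply(seq_along(lp), function(j) {
    xp <- lp; xm <- lp
    xp[j] <- lp[j] + h; xm[j] <- lp[j] - h
    (fit_loss(xp, problem) - fit_loss(xm, problem)) / (2 * h)
  }, numeric(1))
  J <- numjac(function(x) fit_residuals(x, problem), lp)
  col_rms <- sqrt(colMeans(J^2))
  flagged <- fit_result$non_identifiable |
    col_rms < max(col_rms, .Machine$double.eps) * 1e-8
  data.frame(parameter = problem$free,
             dloss_dlog10 = grad,
             sens_rms = col_rms,
             se_log10 = unname(fit_result$se_log10),
             non_identifiable = unname(flagged),
             row.names = NULL)
}

# seeded local RNG helpers: save and restore the global stream so seeded
# package functions do not disturb the caller's RNG state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
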