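sw2_free <- c("mu_max_ph", "K_Fe_ph", "Y_sw2")
ks_free <- c("mu_max_1", "mu_max_2", "K_Fe_ndfo", "K_NO3", "K_NO",
             "Y_ks1", "Y_ks2", "k_tr")

sw2_obs_clean <- generate_observations(
  scenarios$sw2_only$config, truth_params, scenarios$sw2_only$schedule,
  zero_noise(), seed = 7)

test_that("residuals vanish at the generating parameters on noise-free data", {
  pr <- fit_problem(sw2_obs_clean, scenarios$sw2_only$config, truth_params,
                    free = sw2_free)
  r <- fit_residuals(log10(truth_flat[sw2_free]), pr)
  expect_lt(max(abs(r)), 1e-5)
})

test_that("perturbing any free parameter off the truth increases the loss", {
  pr <- fit_problem(sw2_obs_clean, scenarios$sw2_only$config, truth_params,
                    free = sw2_free)
  at_truth <- ferronox:::fit_loss(log10(truth_flat[sw2_free]), pr)
  for (j in seq_along(sw2_free)) for (d in c(-0.1, 0.1)) {
    lp <- log10(truth_flat[sw2_free])
    lp[j] <- lp[j] + d
    expect_gt(ferronox:::fit_loss(lp, pr), at_truth + 1e-4)
  }
})

test_that("duplicating an observation row doubles its loss contribution", {
  obs <- sw2_obs_clean[sw2_obs_clean$replicate == 1, ]
  pr1 <- fit_problem(obs, scenarios$sw2_only$config, truth_params,
                     free = sw2_free)
  pr2 <- fit_problem(rbind(obs, obs[3, ]), scenarios$sw2_only$config,
                     truth_params, free = sw2_free)
  lp <- log10(truth_flat[sw2_free] * c(1.3, 1.3, 1.3))
  r1 <- fit_residuals(lp, pr1)
  r2 <- fit_residuals(lp, pr2)
  expect_equal(sum(r2^2) - sum(r1^2), r1[3]^2, tolerance = 1e-9)
})

test_that("empty or malformed observation sets are rejected", {
  expect_error(fit_problem(sw2_obs_clean[0, ], scenarios$sw2_only$config,
                           truth_params, free = sw2_free), "empty")
  expect_error(fit_problem(data.frame(x = 1), scenarios$sw2_only$config,
                           truth_params, free = sw2_free), "columns")
  expect_error(fit_problem(sw2_obs_clean, scenarios$sw2_only$config,
                           truth_params, free = "mu_banana"), "unknown")
})

test_that("photoferrotrophy parameters are recovered from noise-free data", {
  f <- fit_sw2(sw2_obs_clean, config = scenarios$sw2_only$config,
               params = perturbed_start(sw2_free, 1.75), n_starts = 3,
               seed = 1)
  expect_true(f$converged)
  rel_err <- abs(f$estimates / truth_flat[sw2_free] - 1)
  expect_lt(max(rel_err), 0.01)
  expect_lt(f$loss, 1e-6)
})

test_that("photoferrotrophy parameters recover within 25% under 5% noise", {
  obs <- generate_observations(
    scenarios$sw2_only$config, truth_params, scenarios$sw2_only$schedule,
    flat_noise(0.05), seed = 11)
  f <- fit_sw2(obs, config = scenarios$sw2_only$config,
               params = perturbed_start(sw2_free, 1.5), n_starts = 3,
               seed = 1)
  rel_err <- abs(f$estimates / truth_flat[sw2_free] - 1)
  expect_lt(max(rel_err), 0.25)
  # optimum at least as good as the generating parameters (optimizer sanity)
  pr <- f$problem
  expect_lte(f$loss,
             ferronox:::fit_loss(log10(truth_flat[sw2_free]), pr) + 1e-9)
})

test_that("log-space and linear-space optimization agree on the optimum loss", {
  obs <- sw2_obs_clean[sw2_obs_clean$replicate == 1, ]
  pr <- fit_problem(obs, scenarios$sw2_only$config, truth_params,
                    free = sw2_free)
  start_lin <- truth_flat[sw2_free] * 1.4
  f_log <- ferronox:::fit_core(pr, n_starts = 1)
  # independent route: Nelder-Mead directly on the linear parameters
  f_lin <- stats::optim(start_lin, function(theta) {
    if (any(theta <= 0)) return(1e8)
    ferronox:::fit_loss(log10(theta), pr)
  }, control = list(maxit = 2000, reltol = 1e-14,
                    parscale = abs(start_lin)))
  expect_lt(abs(f_log$deviance - f_lin$value), 1e-6)
})

test_that("the KS fit reproduces the trajectory even where parameters are sloppy", {
  obs <- generate_observations(
    scenarios$ks_only_B$config, truth_params, scenarios$ks_only_B$schedule,
    zero_noise(), seed = 7)
  f <- fit_ks(obs, config = scenarios$ks_only_B$config,
              params = perturbed_start(ks_free, 1.5), n_starts = 3, seed = 1)
  expect_lt(f$loss, 1e-3)
  # the fitted model predicts the true dynamics on a dense grid
  tt <- seq(0, 30, length.out = 121)
  fitted_traj <- simulate_reactor(
    scenarios$ks_only_B$config,
    ferronox:::params_with(truth_params, f$estimates), times = tt)
  true_traj <- simulate_reactor(scenarios$ks_only_B$config, truth_params,
                                times = tt)
  expect_equal(fitted_traj$c_fe, true_traj$c_fe, tolerance = 0.02)
  expect_equal(fitted_traj$c_no3, true_traj$c_no3, tolerance = 0.05)
  expect_equal(fitted_traj$x_ks, true_traj$x_ks, tolerance = 0.05)
  # gas exchange coefficient is well identified by the partial-pressure data
  expect_lt(abs(f$estimates[["k_tr"]] / truth_flat[["k_tr"]] - 1), 0.1)
})

test_that("mixed-model assembly frees only the toxicity parameters, K_I stays fixed", {
  obs <- generate_observations(
    scenarios$mixed$config, truth_params, scenarios$mixed$schedule,
    zero_noise(), seed = 12)
  sw2_fit <- list(estimates = truth_flat[sw2_free])
  ks_fit <- list(estimates = truth_flat[ks_free])
  start <- truth_params
  start$phototroph$k_d <- 1.3
  start$phototroph$p_tox <- 1.4
  f <- fit_mixed_toxicity(obs, sw2_fit, ks_fit,
                          config = scenarios$mixed$config, params = start,
                          n_starts = 1, seed = 1)
  expect_setequal(names(f$estimates), c("k_d", "p_tox"))
  expect_equal(ferronox:::flatten_params(f$params_full)[["K_I_NO"]], 1.2e-5)
  # zero-noise recovery of both toxicity parameters
  rel_err <- abs(f$estimates / truth_flat[c("k_d", "p_tox")] - 1)
  expect_lt(max(rel_err), 0.01)
})

test_that("under 5% noise the identified toxicity combination recovers within 20%", {
  obs <- generate_observations(
    scenarios$mixed$config, truth_params, scenarios$mixed$schedule,
    flat_noise(0.05), seed = 12)
  sw2_fit <- list(estimates = truth_flat[sw2_free])
  ks_fit <- list(estimates = truth_flat[ks_free])
  start <- truth_params
  start$phototroph$k_d <- 1.3
  start$phototroph$p_tox <- 1.4
  f <- fit_mixed_toxicity(obs, sw2_fit, ks_fit,
                          config = scenarios$mixed$config, params = start,
                          n_starts = 3, seed = 1)
  # the decay rate itself is identified ...
  expect_lt(abs(f$estimates[["k_d"]] / truth_flat[["k_d"]] - 1), 0.2)
  # ... as is the effective decay k_d*(1 - f_tox) at the plateau NO level;
  # the steepness exponent alone is not, because aqueous NO sits at K_I
  plateau_no <- max(cached_traj("mixed")$c_no)
  eff <- function(kd, p) {
    ph <- truth_params$phototroph
    ph$k_d <- kd; ph$p_tox <- p
    kd * (1 - toxicity_fraction(plateau_no, ph))
  }
  eff_true <- eff(truth_flat[["k_d"]], truth_flat[["p_tox"]])
  eff_est <- eff(f$estimates[["k_d"]], f$estimates[["p_tox"]])
  expect_lt(abs(eff_est / eff_true - 1), 0.2)
})

test_that("sensitivity analysis flags parameters without influence", {
  obs <- sw2_obs_clean[sw2_obs_clean$replicate == 1, ]
  # K_NO3 cannot influence a phototroph-only incubation
  pr <- fit_problem(obs, scenarios$sw2_only$config, truth_params,
                    free = c("mu_max_ph", "K_NO3"))
  fit <- ferronox:::fit_core(pr, n_starts = 1, maxiter = 5)
  fr <- ferronox:::finish_fit(fit, pr)
  tab <- local_sensitivity(fr)
  expect_true(tab$non_identifiable[tab$parameter == "K_NO3"])
  expect_false(tab$non_identifiable[tab$parameter == "mu_max_ph"])
  expect_equal(tab$sens_rms[tab$parameter == "K_NO3"], 0, tolerance = 1e-10)
})

test_that("sensitivities scale with observation duplication as least squares dictates", {
  obs <- sw2_obs_clean[sw2_obs_clean$replicate == 1, ]
  pr1 <- fit_problem(obs, scenarios$sw2_only$config, truth_params,
                     free = sw2_free)
  pr2 <- fit_problem(rbind(obs, obs), scenarios$sw2_only$config, truth_params,
                     free = sw2_free)
  lp <- log10(truth_flat[sw2_free] * 1.2)
  fr1 <- list(log10_estimates = lp, problem = pr1,
              non_identifiable = stats::setNames(rep(FALSE, 3), sw2_free),
              se_log10 = stats::setNames(rep(NA_real_, 3), sw2_free))
  fr2 <- fr1
  fr2$problem <- pr2
  g1 <- local_sensitivity(fr1)$dloss_dlog10
  g2 <- local_sensitivity(fr2)$dloss_dlog10
  expect_equal(g2, 2 * g1, tolerance = 1e-4)
})

test_that("yield sensitivity is carried by both cell counts and Fe(II) drawdown", {
  # with the inoculum known, X(t) does not depend on Y_sw2, so the yield is
  # identified through the cell counts directly and through the Fe(II)
  # drawdown scale; its Jacobian column must be substantial in both designs
  obs_cells <- sw2_obs_clean
  obs_fe <- sw2_obs_clean[sw2_obs_clean$observable == "Fe2_mM", ]
  lp <- log10(truth_flat[sw2_free])
  pr_cells <- fit_problem(obs_cells, scenarios$sw2_only$config, truth_params,
                          free = sw2_free)
  pr_fe <- fit_problem(obs_fe, scenarios$sw2_only$config, truth_params,
                       free = sw2_free)
  Jc <- ferronox:::numjac(function(x) fit_residuals(x, pr_cells), lp)
  Jf <- ferronox:::numjac(function(x) fit_residuals(x, pr_fe), lp)
  iY <- which(sw2_free == "Y_sw2")
  expect_gt(sqrt(mean(Jc[, iY]^2)), 1e-3)
  expect_gt(sqrt(mean(Jf[, iY]^2)), 1e-3)
  # dropping the cell counts still degrades the conditioning of the problem
  expect_gt(svd(Jf)$d[1] / svd(Jf)$d[3], svd(Jc)$d[1] / svd(Jc)$d[3])
})
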