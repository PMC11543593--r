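# Shared fixtures: the synthetic reference parameters, the standard scenario
# library, and lazily cached reference trajectories reused across test files.

truth_params <- default_params()
truth_flat <- ferronox:::flatten_params(truth_params)
scenarios <- make_default_scenarios()

.traj_cache <- new.env(parent = emptyenv())

cached_traj <- function(name) {
  if (!exists(name, envir = .traj_cache)) {
    traj <- switch(name,
      ks    = simulate_reactor(scenarios$ks_only_B$config, truth_params),
      mixed = simulate_reactor(scenarios$mixed$config, truth_params),
      mixed_flush = simulate_reactor(scenarios$mixed_flush$config, truth_params),
      sw2   = simulate_reactor(scenarios$sw2_only$config, truth_params),
      stop("unknown fixture trajectory: ", name))
    assign(name, traj, envir = .traj_cache)
  }
  get(name, envir = .traj_cache)
}

# perturb a subset of flat parameters by alternating factors, returning a
# full parameter list usable as a fit starting point
perturbed_start <- function(free, factor) {
  flat <- truth_flat
  flat[free] <- flat[free] * rep(c(factor, 1 / factor), length.out = length(free))
  ferronox:::unflatten_params(flat)
}

zero_noise <- function() {
  noise_model(rel_sd = c(Fe2_mM = 0, NO3_mM = 0, cells_per_ml = 0,
                         pNO_Pa = 0, pN2O_Pa = 0))
}

flat_noise <- function(sd) {
  noise_model(rel_sd = c(Fe2_mM = sd, NO3_mM = sd, cells_per_ml = sd,
                         pNO_Pa = sd, pN2O_Pa = sd))
}
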