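#' Measurement-noise model for synthetic incubation data
#'
#' Per-observable relative standard deviations and distribution families.
#' Concentration and pressure observables receive multiplicative Gaussian
#' noise truncated at zero; cell counts, which span decades and are strictly
#' positive, receive multiplicative log-normal noise. Both families are
#' parameterized so the coefficient of variation equals the requested
#' relative sd and the mean of the noise factor is 1.
#'
#' @param rel_sd Named numeric vector of relative standard deviations per
#'   observable. Defaults reflect instrument-class magnitudes: ferrozine-type
#'   Fe(II) assay 3%, ion-chromatography nitrate 5%, flow-cytometry counts
#'   20%, headspace gas chromatography 10%.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rel_sd = c(Fe2_mM = 0.03, NO3_mM = 0.05,
                                   cells_per_ml = 0.20,
                                   pNO_Pa = 0.10, pN2O_Pa = 0.10)) {
  if (any(rel_sd < 0)) stop("noise_model: relative sds must be >= 0")
  structure(list(rel_sd = rel_sd), class = "noise_model")
}

noise_factor <- function(n, cv, lognormal) {
  if (cv == 0) return(rep(1, n))
  if (lognormal) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    pmax(stats::rnorm(n, mean = 1, sd = cv), 0)
  }
}

#' Generate a synthetic incubation observation set
#'
#' Simulates the scenario once (the replicate-independent truth), samples the
#' trajectory at the requested schedule, and perturbs each observation
#' independently per replicate and observable according to the noise model.
#' Noise enters the observations only; the underlying dynamics are
#' deterministic. Generation is a pure function of its arguments and the
#' seed, and the caller's RNG state is left untouched.
#'
#' @param config A [reactor_config()].
#' @param params_all Generating ("true") parameter list.
#' @param schedule Sampling times (days) within the simulation horizon.
#' @param noise A [noise_model()].
#' @param n_replicates Number of replicate vessels (default 3, emulating
#'   biological triplicates).
#' @param observables Which observables to report. `pNO_Pa` emulates the
#'   chemiluminescence NO series measured in a parallel denitrifier-only
#'   incubation and is by default included only for the KS-only scenario.
#' @param seed Integer seed; same inputs and seed give identical output.
#' @return A data.frame of class `observation_set` with columns `replicate`,
#'   `time`, `observable`, `value`; the generating parameters, seed and noise
#'   model are attached as a `provenance` attribute (not used by any fitting
#'   code path).
#' @export
generate_observations <- function(config, params_all, schedule,
                                  noise = noise_model(), n_replicates = 3,
                                  observables = NULL, seed = 1) {
  if (any(schedule < 0) || any(schedule > config$t_end))
    stop("generate_observations: schedule outside the simulation horizon")
  schedule <- sort(unique(schedule))
  if (is.null(observables)) {
    observables <- switch(config$scenario,
      SW2_ONLY = c("Fe2_mM", "NO3_mM", "cells_per_ml"),
      KS_ONLY  = c("Fe2_mM", "NO3_mM", "cells_per_ml", "pNO_Pa", "pN2O_Pa"),
      MIXED    = c("Fe2_mM", "NO3_mM", "cells_per_ml", "pN2O_Pa"))
  }
  truth <- simulate_reactor(config, params_all,
                            times = sort(unique(c(0, schedule))))
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  rows <- list()
  for (ob in observables) {
    cv <- if (ob %in% names(noise$rel_sd)) noise$rel_sd[[ob]] else 0
    # clamp solver-level negatives (~1e-13) so observations are physical
    true_vals <- pmax(observable_from_state(truth, ob)[match(schedule, truth$time)], 0)
    for (rep_i in seq_len(n_replicates)) {
      fac <- noise_factor(length(schedule), cv, ob == "cells_per_ml")
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_i, time = schedule, observable = ob,
        value = true_vals * fac)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("observation_set", "data.frame")
  attr(out, "provenance") <- list(
    params = flatten_params(params_all), seed = seed,
    scenario = config$scenario, rel_sd = noise$rel_sd,
    n_replicates = n_replicates)
  out
}

#' Standard incubation scenario library
#'
#' Ready-made configurations mirroring the incubation design: 50 ml medium
#' under 50 ml headspace, 10 mM Fe(II), nitrate at 0.4 mM (scenario A) or
#' 1 mM (scenario B), starting densities of 2e9 cells/L for the phototroph
#' and 1e9 cells/L for the denitrifier culture (i.e. 2e6 and 1e6 cells/ml),
#' a 30-day horizon and sampling every 2 days. The flushed variant zeroes the
#' headspace after every sampling point.
#'
#' @return A named list of scenarios; each element holds `config` (a
#'   [reactor_config()]) and `schedule` (default sampling times, days).
#' @export
make_default_scenarios <- function() {
  sched <- seq(0, 30, by = 2)
  flush <- sched[sched > 0 & sched < 30]
  list(
    sw2_only = list(
      config = reactor_config("SW2_ONLY",
        reactor_state(c_fe = 10, c_no3 = 1, x_sw2 = 2e9), t_end = 30),
      schedule = sched),
    ks_only_A = list(
      config = reactor_config("KS_ONLY",
        reactor_state(c_fe = 10, c_no3 = 0.4, x_ks = 1e9), t_end = 30),
      schedule = sched),
    ks_only_B = list(
      config = reactor_config("KS_ONLY",
        reactor_state(c_fe = 10, c_no3 = 1, x_ks = 1e9), t_end = 30),
      schedule = sched),
    mixed = list(
      config = reactor_config("MIXED",
        reactor_state(c_fe = 10, c_no3 = 1, x_sw2 = 2e9, x_ks = 1e9),
        t_end = 30),
      schedule = sched),
    mixed_flush = list(
      config = reactor_config("MIXED",
        reactor_state(c_fe = 10, c_no3 = 1, x_sw2 = 2e9, x_ks = 1e9),
        t_end = 30, flush_times = flush),
      schedule = sched)
  )
}

#' Read / write observation sets as delimited text
#'
#' Tab-separated table with a commented metadata header block recording the
#' scenario, seed and noise model (the generating parameters are withheld so
#' that files handed to fitting code carry no ground truth).
#'
#' @param observations An `observation_set`.
#' @param file File path.
#' @return `write_observations()` returns `file` invisibly;
#'   `read_observations()` returns the observation data.frame.
#' @export
write_observations <- function(observations, file) {
  prov <- attr(observations, "provenance")
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(prov)) {
    writeLines(sprintf("# scenario: %s", prov$scenario), con)
    writeLines(sprintf("# seed: %d", prov$seed), con)
    writeLines(sprintf("# n_replicates: %d", prov$n_replicates), con)
    writeLines(sprintf("# rel_sd_%s: %g", names(prov$rel_sd), prov$rel_sd), con)
  }
  utils::write.table(observations, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_observations
#' @export
read_observations <- function(file) {
  out <- utils::read.table(file, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  class(out) <- c("observation_set", "data.frame")
  out
}
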