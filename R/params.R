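#' Kinetic parameters for the photoferrotroph
#'
#' Bundles the Monod growth constants, growth yield and NO-toxicity constants
#' for the phototrophic Fe(II) oxidizer. Units follow the package convention:
#' concentrations in mM, time in days, biomass in cells per litre.
#'
#' @param mu_max_ph Maximum specific growth rate (per day).
#' @param K_Fe_ph Fe(II) half-saturation constant (mM).
#' @param Y_sw2 Growth yield (cells per mmol Fe(II) oxidized).
#' @param k_d First-order decay rate coefficient under NO stress (per day).
#' @param K_I_NO Toxic inhibition (half-effect) NO concentration (mM);
#'   the calibrated value is 12 nM = 1.2e-5 mM.
#' @param p_tox Dimensionless steepness exponent of the toxicity function.
#' @return An object of class `phototroph_params`.
#' @examples
#' phototroph_params(mu_max_ph = 0.3, K_Fe_ph = 1, Y_sw2 = 1e10)
#' @export
phototroph_params <- function(mu_max_ph, K_Fe_ph, Y_sw2,
                              k_d = 1, K_I_NO = 1.2e-5, p_tox = 2) {
  p <- list(mu_max_ph = mu_max_ph, K_Fe_ph = K_Fe_ph, Y_sw2 = Y_sw2,
            k_d = k_d, K_I_NO = K_I_NO, p_tox = p_tox)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("phototroph_params: '", nm, "' must be a single positive number")
  }
  structure(p, class = "phototroph_params")
}

#' Kinetic parameters for the nitrate-reducing Fe(II) oxidizer
#'
#' The denitrification chain is fixed at two microbially mediated steps,
#' NO3- -> NO (step 1) and NO -> 1/2 N2O (step 2), each following dual-Monod
#' kinetics in Fe(II) (electron donor) and the step's nitrogen electron
#' acceptor. Both steps share the Fe(II) half-saturation constant and draw on
#' the same lumped biomass pool.
#'
#' @param mu_max Length-2 vector of maximum specific growth rates (per day);
#'   element 1 is the nitrate step, element 2 the NO step.
#' @param K_Fe_ndfo Fe(II) half-saturation shared by both steps (mM).
#' @param K_N Length-2 vector of electron-acceptor half-saturations
#'   (K_NO3, K_NO), mM.
#' @param Y_ks Length-2 vector of growth yields (cells per mmol Fe(II)).
#' @return An object of class `ndfo_params` with `n_steps = 2`.
#' @export
ndfo_params <- function(mu_max, K_Fe_ndfo, K_N, Y_ks) {
  if (length(mu_max) != 2L || length(K_N) != 2L || length(Y_ks) != 2L)
    stop("ndfo_params: mu_max, K_N and Y_ks must each have exactly two entries")
  p <- list(mu_max = as.numeric(mu_max), K_Fe_ndfo = K_Fe_ndfo,
            K_N = as.numeric(K_N), Y_ks = as.numeric(Y_ks), n_steps = 2L)
  vals <- c(p$mu_max, p$K_Fe_ndfo, p$K_N, p$Y_ks)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("ndfo_params: all rates, half-saturations and yields must be positive")
  structure(p, class = "ndfo_params")
}

#' Gas-liquid exchange parameters
#'
#' Interfacial transfer follows a linear driving force towards Henry's-law
#' equilibrium. `H` is the dimensionless Henry constant expressed as the
#' gas-over-aqueous concentration ratio, so the aqueous equilibrium
#' concentration for partial pressure p (Pa) is p / (R * T * H) in mol m^-3,
#' numerically equal to mM. Defaults for NO and N2O are literature-plausible
#' values at 298.15 K; the transfer coefficient is reactor-specific.
#'
#' @param k_tr First-order mass-transfer rate coefficient (per day).
#' @param H Named numeric vector of dimensionless Henry constants
#'   (gas/aqueous) with entries `NO` and `N2O`.
#' @param T_abs Absolute temperature (K), fixed at 298.15 by default.
#' @return An object of class `gas_params`; the ideal gas constant
#'   `R_gas` = 8.314462618 J mol^-1 K^-1 is stored alongside.
#' @export
gas_params <- function(k_tr, H = c(NO = 21.3, N2O = 1.7), T_abs = 298.15) {
  if (k_tr < 0) stop("gas_params: k_tr must be >= 0")
  if (!all(c("NO", "N2O") %in% names(H)))
    stop("gas_params: H must name entries 'NO' and 'N2O'")
  if (any(H <= 0)) stop("gas_params: Henry constants must be > 0")
  structure(list(k_tr = k_tr, H = H[c("NO", "N2O")],
                 R_gas = 8.314462618, T_abs = T_abs),
            class = "gas_params")
}

#' Packaged synthetic reference parameter set
#'
#' A complete parameter set for both guilds and the gas phase, calibrated
#' against the qualitative study conditions of the incubation experiments
#' (complete photoferrotrophic oxidation of 10 mM Fe(II) in about four weeks;
#' exhaustion of 1 mM nitrate in about four days with ~4 mM Fe(II) oxidized;
#' cessation of mixed-culture Fe(II) oxidation after about 3.5 days; a
#' nanomolar transient aqueous NO peak). It is a synthetic stand-in used for
#' fixtures, demonstrations and replay checks, not a measured calibration.
#'
#' @return A named list with elements `phototroph` (`phototroph_params`),
#'   `ndfo` (`ndfo_params`) and `gas` (`gas_params`).
#' @export
default_params <- function() {
  list(
    phototroph = phototroph_params(
      mu_max_ph = 0.20, K_Fe_ph = 2.0, Y_sw2 = 1e10,
      k_d = 2, K_I_NO = 1.2e-5, p_tox = 2),
    ndfo = ndfo_params(
      mu_max = c(0.6, 1.6), K_Fe_ndfo = 0.5,
      K_N = c(0.05, 1e-4), Y_ks = c(2.5e9, 2.5e9)),
    gas = gas_params(k_tr = 5)
  )
}

# flat key-value view used for serialization and for the calibration layer;
# keys mirror the field symbols (mu_max_1, K_NO3, H_NO, ...)
flatten_params <- function(params) {
  ph <- params$phototroph; nd <- params$ndfo; gs <- params$gas
  c(mu_max_ph = ph$mu_max_ph, K_Fe_ph = ph$K_Fe_ph, Y_sw2 = ph$Y_sw2,
    k_d = ph$k_d, K_I_NO = ph$K_I_NO, p_tox = ph$p_tox,
    mu_max_1 = nd$mu_max[1], mu_max_2 = nd$mu_max[2],
    K_Fe_ndfo = nd$K_Fe_ndfo, K_NO3 = nd$K_N[1], K_NO = nd$K_N[2],
    Y_ks1 = nd$Y_ks[1], Y_ks2 = nd$Y_ks[2],
    k_tr = gs$k_tr, H_NO = unname(gs$H["NO"]), H_N2O = unname(gs$H["N2O"]))
}

unflatten_params <- function(x) {
  x <- unlist(x)
  need <- c("mu_max_ph", "K_Fe_ph", "Y_sw2", "k_d", "K_I_NO", "p_tox",
            "mu_max_1", "mu_max_2", "K_Fe_ndfo", "K_NO3", "K_NO",
            "Y_ks1", "Y_ks2", "k_tr", "H_NO", "H_N2O")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("parameter file is missing: ", paste(missing, collapse = ", "))
  list(
    phototroph = phototroph_params(
      mu_max_ph = x[["mu_max_ph"]], K_Fe_ph = x[["K_Fe_ph"]],
      Y_sw2 = x[["Y_sw2"]], k_d = x[["k_d"]],
      K_I_NO = x[["K_I_NO"]], p_tox = x[["p_tox"]]),
    ndfo = ndfo_params(
      mu_max = c(x[["mu_max_1"]], x[["mu_max_2"]]),
      K_Fe_ndfo = x[["K_Fe_ndfo"]],
      K_N = c(x[["K_NO3"]], x[["K_NO"]]),
      Y_ks = c(x[["Y_ks1"]], x[["Y_ks2"]])),
    gas = gas_params(k_tr = x[["k_tr"]],
                     H = c(NO = x[["H_NO"]], N2O = x[["H_N2O"]]))
  )
}

#' Read / write a parameter set as a flat YAML file
#'
#' Parameter files are flat key-value YAML whose keys mirror the model
#' symbols: `mu_max_ph, K_Fe_ph, Y_sw2, k_d, K_I_NO, p_tox, mu_max_1,
#' mu_max_2, K_Fe_ndfo, K_NO3, K_NO, Y_ks1, Y_ks2, k_tr, H_NO, H_N2O`.
#'
#' @param file Path to a YAML file.
#' @param params For writing, a list as returned by [default_params()].
#' @return `read_params()` returns the parameter list; `write_params()`
#'   returns `file` invisibly.
#' @export
read_params <- function(file) {
  unflatten_params(yaml::read_yaml(file))
}

#' @rdname read_params
#' @export
write_params <- function(params, file) {
  yaml::write_yaml(as.list(flatten_params(params)), file)
  invisible(file)
}
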