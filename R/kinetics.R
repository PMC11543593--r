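#' Photoferrotrophic growth rate
#'
#' Single-Monod growth of the phototroph on Fe(II), assuming light is
#' non-limiting:
#' \deqn{r = \mu_{max}^{ph} \frac{C_{Fe}}{C_{Fe} + K_{Fe}^{ph}} X}
#'
#' @param c_fe Aqueous Fe(II) concentration (mM).
#' @param x_sw2 Phototroph biomass density (cells per litre).
#' @param params A [phototroph_params()] object.
#' @return Growth rate in cells L^-1 day^-1.
#' @export
phototroph_growth_rate <- function(c_fe, x_sw2, params) {
  if (any(c_fe < 0) || any(x_sw2 < 0))
    stop("phototroph_growth_rate: concentrations and biomass must be >= 0")
  params$mu_max_ph * monod(c_fe, params$K_Fe_ph) * x_sw2
}

#' Denitrification-step growth rate of the nitrate-reducing Fe(II) oxidizer
#'
#' Dual-Monod kinetics in the electron donor Fe(II) and the step's nitrogen
#' electron acceptor (nitrate for step 1, aqueous NO for step 2):
#' \deqn{r_i = \mu_{max}^{i}
#'   \frac{C_{Fe}}{C_{Fe} + K_{Fe}} \frac{C_{N_i}}{C_{N_i} + K_{N_i}} X}
#'
#' @param step Denitrification step, 1 (NO3- -> NO) or 2 (NO -> 1/2 N2O).
#' @param c_fe Aqueous Fe(II) (mM).
#' @param c_n Electron-acceptor concentration for the step (mM).
#' @param x_ks Lumped culture biomass density (cells per litre).
#' @param params An [ndfo_params()] object.
#' @return Growth rate in cells L^-1 day^-1.
#' @export
ndfo_growth_rate <- function(step, c_fe, c_n, x_ks, params) {
  if (!step %in% c(1L, 2L)) stop("ndfo_growth_rate: step must be 1 or 2")
  if (any(c_fe < 0) || any(c_n < 0) || any(x_ks < 0))
    stop("ndfo_growth_rate: concentrations and biomass must be >= 0")
  params$mu_max[step] * monod(c_fe, params$K_Fe_ndfo) *
    monod(c_n, params$K_N[step]) * x_ks
}

# Monod saturation term, guarded against solver overshoot into c < 0
monod <- function(c, K) {
  c <- pmax(c, 0)
  c / (c + K)
}

#' NO toxicity function
#'
#' Dimensionless survival fraction of phototroph activity as a function of
#' aqueous NO:
#' \deqn{f_{tox} = \frac{1}{1 + (C_{NO}/K_I)^p}}
#' equal to 1 at zero NO, exactly 1/2 at \eqn{C_{NO} = K_I}, and strictly
#' decreasing; `p_tox` sets the steepness at the inflection.
#'
#' @param c_no Aqueous NO concentration (mM).
#' @param params A [phototroph_params()] object (fields `K_I_NO`, `p_tox`).
#' @return Value in (0, 1].
#' @export
toxicity_fraction <- function(c_no, params) {
  if (any(c_no < 0)) stop("toxicity_fraction: c_no must be >= 0")
  1 / (1 + (pmax(c_no, 0) / params$K_I_NO)^params$p_tox)
}

#' NO-dependent decay rate of the phototroph
#'
#' First-order decay scaled by the toxic stress \eqn{1 - f_{tox}}; lumps cell
#' lysis and dormancy. Zero at zero NO and saturating at `k_d * x` under
#' extreme NO.
#'
#' @inheritParams toxicity_fraction
#' @param x_sw2 Phototroph biomass density (cells per litre).
#' @return Decay rate in cells L^-1 day^-1 (a positive number; the biomass
#'   balance subtracts it).
#' @export
phototroph_decay_rate <- function(c_no, x_sw2, params) {
  if (any(c_no < 0) || any(x_sw2 < 0))
    stop("phototroph_decay_rate: inputs must be >= 0")
  params$k_d * (1 - toxicity_fraction(c_no, params)) * x_sw2
}

#' Gas-liquid interfacial transfer rate
#'
#' Linear-driving-force film diffusion towards Henry's-law equilibrium:
#' \deqn{r_{tr} = k_{tr} \left(C - \frac{p}{R T H}\right)}
#' Positive values denote net aqueous-to-gas transfer. With concentrations in
#' mM (= mol m^-3) and pressure in Pa, p/(R T) is already in mM and no unit
#' factor is needed.
#'
#' @param c_aq Aqueous concentration of the volatile species (mM).
#' @param p_gas Partial pressure in the headspace (Pa).
#' @param species `"NO"` or `"N2O"`.
#' @param params A [gas_params()] object.
#' @return Transfer rate in mM day^-1 referenced to the aqueous phase.
#' @export
gas_transfer_rate <- function(c_aq, p_gas, species, params) {
  if (!species %in% c("NO", "N2O"))
    stop("gas_transfer_rate: species must be 'NO' or 'N2O'")
  if (any(c_aq < 0) || any(p_gas < 0))
    stop("gas_transfer_rate: c_aq and p_gas must be >= 0")
  ceq <- p_gas / (params$R_gas * params$T_abs * params$H[[species]])
  params$k_tr * (c_aq - ceq)
}

#' Moles of Fe(II) oxidized per mole of nitrate reduced
#'
#' For complete denitrification to N2 the overall stoichiometry
#' (10 Fe2+ + 2 NO3-) gives 5 Fe per NO3-. The two-step model chain stops at
#' N2O and transfers one electron fewer per N: 3 Fe per NO3- -> NO plus
#' 1 Fe per NO -> 1/2 N2O, i.e. 4 Fe per NO3-.
#'
#' @param end_product `"N2"` (full denitrification) or `"N2O"` (model chain).
#' @return The dimensionless molar ratio (5 or 4).
#' @examples
#' fe_per_nitrate("N2")   # 5
#' fe_per_nitrate("N2O")  # 4
#' @export
fe_per_nitrate <- function(end_product) {
  switch(end_product,
    N2  = 10 / 2,
    N2O = 3 + 1,
    stop("fe_per_nitrate: end_product must be 'N2' or 'N2O'"))
}
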