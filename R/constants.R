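# Physical constants and the internal unit system.
#
# Internally every quantity is expressed in (um, ms, mM, mV):
#   * lengths in micrometres, times in milliseconds,
#   * concentrations in mM (1 mM = 1 mol m^-3),
#   * potentials in millivolts.
# With these units the diffusion coefficients of Table-type ionic data
# (um^2 ms^-1) and the thermal voltage RT/F (~24 mV) are O(1), which keeps
# the assembled Newton blocks well scaled.  The Poisson equation is divided
# through by the Faraday constant, so its source term is the plain signed
# concentration sum sum_k z_k c_k (mM) and the permittivity carries the
# 1/F factor (see eps_scaled()).

#' Physical constants used by the electrodiffusion model
#'
#' Returns the constants of the model in SI units: the gas constant `R_gas`
#' (J mol-1 K-1), Faraday constant `faraday` (C mol-1), absolute temperature
#' `temperature` (K), vacuum permittivity `eps0` (C m-1 V-1) and the relative
#' permittivities of the aqueous compartments (`eps_water`) and of the
#' membrane (`eps_membrane`).
#'
#' @param temperature absolute temperature in K.  The default corresponds to
#'   6.3 degrees Celsius, the canonical squid-axon temperature.
#' @return named list of constants.
#' @export
#' @examples
#' physical_constants()$faraday
physical_constants <- function(temperature = 279.450) {
  list(
    R_gas        = 8.31454,      # J mol^-1 K^-1
    faraday      = 96485,        # C mol^-1
    temperature  = temperature,  # K
    eps0         = 8.88541e-12,  # C m^-1 V^-1
    eps_water    = 80,
    eps_membrane = 40,
    k_boltzmann  = 1.380649e-23, # J K^-1
    avogadro     = 6.02214076e23 # mol^-1
  )
}

#' Thermal voltage RT/F in millivolts
#'
#' @param constants list from [physical_constants()].
#' @return RT/F in mV (about 24.08 mV at 279.45 K).
#' @export
thermal_voltage_mV <- function(constants = physical_constants()) {
  1000 * constants$R_gas * constants$temperature / constants$faraday
}

#' Scaled permittivity in internal units
#'
#' The Poisson equation is solved in the Faraday-scaled form
#' \deqn{-\nabla\cdot(\hat\varepsilon \nabla V) = \sum_k z_k c_k}
#' with V in mV, lengths in um and c in mM.  The scaled permittivity is
#' \eqn{\hat\varepsilon = \varepsilon_0\varepsilon_r \cdot 10^9 / F}
#' (mM um mV-1): the 1e9 converts C m-1 V-1 to C um-1 mV-1 and the 1/F turns
#' coulombs into "mM um^3" of monovalent charge.
#'
#' @param eps_rel relative permittivity (80 water, 40 membrane).
#' @param constants list from [physical_constants()].
#' @return scaled permittivity (numeric).
#' @export
eps_scaled <- function(eps_rel, constants = physical_constants()) {
  constants$eps0 * eps_rel * 1e9 / constants$faraday
}

#' Default ionic species table
#'
#' Three species: K+, Na+ and a generic anion A-, with diffusion coefficients
#' (um^2 ms^-1) and initial intracellular / extracellular concentrations (mM).
#' The anion concentrations are chosen so that the intracellular medium
#' carries a small net negative charge (-0.02 mM) while the extracellular
#' medium is electroneutral.
#'
#' @return data.frame with columns `name`, `z`, `D`, `c0_in`, `c0_out`.
#' @export
#' @examples
#' sp <- default_species()
#' sum(sp$z * sp$c0_in)   # net intracellular charge, mM
default_species <- function() {
  data.frame(
    name   = c("K", "Na", "A"),
    z      = c(1, 1, -1),
    D      = c(1.96, 1.33, 2.00),
    c0_in  = c(155, 12, 167.02),
    c0_out = c(4, 145, 149),
    stringsAsFactors = FALSE
  )
}

#' Electro-diffusive mobility coefficient
#'
#' Coefficient of the drift term in the Nernst-Planck flux
#' \eqn{F_k = -D_k \nabla c_k - \tilde D_k c_k \nabla V} with
#' \eqn{\tilde D_k = D_k z_k F/(RT)} (um^2 ms^-1 mV-1).  This is the unique
#' choice for which the zero-flux steady state is the Boltzmann distribution
#' \eqn{c_k \propto \exp(-z_k F V/(RT))}.
#'
#' @param D diffusion coefficient (um^2 ms^-1).
#' @param z valence.
#' @param constants list from [physical_constants()].
#' @return drift mobility (um^2 ms^-1 mV^-1).
#' @export
drift_mobility <- function(D, z, constants = physical_constants()) {
  D * z / thermal_voltage_mV(constants)
}

# Convert a current density in mA cm^-2 carried by species of valence z into
# a molar boundary flux in internal units (mM um ms^-1).
# 1 mA cm^-2 = 10 A m^-2; J = I/(zF) mol m^-2 s^-1 = 1e3 * I/(zF) mM um ms^-1.
current_to_flux <- function(I_mA_cm2, z, constants = physical_constants()) {
  1e4 * I_mA_cm2 / (z * constants$faraday)
}

# Region codes used throughout: triangles carry exactly one of these.
REGION_INTRA    <- 1L
REGION_MEMBRANE <- 2L
REGION_EXTRA    <- 3L
REGION_NAMES    <- c("intra", "membrane", "extra")

# Tag codes for boundary / interface edges.
TAG_EXT       <- 1L  # outer extracellular boundary (Dirichlet)
TAG_EXL       <- 2L  # left end of the interior strip (Neumann)
TAG_EXR       <- 3L  # right end of the interior strip (Neumann)
TAG_INN_INTRA <- 4L  # nodal membrane face on the intracellular side
TAG_INN_EXTRA <- 5L  # nodal membrane face on the extracellular side
TAG_INTERFACE <- 6L  # other electrolyte-membrane interface edges
TAG_NAMES <- c("ext", "exl", "exr", "inn_intra", "inn_extra", "interface")

#' @importFrom utils head tail
#' @importFrom methods as
#' @importFrom stats lm coef fitted residuals
NULL
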