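# Hodgkin-Huxley channel kinetics on the nodal membrane and conversion of
# channel current densities into molar boundary fluxes for the PNP system.
#
# The gating model is the classic squid-axon parameterization (the working
# temperature, 279.45 K = 6.3 C, is the canonical HH temperature; no Q10
# correction), expressed in absolute membrane potential with the rate
# functions anchored at the leak-balanced resting potential.

#' Channel conductance set for the node of Ranvier
#'
#' Conductance densities in mS cm-2: voltage-gated K+ and Na+ maxima, and
#' the two leak components.  `stim_amplitude` (mA cm-2) and `stim_duration`
#' (ms) describe the Na+ stimulus flux applied to the nodal membrane at the
#' start of a simulation.
#'
#' @param gbar_kv,gbar_nav voltage-gated maxima, mS cm-2.
#' @param g_kl,g_nal leak conductances, mS cm-2.
#' @param stim_amplitude Na+ stimulus current density, mA cm-2.
#' @param stim_duration stimulus duration, ms.
#' @return list of class `channel_set`.
#' @export
channel_set <- function(gbar_kv = 36, gbar_nav = 120,
                        g_kl = 0.435, g_nal = 0.065,
                        stim_amplitude = 1.0, stim_duration = 0.5) {
  stopifnot(gbar_kv >= 0, gbar_nav >= 0, g_kl >= 0, g_nal >= 0,
            stim_duration >= 0)
  structure(list(gbar_kv = gbar_kv, gbar_nav = gbar_nav,
                 g_kl = g_kl, g_nal = g_nal,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration),
            class = "channel_set")
}

#' Nernst equilibrium potential
#'
#' \eqn{E = (RT/zF)\,\ln(c_{out}/c_{in})} in mV.
#'
#' @param c_in,c_out concentrations on either side of the membrane, mM (> 0).
#' @param z valence.
#' @param constants list from [physical_constants()].
#' @return potential in mV.
#' @export
#' @examples
#' nernst_potential(155, 4, 1)    # K+ at 6.3 C: about -88 mV
#' nernst_potential(12, 145, 1)   # Na+: about +60 mV
nernst_potential <- function(c_in, c_out, z,
                             constants = physical_constants()) {
  if (any(c_in <= 0) || any(c_out <= 0))
    stop("Nernst potential requires positive concentrations", call. = FALSE)
  (thermal_voltage_mV(constants) / z) * log(c_out / c_in)
}

#' Leak-balanced resting potential
#'
#' The potential at which the two leak currents cancel:
#' \eqn{V_{rest} = (g_{KL} E_K + g_{NaL} E_{Na})/(g_{KL}+g_{NaL})}.
#'
#' @param channels a [channel_set()].
#' @param E_K,E_Na reversal potentials, mV.
#' @return mV.
#' @export
resting_potential <- function(channels = channel_set(),
                              E_K = nernst_potential(155, 4, 1),
                              E_Na = nernst_potential(12, 145, 1)) {
  (channels$g_kl * E_K + channels$g_nal * E_Na) /
    (channels$g_kl + channels$g_nal)
}

#' Hodgkin-Huxley gating rate functions
#'
#' Classic squid-axon opening/closing rates (ms-1) for m, h and n, written
#' in absolute potential with the canonical rest shifted to `v_rest`
#' (default -65 mV).  The removable singularities of the alpha_m and alpha_n
#' expressions are evaluated by their analytic limits.
#'
#' @param V_m membrane potential, mV (may be a vector).
#' @param v_rest anchor potential of the rate functions, mV.
#' @return list with components `m`, `h`, `n`, each a list of vectors
#'   `alpha` and `beta` (ms-1).
#' @export
gating_rates <- function(V_m, v_rest = -65) {
  stopifnot(all(is.finite(V_m)))
  v <- V_m - (v_rest + 65)   # express relative to the canonical -65 mV rest
  # vectorized x/(1 - exp(-x/s)) with the removable singularity at x = 0
  ratefun <- function(x, s) ifelse(abs(x) < 1e-7, s * (1 + x / (2 * s)),
                                   x / (1 - exp(-x / s)))
  list(
    m = list(alpha = 0.1 * ratefun(v + 40, 10),
             beta = 4 * exp(-(v + 65) / 18)),
    h = list(alpha = 0.07 * exp(-(v + 65) / 20),
             beta = 1 / (1 + exp(-(v + 35) / 10))),
    n = list(alpha = 0.01 * ratefun(v + 55, 10),
             beta = 0.125 * exp(-(v + 65) / 80))
  )
}

#' Gating steady states and time constants
#'
#' @inheritParams gating_rates
#' @return list with `inf` and `tau` (ms), each with components m, h, n.
#' @export
gating_steady <- function(V_m, v_rest = -65) {
  r <- gating_rates(V_m, v_rest)
  inf <- lapply(r, function(x) x$alpha / (x$alpha + x$beta))
  tau <- lapply(r, function(x) 1 / (x$alpha + x$beta))
  list(inf = inf, tau = tau)
}

#' Initial gating state at a holding potential
#'
#' @param V_m holding potential, mV.
#' @param v_rest anchor potential of the rate functions.
#' @return list of class `gating_state` with `m`, `h`, `n` in [0,1].
#' @export
gating_state <- function(V_m, v_rest = -65) {
  s <- gating_steady(V_m, v_rest)
  structure(list(m = s$inf$m, h = s$inf$h, n = s$inf$n, v_rest = v_rest),
            class = "gating_state")
}

#' Advance the gating variables by the exact exponential update
#'
#' With the membrane potential frozen over the step each gating variable
#' relaxes exponentially, \eqn{x \leftarrow x_\infty + (x - x_\infty)
#' e^{-\Delta t/\tau_x}}, which keeps x in [0, 1] for any V and composes
#' exactly (two half steps equal one full step).
#'
#' @param state a `gating_state`.
#' @param V_m membrane potential over the step, mV.
#' @param dt step, ms (> 0).
#' @return updated `gating_state`.
#' @export
advance_gating <- function(state, V_m, dt) {
  if (!(dt > 0)) stop("dt must be > 0", call. = FALSE)
  s <- gating_steady(V_m, state$v_rest)
  for (x in c("m", "h", "n"))
    state[[x]] <- s$inf[[x]] + (state[[x]] - s$inf[[x]]) *
      exp(-dt / s$tau[[x]])
  state
}

#' Transmembrane current densities and molar fluxes
#'
#' Channel current densities
#' \eqn{I_K = (\bar g_{Kv} n^4 + g_{KL})(V_m - E_K)},
#' \eqn{I_{Na} = (\bar g_{Nav} m^3 h + g_{NaL})(V_m - E_{Na})} (mA cm-2,
#' outward positive), converted to molar fluxes \eqn{f_k = I_k/(z_k F)}.
#' In the returned fluxes, positive means efflux through the intracellular
#' face; the extracellular face receives the opposite sign so that no ions
#' are created inside the membrane.
#'
#' @param V_m membrane potential (intracellular minus extracellular), mV.
#' @param gating a `gating_state`.
#' @param E_K,E_Na reversal potentials, mV (recompute from local
#'   concentrations with [nernst_potential()]).
#' @param channels a [channel_set()].
#' @param constants list from [physical_constants()].
#' @return list with `I` (mA cm-2, named K/Na) and `flux` (internal units
#'   mM um ms-1, named K/Na; positive = efflux on the intracellular face).
#' @export
transmembrane_flux <- function(V_m, gating, E_K, E_Na,
                               channels = channel_set(),
                               constants = physical_constants()) {
  gK <- channels$gbar_kv * gating$n^4 + channels$g_kl
  gNa <- channels$gbar_nav * gating$m^3 * gating$h + channels$g_nal
  I_K <- 1e-3 * gK * (V_m - E_K)      # mS cm-2 * mV = uA cm-2 -> mA cm-2
  I_Na <- 1e-3 * gNa * (V_m - E_Na)
  list(I = c(K = I_K, Na = I_Na),
       flux = c(K = current_to_flux(I_K, 1, constants),
                Na = current_to_flux(I_Na, 1, constants)))
}

#' Stimulus flux gate
#'
#' Constant inward Na+ flux on the nodal membrane for `t < stim_duration`,
#' zero afterwards.
#'
#' @param t time, ms (>= 0).
#' @param channels a [channel_set()].
#' @param constants list from [physical_constants()].
#' @return inward Na+ molar flux in internal units (mM um ms-1, positive =
#'   influx).
#' @export
stimulus_flux <- function(t, channels = channel_set(),
                          constants = physical_constants()) {
  stopifnot(all(t >= 0))
  ifelse(t < channels$stim_duration,
         current_to_flux(channels$stim_amplitude, 1, constants), 0)
}
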