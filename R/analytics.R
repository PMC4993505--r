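# Closed-form quantities used to validate the FEM solution: Debye length,
# the Gauss's-law membrane potential of the no-flux slab, the control-point
# error metric, cylindrical-shell capacitance, and the linearized
# Poisson-Boltzmann decay profile.

#' Debye screening length
#'
#' \eqn{\lambda_D = \sqrt{\varepsilon_0\varepsilon_w R T / (F^2 \sum_k z_k^2
#' c_k^0)}} with concentrations in mol m-3 (mM).  RT is used in place of
#' \eqn{k_B T N_A} (identical by definition).
#'
#' @param species data.frame as [default_species()].
#' @param constants list from [physical_constants()].
#' @param side `"intra"` or `"extra"`: which bulk composition to use.
#' @return Debye length in nm.
#' @export
#' @examples
#' debye_length()            # intracellular, ~0.73 nm
#' debye_length(side = "extra")
debye_length <- function(species = default_species(),
                         constants = physical_constants(),
                         side = c("intra", "extra")) {
  side <- match.arg(side)
  c0 <- if (side == "intra") species$c0_in else species$c0_out
  s <- sum(species$z^2 * c0)
  if (s <= 0) stop("sum z^2 c must be positive", call. = FALSE)
  lam2 <- eps_scaled(constants$eps_water, constants) *
    thermal_voltage_mV(constants) / s          # um^2
  1000 * sqrt(lam2)
}

#' Exact membrane potential of the no-flux slab (Gauss's law)
#'
#' At the zero-flux steady state the net intracellular charge (conserved from
#' the initial condition) accumulates in the Debye layers; by symmetry each
#' membrane screens half of it, and since the membrane itself is charge-free
#' the field inside it is uniform.  A Gauss box from the symmetry plane into
#' the membrane gives the exact potential jump between the two faces:
#' \deqn{V_{mem} = \frac{F \sum_k z_k c_k^{0,intra} \cdot (d_{intra}/2)\, d_{mem}}
#' {\varepsilon_0 \varepsilon_{mem}}}
#' (negative for a net-negative cytosol).  Value in mV.
#'
#' @param geom a [slab_geometry()].
#' @param species data.frame as [default_species()].
#' @param constants list from [physical_constants()].
#' @return potential difference V(intra face) - V(extra face), mV.
#' @export
#' @examples
#' analytic_membrane_potential(slab_geometry())   # about -235.6 mV
analytic_membrane_potential <- function(geom, species = default_species(),
                                        constants = physical_constants()) {
  qnet <- sum(species$z * species$c0_in)                  # mM
  qnet * (geom$d_intra / 2) * geom$d_mem /
    eps_scaled(constants$eps_membrane, constants)
}

#' Control-point membrane-potential error
#'
#' \eqn{|\Delta V_{exact} - (V_\eta(x_a) - V_\eta(x_b))|} with the two
#' control points on either face of the upper membrane.  Adding a global
#' constant to the potential leaves this error unchanged.
#'
#' @param V_field potential as a `discrete_field`.
#' @param geom a [slab_geometry()] carrying the control points.
#' @param exact exact potential difference, mV (defaults to
#'   [analytic_membrane_potential()] with the default species).
#' @return absolute error in mV.
#' @export
membrane_potential_error <- function(V_field, geom,
                                     exact = analytic_membrane_potential(geom)) {
  va <- evaluate_field(V_field, geom$x_a)
  vb <- evaluate_field(V_field, geom$x_b)
  abs(exact - (va - vb))
}

#' Capacitance of a cylindrical membrane shell
#'
#' \eqn{Cap = 2\pi\varepsilon_0\varepsilon_{mem} L / \log((D+d)/d)} for an
#' axon of radius `d`, membrane width `D` and length `L`; the per-area value
#' divides by the inner lateral surface \eqn{2\pi d L}.
#'
#' @param d axon radius, um.
#' @param D membrane width, um.
#' @param L length, um.
#' @param eps_mem relative membrane permittivity.
#' @param constants list from [physical_constants()].
#' @return list with `cap_F` (farads) and `per_area_uF_cm2`.
#' @export
#' @examples
#' shell_capacitance(0.434, 0.02, 4)$per_area_uF_cm2   # ~1.8 at the node
shell_capacitance <- function(d, D, L, eps_mem = 40,
                              constants = physical_constants()) {
  stopifnot(d > 0, D > 0, L > 0)
  cap <- 2 * pi * constants$eps0 * eps_mem * (L * 1e-6) / log((D + d) / d)
  per_area_F_m2 <- cap / (2 * pi * (d * 1e-6) * (L * 1e-6))
  list(cap_F = cap, per_area_uF_cm2 = 100 * per_area_F_m2)
}

#' Linearized Poisson-Boltzmann decay profile
#'
#' One-dimensional solution of the linearized Poisson-Boltzmann equation in
#' the electrolyte: exponential relaxation of the potential from its surface
#' value over the Debye length.
#'
#' @param x distance from the membrane surface (same unit as `lambda`).
#' @param V_surface surface potential (relative to the bulk), mV.
#' @param lambda Debye length (same unit as `x`).
#' @return potential at `x`, mV.
#' @export
linearized_pb_profile <- function(x, V_surface, lambda) {
  V_surface * exp(-x / lambda)
}
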