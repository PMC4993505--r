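# Structured-text (YAML) configuration for the command-line interface and
# batch runs.  Every key is optional; defaults mirror the package defaults.

#' Read a run configuration
#'
#' Reads a YAML file with (all optional) blocks:
#' \preformatted{
#' geometry:
#'   slab:    {L, d_intra, d_mem, d_out}
#'   ranvier: {d, D_n, D_m, L, L_node, d_out}
#' mesh:      {target_h, grading: {h0, r, h_max}}
#' time:      {dt0, dt_min, dt_max, duration}
#' newton:    {tol, max_iter}
#' controller:{n_min, n_max, f_min, f_max}
#' channels:  {gbar_kv, gbar_nav, g_kl, g_nal, stim_amplitude, stim_duration}
#' adapt:     {e_omega, max_outer, sweeps, stop_node_change, stop_error_band}
#' }
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return nested list of resolved settings (class `pnp_config`).
#' @export
read_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  g <- function(...) {
    out <- user
    for (k in c(...)) {
      if (is.null(out)) return(NULL)
      out <- out[[k]]
    }
    out
  }
  merge_args <- function(fun, args) {
    args <- args[!vapply(args, is.null, TRUE)]
    # YAML 1.1 leaves exponent-style scalars like 2e-4 as strings
    args <- lapply(args, function(a) {
      if (is.character(a) && length(a) == 1L &&
            !is.na(suppressWarnings(as.numeric(a)))) as.numeric(a) else a
    })
    do.call(fun, args)
  }
  slab <- merge_args(slab_geometry, list(
    L = g("geometry", "slab", "L"),
    d_intra = g("geometry", "slab", "d_intra"),
    d_mem = g("geometry", "slab", "d_mem"),
    d_out = g("geometry", "slab", "d_out")))
  ranvier <- merge_args(ranvier_geometry, list(
    d = g("geometry", "ranvier", "d"), D_n = g("geometry", "ranvier", "D_n"),
    D_m = g("geometry", "ranvier", "D_m"), L = g("geometry", "ranvier", "L"),
    L_node = g("geometry", "ranvier", "L_node"),
    d_out = g("geometry", "ranvier", "d_out")))
  grading <- if (!is.null(g("mesh", "grading")))
    merge_args(grading_spec, list(h0 = g("mesh", "grading", "h0"),
                                  r = g("mesh", "grading", "r"),
                                  h_max = g("mesh", "grading", "h_max")))
  else NULL
  controller <- merge_args(time_controller, list(
    n_min = g("controller", "n_min"), n_max = g("controller", "n_max"),
    f_min = g("controller", "f_min"), f_max = g("controller", "f_max"),
    dt0 = g("time", "dt0"), dt_min = g("time", "dt_min"),
    dt_max = g("time", "dt_max")))
  channels <- merge_args(channel_set, list(
    gbar_kv = g("channels", "gbar_kv"), gbar_nav = g("channels", "gbar_nav"),
    g_kl = g("channels", "g_kl"), g_nal = g("channels", "g_nal"),
    stim_amplitude = g("channels", "stim_amplitude"),
    stim_duration = g("channels", "stim_duration")))
  adapt <- if (!is.null(g("adapt", "e_omega")))
    merge_args(adapt_config, list(
      e_omega = g("adapt", "e_omega"), max_outer = g("adapt", "max_outer"),
      sweeps = g("adapt", "sweeps"),
      node_tol = g("adapt", "stop_node_change"),
      err_band = g("adapt", "stop_error_band")))
  else NULL
  structure(list(
    slab = slab, ranvier = ranvier,
    target_h = g("mesh", "target_h") %||% 0.25,
    grading = grading,
    duration = g("time", "duration") %||% 10,
    newton = merge_args(newton_settings,
                        list(tol = g("newton", "tol"),
                             max_iter = g("newton", "max_iter"))),
    controller = controller, channels = channels, adapt = adapt),
    class = "pnp_config")
}

#' Print the analytic quantities of a configuration
#'
#' Debye lengths, Nernst potentials, the slab Gauss's-law membrane
#' potential, leak-balanced resting potential and the shell capacitances of
#' the nodal and myelinated membrane.
#'
#' @param config a `pnp_config` from [read_config()].
#' @param species,constants model parameters.
#' @return invisibly, a named list of the printed values.
#' @export
print_analytics <- function(config = read_config(),
                            species = default_species(),
                            constants = physical_constants()) {
  rg <- config$ranvier
  vals <- list(
    debye_intra_nm = debye_length(species, constants, "intra"),
    debye_extra_nm = debye_length(species, constants, "extra"),
    E_K_mV = nernst_potential(species$c0_in[1], species$c0_out[1], 1,
                              constants),
    E_Na_mV = nernst_potential(species$c0_in[2], species$c0_out[2], 1,
                               constants),
    V_rest_mV = resting_potential(config$channels %||% channel_set()),
    V_mem_slab_mV = analytic_membrane_potential(config$slab, species,
                                                constants),
    cap_node_uF_cm2 = shell_capacitance(rg$d, rg$D_n, rg$L,
                                        constants$eps_membrane,
                                        constants)$per_area_uF_cm2,
    cap_myelin_uF_cm2 = shell_capacitance(rg$d, rg$D_m, rg$L,
                                          constants$eps_membrane,
                                          constants)$per_area_uF_cm2)
  for (nm in names(vals))
    cat(sprintf("%-20s %12.6g\n", nm, vals[[nm]]))
  invisible(vals)
}
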