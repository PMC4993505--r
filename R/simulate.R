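# Transient PNP simulation with Hodgkin-Huxley membrane currents on the
# nodal boundary: Algorithm-style loop of (gating ODE step, flux assembly,
# implicit PNP step, time-step adaptation).

#' Probe points for a node-of-Ranvier mesh
#'
#' Membrane-potential probes on either face of the nodal membrane at the
#' node centre, and a concentration probe just inside the axon.
#'
#' @param geom a [ranvier_geometry()].
#' @return list of (x, y) points: `v_in`, `v_out`, `c_in`, `c_out`.
#' @export
ranvier_probes <- function(geom) {
  xc <- geom$L / 2
  list(v_in = c(xc, geom$d), v_out = c(xc, geom$d + geom$D_n),
       c_in = c(xc, 0.9 * geom$d), c_out = c(xc, geom$d + geom$D_n))
}

# membrane potential from the probe pair (intra side minus extra side)
probe_vm <- function(problem, V, probes) {
  Vf <- discrete_field(problem$Vh, V)
  evaluate_field(Vf, probes$v_in, region = "intra") -
    evaluate_field(Vf, probes$v_out, region = "extra")
}

#' Run a transient PNP simulation
#'
#' BDF2 time marching (backward-Euler startup) with the coupled Newton
#' solve per step and the iteration-count step controller.  When `channels`
#' is supplied and the mesh carries `inn` boundary tags, Hodgkin-Huxley
#' currents (plus the initial Na+ stimulus) are converted to molar fluxes on
#' the nodal faces each step: the gating ODEs are advanced first with the
#' exact exponential update at the current membrane potential, then the PNP
#' step is taken with those fluxes (one lumped m, h, n triple for the node).
#'
#' @param problem a [pnp_problem()].
#' @param duration simulated time, ms.
#' @param channels a [channel_set()], or `NULL` for a flux-free relaxation.
#' @param probes probe points (see [ranvier_probes()]); required with
#'   `channels`.
#' @param controller a [time_controller()].
#' @param newton [newton_settings()].
#' @param v_rest_anchor anchor potential for the gating rates; defaults to
#'   the initial membrane potential of the run.
#' @param dt_max_fn optional `function(t)` returning an extra step cap at
#'   time `t` (ms); used to keep the stimulus/upstroke window resolved when
#'   the lumped gating update would otherwise lag the potential.
#' @param record_every record a trace row every this many steps.
#' @param snapshot_times optional times (ms) at which VTU snapshots are
#'   written (requires `snapshot_dir`).
#' @param snapshot_dir directory for VTU snapshots.
#' @param verbose print progress every 50 steps.
#' @return list with `trace` (data.frame: t_ms, dt_ms, n_iter, V_m_mV,
#'   c_K_mM, c_Na_mM, c_A_mM, m, h, n), `state` (final `pnp_state`),
#'   `gating` (final state), `problem`.
#' @export
run_simulation <- function(problem, duration, channels = NULL, probes = NULL,
                           controller = time_controller(),
                           newton = newton_settings(),
                           v_rest_anchor = NULL, dt_max_fn = NULL,
                           record_every = 1L, snapshot_times = NULL,
                           snapshot_dir = NULL, verbose = FALSE) {
  state <- pnp_initial_state(problem)
  ns <- problem$ns
  sp_names <- problem$species$name
  has_inn <- any(problem$mesh$btag %in% c(TAG_INN_INTRA, TAG_INN_EXTRA))
  use_channels <- !is.null(channels) && has_inn
  if (!is.null(channels) && !has_inn)
    stop("channel model requires a mesh with 'inn' boundary tags",
         call. = FALSE)
  if (use_channels && is.null(probes))
    stop("probes are required for a channel simulation", call. = FALSE)
  # unit boundary loads: load for f = 1 on each nodal face, scaled per step
  if (use_channels) {
    load_in <- assemble_boundary_load(problem$Ch, "inn_intra", 1)
    load_out <- assemble_boundary_load(problem$Ch, "inn_extra", 1)
    vm0 <- probe_vm(problem, state$V, probes)
    if (is.null(v_rest_anchor)) v_rest_anchor <- vm0
    # gates start in their resting configuration; the instantaneous initial
    # potential of a not-yet-equilibrated state must not pre-inactivate them
    gate <- gating_state(v_rest_anchor, v_rest = v_rest_anchor)
  } else gate <- NULL
  dt <- controller$dt0
  trace <- list()
  snap_left <- sort(snapshot_times)
  step <- 0L
  rec <- function(vm, cin) {
    data.frame(t_ms = state$t, dt_ms = attr(state, "dt_used") %||% dt,
               n_iter = attr(state, "n_iter") %||% NA_integer_,
               V_m_mV = vm,
               c_K_mM = cin[1], c_Na_mM = cin[2], c_A_mM = cin[3],
               m = if (is.null(gate)) NA_real_ else gate$m,
               h = if (is.null(gate)) NA_real_ else gate$h,
               n = if (is.null(gate)) NA_real_ else gate$n)
  }
  conc_at <- function(cs, pt, region) {
    vapply(seq_len(ns), function(k)
      evaluate_field(discrete_field(problem$Ch, cs[[k]]), pt,
                     region = region), 0)
  }
  vm <- if (use_channels) probe_vm(problem, state$V, probes) else NA_real_
  cin <- if (!is.null(probes)) conc_at(state$c, probes$c_in, "intra")
  else rep(NA_real_, ns)
  trace[[1]] <- rec(vm, cin)
  while (state$t < duration - 1e-12) {
    dt_step <- min(dt, duration - state$t)
    if (!is.null(dt_max_fn)) dt_step <- min(dt_step, dt_max_fn(state$t))
    loads <- NULL
    if (use_channels) {
      vm <- probe_vm(problem, state$V, probes)
      gate <- advance_gating(gate, vm, dt_step)
      cin <- conc_at(state$c, probes$c_in, "intra")
      cout <- conc_at(state$c, probes$c_out, "extra")
      E_K <- nernst_potential(cin[1], cout[1], 1, problem$constants)
      E_Na <- nernst_potential(cin[2], cout[2], 1, problem$constants)
      fl <- transmembrane_flux(vm, gate, E_K, E_Na, channels,
                               problem$constants)
      f_stim <- stimulus_flux(state$t, channels, problem$constants)
      fK <- fl$flux[["K"]]
      fNa <- fl$flux[["Na"]] - f_stim     # stimulus = extra Na+ influx
      loads <- vector("list", ns)
      names(loads) <- sp_names
      loads[[which(sp_names == "K")]] <- fK * load_in - fK * load_out
      loads[[which(sp_names == "Na")]] <- fNa * load_in - fNa * load_out
    }
    state <- advance_time_step(problem, state, dt_step, loads = loads,
                               settings = newton)
    step <- step + 1L
    dt <- adapt_dt(attr(state, "n_iter"), attr(state, "dt_used"), controller)
    if (step %% record_every == 0L || state$t >= duration - 1e-12) {
      vm <- if (use_channels) probe_vm(problem, state$V, probes) else NA_real_
      cin <- if (!is.null(probes)) conc_at(state$c, probes$c_in, "intra")
      else rep(NA_real_, ns)
      trace[[length(trace) + 1L]] <- rec(vm, cin)
    }
    if (length(snap_left) && state$t >= snap_left[1] - 1e-12) {
      if (!is.null(snapshot_dir)) {
        fn <- file.path(snapshot_dir,
                        sprintf("snapshot_t%07.3fms.vtu", state$t))
        write_mesh_vtu(problem$mesh, fn,
                       fields = list(V = discrete_field(problem$Vh, state$V)))
      }
      snap_left <- snap_left[-1]
    }
    if (verbose && step %% 10L == 0L)
      message(sprintf("t = %.4f ms (dt %.2e, %d Newton its, V_m %.2f mV)",
                      state$t, attr(state, "dt_used"),
                      attr(state, "n_iter"), vm))
  }
  list(trace = do.call(rbind, trace), state = state, gating = gate,
       problem = problem)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
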