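# End-to-end studies: the mesh-strategy convergence comparison on the slab
# benchmark, node-distance histograms, and the 2D node-of-Ranvier
# action-potential demonstration.

#' Membrane-potential error versus mesh size for one meshing strategy
#'
#' For each mesh in a series, solves the stationary no-flux slab problem and
#' records the control-point membrane-potential error against the Gauss's-law
#' value, together with vertex, element and P2-dof counts.
#'
#' Series specifications:
#' * `uniform`: a decreasing vector `target_h` of element sizes;
#' * `tailored`: vectors `h0` (first-layer sizes) and `nx` (horizontal
#'   intervals), jointly refined, with fixed growth ratio `r` and cap
#'   `h_max`;
#' * `adapted`: a decreasing vector `e_omega` of estimator targets; each
#'   point continues the adaptation from the previous point's mesh.
#'
#' @param strategy `"uniform"`, `"tailored"` or `"adapted"`.
#' @param geom a [slab_geometry()].
#' @param target_h,h0,nx,r,h_max,e_omega series parameters (see above).
#' @param adapt_opts list of overrides for [adapt_config()] fields.
#' @param species,constants model parameters.
#' @param verbose print per-point progress.
#' @return data.frame of class `convergence_record` with columns `strategy`,
#'   `nodes` (vertices), `elements`, `p2_nodes`, `error_mV` and, for the
#'   adapted strategy, `e_omega`, `outer_iterations`, `stabilized`.
#' @export
run_convergence_study <- function(strategy = c("uniform", "tailored",
                                               "adapted"),
                                  geom = slab_geometry(),
                                  target_h = c(0.2, 0.12, 0.08, 0.05, 0.03),
                                  h0 = 2e-3 / 4^(0:4),
                                  nx = pmax(8L, as.integer(8 * 1.5^(0:4))),
                                  r = 2, h_max = 0.1,
                                  e_omega = 10^seq(-2, -4, length.out = 5),
                                  adapt_opts = list(),
                                  species = default_species(),
                                  constants = physical_constants(),
                                  verbose = FALSE) {
  strategy <- match.arg(strategy)
  exact <- analytic_membrane_potential(geom, species, constants)
  rows <- list()
  measure <- function(mesh, sol, extra = NULL) {
    err <- membrane_potential_error(sol$V, geom, exact)
    st <- mesh_edges(mesh)
    c(list(strategy = strategy, nodes = nrow(mesh$nodes),
           elements = nrow(mesh$tri),
           p2_nodes = nrow(mesh$nodes) + nrow(st$edges),
           error_mV = err), extra)
  }
  cb <- stationary_solve_callback(species, constants)
  if (strategy == "uniform") {
    for (h in target_h) {
      mesh <- build_slab_mesh(geom, h)
      sol <- cb(mesh, NULL)
      rows[[length(rows) + 1L]] <- measure(mesh, sol)
      if (verbose) message(sprintf("uniform h=%g: %d elements, err %.3e mV",
                                   h, nrow(mesh$tri),
                                   rows[[length(rows)]]$error_mV))
    }
  } else if (strategy == "tailored") {
    stopifnot(length(h0) == length(nx))
    for (i in seq_along(h0)) {
      mesh <- build_tailored_mesh(geom, grading_spec(h0[i], r, h_max),
                                  nx = nx[i])
      sol <- cb(mesh, NULL)
      rows[[length(rows) + 1L]] <- measure(mesh, sol)
      if (verbose) message(sprintf(
        "tailored h0=%g nx=%d: %d elements, err %.3e mV",
        h0[i], nx[i], nrow(mesh$tri), rows[[length(rows)]]$error_mV))
    }
  } else {
    # initial mesh for the adaptive loop: mildly graded towards the
    # membranes so that the Debye-layer structure is visible to the first
    # error estimate (the hierarchical estimator, like any a-posteriori
    # estimator, cannot see features the discrete solution hides entirely)
    mesh <- build_tailored_mesh(geom, grading_spec(2.5e-4, 2.2, 0.2), nx = 8)
    prev <- NULL
    # looser Newton tolerance while iterating; the measured solve is tight
    cb_loop <- stationary_solve_callback(species, constants, tol = 1e-9)
    for (i in seq_along(e_omega)) {
      cfg_args <- utils::modifyList(list(e_omega = e_omega[i]), adapt_opts)
      cfg <- do.call(adapt_config, cfg_args)
      wrapped <- function(m, p) cb_loop(m, if (is.null(p)) prev else p)
      res <- adapt_mesh(mesh, wrapped, cfg, verbose = verbose)
      mesh <- res$mesh
      res$solution <- cb(mesh, res$solution)   # precise final solve
      prev <- res$solution
      rows[[length(rows) + 1L]] <- measure(mesh, res$solution,
                                           list(e_omega = e_omega[i],
                                                outer_iterations =
                                                  res$iterations,
                                                stabilized = res$stabilized))
      attr(rows[[length(rows)]], "mesh") <- mesh
      if (verbose) message(sprintf(
        "adapted e_omega=%.2e: %d nodes, %d elements, err %.3e mV (%d outer)",
        e_omega[i], nrow(mesh$nodes), nrow(mesh$tri),
        rows[[length(rows)]]$error_mV, res$iterations))
    }
  }
  meshes <- lapply(rows, attr, "mesh")
  rec <- do.call(rbind, lapply(rows, function(r) as.data.frame(r[
    setdiff(names(r), "mesh")])))
  class(rec) <- c("convergence_record", class(rec))
  attr(rec, "meshes") <- meshes
  rec
}

#' Fitted order of convergence from a series
#'
#' Least-squares slope of log10(error) against log10(nodes), returned as a
#' positive order.
#'
#' @param record a `convergence_record` (or any data.frame with `nodes` and
#'   `error_mV`).
#' @param use column to use as the size measure (default `"nodes"`).
#' @return positive slope (convergence order).
#' @export
#' @examples
#' r <- data.frame(nodes = c(100, 200, 400), error_mV = c(4, 2, 1))
#' fit_convergence_order(r)   # exactly 1
fit_convergence_order <- function(record, use = "nodes") {
  ok <- record$error_mV > 0 & is.finite(record$error_mV)
  if (sum(ok) < 3) stop("need at least 3 series points", call. = FALSE)
  fit <- stats::lm(log10(record$error_mV[ok]) ~ log10(record[[use]][ok]))
  -unname(stats::coef(fit)[2])
}

#' Histogram of node distances from the membrane
#'
#' Fraction of a region's mesh vertices per distance bin from the nearest
#' membrane interface.
#'
#' @param mesh a `pnp_mesh`.
#' @param region region name (default `"intra"`).
#' @param bin_nm bin width in nm.
#' @param max_nm upper edge of the last finite bin; the remainder goes into
#'   an overflow bin.
#' @return data.frame with `lower_nm`, `upper_nm`, `fraction` (sums to 1).
#' @export
node_distance_histogram <- function(mesh, region = "intra", bin_nm = 0.25,
                                    max_nm = 20) {
  d <- node_membrane_distance(mesh, region)$dist * 1000   # um -> nm
  breaks <- c(seq(0, max_nm, by = bin_nm), Inf)
  cnt <- table(cut(d, breaks, include.lowest = TRUE, right = TRUE))
  data.frame(lower_nm = head(breaks, -1), upper_nm = breaks[-1],
             fraction = as.numeric(cnt) / length(d))
}

#' Fraction of region vertices within a distance of the membrane
#' @param mesh a `pnp_mesh`.
#' @param within_nm distance threshold in nm.
#' @param region region name.
#' @return fraction in [0, 1].
#' @export
node_fraction_within <- function(mesh, within_nm = 1, region = "intra") {
  d <- node_membrane_distance(mesh, region)$dist * 1000
  mean(d <= within_nm)
}

#' Node-of-Ranvier action-potential demonstration
#'
#' Builds the 2D nodal section with grading towards the membrane faces,
#' then runs the transient PNP system with Hodgkin-Huxley channels for
#' `duration` ms including the initial Na+ stimulus, and returns the probe
#' trace plus a cross-membrane potential profile at the myelin step taken
#' at the peak of the action potential.
#'
#' @param geom a [ranvier_geometry()].
#' @param channels a [channel_set()].
#' @param duration simulated time, ms.
#' @param target_h horizontal element size, um.
#' @param grading [grading_spec()] for the vertical direction.
#' @param controller,newton solver settings.
#' @param snapshot_dir optional directory for VTU snapshots.
#' @param verbose progress output.
#' @return list with `trace`, `profile` (data.frame y/V across the membrane
#'   at the myelin junction at the recorded peak), `result` (full
#'   [run_simulation()] value) and `geom`.
#' @export
run_ranvier_demo <- function(geom = ranvier_geometry(),
                             channels = channel_set(),
                             duration = 10,
                             target_h = 0.45,
                             grading = grading_spec(5e-3, 2.5, 0.2),
                             controller = time_controller(f_min = 0.4,
                                                          dt0 = 2e-3,
                                                          dt_max = 0.1),
                             newton = newton_settings(tol = 3e-6),
                             species = section_species(geom, channels),
                             snapshot_dir = NULL, verbose = FALSE) {
  mesh <- build_ranvier_mesh(geom, target_h, grading = grading)
  probes <- ranvier_probes(geom)
  vrest <- resting_potential(channels)
  # mesh-consistent charge equivalence: on a mesh that resolves the Debye
  # layer only partially, a given cytosolic charge produces a larger
  # discrete membrane potential than in the continuum; a short channel-free
  # relaxation measures the discrete equilibrium and the anion excess is
  # rescaled so that the model rests at the leak-balanced potential
  pb0 <- pnp_problem(mesh, species = species)
  st <- pnp_initial_state(pb0)
  dtr <- 2e-3
  for (i in 1:25) {
    st$c_prev <- NULL
    st <- advance_time_step(pb0, st, dtr,
                            settings = newton_settings(tol = 1e-7,
                                                       max_iter = 8))
    dtr <- min(dtr * 1.6, 0.5)
  }
  vm_eq <- probe_vm(pb0, st$V, probes)
  cations <- sum(species$c0_in[species$z > 0])
  nnet0 <- cations - species$c0_in[species$name == "A"]
  species$c0_in[species$name == "A"] <-
    cations - nnet0 * (vrest / vm_eq)
  if (verbose)
    message(sprintf("charge calibration: discrete rest %.1f mV -> scale %.3f",
                    vm_eq, vrest / vm_eq))
  problem <- pnp_problem(mesh, species = species)
  res <- run_simulation(problem, duration = duration, channels = channels,
                        probes = probes, controller = controller,
                        newton = newton,
                        v_rest_anchor = vrest,
                        # resolve the stimulus and spike window; the lumped
                        # gating is advanced at frozen V over each step
                        dt_max_fn = function(t) if (t < 1.2) 0.01 else Inf,
                        snapshot_times = if (!is.null(snapshot_dir))
                          seq(0.5, duration, by = 0.5),
                        snapshot_dir = snapshot_dir, verbose = verbose)
  profile <- membrane_cross_profile(problem, res$state$V, geom)
  list(trace = res$trace, profile = profile, result = res, geom = geom)
}

#' Species set with the section-equivalent net charge
#'
#' The default ionic composition carries the net cytosolic charge of the
#' three-dimensional cylindrical model.  In the plane section the membrane
#' "capacitance" per unit depth differs, so the same charge would produce an
#' unphysiological resting potential; this helper rescales the anion excess
#' so that the section's equilibrium membrane potential equals the
#' leak-balanced rest of the channel set -- the same kind of
#' geometry-equivalence correction as matching the membrane permittivity to
#' a target capacitance.
#'
#' @param geom a [ranvier_geometry()].
#' @param channels a [channel_set()] (sets the target rest).
#' @param species base species table.
#' @param constants physical constants.
#' @return adjusted species data.frame.
#' @export
section_species <- function(geom, channels = channel_set(),
                            species = default_species(),
                            constants = physical_constants()) {
  ehat <- eps_scaled(constants$eps_membrane, constants)
  # series "conductance" of the membrane per unit depth: both cuts, nodal
  # and myelinated spans in parallel
  G <- 2 * (geom$L_node / geom$D_n + (geom$L - geom$L_node) / geom$D_m) * ehat
  vrest <- resting_potential(channels)
  nnet <- vrest * G / (2 * geom$d * geom$L)
  species$c0_in[species$name == "A"] <-
    sum(species$c0_in[species$z > 0]) - nnet
  species
}

#' Potential profile across the membrane at the myelin step
#'
#' Samples the potential along a vertical line just on the myelinated side
#' of the node-myelin junction, through the full membrane thickness.  Near
#' the step the field inside the membrane is genuinely two-dimensional, so
#' the profile deviates from the affine shape a uniform-width membrane
#' would give; the returned data.frame carries the sampled values and the
#' residual of their best affine fit.
#'
#' @param problem a [pnp_problem()] on a Ranvier mesh.
#' @param V potential coefficient vector.
#' @param geom the [ranvier_geometry()].
#' @param n_sample number of sample points across the membrane.
#' @param dx_off horizontal offset into the myelinated side, um.
#' @return data.frame with `y_um`, `V_mV`, `affine_fit`, `residual_mV`.
#' @export
membrane_cross_profile <- function(problem, V, geom, n_sample = 21,
                                   dx_off = 0.05) {
  Vf <- discrete_field(problem$Vh, V)
  x <- (geom$L - geom$L_node) / 2 - dx_off
  ys <- seq(geom$d, geom$d + geom$D_m, length.out = n_sample)
  vv <- vapply(ys, function(y)
    evaluate_field(Vf, c(x, y), region = "membrane"), 0)
  fit <- stats::lm(vv ~ ys)
  data.frame(y_um = ys, V_mV = vv, affine_fit = stats::fitted(fit),
             residual_mV = stats::residuals(fit))
}
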