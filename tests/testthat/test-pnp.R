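test_that("BDF2 coefficients match the two-step formula", {
  co <- bdf2_coefficients(0.1)
  expect_equal(unlist(co), c(alpha = 5, beta = -20, gamma = 15))
  be <- bdf2_coefficients(0.1, order = 1)
  expect_equal(unlist(be), c(alpha = 0, beta = -10, gamma = 10))
  expect_error(bdf2_coefficients(0), "dt")
  # constant preservation: gamma*y + beta*y + alpha*y = 0 for dy/dt = 0
  expect_equal(co$gamma + co$beta + co$alpha, 0)
})

test_that("scalar BDF2 is second order against the exponential", {
  # y' = -y, exact history; the local error of one step is O(dt^3)
  step_bdf2 <- function(dt, t) {
    co <- bdf2_coefficients(dt)
    # (gamma + 1) y_{r+1} = -(beta y_r + alpha y_{r-1})
    y1 <- exp(-(t - dt)); y2 <- exp(-t)
    -(co$beta * y2 + co$alpha * y1) / (co$gamma + 1)
  }
  errs <- vapply(c(0.1, 0.05, 0.025), function(dt)
    abs(step_bdf2(dt, 1) - exp(-(1 + dt))), 0)
  order_loc <- log2(errs[1] / errs[2])
  expect_equal(order_loc, 3, tolerance = 0.2)   # local order 3 = global 2
})

test_that("the time-step controller follows the three-branch rule", {
  ctl <- time_controller(n_min = 3, n_max = 6, f_min = 0.2, f_max = 0.2,
                         dt_min = 1e-6, dt_max = 0.05)
  expect_equal(adapt_dt(2, 0.01, ctl), 0.012)
  expect_equal(adapt_dt(4, 0.01, ctl), 0.01)
  expect_equal(adapt_dt(7, 0.01, ctl), 0.008)
  expect_equal(adapt_dt(2, 0.049, ctl), 0.05)      # clamped above
  expect_equal(adapt_dt(9, 1.1e-6, ctl), 1e-6)     # clamped below
  expect_error(adapt_dt(3, 0, ctl), "dt_prev")
})

test_that("Newton solves a decoupled linear problem in one iteration", {
  g <- slab_geometry()
  m <- build_slab_mesh(g, 0.3)
  pb <- pnp_problem(m)
  # force the drift mobility to zero: the stationary system is linear
  for (k in 1:3) pb$dtilde[[k]] <- c(intra = 0, extra = 0)
  sol <- solve_stationary(pb, tol = 1e-10)
  expect_true(sol$converged)
  expect_lte(sol$iterations, 2)   # one correction + the convergence check
  # with no drift the concentrations stay uniform per region
  expect_equal(max(abs(sol$c[[1]] - pb$c0[[1]])), 0, tolerance = 1e-8)
})

test_that("electroneutral composition is an equilibrium fixed point", {
  g <- slab_geometry()
  m <- build_slab_mesh(g, 0.3)
  sp <- default_species()
  sp$c0_in[3] <- 167        # zero net charge everywhere
  sp$c0_out[3] <- 149
  pb <- pnp_problem(m, species = sp)
  st <- pnp_initial_state(pb)
  expect_lt(max(abs(st$V)), 1e-8)
  st2 <- advance_time_step(pb, st, 1e-3)
  expect_lt(max(abs(st2$V)), 1e-8)
  for (k in 1:3)
    expect_lt(max(abs(st2$c[[k]] - pb$c0[[k]])), 1e-9 * max(pb$c0[[k]]))
})

test_that("species are conserved on a closed domain", {
  g <- slab_geometry()
  m <- build_slab_mesh(g, 0.3)
  pb <- pnp_problem(m, closed = TRUE)
  st <- pnp_initial_state(pb)
  tot0 <- species_totals(pb, st$c)
  t_end <- 0
  dt <- 5e-3
  for (i in 1:10) {
    st <- advance_time_step(pb, st, dt)
    t_end <- st$t
  }
  expect_gt(t_end, 0.049)
  tot1 <- species_totals(pb, st$c)
  expect_lt(max(abs(tot1 - tot0) / tot0), 1e-8)
})

test_that("one coupled Newton correction matches a dense-solve oracle", {
  # tiny mesh so that the full block Jacobian fits densely
  g <- slab_geometry()
  m <- build_slab_mesh(g, 0.6)
  pb <- pnp_problem(m)
  cs <- pb$c0
  Vs <- solve_poisson(pb, cs)
  cp <- coupling_all(pb, cs, Vs)
  intra_dofs <- which(pb$dof_region == REGION_INTRA)
  crow <- intra_dofs[which.max(pb$w_intra[intra_dofs])]
  res <- stationary_residual(pb, cp, cs, Vs, vector("list", 3),
                             rep(crow, 3))
  sol <- solve_block_system(pb, cp, res$rc, res$rv, gamma = 0,
                            constrain = rep(crow, 3), cs = cs,
                            lintol = 1e-13)
  # dense oracle: assemble the full Jacobian explicitly and solve with base R
  fc <- pb$free_c; fv <- pb$free_v
  nc <- length(fc); nv <- length(fv)
  Jd <- matrix(0, 3 * nc + nv, 3 * nc + nv)
  R <- numeric(3 * nc + nv)
  for (k in 1:3) {
    A <- as.matrix((pb$Dk[[k]] + cp[[k]]$Dcc)[fc, fc])
    B <- as.matrix(cp[[k]]$Dcv[fc, fv])
    row <- match(crow, fc)
    A[row, ] <- pb$w_intra[fc]
    B[row, ] <- 0
    idx <- (k - 1) * nc + seq_len(nc)
    Jd[idx, idx] <- A
    Jd[idx, 3 * nc + seq_len(nv)] <- B
    Jd[3 * nc + seq_len(nv), idx] <- as.matrix(pb$Sk[[k]][fv, fc])
    R[idx] <- res$rc[[k]][fc]
  }
  Jd[3 * nc + seq_len(nv), 3 * nc + seq_len(nv)] <- as.matrix(pb$Dv[fv, fv])
  R[3 * nc + seq_len(nv)] <- res$rv[fv]
  delta <- solve(Jd, -R)
  for (k in 1:3)
    expect_equal(sol$dc[[k]], delta[(k - 1) * nc + seq_len(nc)],
                 tolerance = 1e-5)
  expect_equal(sol$dv, delta[3 * nc + seq_len(nv)], tolerance = 1e-5)
})

test_that("starting from the converged state the first correction is tiny", {
  g <- slab_geometry()
  m <- build_tailored_mesh(g, grading_spec(5e-3, 2, 0.1), nx = 6)
  pb <- pnp_problem(m)
  sol <- solve_stationary(pb, tol = 1e-12)
  expect_true(sol$converged)
  again <- solve_stationary(pb, tol = 1e-8,
                            init = list(c = sol$c, V = sol$V))
  expect_lte(again$iterations, 1)
})

test_that("halving dt reduces the probe's time-discretization error ~4x", {
  # closed slab relaxing from a perturbed anion distribution; probe = total
  # potential at a fixed point after T; BDF2 should be second order in dt
  g <- slab_geometry()
  m <- build_tailored_mesh(g, grading_spec(5e-3, 2, 0.2), nx = 4)
  pb <- pnp_problem(m)
  run_fixed <- function(dt, T = 0.02) {
    st <- pnp_initial_state(pb)
    n <- round(T / dt)
    for (i in seq_len(n))
      st <- advance_time_step(pb, st, dt,
                              settings = newton_settings(tol = 1e-12))
    evaluate_field(discrete_field(pb$Vh, st$V), c(2, 0.3), "intra")
  }
  ref <- run_fixed(0.02 / 64)
  e1 <- abs(run_fixed(0.02 / 4) - ref)
  e2 <- abs(run_fixed(0.02 / 8) - ref)
  expect_gt(e1 / e2, 2.5)
  expect_lt(e1 / e2, 6.5)
})
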