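test_that("Debye length: value, scaling and diffusion independence", {
  sp1 <- data.frame(name = c("X", "Y"), z = c(1, -1), D = c(1, 1),
                    c0_in = c(100, 100), c0_out = c(100, 100))
  # direct formula oracle with Table-style constants
  cn <- physical_constants()
  lam_SI <- sqrt(cn$eps0 * cn$eps_water * cn$R_gas * cn$temperature /
                   (cn$faraday^2 * 200)) * 1e9
  expect_equal(debye_length(sp1, side = "intra"), lam_SI, tolerance = 1e-10)
  expect_equal(lam_SI, 0.94, tolerance = 1e-2)
  sp2 <- sp1; sp2$c0_in <- 2 * sp2$c0_in
  expect_equal(debye_length(sp2) * sqrt(2), debye_length(sp1),
               tolerance = 1e-12)
  sp3 <- sp1; sp3$D <- c(17, 0.01)
  expect_equal(debye_length(sp3), debye_length(sp1))
  expect_error(debye_length(data.frame(name = "N", z = 0, D = 1,
                                       c0_in = 1, c0_out = 1)), "positive")
})

test_that("slab membrane potential matches the 1D Gauss's-law oracle", {
  g <- slab_geometry()
  sp <- default_species()
  cn <- physical_constants()
  v_pkg <- analytic_membrane_potential(g, sp, cn)
  v_oracle <- slab_vmem_oracle_1d(g, sp, cn)
  expect_equal(v_pkg, v_oracle, tolerance = 1e-3)
  expect_equal(v_pkg, -235.64, tolerance = 1e-4)
  # electroneutral cytosol gives zero
  spn <- sp; spn$c0_in <- c(155, 12, 167)
  expect_equal(analytic_membrane_potential(g, spn, cn), 0)
  # linear in membrane width and net charge
  g2 <- slab_geometry(d_mem = 0.2,
                      x_b = c(2, slab_geometry()$y1 + 0.2))
  expect_equal(analytic_membrane_potential(g2, sp, cn), 2 * v_pkg,
               tolerance = 1e-12)
  sp2 <- sp; sp2$c0_in[3] <- 167.04
  expect_equal(analytic_membrane_potential(g, sp2, cn), 2 * v_pkg,
               tolerance = 1e-9)
})

test_that("control-point error metric is gauge invariant", {
  g <- slab_geometry()
  m <- build_slab_mesh(g, 0.2)
  Vh <- fe_space(m, "all")
  exact <- 3
  u <- interpolate_field(Vh, function(x, y) -3 * (abs(y) > 0.484))
  # synthetic field with a -3 mV jump outward across the membrane, so the
  # inside-minus-outside difference at the control points is +3 (u is of
  # course not the PDE solution; only the two point values matter here)
  e0 <- membrane_potential_error(u, g, exact = exact)
  expect_equal(e0, 0, tolerance = 1e-12)
  u2 <- discrete_field(Vh, u$coef + 17.3)
  expect_equal(membrane_potential_error(u2, g, exact = exact), e0,
               tolerance = 1e-12)
})

test_that("shell capacitance: nodal value, planar limit and L scaling", {
  sc <- shell_capacitance(0.434, 0.02, 4)
  expect_equal(sc$per_area_uF_cm2, 1.82, tolerance = 1e-2)
  cn <- physical_constants()
  # independent direct evaluation of the formula
  cap <- 2 * pi * cn$eps0 * 40 * 4e-6 / log((0.02 + 0.434) / 0.434)
  expect_equal(sc$cap_F, cap, tolerance = 1e-12)
  # planar limit: per-area -> eps0 epsmem / D as D -> 0
  tiny <- shell_capacitance(0.434, 1e-6, 4)
  planar <- 100 * cn$eps0 * 40 / 1e-12    # uF/cm2 with D in m
  expect_equal(tiny$per_area_uF_cm2, planar, tolerance = 1e-3)
  expect_equal(shell_capacitance(0.434, 0.02, 8)$cap_F, 2 * sc$cap_F,
               tolerance = 1e-12)
  # myelinated value for reference stays below the nodal one
  expect_lt(shell_capacitance(0.434, 0.406, 4)$per_area_uF_cm2,
            sc$per_area_uF_cm2)
})

test_that("linearized Poisson-Boltzmann profile decays exponentially", {
  expect_equal(linearized_pb_profile(0, -5, 0.73), -5)
  expect_equal(linearized_pb_profile(0.73, -5, 0.73), -5 / exp(1),
               tolerance = 1e-12)
})
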