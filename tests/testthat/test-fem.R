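make_spaces <- function(h = 0.2) {
  g <- slab_geometry()
  m <- build_slab_mesh(g, h)
  st <- mesh_edges(m)
  list(g = g, m = m,
       Vh = fe_space(m, "all", struct = st),
       Ch = fe_space(m, c("intra", "extra"), struct = st))
}

# smallest eigenvalue via a few inverse-power iterations (no extra deps)
smallest_rayleigh <- function(M) {
  set.seed(1)
  x <- rnorm(nrow(M))
  f <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
  for (i in 1:30) {
    x <- as.numeric(Matrix::solve(f, x, system = "A"))
    x <- x / sqrt(sum(x^2))
  }
  as.numeric(t(x) %*% (M %*% x))
}

test_that("mass matrix: partition of unity, symmetry, positive definiteness", {
  s <- make_spaces()
  M <- assemble_mass(s$Ch, "intra")
  expect_equal(sum(M), s$g$d_intra * s$g$L, tolerance = 1e-10)
  expect_lt(max(abs(M - Matrix::t(M))), 1e-12)
  Mfull <- assemble_mass(s$Ch)
  expect_gt(smallest_rayleigh(Mfull), 0)
  expect_error(assemble_mass(s$Ch, "membrane"), "empty region")
})

test_that("single-element P2 blocks match an independent dense quadrature", {
  # one-triangle mesh: use the reference-style triangle scaled/offset
  nodes <- rbind(c(0.2, 0.1), c(1.1, 0.3), c(0.4, 0.9))
  tri <- matrix(1:3, 1)
  m <- new_pnp_mesh(nodes, tri, REGION_INTRA,
                    bedges = rbind(c(1, 2), c(2, 3), c(3, 1)),
                    btag = rep(TAG_EXL, 3))
  sp <- fe_space(m, "all", dirichlet_tags = character(0))
  M <- as.matrix(assemble_mass(sp))
  K <- as.matrix(assemble_stiffness(sp, 1.7))
  # oracle: dense Duffy-transform integration of the same bilinear forms
  P <- nodes
  ord <- sp$T6[1, ]
  Mo <- matrix(0, 6, 6); Ko <- matrix(0, 6, 6)
  J <- rbind(P[2, ] - P[1, ], P[3, ] - P[1, ])
  Jinv <- solve(J)
  for (i in 1:6) for (j in 1:6) {
    Mo[i, j] <- triangle_integral(function(x, y) {
      # map back to reference coordinates
      u <- cbind(x - P[1, 1], y - P[1, 2]) %*% Jinv
      vapply(seq_along(x), function(s)
        oracle_p2(u[s, 1], u[s, 2])[i] * oracle_p2(u[s, 1], u[s, 2])[j], 0)
    }, P)
    dgrad <- function(xi, eta, k) {
      e <- 1e-6
      (oracle_p2(xi + e, eta)[k] - oracle_p2(xi - e, eta)[k]) / (2 * e) *
        Jinv[1, ] +
        (oracle_p2(xi, eta + e)[k] - oracle_p2(xi, eta - e)[k]) / (2 * e) *
        Jinv[2, ]
    }
    Ko[i, j] <- 1.7 * triangle_integral(function(x, y) {
      u <- cbind(x - P[1, 1], y - P[1, 2]) %*% Jinv
      vapply(seq_along(x), function(s)
        sum(dgrad(u[s, 1], u[s, 2], i) * dgrad(u[s, 1], u[s, 2], j)), 0)
    }, P)
  }
  expect_equal(M[ord, ord], Mo, tolerance = 1e-12)
  expect_equal(K[ord, ord], Ko, tolerance = 1e-6)  # fd-gradient oracle
})

test_that("stiffness: constants in the null space and linear-field energy", {
  s <- make_spaces()
  K <- assemble_stiffness(s$Vh, c(intra = 1, membrane = 1, extra = 1))
  expect_lt(max(abs(K %*% rep(1, s$Vh$ndof))), 1e-10)
  u <- interpolate_field(s$Vh, function(x, y) x)
  area <- sum(mesh_areas(s$m))
  expect_equal(as.numeric(t(u$coef) %*% K %*% u$coef), area,
               tolerance = 1e-10)
  expect_error(assemble_stiffness(s$Vh, -1), "non-negative")
})

test_that("discontinuous permittivity energy matches per-region analytics", {
  s <- make_spaces()
  K <- assemble_stiffness(s$Vh, c(intra = 80, membrane = 40, extra = 80))
  u <- interpolate_field(s$Vh, function(x, y) y)
  a <- region_areas(s$m)
  expect_equal(as.numeric(t(u$coef) %*% K %*% u$coef),
               80 * a[["intra"]] + 40 * a[["membrane"]] + 80 * a[["extra"]],
               tolerance = 1e-10)
})

test_that("coupling blocks vanish appropriately and match direct values", {
  s <- make_spaces()
  cp0 <- assemble_coupling(s$Ch, s$Vh, interpolate_field(s$Ch, 3),
                           interpolate_field(s$Vh, 7),
                           c(intra = 1, extra = 1))
  expect_equal(max(abs(cp0$Dcc)), 0, tolerance = 1e-12)
  cp1 <- assemble_coupling(s$Ch, s$Vh, interpolate_field(s$Ch, 0),
                           interpolate_field(s$Vh, function(x, y) x + 2 * y),
                           c(intra = 1, extra = 1))
  expect_equal(max(abs(cp1$Dcv)), 0)
  # Dcc action on a constant concentration equals the drift residual
  cp <- assemble_coupling(s$Ch, s$Vh, interpolate_field(s$Ch, 2),
                          interpolate_field(s$Vh, function(x, y) 3 * x),
                          c(intra = 1.5, extra = 1.5))
  K <- assemble_stiffness(s$Ch, c(intra = 1.5, extra = 1.5))
  v_on_c <- interpolate_field(s$Ch, function(x, y) 3 * x)
  expect_lt(max(abs(cp$Dcc %*% rep(2, s$Ch$ndof) -
                      2 * (K %*% v_on_c$coef))), 1e-10)
})

test_that("charge matrix scales in z and sums to -F z area", {
  s <- make_spaces()
  Sp <- assemble_charge_matrix(s$Ch, s$Vh, 1)
  Sm <- assemble_charge_matrix(s$Ch, s$Vh, -1)
  S0 <- assemble_charge_matrix(s$Ch, s$Vh, 0)
  expect_equal(max(abs(Sp + Sm)), 0)
  expect_equal(max(abs(S0)), 0)
  area_el <- s$g$L * (s$g$d_intra + 2 * s$g$d_out)
  expect_equal(sum(Sp), -area_el, tolerance = 1e-10)
})

test_that("boundary loads integrate the flux with the right sign", {
  rg <- ranvier_geometry()
  m <- build_ranvier_mesh(rg, 0.2)
  Ch <- fe_space(m, c("intra", "extra"))
  F0 <- assemble_boundary_load(Ch, "inn_intra", 0)
  expect_equal(max(abs(F0)), 0)
  F1 <- assemble_boundary_load(Ch, "inn_intra", 1)
  # both membrane cuts carry a nodal face of length L_node
  expect_equal(sum(F1), -2 * rg$L_node, tolerance = 1e-10)
  # linear flux against the 1D line-quadrature oracle
  f <- function(x, y) 2 * x + 1
  F2 <- assemble_boundary_load(Ch, "inn_intra", f)
  xl <- (rg$L - rg$L_node) / 2; xr <- (rg$L + rg$L_node) / 2
  oracle <- -2 * integrate(function(x) 2 * x + 1, xl, xr,
                           rel.tol = 1e-12)$value
  expect_equal(sum(F2), oracle, tolerance = 1e-10)
  expect_error(assemble_boundary_load(Ch, "inn_intra",
                                      f)[0] -> x, NA)
  expect_error(assemble_boundary_load(fe_space(build_slab_mesh(
    slab_geometry(), 0.5), "all"), "inn_intra", 1), "absent")
})

test_that("P2 interpolation and evaluation reproduce quadratics exactly", {
  s <- make_spaces()
  f <- function(x, y) 1.5 - x + 2 * y + 0.3 * x^2 - x * y + 0.7 * y^2
  u <- interpolate_field(s$Vh, f)
  for (p in list(c(0.37, 0.11), c(2.5, -0.61), c(3.9, 0.9))) {
    expect_equal(evaluate_field(u, p), f(p[1], p[2]), tolerance = 1e-12)
  }
  expect_error(evaluate_field(u, c(10, 10)), "outside")
  # control point on the interface resolves from the requested side
  expect_equal(evaluate_field(u, slab_geometry()$x_a, region = "intra"),
               f(2, 0.434), tolerance = 1e-12)
})

test_that("assembly is invariant under triangle reordering", {
  s <- make_spaces(0.35)
  m2 <- s$m
  set.seed(42)
  perm <- sample(nrow(m2$tri))
  m2$tri <- m2$tri[perm, , drop = FALSE]
  m2$region <- m2$region[perm]
  st2 <- mesh_edges(m2)
  Vh2 <- fe_space(m2, "all", struct = st2)
  K1 <- assemble_stiffness(s$Vh, c(intra = 2, membrane = 1, extra = 3))
  K2 <- assemble_stiffness(Vh2, c(intra = 2, membrane = 1, extra = 3))
  # compare via quadratic forms on a shared function (dof order differs)
  f <- function(x, y) sin(x) + y^2
  u1 <- interpolate_field(s$Vh, f); u2 <- interpolate_field(Vh2, f)
  expect_equal(as.numeric(t(u1$coef) %*% K1 %*% u1$coef),
               as.numeric(t(u2$coef) %*% K2 %*% u2$coef), tolerance = 1e-12)
})
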