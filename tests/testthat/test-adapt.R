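quad_field <- function(mesh) {
  Vh <- fe_space(mesh, "all", dirichlet_tags = character(0))
  interpolate_field(Vh, function(x, y) 1 + x - 2 * y + 0.5 * x^2 +
                      0.25 * x * y - y^2)
}

test_that("gradient recovery reproduces polynomial gradients and is linear", {
  m <- build_slab_mesh(slab_geometry(), 0.25)
  u <- quad_field(m)
  g <- recover_gradient(u)
  co <- hierarchical_correction(u, g)
  # the safeguarded recovery (quadrature weighting, ridge, midside clamp)
  # reproduces quadratics to fitting accuracy rather than exactly
  expect_lt(max(abs(co$der3)), 1e-4)
  expect_lt(sum(co$l2sq), 1e-12)
  Vh <- u$space
  u1 <- interpolate_field(Vh, function(x, y) sin(x))
  u2 <- interpolate_field(Vh, function(x, y) cos(2 * y))
  g1 <- recover_gradient(u1); g2 <- recover_gradient(u2)
  g12 <- recover_gradient(discrete_field(Vh, 2 * u1$coef - 3 * u2$coef))
  expect_lt(max(abs(g12$gx - 2 * g1$gx + 3 * g2$gx)), 1e-10)
  expect_lt(max(abs(g12$gy - 2 * g1$gy + 3 * g2$gy)), 1e-10)
})

test_that("recovered gradient beats the broken gradient on a smooth field", {
  m <- build_slab_mesh(slab_geometry(), 0.15)
  Vh <- fe_space(m, "all", dirichlet_tags = character(0))
  u <- interpolate_field(Vh, function(x, y) sin(x))
  g <- recover_gradient(u)
  # L2 errors of both gradients against cos(x), evaluated at quad points
  gg <- space_geom(Vh)
  cf <- matrix(u$coef[Vh$T6], ncol = 6)
  err_broken <- 0; err_rec <- 0
  for (qi in seq_along(gg$w)) {
    bx <- rowSums(vapply(1:6, function(i) cf[, i] * gg$gx[, qi, i],
                         numeric(nrow(cf))))
    rx <- rowSums(vapply(1:6, function(i) g$gx[, i] * gg$N[qi, i],
                         numeric(nrow(cf))))
    tru <- cos(gg$qx[, qi])
    err_broken <- err_broken + sum(gg$w[qi] * gg$detJ * (bx - tru)^2)
    err_rec <- err_rec + sum(gg$w[qi] * gg$detJ * (rx - tru)^2)
  }
  expect_lt(err_rec, err_broken)
})

test_that("correction norms scale like h^3 under uniform refinement", {
  g <- slab_geometry()
  est <- vapply(c(0.2, 0.1, 0.05), function(h) {
    m <- build_slab_mesh(g, h)
    Vh <- fe_space(m, "all", dirichlet_tags = character(0))
    u <- interpolate_field(Vh, function(x, y) x^3)
    sqrt(sum(hierarchical_correction(u)$l2sq))
  }, 0)
  slopes <- diff(log(est)) / diff(log(c(0.2, 0.1, 0.05)))
  expect_gt(mean(slopes), 2.2)   # ~3 with boundary-patch pollution
  expect_lt(mean(slopes), 3.8)
})

test_that("the correction energy is invariant under rigid rotation", {
  m <- build_slab_mesh(slab_geometry(), 0.3)
  Vh <- fe_space(m, "all", dirichlet_tags = character(0))
  f <- function(x, y) x^3 - 2 * x * y^2 + 0.5 * y^3
  u <- interpolate_field(Vh, f)
  co <- hierarchical_correction(u)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m2 <- m; m2$nodes <- m$nodes %*% t(R)
  Vh2 <- fe_space(m2, "all", dirichlet_tags = character(0))
  # rotate the data with the mesh
  u2 <- interpolate_field(Vh2, function(x, y) {
    p <- cbind(x, y) %*% R
    f(p[, 1], p[, 2])
  })
  co2 <- hierarchical_correction(u2)
  # per-axis patch scaling makes the fits only approximately equivariant
  expect_equal(sum(co2$l2sq), sum(co$l2sq), tolerance = 0.05)
})

test_that("splitting a single interior edge obeys the Euler count", {
  m <- build_slab_mesh(slab_geometry(), 0.4)
  Vh <- fe_space(m, "all", dirichlet_tags = character(0))
  u <- interpolate_field(Vh, function(x, y) exp(3 * y))
  co <- hierarchical_correction(u)
  tg <- error_targets(1e-9, m)
  r <- refine_edges(m, co$der3, tg, max_marks = 1)
  expect_equal(r$n_marked, 1L)
  # an interior edge split adds 1 node and 2 triangles (boundary: 1 and 1)
  dn <- nrow(r$mesh$nodes) - nrow(m$nodes)
  dt <- nrow(r$mesh$tri) - nrow(m$tri)
  expect_equal(dn, 1L)
  expect_true(dt %in% c(1L, 2L))
  expect_silent(mesh_check(r$mesh))
})

test_that("patch equal to the whole domain reproduces the global target", {
  m <- build_slab_mesh(slab_geometry(), 0.5)
  tg <- error_targets(0.123, m)
  expect_equal(tg$patch_target(sum(mesh_areas(m))), 0.123^2,
               tolerance = 1e-12)
})

test_that("elimination coarsens an over-refined mesh conservatively", {
  m <- build_slab_mesh(slab_geometry(), 0.08)
  Vh <- fe_space(m, "all", dirichlet_tags = character(0))
  u <- interpolate_field(Vh, function(x, y) x^3)   # tame cubic content
  co <- hierarchical_correction(u)
  tg <- error_targets(50, m)                       # generous target
  r <- eliminate_nodes(m, co$der3, tg)
  expect_gt(r$n_removed, 0)
  expect_lt(nrow(r$mesh$nodes), nrow(m$nodes))
  expect_silent(mesh_check(r$mesh))
  expect_equal(region_areas(r$mesh), region_areas(m), tolerance = 1e-8)
  expect_equal(tag_length(r$mesh, "ext"), tag_length(m, "ext"),
               tolerance = 1e-8)
  expect_equal(tag_length(r$mesh, "interface"),
               tag_length(m, "interface"), tolerance = 1e-8)
  # estimated global error stays within the target after coarsening
  est <- sqrt(sum(cubic_norms(r$mesh$nodes, r$mesh$tri, r$der3)$l2sq))
  expect_lte(est, 50 * 1.05)
})

test_that("edge swapping decreases the H1 energy and preserves topology", {
  m <- build_slab_mesh(slab_geometry(), 0.3)
  Vh <- fe_space(m, "all", dirichlet_tags = character(0))
  u <- interpolate_field(Vh, function(x, y) (x - 2)^3 + (x - 2) * y^2)
  co <- hierarchical_correction(u)
  before <- sum(elem_h1sq(m, co$der3))
  r <- swap_edges(m, co$der3)
  after <- sum(elem_h1sq(r$mesh, r$der3))
  expect_lte(after, before + 1e-12)
  expect_equal(nrow(r$mesh$nodes), nrow(m$nodes))
  expect_equal(nrow(r$mesh$tri), nrow(m$tri))
  expect_silent(mesh_check(r$mesh))
  # a perfectly symmetric configuration is left alone (strict decrease rule)
  msym <- build_slab_mesh(slab_geometry(), 0.5)
  co0 <- list(der3 = matrix(0, nrow(msym$tri), 4))
  r0 <- swap_edges(msym, co0$der3)
  # zero correction everywhere: all configurations tie, nothing may flip
  expect_equal(r0$n_flipped, 0L)
})

test_that("node movement lowers the objective and never inverts", {
  m <- build_slab_mesh(slab_geometry(), 0.35)
  Vh <- fe_space(m, "all", dirichlet_tags = character(0))
  u <- interpolate_field(Vh, function(x, y) exp(2 * (y - 0.4)))
  co <- hierarchical_correction(u)
  before <- sum(elem_h1sq(m, co$der3))
  r <- move_nodes(m, co$der3, iters = 2)
  expect_true(all(mesh_areas(r$mesh) > 0))
  after <- sum(elem_h1sq(r$mesh, r$der3))
  expect_lte(after, before * 1.01)   # Jacobi sweep: near-monotone
  expect_silent(mesh_check(r$mesh))
  # boundary nodes only slide along their own line
  tagged <- unique(as.vector(m$bedges))
  moved <- which(rowSums(abs(r$mesh$nodes - m$nodes)) > 0)
  for (v in intersect(tagged, moved)) {
    # the node stayed on one of the straight mesh lines it started on
    onx <- any(abs(m$nodes[v, 1] - r$mesh$nodes[v, 1]) < 1e-12)
    ony <- any(abs(m$nodes[v, 2] - r$mesh$nodes[v, 2]) < 1e-12)
    expect_true(onx || ony)
  }
})

test_that("single-vertex relocation approaches the grid-search optimum", {
  # 4-triangle fan around a central vertex; der3 constant
  nodes <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0.6, 0.9))
  tri <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  bed <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  m <- new_pnp_mesh(nodes, tri, rep(REGION_INTRA, 4), bed, rep(TAG_EXL, 4))
  der3 <- matrix(rep(c(2, 0.5, -1, 0.7), each = 4), 4)
  r <- move_nodes(m, der3, iters = 25, step0 = 0.3)
  e_mine <- sum(elem_h1sq(r$mesh, r$der3))
  # brute-force grid search over the interior
  grid <- expand.grid(x = seq(0.2, 1.8, by = 0.05),
                      y = seq(0.2, 1.8, by = 0.05))
  evals <- vapply(seq_len(nrow(grid)), function(i) {
    m2 <- m; m2$nodes[5, ] <- c(grid$x[i], grid$y[i])
    if (any(tri_signed_area2(m2$nodes, m2$tri) <= 0)) return(Inf)
    sum(elem_h1sq(m2, der3))
  }, 0)
  expect_lte(e_mine, min(evals) * 1.05)
})

test_that("solution transfer is exact where it should be", {
  g <- slab_geometry()
  m1 <- build_slab_mesh(g, 0.3)
  m2 <- build_slab_mesh(g, 0.17)
  f <- function(x, y) 2 + x - y + 0.3 * x * y + 0.1 * y^2
  C1 <- fe_space(m1, c("intra", "extra"))
  C2 <- fe_space(m2, c("intra", "extra"))
  u1 <- interpolate_field(C1, f)
  # identity on the same mesh
  tid <- transfer_solution(u1, C1)
  expect_lt(max(abs(tid$coef - u1$coef)), 1e-12)
  # exact for quadratics on a different mesh of the same regions
  t21 <- transfer_solution(u1, C2)
  uref <- interpolate_field(C2, f)
  expect_lt(max(abs(t21$coef - uref$coef)), 1e-10)
  # mass change on a refinement-style transfer below 1 percent
  conc <- interpolate_field(C1, function(x, y) 155 + 5 * sin(x) * y)
  tr <- transfer_solution(conc, C2)
  m_old <- integrate_field(conc, "intra")
  m_new <- integrate_field(tr, "intra")
  expect_lt(abs(m_new - m_old) / m_old, 0.01)
})
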