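test_that("slab mesh partitions the rectangle into the five bands", {
  g <- slab_geometry()
  m <- build_slab_mesh(g, 0.2)
  expect_silent(mesh_check(m))
  a <- region_areas(m)
  expect_equal(a[["intra"]], g$d_intra * g$L, tolerance = 1e-10)
  expect_equal(a[["membrane"]], 2 * g$d_mem * g$L, tolerance = 1e-10)
  expect_equal(a[["extra"]], 2 * g$d_out * g$L, tolerance = 1e-10)
  # membrane band contains the control-point span [0.434, 0.534]
  ymem <- m$nodes[unique(as.vector(m$tri[m$region == REGION_MEMBRANE, ])), 2]
  expect_equal(range(abs(ymem)), c(0.434, 0.534))
  # no Gamma_inn edges in the no-flux benchmark
  expect_equal(tag_length(m, "inn_intra") + tag_length(m, "inn_extra"), 0)
  # tagged boundary lengths match the analytic perimeter pieces
  expect_equal(tag_length(m, "ext"), 2 * g$L + 4 * g$d_out, tolerance = 1e-8)
  expect_equal(tag_length(m, "exl"), g$d_intra + 2 * g$d_mem,
               tolerance = 1e-8)
  expect_equal(tag_length(m, "interface"), 4 * g$L, tolerance = 1e-8)
})

test_that("even the coarsest slab mesh is valid", {
  g <- slab_geometry()
  m <- build_slab_mesh(g, g$L)
  expect_silent(mesh_check(m))
  for (r in 1:3) expect_gte(sum(m$region == r), 2)
  expect_true(all(mesh_areas(m) > 0))
})

test_that("ranvier mesh has a two-valued membrane thickness profile", {
  rg <- ranvier_geometry()
  m <- build_ranvier_mesh(rg, 0.2)
  expect_silent(mesh_check(m))
  # membrane thickness at sampled x: sum of membrane band heights above y=0
  xs <- c(0.5, rg$L / 2, rg$L - 0.5)
  th <- vapply(xs, function(x) {
    sel <- m$region == REGION_MEMBRANE
    tri <- m$tri[sel, , drop = FALSE]
    cx <- rowMeans(matrix(m$nodes[tri, 1], ncol = 3))
    cy <- rowMeans(matrix(m$nodes[tri, 2], ncol = 3))
    a <- mesh_areas(m)[sel]
    # crude thickness via area of membrane triangles in a thin x-window
    w <- 0.1
    keep <- abs(cx - x) < w / 2 & cy > 0
    sum(a[keep]) / w
  }, 0)
  expect_lt(th[2], 3 * rg$D_n)          # thin at the node ...
  expect_gt(th[1], 0.8 * rg$D_m)        # ... thick under the myelin
  # Gamma_inn length per membrane cut and side equals L_node
  inn_in <- m$bedges[m$btag == TAG_INN_INTRA, , drop = FALSE]
  upper <- m$nodes[inn_in[, 1], 2] > 0
  len <- function(e) sum(sqrt(rowSums((m$nodes[e[, 1], , drop = FALSE] -
                                         m$nodes[e[, 2], , drop = FALSE])^2)))
  expect_equal(len(inn_in[upper, , drop = FALSE]), rg$L_node,
               tolerance = 1e-8)
  expect_equal(len(inn_in[!upper, , drop = FALSE]), rg$L_node,
               tolerance = 1e-8)
  expect_equal(tag_length(m, "inn_extra"), 2 * rg$L_node, tolerance = 1e-8)
})

test_that("degenerate ranvier section reduces to the uniform slab", {
  rg <- ranvier_geometry(d = 0.434, D_n = 0.1, D_m = 0.1, L = 4,
                         L_node = 3.999999, d_out = 0.4)
  m <- build_ranvier_mesh(rg, 0.25)
  g <- slab_geometry(L = 4, d_intra = 2 * rg$d, d_mem = 0.1, d_out = 0.4)
  ms <- build_slab_mesh(g, 0.25)
  expect_equal(region_areas(m), region_areas(ms), tolerance = 1e-6)
})

test_that("tailored mesh layers follow the grading and densify the wall", {
  g <- slab_geometry()
  sp <- grading_spec(5e-4, 2, 0.05)
  m <- build_tailored_mesh(g, sp, nx = 8)
  expect_silent(mesh_check(m))
  # layer thicknesses above the upper membrane face follow ratio r
  ys <- sort(unique(m$nodes[, 2]))
  up <- ys[ys > g$y2 - 1e-12]
  dl <- diff(up)
  expect_true(all(abs(dl[2:5] / dl[1:4] - 2) < 1e-6))
  # halving h0 strictly increases the node count
  m2 <- build_tailored_mesh(g, grading_spec(2.5e-4, 2, 0.05), nx = 8)
  expect_gt(nrow(m2$nodes), nrow(m$nodes))
  # node density decreases away from the membrane
  h <- node_distance_histogram(m, "intra", bin_nm = 100, max_nm = 400)
  expect_true(all(diff(h$fraction[1:4]) <= 0))
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
})

test_that("remeshing the same geometry conserves region areas", {
  g <- slab_geometry()
  a1 <- region_areas(build_slab_mesh(g, 0.3))
  a2 <- region_areas(build_slab_mesh(g, 0.11))
  a3 <- region_areas(build_tailored_mesh(g, grading_spec(1e-3, 2, 0.1)))
  expect_equal(a1, a2, tolerance = 1e-8)
  expect_equal(a1, a3, tolerance = 1e-8)
})
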