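test_that("MSH v2.2 round trip preserves everything", {
  m <- build_slab_mesh(slab_geometry(), 0.3)
  f <- tempfile(fileext = ".msh")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_equal(m2$tri, m$tri)
  expect_lt(max(abs(m2$nodes - m$nodes)), 1e-12)
  expect_equal(m2$region, m$region)
  ord <- order(edge_key(m$bedges[, 1], m$bedges[, 2]))
  ord2 <- order(edge_key(m2$bedges[, 1], m2$bedges[, 2]))
  expect_equal(m2$btag[ord2], m$btag[ord])
  unlink(f)
})

test_that("VTU round trip preserves the mesh and carries fields", {
  skip_if_not_installed("xml2")
  m <- build_ranvier_mesh(ranvier_geometry(), 0.3)
  f <- tempfile(fileext = ".vtu")
  Vh <- fe_space(m, "all")
  u <- interpolate_field(Vh, function(x, y) x + y^2)
  write_mesh_vtu(m, f, fields = list(V = u))
  m2 <- read_mesh(f)
  expect_equal(m2$tri, m$tri)
  expect_lt(max(abs(m2$nodes - m$nodes)), 1e-12)
  expect_equal(sort(m2$btag), sort(m$btag))
  flds <- attr(m2, "fields")
  expect_named(flds, "V")
  expect_equal(flds$V, field_vertex_values(u), tolerance = 1e-12)
  unlink(f)
})

test_that("missing metadata is reported by name", {
  m <- build_slab_mesh(slab_geometry(), 0.5)
  f <- tempfile(fileext = ".msh")
  write_mesh(m, f)
  # strip the physical tags from the triangle records
  lines <- readLines(f)
  el <- grep("^\\d+ 2 2 ", lines)
  lines[el] <- sub("^(\\d+) 2 2 \\d+ \\d+", "\\1 2 0", lines[el])
  writeLines(lines, f)
  expect_error(read_mesh(f), "region labels")
  expect_error(read_mesh("nope.xyz"), "unknown format")
  unlink(f)
})
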