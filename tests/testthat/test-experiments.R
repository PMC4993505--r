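test_that("convergence-order fit recovers exact power laws", {
  r1 <- data.frame(nodes = c(100, 400, 1600), error_mV = 5 / c(100, 400, 1600))
  expect_equal(fit_convergence_order(r1), 1, tolerance = 1e-10)
  r2 <- data.frame(nodes = c(100, 200, 800),
                   error_mV = 3 / c(100, 200, 800)^2)
  expect_equal(fit_convergence_order(r2), 2, tolerance = 1e-10)
  expect_error(fit_convergence_order(r1[1:2, ]), "3 series points")
})

test_that("node-distance histogram is a normalized decreasing profile for a graded mesh", {
  m <- build_tailored_mesh(slab_geometry(), grading_spec(1e-3, 2, 0.05),
                           nx = 6)
  h <- node_distance_histogram(m, "intra", bin_nm = 2, max_nm = 40)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
  expect_true(all(h$fraction >= 0))
  # graded: the first bins dominate the tail bins
  expect_gt(mean(h$fraction[1:3]), mean(h$fraction[15:20]))
})

test_that("uniform meshes put the area-proportional share near the wall", {
  m <- build_slab_mesh(slab_geometry(), 0.03)
  # within a 60 nm band: fraction of intra vertices ~ band area / region area
  f <- node_fraction_within(m, within_nm = 60, region = "intra")
  band_frac <- 2 * 0.06 / 0.868          # both membranes
  expect_lt(abs(f - band_frac), 0.06)
})

test_that("configuration reader resolves defaults and overrides", {
  cfg <- read_config(NULL)
  expect_s3_class(cfg$slab, "slab_geometry")
  expect_equal(cfg$duration, 10)
  f <- tempfile(fileext = ".yaml")
  writeLines(c("geometry:", "  ranvier:", "    L_node: 0.9",
               "channels:", "  stim_amplitude: 2.5",
               "time:", "  dt0: 2e-4"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$ranvier$L_node, 0.9)
  expect_equal(cfg2$channels$stim_amplitude, 2.5)
  expect_equal(cfg2$controller$dt0, 2e-4)
  unlink(f)
})

test_that("analytics printer reports the derived quantities", {
  out <- capture.output(vals <- print_analytics())
  expect_true(any(grepl("debye_intra_nm", out)))
  expect_equal(vals$V_mem_slab_mV, -235.64, tolerance = 1e-3)
  expect_equal(vals$cap_node_uF_cm2, 1.82, tolerance = 0.01)
  expect_gt(vals$V_rest_mV, -80)
  expect_lt(vals$V_rest_mV, -60)
})
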