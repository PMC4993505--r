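test_that("geometry constructors enforce their invariants", {
  g <- slab_geometry()
  expect_equal(g$y1, 0.434)
  expect_equal(g$y2, 0.534)
  expect_error(slab_geometry(d_mem = 0), "band widths")
  expect_error(slab_geometry(x_a = c(1, 0.4), x_b = c(2, 0.6)),
               "common perpendicular")
  rg <- ranvier_geometry()
  expect_equal(rg$d, 0.434)
  expect_error(ranvier_geometry(L_node = 5), "L_node")
  expect_error(ranvier_geometry(D_n = 0.5, D_m = 0.4), "D_n")
  expect_error(grading_spec(h0 = 1e-3, r = 1), "r must")
})

test_that("graded increments follow the geometric law and fill the segment", {
  inc <- graded_increments(0.05, h0 = 5e-4, r = 2, hmax = 0.05)
  # consecutive uncapped layers grow by exactly r
  grow <- inc[-length(inc)]
  ratios <- grow[-1] / grow[-length(grow)]
  expect_true(all(abs(ratios[grow[-1] < 0.05] - 2) < 1e-6))
  expect_equal(sum(inc), 0.05, tolerance = 1e-12)
  expect_equal(inc[1], 5e-4)
})

test_that("uniform increments cover the segment with bounded spacing", {
  inc <- uniform_increments(1, 0.3)
  expect_equal(sum(inc), 1)
  expect_true(all(inc <= 0.3 + 1e-12))
})
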