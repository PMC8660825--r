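test_that("a degenerate grid at the default reports itself as the interval", {
  p <- default_parameters()
  rng <- limit_cycle_range(p, "k_s8", p[["k_s8"]], t_end = 300)
  expect_equal(rng$left, p[["k_s8"]])
  expect_equal(rng$right, p[["k_s8"]])
})

test_that("grid refinement never widens the interval beyond one coarse step", {
  p <- default_parameters()
  v <- p[["k_s8"]]
  coarse_grid <- v * c(0.25, 0.5, 1, 2, 4, 6)
  fine_grid <- sort(c(coarse_grid, v * c(0.375, 0.75, 1.5, 3, 5)))
  coarse <- limit_cycle_range(p, "k_s8", coarse_grid, t_end = 300)
  fine <- limit_cycle_range(p, "k_s8", fine_grid, t_end = 300)
  step_left <- diff(coarse_grid)[max(1, which(coarse_grid == coarse$left) - 1)]
  step_right <- diff(coarse_grid)[min(length(coarse_grid) - 1,
                                      which(coarse_grid == coarse$right))]
  expect_gte(fine$left, coarse$left - step_left)
  expect_lte(fine$right, coarse$right + step_right)
})

test_that("unknown symbols and unsorted grids are rejected", {
  p <- default_parameters()
  expect_error(limit_cycle_range(p, "k_bogus", c(0.1, 0.2)), "unknown")
  expect_error(limit_cycle_range(p, "k_s8", c(0.2, 0.1)), "ascending")
})
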