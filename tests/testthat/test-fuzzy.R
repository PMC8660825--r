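test_that("bands vanish at full membership and nest across levels", {
  p <- default_parameters()
  fb <- fuzzy_analysis(p, parameters = c("k_s1", "k_s8"),
                       alpha_levels = c(0, 0.5, 1),
                       quantities = c("CyclinB", "Mad2:Cdc20P", "Cdc25"))
  at1 <- fb$band[fb$alpha == 1]
  expect_true(all(at1 == 0))
  expect_true(all(fb$band >= 0, na.rm = TRUE))
  wide <- tidyr::pivot_wider(fb, names_from = "alpha",
                             values_from = "band")
  expect_true(all(wide$`0.5` <= wide$`0` + 1e-12, na.rm = TRUE))
  expect_true(all(wide$`1` <= wide$`0.5` + 1e-12, na.rm = TRUE))
})

test_that("endpoint bands agree with a dense grid search for a monotone response", {
  p <- default_parameters()
  # dense 11-point grid over the alpha = 0 interval of k_s1, CyclinB average
  sym <- "k_s1"; p0 <- p[[sym]]
  grid <- seq(p0 * 0.99, p0 * 1.01, length.out = 11)
  vals <- vapply(grid, function(v) {
    pp <- p; pp[sym] <- v
    sim <- simulate_cycle(pp, t_end = 96)
    average_concentration(sim, "CyclinB")
  }, numeric(1))
  dense_band <- max(vals) - min(vals)
  fb <- fuzzy_analysis(p, parameters = sym, alpha_levels = c(0, 1),
                       quantities = "CyclinB")
  band0 <- fb$band[fb$alpha == 0 & fb$quantity == "CyclinB"]
  expect_equal(band0, dense_band, tolerance = 0.05 * max(dense_band, 1e-12))
})

test_that("alpha levels outside the unit interval are rejected", {
  expect_error(fuzzy_analysis(default_parameters(), alpha_levels = c(0, 1.1)),
               "alpha")
})
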