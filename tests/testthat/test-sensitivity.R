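test_that("the window average matches its defining sum exactly", {
  sim <- wt_sim()
  a <- average_concentration(sim, "CyclinB")
  ts <- 0 + 1:96
  manual <- mean(stats::approx(sim$trajectories$time,
                               sim$trajectories$CyclinB, xout = ts)$y)
  expect_equal(a, manual, tolerance = 1e-10)
  # constant trajectory averages to the constant
  fake <- structure(list(trajectories = tibble::tibble(
    time = seq(0, 100, 0.5), CyclinB = 0.7)), class = "g2m_sim")
  expect_equal(average_concentration(fake, "CyclinB"), 0.7)
})

test_that("a zero-mean sinusoid over whole periods averages to zero", {
  tt <- seq(0, 100, by = 0.05)
  fake <- structure(list(trajectories = tibble::tibble(
    time = tt, CyclinB = sin(2 * pi * tt / 48))), class = "g2m_sim")
  expect_lt(abs(average_concentration(fake, "CyclinB")), 1e-3)
})

test_that("too-short simulations are rejected", {
  short <- structure(list(trajectories = tibble::tibble(
    time = seq(0, 50, 0.5), CyclinB = 0.5)), class = "g2m_sim")
  expect_error(average_concentration(short, "CyclinB"), "spans")
})

test_that("central-difference sensitivities converge under step halving", {
  p <- default_parameters()
  s1 <- log_sensitivity(p, quantities = "Cdc25", parameters = "k_s8",
                        h_fraction = 0.01)$values$S
  s2 <- log_sensitivity(p, quantities = "Cdc25", parameters = "k_s8",
                        h_fraction = 0.005)$values$S
  expect_lt(abs(s1 - s2) / abs(s1), 0.05)
})

test_that("zero-valued parameters are excluded with S = 0", {
  sc <- scenario_params("null")
  rep <- log_sensitivity(sc$params, quantities = "Mad2:Cdc20P",
                         parameters = c("k_s28", "k_s1"), init = sc$init)
  row28 <- rep$values[rep$values$parameter == "k_s28", ]
  expect_true(row28$excluded)
  expect_equal(unname(row28$S), 0)
  row1 <- rep$values[rep$values$parameter == "k_s1", ]
  expect_false(row1$excluded)
})

test_that("row averages equal a direct mean oracle", {
  p <- default_parameters()
  rep <- log_sensitivity(p, quantities = c("CyclinB", "Cdc25"),
                         parameters = c("k_s1", "k_s8", "k_s17"))
  # settings record 3 varied parameters; the mean divides by that count
  av <- average_log_sensitivity(rep)
  for (q in c("CyclinB", "Cdc25")) {
    vals <- rep$values$S[rep$values$quantity == q]
    expect_equal(av$mean_S[av$quantity == q], mean(vals), tolerance = 1e-12)
  }
})
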