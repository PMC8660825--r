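test_that("integration output is well-formed dense output", {
  sim <- wt_sim()
  tr <- sim$trajectories
  expect_s3_class(tr, "tbl_df")
  expect_identical(names(tr), c("time", species_registry()$dynamic))
  expect_true(all(diff(tr$time) > 0))
  expect_lt(max(diff(tr$time)), 0.1 + 1e-9)
  expect_identical(sim$events$time, sort(sim$events$time))
})

test_that("doubling tau halves the detected period (time-rescaling law)", {
  p <- default_parameters()
  p["tau"] <- p[["tau"]] * 2
  sim2 <- simulate_cycle(p, t_end = 200)
  per2 <- estimate_period(sim2, burn_in = 50)
  expect_equal(per2, wt_period() / 2, tolerance = 0.02)
})

test_that("halving the solver tolerances barely moves the endpoint state", {
  p <- default_parameters()
  y0 <- default_initial_state()
  a <- simulate_cycle(p, init = y0, t_end = 150)
  b <- simulate_cycle(p, init = y0, t_end = 150, rtol = 5e-7, atol = 5e-10)
  ya <- unlist(a$trajectories[nrow(a$trajectories), -1])
  yb <- unlist(b$trajectories[nrow(b$trajectories), -1])
  expect_lt(max(abs(ya - yb)) / max(abs(ya)), 1e-3)
})

test_that("trajectories stay non-negative within solver tolerance", {
  sim <- simulate_cycle(t_end = 500)
  expect_gt(min(as.matrix(sim$trajectories[, -1])), -1e-6)
})

test_that("conserved pool totals stay constant along trajectories", {
  sim <- wt_sim()
  m <- derived_quantities(as.matrix(sim$trajectories[, -1]))
  for (tn in c("CDK1_T", "Emi1_T", "Separase_T")) {
    drift <- diff(range(m[, tn]))
    expect_lt(drift, 10 * 1e-6)
  }
})

test_that("the arrest event resets Cdc20 once per upward crossing", {
  p <- default_parameters()
  p["k_s12"] <- 0  # Plk1 loss drives the checkpoint complex past 0.6
  sim <- simulate_cycle(p, t_end = 300)
  resets <- sim$events[sim$events$kind == "arrest_reset", ]
  expect_gt(nrow(resets), 0)
  for (st in resets$state) expect_equal(unname(st[["Cdc20"]]), 0)
  # between consecutive resets the signal must have fallen below 0.6 again
  if (nrow(resets) > 1) {
    tr <- sim$trajectories
    for (i in seq_len(nrow(resets) - 1)) {
      seg <- tr$`Mad2:Cdc20P`[tr$time > resets$time[i] &
                                tr$time < resets$time[i + 1]]
      expect_lt(min(seg), 0.6)
    }
  }
  # with events disabled, no resets are applied
  sim0 <- simulate_cycle(p, t_end = 200, events_enabled = FALSE)
  expect_identical(sum(sim0$events$kind == "arrest_reset"), 0L)
})

test_that("tidy and glance return the documented shapes", {
  sim <- wt_sim()
  td <- tidy(sim)
  expect_identical(names(td), c("time", "species", "value"))
  expect_identical(dplyr::n_distinct(td$species), 34L)
  td50 <- tidy(sim, derived = TRUE)
  expect_identical(dplyr::n_distinct(td50$species), 50L)
  g <- glance(sim)
  expect_identical(nrow(g), 1L)
  expect_true(is.finite(g$period_h))
})
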