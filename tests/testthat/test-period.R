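test_that("a synthetic sinusoid of known period is recovered", {
  tt <- seq(0, 400, by = 0.1)
  traj <- tibble::tibble(time = tt,
                         CyclinB = 0.5 + 0.4 * sin(2 * pi * tt / 24))
  expect_equal(estimate_period(traj), 24, tolerance = 0.1 / 24)
})

test_that("constant and damped trajectories yield no period", {
  tt <- seq(0, 400, by = 0.1)
  expect_true(is.na(estimate_period(tibble::tibble(time = tt, CyclinB = 0.3))))
  damped <- tibble::tibble(
    time = tt, CyclinB = 0.3 + 0.4 * exp(-tt / 40) * sin(2 * pi * tt / 24))
  expect_true(is.na(estimate_period(damped)))
})

test_that("period estimation is invariant to 2x subsampling", {
  sim <- wt_sim()
  tr <- sim$trajectories
  sub <- tr[seq(1, nrow(tr), by = 2), ]
  expect_equal(estimate_period(sub), estimate_period(tr), tolerance = 0.01)
})

test_that("an unperturbed run compared against itself is viable with ratio 1", {
  ph <- classify_phenotype(wt_sim(), wt_period(),
                           wt_mpf_peak = wt_mpf_peak())
  expect_true(ph$viable)
  expect_equal(ph$tm_over_t, 1, tolerance = 1e-6)
  expect_identical(ph$arrest_class, "none")
})

test_that("Cdc20 and Cdc25 deletions give the two distinct arrest classes", {
  ph20 <- call_mutant(list(k_s17 = 0))
  expect_false(ph20$viable)
  expect_identical(ph20$arrest_class, "M-phase-high-MPF")
  ph25 <- call_mutant(list(k_s8 = 0))
  expect_false(ph25$viable)
  expect_identical(ph25$arrest_class, "early-low-MPF")
})

test_that("an arrested cell keeps the checkpoint complex above the cycling mean", {
  p <- default_parameters(); p["k_s12"] <- 0
  sim <- simulate_cycle(p, t_end = 400)
  expect_gt(sum(sim$events$kind == "arrest_reset"), 0)
  tr <- sim$trajectories
  final_mean <- mean(tr$`Mad2:Cdc20P`[tr$time > max(tr$time) - 24])
  wt_mean <- mean(wt_sim()$trajectories$`Mad2:Cdc20P`)
  expect_gt(final_mean, wt_mean)
})

test_that("phenotype preconditions are enforced", {
  expect_error(classify_phenotype(wt_sim(), -1), "reference_period")
  short <- simulate_cycle(t_end = 120)
  expect_error(classify_phenotype(short, 48), "at least")
  expect_error(estimate_period(wt_sim(), species = "nope"), "unknown species")
})
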