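test_that("the damage signal follows the piecewise-linear branch rules", {
  # below activation: off
  r <- dds_signal(0.30, t = 0)
  expect_equal(r$dds, 0)
  expect_equal(r$sig, 0)
  expect_false(r$arrest_triggered)
  # activation branch: 200 * (x - 0.36)
  r <- dds_signal(0.50, t = 0)
  expect_equal(r$dds, 200 * (0.50 - 0.36))
  expect_equal(r$dds, 28)
  expect_false(r$arrest_triggered)
  # arrest branch: 200 * (x - 0.6), arrest flagged
  r <- dds_signal(0.70, t = 0)
  expect_equal(r$dds, 200 * (0.70 - 0.60))
  expect_equal(r$dds, 20)
  expect_true(r$arrest_triggered)
})

test_that("dds is continuous at 0.36 and drops discontinuously at 0.6", {
  eps <- 1e-9
  below <- dds_signal(0.36 - eps)$dds
  above <- dds_signal(0.36 + eps)$dds
  expect_lt(abs(above - below), 1e-5)
  left <- dds_signal(0.6 - eps)$dds
  right <- dds_signal(0.6 + eps)$dds
  expect_gt(left - right, 40)  # jump of 200 * 0.24 as printed
})

test_that("the signal decays in time at 1e-8 per hour", {
  r0 <- dds_signal(0.5, t = 0)
  r1 <- dds_signal(0.5, t = 1e6)
  expect_equal(r1$sig, r0$dds * exp(-1e-8 * 1e6))
})

test_that("negative inputs raise domain errors", {
  expect_error(dds_signal(-0.1), "mad2cdc20p")
  expect_error(dds_signal(0.2, t = -1), "t must")
})
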