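test_that("reference and compiled right-hand sides agree along a trajectory", {
  p <- default_parameters()
  y0 <- default_initial_state()
  # integrate the compiled model with the R implementation as oracle route
  o_c <- deSolve::lsodar(y = as.numeric(y0), times = seq(0, 60, 0.5),
                         func = "g2m_derivs", parms = as.numeric(p),
                         dllname = "g2mcycle", initfunc = "g2m_init",
                         rtol = 1e-8, atol = 1e-11)
  o_r <- deSolve::lsodar(y = as.numeric(y0), times = seq(0, 60, 0.5),
                         func = function(t, y, parms) {
                           names(y) <- species_registry()$dynamic
                           list(unname(rhs_full(t, y, p)))
                         }, parms = NULL, rtol = 1e-8, atol = 1e-11)
  expect_lt(max(abs(o_c[nrow(o_c), -1] - o_r[nrow(o_r), -1])), 1e-6)
})

test_that("the p53P:Plk1P exchange vanishes at its own equilibrium", {
  p <- default_parameters()
  y <- default_initial_state()
  # choose the complex concentration that balances k_f17 [p53P][Plk1P]
  y["p53P"] <- 0.2; y["Plk1P"] <- 0.15
  y["p53P:Plk1P"] <- p[["k_f17"]] * 0.2 * 0.15 / p[["k_r17"]]
  # turn off the complex's degradation to isolate the binding balance
  p["k_d30.1"] <- 0
  d <- rhs_full(0, y, p)
  expect_equal(unname(d[["p53P:Plk1P"]]), 0, tolerance = 1e-12)
})

test_that("the origin is a fixed point when all synthesis rates vanish", {
  p <- default_parameters()
  p[synthesis_parameters()] <- 0
  p[c("k_s31.1", "k_s32.1")] <- 0
  y <- stats::setNames(rep(0, 34), species_registry()$dynamic)
  d <- rhs_full(0, y, p)
  expect_true(all(d == 0))
})

test_that("the numerical Jacobian matches a central-difference oracle", {
  p <- default_parameters()
  set.seed(21)
  reg <- species_registry()
  for (rep in 1:3) {
    y <- stats::setNames(runif(34, 0.01, 0.3), reg$dynamic)
    y[c("MPF", "preMPF", "p21:MPF")] <- y[c("MPF", "preMPF", "p21:MPF")] / 4
    f <- function(v) unname(rhs_full(0, stats::setNames(v, reg$dynamic), p))
    jac_pracma <- pracma::jacobian(f, as.numeric(y))
    h <- 1e-7
    jac_fd <- matrix(0, 34, 34)
    for (j in 1:34) {
      e <- numeric(34); e[j] <- h
      jac_fd[, j] <- (f(as.numeric(y) + e) - f(as.numeric(y) - e)) / (2 * h)
    }
    scale <- pmax(abs(jac_fd), 1e-4)
    expect_lt(max(abs(jac_pracma - jac_fd) / scale), 1e-5)
  }
})

test_that("non-finite inputs are rejected with the offending entry named", {
  p <- default_parameters()
  y <- default_initial_state()
  y[3] <- NaN
  expect_error(rhs_full(0, y, p), "non-finite state")
  y <- default_initial_state()
  p[["k_s1"]] <- NA
  expect_error(rhs_full(0, y, p), "k_s1")
})

test_that("the standalone checkpoint module needs damage to oscillate", {
  # without damage: settles, no sustained oscillation in the final window
  res_off <- module_period(damage_on = FALSE, t_end = 500)
  expect_true(is.na(res_off$period))
  expect_lt(res_off$amplitude, 0.005)
  # with damage: sustained oscillation
  res_on <- module_period(damage_on = TRUE)
  expect_false(is.na(res_on$period))
  expect_gt(res_on$amplitude, 0.05)
})
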