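test_that("a planted linear signal is recovered and inert inputs are not", {
  set.seed(4)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- 3 * X[, 2] + rnorm(200, sd = 0.3)
  r <- prcc(X, y)
  expect_gt(r$prcc["x2", 1], 0.95)
  expect_lt(max(abs(r$prcc[c("x1", "x3", "x4", "x5"), 1])), 0.2)
  expect_lt(r$p_value["x2", 1], 1e-10)
})

test_that("prcc matches the definitional residual-correlation oracle", {
  set.seed(8)
  n <- 200; k <- 5
  X <- matrix(rnorm(n * k), n, k)
  y <- X %*% c(1, -2, 0.5, 0, 3) + rnorm(n)
  r <- prcc(X, y)
  rx <- apply(X, 2, rank); ry <- rank(y)
  for (i in seq_len(k)) {
    others <- rx[, -i, drop = FALSE]
    res_x <- stats::residuals(stats::lm(rx[, i] ~ others))
    res_y <- stats::residuals(stats::lm(ry ~ others))
    expect_equal(unname(r$prcc[i, 1]), stats::cor(res_x, res_y),
                 tolerance = 1e-10)
  }
})

test_that("prcc values are bounded and rank-invariant", {
  set.seed(13)
  X <- matrix(rexp(150 * 4), 150, 4)
  Y <- cbind(X[, 1]^2 + rnorm(150, sd = 0.1), rnorm(150))
  r <- prcc(X, Y)
  expect_true(all(abs(r$prcc) <= 1, na.rm = TRUE))
  expect_true(all(r$p_value >= 0 & r$p_value <= 1, na.rm = TRUE))
  # strictly monotone transform of an input leaves its PRCC unchanged
  X2 <- X; X2[, 1] <- exp(X2[, 1])
  r2 <- prcc(X2, Y)
  expect_equal(r$prcc, r2$prcc, tolerance = 1e-12)
})

test_that("constant outputs are flagged rather than fatal", {
  set.seed(2)
  X <- matrix(rnorm(60 * 3), 60, 3)
  Y <- cbind(rep(1, 60), X[, 1] + rnorm(60, sd = 0.1))
  r <- prcc(X, Y)
  expect_true(all(is.na(r$prcc[, 1])))
  expect_false(anyNA(r$prcc[, 2]))
})

test_that("the model-level analysis is reproducible under a fixed seed", {
  p <- default_parameters()
  a <- prcc_analysis(p, n_samples = 24, seed = 7,
                     quantities = c("CyclinB", "Mad2:Cdc20P"),
                     parameters = c("k_s1", "k_s8", "k_s17", "k_s33"))
  b <- prcc_analysis(p, n_samples = 24, seed = 7,
                     quantities = c("CyclinB", "Mad2:Cdc20P"),
                     parameters = c("k_s1", "k_s8", "k_s17", "k_s33"))
  expect_equal(a$prcc, b$prcc, tolerance = 1e-12)
  expect_true(all(abs(a$prcc$prcc) <= 1, na.rm = TRUE))
  expect_true(a$settings$unreliable == FALSE)
  # zero-valued parameters are excluded from variation
  sc <- scenario_params("null")
  d <- prcc_analysis(sc$params, n_samples = 12, seed = 1,
                     quantities = "CyclinB",
                     parameters = c("k_s28", "k_s1", "k_s8"),
                     init = sc$init)
  expect_identical(d$excluded, "k_s28")
})
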