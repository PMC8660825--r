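test_that("the fixture generator is seeded and reproducible", {
  a <- simulate_cell_lines(150, seed = 42)
  b <- simulate_cell_lines(150, seed = 42)
  expect_identical(a, b)
  c <- simulate_cell_lines(150, seed = 43)
  expect_false(identical(a, c))
})

test_that("the most frequently mutated gene forms the largest group", {
  rates <- default_mutation_rates()
  rates["TP53"] <- 0.6
  rates[names(rates) != "TP53"] <- pmin(rates[names(rates) != "TP53"], 0.2)
  lines <- simulate_cell_lines(1000, rates = rates, seed = 5)
  groups <- group_cell_lines(lines)
  singles <- groups[lengths(groups$genes) == 1, ]
  expect_identical(singles$label[which.max(singles$n_lines)], "TP53")
})

test_that("co-mutation counts respect exact binomial bounds", {
  n <- 2000
  rates <- c(TP53 = 0.5, ATM = 0.2)
  lines <- simulate_cell_lines(n, rates = rates, seed = 9)
  groups <- group_cell_lines(lines, pairs = list(c("ATM", "TP53")))
  obs <- groups$n_lines[groups$label == "ATM+TP53"]
  bounds <- qbinom(c(0.005, 0.995), n, 0.5 * 0.2)
  expect_gte(obs, bounds[1])
  expect_lte(obs, bounds[2])
})

test_that("rate validation rejects out-of-range values", {
  expect_error(simulate_cell_lines(10, rates = c(TP53 = 1.2)), "0, 1")
  expect_error(simulate_cell_lines(0), "n_lines")
})

test_that("mutation profiles zero nonessential genes and reduce essential ones", {
  p <- default_parameters()
  prof <- cell_line_params(p, c("TP53", "PLK1"))
  expect_equal(prof$params[["k_s28"]], 0)
  expect_equal(prof$params[["k_s12"]], 0.7 * p[["k_s12"]])
  expect_equal(unname(prof$init_overrides[["p53"]]), 0)
})

test_that("modelled cell-line groups keep cycling before any knockout", {
  lines <- simulate_cell_lines(300, seed = 3)
  groups <- group_cell_lines(lines)
  # spot-check the three structurally most aggressive profiles
  pick <- groups[groups$label %in% c("TP53", "PLK1", "ATM+TP53"), ]
  em <- essentiality_matrix(pick, targets = character(0))
  ctrl <- em[em$target == "control", ]
  expect_true(all(ctrl$viable))
})
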