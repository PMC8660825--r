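test_that("the registry defines 34 dynamic plus 16 derived quantities", {
  reg <- species_registry()
  expect_length(reg$dynamic, 34)
  expect_identical(anyDuplicated(reg$dynamic), 0L)
  expect_length(reg$derived, 16)
  expect_length(reg$reported, 50)
  expect_identical(reg$index_of("CyclinB"), 1L)
  expect_identical(reg$index_of("Mad2:Cdc20P"), 34L)
  expect_error(reg$index_of("nonexistent"), "unknown species")
})

test_that("derived totals equal brute-force sums over member species", {
  reg <- species_registry()
  tab <- conservation_table()
  set.seed(11)
  for (rep in 1:5) {
    y <- stats::setNames(runif(34, 0, 0.3), reg$dynamic)
    # keep the CDK1 closure valid
    y[c("MPF", "preMPF", "p21:MPF")] <- y[c("MPF", "preMPF", "p21:MPF")] / 4
    d <- derived_quantities(y)
    expect_length(d, 50)
    for (tn in reg$derived) {
      rows <- tab[tab$total_name == tn, ]
      manual <- sum(vapply(seq_len(nrow(rows)), function(j) {
        sp <- rows$member_species[j]
        rows$stoichiometry[j] * (if (sp == "1") 1 else y[[sp]])
      }, numeric(1)))
      expect_equal(unname(d[[tn]]), manual, tolerance = 1e-12)
    }
    expect_equal(unname(d[["CDK1_T"]]), 1)
  }
})

test_that("total CDK1 is 1 by construction, including edge states", {
  reg <- species_registry()
  y <- stats::setNames(rep(0, 34), reg$dynamic)
  y["MPF"] <- 1
  d <- derived_quantities(y)
  expect_equal(unname(d[["CDK1_T"]]), 1)
  expect_equal(unname(d[["CDK1"]]), 0)
  expect_equal(unname(d[["CyclinB_T"]]), 1)
})

test_that("p21 enters its pool total with stoichiometry 3 in the trimer complex", {
  reg <- species_registry()
  y <- stats::setNames(rep(0, 34), reg$dynamic)
  y["p21"] <- 0.1
  y["p21:MPF"] <- 0.05
  d <- derived_quantities(y)
  expect_equal(unname(d[["p21_T"]]), 0.1 + 3 * 0.05)
})
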