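test_that("every mapped gene resolves to a real parameter", {
  gm <- gene_map()
  expect_true(all(gm$parameter %in% param_symbols()))
  expect_setequal(unique(gm$parameter),
                  c(synthesis_parameters()))
})

test_that("TP53 deletion zeroes synthesis and the initial condition", {
  m <- make_mutant(default_parameters(), "TP53", "deletion")
  expect_equal(m$params[["k_s28"]], 0)
  expect_equal(unname(m$init_overrides[["p53"]]), 0)
})

test_that("family paralogs are scaled while full family loss is zeroed", {
  p <- default_parameters()
  m1 <- make_mutant(p, "CCNB1", "crispr")
  expect_equal(m1$params[["k_s1"]], 0.5 * p[["k_s1"]])
  m2 <- make_mutant(p, c("CCNB1", "CCNB2"), "deletion")
  expect_equal(m2$params[["k_s1"]], 0)
  # APC/C subunit knockout disrupts the whole complex
  m3 <- make_mutant(p, "CDC27", "crispr")
  expect_equal(m3$params[["k_s15"]], 0)
})

test_that("multi-gene edits compose like sequential single edits", {
  p <- default_parameters()
  both <- make_mutant(p, c("CDH1", "MAD2L1"), "deletion")
  expect_equal(both$params[["k_s20"]], 0)
  expect_equal(both$params[["k_s33"]], 0)
  seq1 <- make_mutant(p, "CDH1", "deletion")
  seq2 <- make_mutant(seq1$params, "MAD2L1", "deletion")
  expect_equal(as.numeric(both$params), as.numeric(seq2$params))
})

test_that("depletion scales the synthesis rate by one minus the level", {
  p <- default_parameters()
  m <- make_mutant(p, "PLK1", "depletion", level = 0.7)
  expect_equal(m$params[["k_s12"]], 0.3 * p[["k_s12"]])
  expect_error(make_mutant(p, "PLK1", "depletion", level = 1.5), "level")
  expect_error(make_mutant(p, "PLK1", "depletion"), "level")
})

test_that("unknown genes are rejected by name", {
  expect_error(make_mutant(default_parameters(), "NOPE1", "deletion"),
               "NOPE1")
})

test_that("scenario construction matches its label", {
  sc <- scenario_params("null", 0.45)
  expect_equal(sc$params[["k_s28"]], 0)
  expect_equal(unname(sc$init[["p53"]]), 0)
  expect_equal(sc$params[["k_s12"]],
               default_parameters()[["k_s12"]] * 0.55)
  expect_match(sc$label, "p53-null")
  expect_match(sc$label, "45")
})

test_that("the response surface dies without Mad2 synthesis", {
  p <- default_parameters()
  rs <- response_surface(k_s28_grid = p[["k_s28"]],
                         k_s12_grid = p[["k_s12"]],
                         k_s33_grid = 0, params = p)
  expect_lt(rs$mad2cdc20p_mean, 0.02)
})
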