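test_that("the parameter set has exactly 137 kinetic constants plus tau", {
  syms <- param_symbols()
  expect_length(syms, 138)
  expect_identical(syms[138], "tau")
  expect_identical(anyDuplicated(syms), 0L)
  p <- default_parameters()
  expect_s3_class(p, "param_set")
  expect_length(p, 138)
  expect_equal(p[["tau"]], 1.65)
  expect_true(all(p >= 0))
})

test_that("parameter tables round-trip losslessly through CSV and YAML", {
  p <- default_parameters()
  for (ext in c(".csv", ".yml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_parameters(p, path)
    p2 <- read_parameters(path)
    expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-12)
    expect_identical(names(p2), names(p))
  }
})

test_that("missing, unknown and invalid entries are reported by name", {
  p <- default_parameters()
  broken <- as.numeric(p)
  names(broken) <- names(p)
  broken <- broken[names(broken) != "k_s28"]
  expect_error(as_param_set(broken), "k_s28")

  extra <- c(stats::setNames(as.numeric(p), names(p)), bogus = 1)
  expect_error(as_param_set(extra), "bogus")

  neg <- p
  neg[["k_s1"]] <- -1
  expect_error(validate_parameters(neg), "k_s1")

  zt <- p
  zt[["tau"]] <- 0
  expect_error(validate_parameters(zt), "tau")
})

test_that("the bundled table carries one value per canonical symbol", {
  path <- system.file("extdata", "parameters_synthetic.csv",
                      package = "g2mcycle")
  tab <- read.csv(path)
  expect_setequal(tab$symbol, param_symbols())
  expect_identical(nrow(tab), 138L)
})
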