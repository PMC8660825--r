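#' Canonical parameter symbols
#'
#' The model has exactly 137 kinetic constants plus the dimensionless
#' timescale `tau`. Symbols follow the field's conventions: `k_s*` synthesis
#' rates, `k_f*`/`k_r*` forward/reverse rate constants of the interaction
#' reactions, `k_d*` degradation rate constants (a `.2` suffix marks
#' degradation mediated by APC/CP:Cdc20, `.3` by APC/CT:Cdh1), `K_*`
#' Michaelis/threshold constants, and the weighting factors of the
#' Mad2:Cdc20P disassembly term. All rates are h^-1 on the relative
#' concentration scale (total CDK1 = 1).
#'
#' @return Character vector of the 138 parameter symbols in canonical order
#'   (`tau` last).
#' @export
param_symbols <- function() {
  c(
    # -- synthesis rates (15 synthesis reactions + 2 p53-induced terms)
    "k_s1", "k_s5", "k_s8", "k_s9", "k_s12", "k_s13", "k_s15", "k_s17",
    "k_s20", "k_s24", "k_s27", "k_s28", "k_s31", "k_s32", "k_s33",
    "k_s31.1", "k_s32.1",
    # -- interaction reactions
    "k_f1", "k_r1",
    "k_f2", "k_f2.1", "k_r2", "k_r2.1",
    "k_f3", "k_r3",
    "k_f4", "k_r4", "k_r4.1",
    "k_f5", "k_r5",
    "k_f6p", "k_r6",
    "k_f7", "k_r7",
    "k_f8", "k_r8",
    "k_f9", "k_r9",
    "k_f10", "k_r10", "k_r10.1",
    "k_f11", "k_r11",
    "k_f12", "k_r12", "k_r12.1", "k_r12.2",
    "k_f13", "k_r13",
    "k_f14", "k_r14",
    "k_f16", "k_r16",
    "k_f17", "k_r17",
    "k_f18", "k_r18p",
    "k_f19",
    # -- degradations
    "k_d1", "k_d1.2", "k_d1.3",
    "k_d2.2", "k_d3.2", "k_d4.2",
    "k_d5",
    "k_d6.1", "k_d6.3",
    "k_d7.1",
    "k_d8.1", "k_d8.3",
    "k_d9.1", "k_d9.3",
    "k_d10",
    "k_d11.1", "k_d11.3",
    "k_d12", "k_d12.3",
    "k_d13",
    "k_d15",
    "k_d17.1", "k_d17.3",
    "k_d18.1", "k_d18.3",
    "k_d19.3",
    "k_d20", "k_d21",
    "k_d24.1", "k_d24.2", "k_d25.2",
    "k_d27", "k_d27.1",
    "k_d28", "k_d28.1",
    "k_d29", "k_d29.1",
    "k_d30.1",
    "k_d31", "k_d31.1",
    "k_d32", "k_d33",
    # -- Michaelis / threshold constants and weights
    "K_p53", "K_A1", "K_A2", "K_A3",
    "K_Cdc25P1", "K_Cdc25P2", "K_Cdc25",
    "K_Wee1", "K_Wee1P",
    "K_Plk1P1", "K_Plk1P2", "K_Plk1",
    "K_Cdc20P1", "K_Cdc20P2", "K_Cdc20",
    "K_CycB1", "K_CycB2", "K_MPF", "K_preMPF", "K_p21MPF",
    "K_APC20", "K_Pttg1", "K_PtSep", "K_Emi1",
    "K_Wee1f", "K_APC", "K_APP", "K_Cdh1", "K_APCH", "K_Cdh1P", "K_Sep",
    "K_Wip1", "K_MCD", "K_DDS",
    "eps_MCD",
    "Emi1_tot", "Sep_tot",
    # -- timescale
    "tau"
  )
}

#' Number of kinetic parameters (excluding tau)
#' @noRd
N_KINETIC <- 137L

new_param_set <- function(x) {
  structure(x, class = c("param_set", "numeric"))
}

#' Read a parameter table
#'
#' Parses a flat two-column `symbol,value` CSV (or a YAML mapping) into a
#' validated parameter set. The file must contain one value for every
#' canonical symbol; missing or unknown symbols are reported by name.
#'
#' @param path Path to a CSV file with columns `symbol,value`, or a YAML
#'   file mapping symbols to values (extension `.yml`/`.yaml`).
#' @return A `param_set`: a named numeric vector of length 138 in canonical
#'   order with `tau` last.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("parameter table not found: ", path, call. = FALSE)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    vals <- vapply(lst, as.numeric, numeric(1))
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           comment.char = "#", strip.white = TRUE)
    if (!all(c("symbol", "value") %in% names(tab))) {
      stop("parameter table must have columns 'symbol' and 'value'",
           call. = FALSE)
    }
    vals <- stats::setNames(as.numeric(tab$value), tab$symbol)
  }
  as_param_set(vals)
}

#' Coerce a named numeric vector to a parameter set
#'
#' @param x Named numeric vector covering all canonical symbols.
#' @return A validated `param_set` in canonical order.
#' @export
as_param_set <- function(x) {
  syms <- param_symbols()
  missing <- setdiff(syms, names(x))
  if (length(missing) > 0) {
    stop("missing parameter symbol(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), syms)
  if (length(extra) > 0) {
    stop("unknown parameter symbol(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  ps <- new_param_set(as.numeric(x[syms]))
  names(ps) <- syms
  validate_parameters(ps)
  ps
}

#' Validate a parameter set
#'
#' Checks completeness (137 kinetic constants plus `tau`), non-negativity,
#' and `tau > 0`.
#'
#' @param params A `param_set`.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.numeric(params))
  if (length(params) != N_KINETIC + 1L) {
    stop("parameter set must contain exactly ", N_KINETIC,
         " kinetic constants plus tau", call. = FALSE)
  }
  bad <- names(params)[!is.finite(params) | params < 0]
  if (length(bad) > 0) {
    stop("parameter(s) negative or non-finite: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (params[["tau"]] <= 0) stop("tau must be > 0", call. = FALSE)
  invisible(params)
}

#' Default (calibrated) parameter set
#'
#' Loads the bundled parameter table. The bundled values are a synthetic
#' reconstruction: the checkpoint equations' constants and the mitotic-core
#' constants were calibrated so that the model reproduces the reference
#' behaviors of the published system (48 h wild-type cycle at `tau = 1.65`,
#' checkpoint-oscillator period, knockout viability pattern, Plk1-depletion
#' arrest thresholds); see the package vignette.
#'
#' @param file Optional path to an alternative parameter table.
#' @return A `param_set` with `tau = 1.65`.
#' @export
default_parameters <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "parameters_synthetic.csv",
                        package = "g2mcycle", mustWork = TRUE)
  }
  read_parameters(file)
}

#' Write a parameter table
#'
#' Writes `symbol,value` CSV (or YAML) that round-trips losslessly through
#' [read_parameters()].
#'
#' @param params A `param_set`.
#' @param path Output path (`.csv`, `.yml` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(as.list(stats::setNames(as.numeric(params),
                                             names(params))), path,
                     precision = 17L)
  } else {
    utils::write.csv(
      data.frame(symbol = names(params),
                 value = formatC(as.numeric(params), digits = 17,
                                 format = "g"),
                 stringsAsFactors = FALSE),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> ", N_KINETIC, " kinetic constants + tau = ",
      format(x[["tau"]]), "\n", sep = "")
  print(tibble::tibble(symbol = names(x), value = as.numeric(x)), ...)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.param_set <- function(x, ...) {
  tibble::tibble(symbol = names(x), value = as.numeric(x))
}

#' Symbols of the 15 synthesis-rate constants
#'
#' These control synthesis of Cyclin B, p21, Cdc25, Wee1, Plk1, PP2A, APC/C,
#' Cdc20, Cdh1, Pttg1, ATM/ATR, p53, Mdm2, Wip1 and Mad2, and are the
#' parameters varied in the fuzzy uncertainty analysis.
#'
#' @return Character vector of length 15.
#' @export
synthesis_parameters <- function() {
  c("k_s1", "k_s5", "k_s8", "k_s9", "k_s12", "k_s13", "k_s15", "k_s17",
    "k_s20", "k_s24", "k_s27", "k_s28", "k_s31", "k_s32", "k_s33")
}
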