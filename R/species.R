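#' Species registry
#'
#' The model tracks 34 dynamic species (relative concentrations, normalized
#' to total CDK1 = 1). Sixteen additional reported quantities are defined by
#' conservation laws / pool totals, giving 50 reported quantities in all.
#'
#' @return An object of class `species_registry` with elements
#'   `dynamic` (34 names, in state-vector order), `derived` (16 names),
#'   `reported` (all 50), and `index_of(name)`.
#' @export
species_registry <- function() {
  dynamic <- c(
    "CyclinB", "MPF", "preMPF", "p21:MPF", "p21",
    "Cdc25P", "Wee1P", "Cdc25", "Wee1",
    "PP2AP", "Plk1P", "Plk1", "PP2A",
    "Emi1", "APC/C", "APC/CP", "Cdc20", "Cdc20P",
    "APC/CP:Cdc20", "Cdh1", "Cdh1P", "APC/CT:Cdh1",
    "Separase", "Pttg1", "Pttg1:Separase", "Emi1P",
    "ATM/ATR", "p53", "p53P", "p53P:Plk1P",
    "Mdm2", "Wip1", "Mad2", "Mad2:Cdc20P")
  derived <- c(
    "CDK1", "CDK1_T", "CyclinB_T", "p21_T", "Cdc25_T", "Wee1_T",
    "Plk1_T", "PP2A_T", "APC_T", "Cdc20_T", "Cdh1_T", "Emi1_T",
    "Separase_T", "Pttg1_T", "p53_T", "Mad2_T")
  idx <- stats::setNames(seq_along(dynamic), dynamic)
  structure(
    list(dynamic = dynamic, derived = derived,
         reported = c(dynamic, derived),
         index_of = function(name) {
           i <- idx[name]
           if (anyNA(i)) stop("unknown species: ",
                              paste(name[is.na(i)], collapse = ", "),
                              call. = FALSE)
           unname(i)
         }),
    class = "species_registry")
}

#' @export
print.species_registry <- function(x, ...) {
  cat("<species_registry> 34 dynamic + 16 derived = 50 reported quantities\n")
  cat("dynamic:", paste(x$dynamic, collapse = ", "), "\n")
  cat("derived:", paste(x$derived, collapse = ", "), "\n")
  invisible(x)
}

#' Conservation-law membership table
#'
#' Defines each derived quantity as a stoichiometry-weighted sum over member
#' species (plus a constant offset for the free-CDK1 closure: free CDK1 is
#' `1 - MPF - preMPF - p21:MPF` by the normalization convention). Only
#' `CDK1_T`, `Emi1_T` and `Separase_T` are true constants of motion; the
#' other pool totals have synthesis/degradation turnover and are reported
#' quantities, not invariants.
#'
#' @param file Optional path to an alternative membership CSV with columns
#'   `total_name,member_species,stoichiometry`.
#' @return A tibble with columns `total_name`, `member_species`,
#'   `stoichiometry`, plus attribute `offset` (named numeric) and
#'   `conserved` (names of the true constants of motion).
#' @export
conservation_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "conservation_synthetic.csv",
                        package = "g2mcycle", mustWork = TRUE)
  }
  tab <- readr::read_csv(file, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("total_name", "member_species", "stoichiometry")
                %in% names(tab)))
  reg <- species_registry()
  bad <- setdiff(tab$member_species, c(reg$dynamic, "1"))
  if (length(bad) > 0) {
    stop("membership table references unknown species: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  structure(tab,
            conserved = c("CDK1_T", "Emi1_T", "Separase_T"))
}

#' Expand a dynamic state to the 50 reported quantities
#'
#' Concatenates the 34 dynamic concentrations with the 16 conservation-law /
#' pool totals. The total-CDK1 entry is exactly 1 by construction.
#'
#' @param state Named numeric vector of the 34 dynamic species (or a matrix
#'   with 34 named columns).
#' @param params Parameter set (accepted for interface symmetry; totals are
#'   purely structural).
#' @return Named numeric vector of length 50 (or a 50-column matrix).
#' @export
derived_quantities <- function(state, params = NULL) {
  reg <- species_registry()
  tab <- conservation_table()
  one_row <- is.null(dim(state))
  m <- if (one_row) matrix(state, nrow = 1,
                           dimnames = list(NULL, names(state)))
       else state
  if (!all(reg$dynamic %in% colnames(m))) {
    stop("state must contain all 34 dynamic species", call. = FALSE)
  }
  m <- m[, reg$dynamic, drop = FALSE]
  out <- matrix(0, nrow(m), length(reg$derived),
                dimnames = list(NULL, reg$derived))
  for (tn in reg$derived) {
    rows <- tab[tab$total_name == tn, ]
    acc <- numeric(nrow(m))
    for (j in seq_len(nrow(rows))) {
      sp <- rows$member_species[j]
      acc <- acc + rows$stoichiometry[j] *
        (if (sp == "1") rep(1, nrow(m)) else m[, sp])
    }
    out[, tn] <- acc
  }
  res <- cbind(m, out)
  if (one_row) res[1, ] else res
}
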