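#' Gene-to-parameter map
#'
#' Maps the 15 model genes/families to the synthesis-rate constants of their
#' model components. `family = TRUE` marks genes that share a lumped model
#' component with at least one paralog (CCNB1/CCNB2, CDC25A/CDC25B, ATM/ATR):
#' a CRISPR knockout of one paralog reduces, rather than zeroes, the shared
#' synthesis rate. `complex = TRUE` marks APC/C subunit genes: perturbation
#' of any subunit disrupts the whole complex, so their knockout zeroes the
#' APC/C synthesis rate.
#'
#' @param apc_subunits Character vector of APC/C subunit gene symbols mapped
#'   to the APC/C component (configurable; defaults to the three named
#'   examples).
#' @return Tibble with columns `gene`, `component`, `parameter`, `family`,
#'   `complex`.
#' @export
gene_map <- function(apc_subunits = c("ANAPC1", "CDC27", "CDC23", "CDC16")) {
  base <- tibble::tribble(
    ~gene,     ~component, ~parameter, ~family, ~complex,
    "CCNB1",   "CyclinB",  "k_s1",     TRUE,    FALSE,
    "CCNB2",   "CyclinB",  "k_s1",     TRUE,    FALSE,
    "CDKN1A",  "p21",      "k_s5",     FALSE,   FALSE,
    "CDC25A",  "Cdc25",    "k_s8",     TRUE,    FALSE,
    "CDC25B",  "Cdc25",    "k_s8",     TRUE,    FALSE,
    "WEE1",    "Wee1",     "k_s9",     FALSE,   FALSE,
    "PLK1",    "Plk1",     "k_s12",    FALSE,   FALSE,
    "PP2A",    "PP2A",     "k_s13",    FALSE,   FALSE,
    "CDC20",   "Cdc20",    "k_s17",    FALSE,   FALSE,
    "CDH1",    "Cdh1",     "k_s20",    FALSE,   FALSE,
    "PTTG1",   "Pttg1",    "k_s24",    FALSE,   FALSE,
    "ATM",     "ATM/ATR",  "k_s27",    TRUE,    FALSE,
    "ATR",     "ATM/ATR",  "k_s27",    TRUE,    FALSE,
    "TP53",    "p53",      "k_s28",    FALSE,   FALSE,
    "MDM2",    "Mdm2",     "k_s31",    FALSE,   FALSE,
    "PPM1D",   "Wip1",     "k_s32",    FALSE,   FALSE,
    "MAD2L1",  "Mad2",     "k_s33",    FALSE,   FALSE)
  apc <- tibble::tibble(gene = apc_subunits, component = "APC/C",
                        parameter = "k_s15", family = FALSE, complex = TRUE)
  out <- dplyr::bind_rows(base, apc)
  stopifnot(all(out$parameter %in% param_symbols()))
  out
}

#' Genes whose loss arrests the cell cycle in this model
#'
#' Used by the cancer-cell-line mutation convention: a mutated essential
#' gene is modelled with a reduced synthesis rate (the line must keep
#' cycling), a mutated nonessential gene with a zeroed one.
#'
#' @return Character vector of gene symbols.
#' @export
essential_genes <- function() {
  gm <- gene_map()
  ess_par <- c("k_s1", "k_s8", "k_s9", "k_s12", "k_s13", "k_s15", "k_s17",
               "k_s20")
  gm$gene[gm$parameter %in% ess_par]
}

#' Build a mutant parameter set
#'
#' Translates gene-level perturbations into parameter edits following the
#' synthesis-rate convention: a deletion or CRISPR knockout of a uniquely
#' mapped gene sets its synthesis constant to zero; knocking out one paralog
#' of a family-mapped gene scales the shared constant by `family_factor`
#' (knocking out *all* paralogs of a family zeroes it); APC/C subunit
#' knockouts zero the APC/C synthesis rate (complex disruption). TP53 loss
#' additionally sets the p53 initial condition to zero. `depletion` scales
#' the synthesis rate to `(1 - level)` of its current value. Edits compose
#' across genes; contradictory edits to the same symbol raise an error.
#'
#' @param base A `param_set` to edit.
#' @param genes Character vector of gene symbols (see [gene_map()]).
#' @param mode One of `"deletion"`, `"crispr"`, `"depletion"`.
#' @param level Depletion level in `[0, 1]` (required for
#'   `mode = "depletion"`).
#' @param family_factor Scaling applied per lost paralog of a family gene
#'   (default 0.5).
#' @param map Gene map (see [gene_map()]).
#' @return A `mutant_spec`: list with `params` (edited `param_set`),
#'   `init_overrides` (named numeric), `label`, and `edits` (tibble).
#' @export
make_mutant <- function(base, genes, mode = c("deletion", "crispr",
                                              "depletion"),
                        level = NULL, family_factor = 0.5,
                        map = gene_map()) {
  mode <- match.arg(mode)
  unknown <- setdiff(genes, map$gene)
  if (length(unknown) > 0) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (mode == "depletion") {
    if (is.null(level) || level < 0 || level > 1) {
      stop("depletion requires a level in [0, 1]", call. = FALSE)
    }
  }
  params <- base
  init_overrides <- numeric(0)
  edits <- list()
  rows <- map[map$gene %in% genes, ]
  for (par in unique(rows$parameter)) {
    sub <- rows[rows$parameter == par, ]
    if (mode == "depletion") {
      action <- "scale"; value <- 1 - level
    } else if (any(sub$complex)) {
      action <- "set_zero"; value <- 0
    } else if (any(sub$family)) {
      fam_all <- map$gene[map$parameter == par]
      if (all(fam_all %in% genes)) {
        action <- "set_zero"; value <- 0
      } else {
        action <- "scale"; value <- family_factor^nrow(sub)
      }
    } else {
      action <- "set_zero"; value <- 0
    }
    params[par] <- if (action == "set_zero") 0 else params[par] * value
    edits[[length(edits) + 1L]] <- tibble::tibble(
      parameter = par, action = action, value = value)
  }
  if ("TP53" %in% genes && mode != "depletion") {
    init_overrides <- c(init_overrides, "p53" = 0)
  }
  structure(
    list(params = params, init_overrides = init_overrides,
         label = paste0(paste(genes, collapse = "+"), "-", mode,
                        if (mode == "depletion") sprintf("(%d%%)",
                                                         round(level * 100))
                        else ""),
         edits = dplyr::bind_rows(edits)),
    class = "mutant_spec")
}

#' @export
print.mutant_spec <- function(x, ...) {
  cat("<mutant_spec>", x$label, "\n")
  print(x$edits)
  invisible(x)
}

#' Apply initial-condition overrides
#' @noRd
apply_overrides <- function(init, overrides) {
  for (nm in names(overrides)) init[nm] <- overrides[nm]
  init
}

#' Scenario parameter sets
#'
#' Builds the standard study backgrounds: p53 wild-type or null (p53
#' synthesis zeroed and p53 started at zero) crossed with a fractional Plk1
#' synthesis-rate depletion.
#'
#' @param p53 `"wt"` or `"null"`.
#' @param plk1_depletion Fractional reduction of `k_s12` in `[0, 1]`.
#' @param params Base `param_set`.
#' @param init Base initial state.
#' @return List with `params`, `init`, `label`.
#' @export
scenario_params <- function(p53 = c("wt", "null"), plk1_depletion = 0,
                            params = default_parameters(),
                            init = default_initial_state()) {
  p53 <- match.arg(p53)
  stopifnot(plk1_depletion >= 0, plk1_depletion <= 1)
  if (p53 == "null") {
    params["k_s28"] <- 0
    init["p53"] <- 0
  }
  params["k_s12"] <- params["k_s12"] * (1 - plk1_depletion)
  list(params = params, init = init,
       label = sprintf("p53-%s%s", p53,
                       if (plk1_depletion > 0)
                         sprintf(" Plk1-depleted %d%%",
                                 round(plk1_depletion * 100)) else ""))
}

#' Plk1-depletion scan
#'
#' Simulates 10--100% reductions of the Plk1 synthesis rate in a p53
#' wild-type or null background and reports viability and the cell cycle
#' period normalized to the unperturbed cell of the same background.
#'
#' @param background `"p53-wt"` or `"p53-null"`.
#' @param levels Depletion levels in `(0, 1]`.
#' @param params Base `param_set`.
#' @param t_end Simulation length per level (h).
#' @return Tibble with columns `level`, `viable`, `period_h`,
#'   `normalized_period`, `arrest_class`, `mad2cdc20p_mean`, `background`;
#'   class `depletion_scan`.
#' @export
plk1_depletion_scan <- function(background = c("p53-wt", "p53-null"),
                                levels = seq(0.1, 1, by = 0.1),
                                params = default_parameters(),
                                t_end = 400) {
  background <- match.arg(background)
  sc0 <- scenario_params(ifelse(background == "p53-null", "null", "wt"),
                         0, params)
  ref_sim <- simulate_cycle(sc0$params, init = sc0$init, t_end = t_end)
  ref_per <- estimate_period(ref_sim)
  wtpk <- wt_reference(params)$mpf_peak
  rows <- purrr::map(levels, function(lev) {
    sc <- scenario_params(ifelse(background == "p53-null", "null", "wt"),
                          lev, params)
    ph <- tryCatch({
      sim <- simulate_cycle(sc$params, init = sc$init, t_end = t_end)
      classify_phenotype(sim, ref_per, wt_mpf_peak = wtpk)
    }, error = function(e) {
      tibble::tibble(viable = NA, period_h = NA_real_, tm_over_t = NA_real_,
                     arrest_class = paste("error:", conditionMessage(e)),
                     mad2cdc20p_mean = NA_real_)
    })
    tibble::tibble(level = lev, viable = ph$viable, period_h = ph$period_h,
                   normalized_period = ph$period_h / ref_per,
                   arrest_class = ph$arrest_class,
                   mad2cdc20p_mean = ph$mad2cdc20p_mean)
  })
  out <- dplyr::bind_rows(rows)
  out$background <- background
  class(out) <- c("depletion_scan", class(out))
  out
}

#' Smallest arresting depletion level
#'
#' @param scan A `depletion_scan`.
#' @return Smallest level with an inviable call, or `NA` if none.
#' @export
arrest_threshold <- function(scan) {
  lev <- scan$level[!scan$viable %in% TRUE]
  if (length(lev) == 0) NA_real_ else min(lev)
}

#' Mad2:Cdc20P response surface
#'
#' Evaluates the time-averaged Mad2:Cdc20P concentration over a grid of the
#' p53 (`k_s28`), Plk1 (`k_s12`) and Mad2 (`k_s33`) synthesis rates.
#'
#' @param k_s28_grid,k_s12_grid,k_s33_grid Non-negative grid values; the
#'   defaults span zero to the nominal rate (and up to 0.1 for `k_s33`, the
#'   high-Mad2 end).
#' @param params Base `param_set`.
#' @param t_end Simulation length (h); the mean is taken over the assessment
#'   window after `burn_in`.
#' @param burn_in Hours discarded.
#' @return Tibble `(k_s28, k_s12, k_s33, mad2cdc20p_mean)`; failed points
#'   carry `NA`.
#' @export
response_surface <- function(k_s28_grid = NULL, k_s12_grid = NULL,
                             k_s33_grid = NULL,
                             params = default_parameters(),
                             t_end = 250, burn_in = 100) {
  if (is.null(k_s28_grid)) k_s28_grid <- seq(0, params[["k_s28"]], length.out = 3)
  if (is.null(k_s12_grid)) k_s12_grid <- seq(0, params[["k_s12"]], length.out = 3)
  if (is.null(k_s33_grid)) k_s33_grid <- seq(0, 0.1, length.out = 3)
  stopifnot(all(k_s28_grid >= 0), all(k_s12_grid >= 0), all(k_s33_grid >= 0))
  grid <- expand.grid(k_s28 = k_s28_grid, k_s12 = k_s12_grid,
                      k_s33 = k_s33_grid)
  init <- default_initial_state()
  vals <- purrr::pmap_dbl(grid, function(k_s28, k_s12, k_s33) {
    p <- params
    p["k_s28"] <- k_s28; p["k_s12"] <- k_s12; p["k_s33"] <- k_s33
    y <- init
    if (k_s28 == 0) y["p53"] <- 0
    tryCatch({
      sim <- simulate_cycle(p, init = y, t_end = t_end)
      tr <- sim$trajectories
      mean(tr[["Mad2:Cdc20P"]][tr$time >= burn_in])
    }, error = function(e) NA_real_)
  })
  out <- tibble::as_tibble(grid)
  out$mad2cdc20p_mean <- vals
  out
}

#' Standard deletion-mutant panel
#'
#' The single- and double-gene deletion mutants whose phenotypes the model
#' predicts, with the gene sets expressed through [gene_map()] symbols
#' ("-null" means complete loss of the family).
#'
#' @return Tibble with columns `label`, `genes` (list-column).
#' @export
deletion_mutant_panel <- function() {
  tibble::tibble(
    label = c("cyclinB-null", "p21-null", "cdc25-null", "wee1-null",
              "plk1-null", "PP2A-null", "APC-null", "cdc20-null",
              "cdh1-null", "pttg1-null", "ATM-null", "p53-null",
              "mad2-null",
              "cdh1-null p21-null", "p21-null PP2A-null",
              "p21-null wee1-null", "p21-null pttg1-null",
              "cdh1-null mad2-null", "cdc20-null pttg1-null",
              "cdc20-null mad2-null", "PP2A-null mad2-null",
              "PP2A-null pttg1-null", "cdc25-null wee1-null"),
    genes = list(
      c("CCNB1", "CCNB2"), "CDKN1A", c("CDC25A", "CDC25B"), "WEE1",
      "PLK1", "PP2A", "ANAPC1", "CDC20", "CDH1", "PTTG1", "ATM", "TP53",
      "MAD2L1",
      c("CDH1", "CDKN1A"), c("CDKN1A", "PP2A"), c("CDKN1A", "WEE1"),
      c("CDKN1A", "PTTG1"), c("CDH1", "MAD2L1"), c("CDC20", "PTTG1"),
      c("CDC20", "MAD2L1"), c("PP2A", "MAD2L1"), c("PP2A", "PTTG1"),
      c("CDC25A", "CDC25B", "WEE1")))
}

#' Mutant phenotype table
#'
#' Classifies each mutant in each background (p53 wild-type/null crossed
#' with normal/depleted Plk1) with the mutant-to-reference period ratio
#' computed against that background's unperturbed reference.
#'
#' @param mutants Tibble like [deletion_mutant_panel()].
#' @param backgrounds Character vector drawn from
#'   `c("p53-wt", "p53-null", "p53-wt depleted", "p53-null depleted")`.
#' @param depletion Plk1 depletion applied in the depleted backgrounds
#'   (default 0.3).
#' @param params Base `param_set`.
#' @param t_end Simulation length per cell (h).
#' @return Tibble `(label, background, viable, period_h, tm_over_t,
#'   arrest_class, mad2cdc20p_mean)`.
#' @export
mutant_table <- function(mutants = deletion_mutant_panel(),
                         backgrounds = c("p53-wt", "p53-null",
                                         "p53-wt depleted",
                                         "p53-null depleted"),
                         depletion = 0.3,
                         params = default_parameters(), t_end = 400) {
  wtpk <- wt_reference(params)$mpf_peak
  bg_setup <- purrr::map(backgrounds, function(bg) {
    sc <- scenario_params(ifelse(grepl("null", bg), "null", "wt"),
                          ifelse(grepl("depleted", bg), depletion, 0),
                          params)
    sim <- simulate_cycle(sc$params, init = sc$init, t_end = t_end)
    sc$ref_period <- estimate_period(sim)
    sc
  })
  names(bg_setup) <- backgrounds
  rows <- list()
  for (i in seq_len(nrow(mutants))) {
    for (bg in backgrounds) {
      sc <- bg_setup[[bg]]
      row <- tryCatch({
        mut <- make_mutant(sc$params, mutants$genes[[i]], mode = "deletion")
        init <- apply_overrides(sc$init, mut$init_overrides)
        sim <- simulate_cycle(mut$params, init = init, t_end = t_end)
        ph <- classify_phenotype(sim, sc$ref_period, wt_mpf_peak = wtpk)
        tibble::tibble(label = mutants$label[i], background = bg,
                       viable = ph$viable, period_h = ph$period_h,
                       tm_over_t = ph$tm_over_t,
                       arrest_class = ph$arrest_class,
                       mad2cdc20p_mean = ph$mad2cdc20p_mean)
      }, error = function(e) {
        tibble::tibble(label = mutants$label[i], background = bg,
                       viable = NA, period_h = NA_real_,
                       tm_over_t = NA_real_,
                       arrest_class = paste("error:", conditionMessage(e)),
                       mad2cdc20p_mean = NA_real_)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
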