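#' Default per-gene mutation rates for the synthetic cell-line fixture
#'
#' Marginal mutation frequencies chosen to mimic the qualitative structure
#' of large cancer-cell-line panels: TP53 by far the most frequent, ATM and
#' ATR next, the rest rarer. Genes are mutated independently, so co-mutated
#' lines (e.g. ATM+TP53) arise at approximately the product frequency.
#'
#' @return Named numeric vector of Bernoulli rates in `[0, 1]`.
#' @export
default_mutation_rates <- function() {
  c(TP53 = 0.62, ATM = 0.15, ATR = 0.11, CCNB1 = 0.03, CCNB2 = 0.03,
    CDKN1A = 0.04, CDC25A = 0.03, CDC25B = 0.03, WEE1 = 0.04, PLK1 = 0.02,
    PP2A = 0.04, ANAPC1 = 0.03, CDC20 = 0.03, CDH1 = 0.04, PTTG1 = 0.03,
    MDM2 = 0.05, PPM1D = 0.04, MAD2L1 = 0.03)
}

#' Generate a synthetic cancer-cell-line mutation table
#'
#' Seeded generator emulating a mutation export from a cancer dependency
#' screen: one row per (cell line, mutated gene). This synthetic fixture
#' stands in for real database retrieval, which is out of scope; an adapter
#' only needs to produce the same `(cell_line_id, gene, mutation_flag)`
#' schema.
#'
#' @param n_lines Number of cell lines (>= 1).
#' @param rates Named per-gene mutation rates in `[0, 1]`.
#' @param seed Integer seed; the output is reproducible byte-for-byte.
#' @return Tibble `(cell_line_id, gene, mutation_flag)` with
#'   `mutation_flag = 1` rows only.
#' @export
simulate_cell_lines <- function(n_lines = 200,
                                rates = default_mutation_rates(),
                                seed = 1) {
  if (n_lines < 1) stop("n_lines must be >= 1", call. = FALSE)
  if (any(rates < 0 | rates > 1)) {
    stop("mutation rates must lie in [0, 1]", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ids <- sprintf("LINE%04d", seq_len(n_lines))
  rows <- purrr::map(names(rates), function(g) {
    hit <- stats::runif(n_lines) < rates[[g]]
    tibble::tibble(cell_line_id = ids[hit], gene = g, mutation_flag = 1L)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$cell_line_id, .data$gene)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Group cell lines by mutated model gene
#'
#' Builds the single-gene groups (one per model gene present in the table)
#' plus optional co-mutation pair groups.
#'
#' @param lines Mutation table from [simulate_cell_lines()] (or an adapter
#'   with the same schema).
#' @param pairs List of character pairs for double-mutant groups (default
#'   ATM+TP53 and PLK1+TP53, frequent co-mutations).
#' @return Tibble `(label, genes, n_lines)`, `genes` a list-column.
#' @export
group_cell_lines <- function(lines,
                             pairs = list(c("ATM", "TP53"),
                                          c("PLK1", "TP53"))) {
  stopifnot(all(c("cell_line_id", "gene", "mutation_flag") %in% names(lines)))
  genes <- sort(unique(lines$gene[lines$mutation_flag == 1]))
  singles <- purrr::map(genes, function(g) {
    tibble::tibble(label = g, genes = list(g),
                   n_lines = dplyr::n_distinct(
                     lines$cell_line_id[lines$gene == g &
                                          lines$mutation_flag == 1]))
  })
  doubles <- purrr::map(pairs, function(pr) {
    ids <- purrr::map(pr, function(g)
      lines$cell_line_id[lines$gene == g & lines$mutation_flag == 1])
    tibble::tibble(label = paste(pr, collapse = "+"), genes = list(pr),
                   n_lines = length(Reduce(intersect, ids)))
  })
  out <- dplyr::bind_rows(c(singles, doubles))
  out[out$n_lines > 0, ]
}

#' Parameter edits representing a cell-line mutation profile
#'
#' A mutated gene that is nonessential for cell cycle progression is
#' modelled with its synthesis rate set to zero; a mutated essential gene is
#' modelled with a reduced rate (default 70% of nominal) so that the modelled
#' line keeps cycling.
#'
#' @param params Base `param_set`.
#' @param genes Mutated genes.
#' @param essential_level Residual fraction of the synthesis rate for
#'   essential genes (default 0.7).
#' @return List `params`, `init_overrides` (TP53 mutation zeroes p53(0)).
#' @export
cell_line_params <- function(params, genes, essential_level = 0.7) {
  gm <- gene_map()
  ess <- essential_genes()
  init_overrides <- numeric(0)
  for (g in genes) {
    row <- gm[gm$gene == g, ]
    if (nrow(row) == 0) stop("unknown gene: ", g, call. = FALSE)
    par <- row$parameter[1]
    if (g %in% ess) {
      params[par] <- params[par] * essential_level
    } else {
      params[par] <- 0
      if (g == "TP53") init_overrides <- c(init_overrides, "p53" = 0)
    }
  }
  list(params = params, init_overrides = init_overrides)
}

#' Essentiality matrix over cell-line groups
#'
#' For each (cell-line group, knockout target) the group's mutation profile
#' is applied, the target gene is knocked out CRISPR-style, the model is
#' integrated, and the phenotype classified. A gene is *essential* in a
#' group when the knockout arrests the cycle. The control column carries
#' the unperturbed groups.
#'
#' @param groups Group table from [group_cell_lines()].
#' @param targets Genes to knock out (default the 15 model genes, one
#'   representative per component).
#' @param params Base `param_set`.
#' @param t_end Simulation length per cell (h).
#' @return Tibble `(group, target, essential, viable, arrest_class)` with
#'   `target = "control"` rows for the unperturbed groups; class
#'   `essentiality_matrix`.
#' @export
essentiality_matrix <- function(groups,
                                targets = c("CCNB1", "CDKN1A", "CDC25A",
                                            "WEE1", "PLK1", "PP2A",
                                            "ANAPC1", "CDC20", "CDH1",
                                            "PTTG1", "ATM", "TP53", "MDM2",
                                            "PPM1D", "MAD2L1"),
                                params = default_parameters(),
                                t_end = 400) {
  init0 <- default_initial_state()
  ref <- wt_reference(params)
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    g_genes <- groups$genes[[i]]
    base <- cell_line_params(params, g_genes)
    for (tg in c("control", targets)) {
      row <- tryCatch({
        if (tg == "control") {
          p2 <- base$params; ov <- base$init_overrides
        } else {
          mut <- make_mutant(base$params, tg, mode = "crispr")
          p2 <- mut$params
          ov <- c(base$init_overrides, mut$init_overrides)
        }
        sim <- simulate_cycle(p2, init = apply_overrides(init0, ov),
                              t_end = t_end)
        ph <- classify_phenotype(sim, ref$period, wt_mpf_peak = ref$mpf_peak)
        tibble::tibble(group = groups$label[i], target = tg,
                       essential = !ph$viable, viable = ph$viable,
                       arrest_class = ph$arrest_class)
      }, error = function(e) {
        tibble::tibble(group = groups$label[i], target = tg,
                       essential = NA, viable = NA,
                       arrest_class = paste("error:", conditionMessage(e)))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("essentiality_matrix", class(out))
  out
}
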