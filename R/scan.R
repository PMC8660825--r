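#' Limit-cycle existence scan over one parameter
#'
#' Sets the named parameter to each grid value, integrates, and tests for a
#' sustained limit cycle with [estimate_period()]. Returns the smallest and
#' largest grid values at which a cycle is detected; the true Hopf points
#' are bracketed only up to the grid resolution, and the reported endpoints
#' are always grid values themselves (no interpolation).
#'
#' @param params Base `param_set`.
#' @param symbol Parameter symbol to scan.
#' @param grid Ascending grid of non-negative values.
#' @param init Initial state (default bundled wild-type state).
#' @param t_end Simulation length per grid point (h).
#' @param burn_in Burn-in for period detection (h).
#' @return List with `left`, `right` (grid endpoints of the oscillatory
#'   interval, `NA` if no grid point oscillates) and `detail` (tibble
#'   `value`, `period_h`).
#' @export
limit_cycle_range <- function(params, symbol, grid,
                              init = default_initial_state(),
                              t_end = 400, burn_in = 100) {
  if (!symbol %in% param_symbols()) {
    stop("unknown parameter symbol: ", symbol, call. = FALSE)
  }
  if (is.unsorted(grid)) stop("grid must be ascending", call. = FALSE)
  pers <- purrr::map_dbl(grid, function(v) {
    p <- params; p[symbol] <- v
    tryCatch(estimate_period(simulate_cycle(p, init = init, t_end = t_end),
                             burn_in = burn_in),
             error = function(e) NA_real_)
  })
  osc <- which(is.finite(pers))
  list(left = if (length(osc)) grid[min(osc)] else NA_real_,
       right = if (length(osc)) grid[max(osc)] else NA_real_,
       detail = tibble::tibble(value = grid, period_h = pers))
}
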