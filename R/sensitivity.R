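#' Time-averaged concentration of a reported quantity
#'
#' The average concentration entering all three sensitivity analyses:
#' `(1/N) * sum_j X(t0 + j*dt)` with `N = floor(T/dt)`, sampled by
#' interpolation on the dense solver output (default `t0 = 0`, `dt = 1` h,
#' `T = 96` h, so `N = 96`; the integration window is chosen to cover the
#' cycle even when Plk1 depletion roughly doubles the period).
#'
#' @param sim A `g2m_sim` spanning at least `t0 + T`.
#' @param quantity One of the 50 reported quantities (34 dynamic species or
#'   16 pool totals).
#' @param t0 Window start (h).
#' @param dt Sampling interval (h).
#' @param T Window length (h).
#' @return Mean relative concentration.
#' @export
average_concentration <- function(sim, quantity, t0 = 0, dt = 1, T = 96) {
  t_span <- max(sim$trajectories$time)
  if (t_span < t0 + T - 1e-9) {
    stop("simulation spans only ", t_span, " h; need ", t0 + T, call. = FALSE)
  }
  n <- floor(T / dt)
  ts <- t0 + seq_len(n) * dt
  mean(interp_quantity(sim, quantity, ts))
}

# all 50 averages from one simulation
average_all <- function(sim, t0 = 0, dt = 1, T = 96) {
  reg <- species_registry()
  n <- floor(T / dt)
  ts <- t0 + seq_len(n) * dt
  traj <- sim$trajectories
  m <- derived_quantities(as.matrix(traj[, reg$dynamic]))
  vapply(reg$reported, function(q) {
    mean(stats::approx(traj$time, m[, q], xout = ts, rule = 2)$y)
  }, numeric(1))
}

#' Logarithmic sensitivity intensities
#'
#' Central-difference logarithmic sensitivity of the time-averaged
#' concentrations with respect to the kinetic parameters:
#' `S = (P/f(P)) * |f(P+h) - f(P-h)| / (2h)` with `h = h_fraction * P`
#' (default 1%). Each evaluation integrates the model from the scenario's
#' standard initial state. Parameters with value zero in the scenario (e.g.
#' the p53 synthesis rate in a p53-null background) get `S = 0` and are
#' flagged excluded; quantities whose base average is zero are flagged
#' undefined rather than infinite.
#'
#' @param params Scenario `param_set`.
#' @param quantities Reported quantities (default all 50).
#' @param parameters Parameter symbols to vary (default all 137 kinetic
#'   constants).
#' @param h_fraction Relative step (default 0.01).
#' @param init Scenario initial state.
#' @param t_end Simulation length; must cover `T`.
#' @param t0,dt,T Averaging window (see [average_concentration()]).
#' @param scenario Label stored in the report.
#' @return A `sensitivity_report`: list with `values` (long tibble
#'   `quantity`, `parameter`, `S`, `excluded`, `undefined`), `base`
#'   (named base averages), and `settings`.
#' @export
log_sensitivity <- function(params,
                            quantities = species_registry()$reported,
                            parameters = setdiff(param_symbols(), "tau"),
                            h_fraction = 0.01,
                            init = default_initial_state(),
                            t_end = 96, t0 = 0, dt = 1, T = 96,
                            scenario = "") {
  stopifnot(t_end >= t0 + T)
  base_sim <- simulate_cycle(params, init = init, t_end = t_end)
  f0 <- average_all(base_sim, t0, dt, T)[quantities]
  rows <- purrr::map(parameters, function(sym) {
    p0 <- params[[sym]]
    if (p0 == 0) {
      return(tibble::tibble(quantity = quantities, parameter = sym,
                            S = 0, excluded = TRUE, undefined = FALSE))
    }
    h <- h_fraction * p0
    fp <- fm <- NULL
    for (sgn in c(1, -1)) {
      p <- params; p[sym] <- p0 + sgn * h
      sim <- simulate_cycle(p, init = init, t_end = t_end)
      av <- average_all(sim, t0, dt, T)[quantities]
      if (sgn > 0) fp <- av else fm <- av
    }
    S <- (p0 / f0) * abs(fp - fm) / (2 * h)
    undef <- !is.finite(S)
    S[undef] <- NA_real_
    tibble::tibble(quantity = quantities, parameter = sym, S = S,
                   excluded = FALSE, undefined = undef)
  })
  structure(
    list(values = dplyr::bind_rows(rows),
         base = f0,
         settings = list(h_fraction = h_fraction, t0 = t0, dt = dt, T = T,
                         scenario = scenario,
                         n_parameters = length(parameters),
                         n_quantities = length(quantities))),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> ", x$settings$n_quantities, " quantities x ",
      x$settings$n_parameters, " parameters",
      if (nzchar(x$settings$scenario)) paste0(" (", x$settings$scenario, ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sensitivity_report <- function(x, ...) x$values

#' Average logarithmic sensitivity per quantity
#'
#' Row means of the sensitivity matrix over the varied parameters
#' (`<S^k> = (1/n) * sum_i S[k, i]`, `n = 137` for the full analysis).
#' Undefined entries are excluded with their count recorded.
#'
#' @param report A `sensitivity_report`.
#' @return Tibble `(quantity, mean_S, n_undefined)`.
#' @export
average_log_sensitivity <- function(report) {
  v <- report$values
  out <- dplyr::summarise(
    dplyr::group_by(v, .data$quantity),
    mean_S = sum(.data$S[!.data$undefined]) / report$settings$n_parameters,
    n_undefined = sum(.data$undefined), .groups = "drop")
  out[match(unique(v$quantity), out$quantity), ]
}

#' @export
glance.sensitivity_report <- function(x, ...) {
  tibble::tibble(scenario = x$settings$scenario,
                 n_quantities = x$settings$n_quantities,
                 n_parameters = x$settings$n_parameters,
                 n_excluded = length(unique(
                   x$values$parameter[x$values$excluded])))
}
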