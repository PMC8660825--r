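#' Find local maxima with a prominence floor
#'
#' @param x Numeric vector (uniformly sampled).
#' @param min_prominence Minimum topographic prominence.
#' @return Integer indices of accepted peaks.
#' @noRd
find_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    pk <- cand[i]; h <- x[pk]
    # walk left/right to the first strictly higher point (or the edge);
    # prominence = height minus the highest of the two valley floors
    left <- x[seq_len(pk - 1)]
    hi_l <- which(left > h)
    base_l <- min(x[(if (length(hi_l)) max(hi_l) else 1):pk])
    right <- x[pk:n]
    hi_r <- which(right > h)
    base_r <- min(x[pk:(pk - 1 + (if (length(hi_r)) min(hi_r) else n - pk + 1))])
    keep[i] <- (h - max(base_l, base_r)) >= min_prominence
  }
  cand[keep]
}

#' Estimate the limit-cycle period of a simulated trajectory
#'
#' Resamples the named trajectory on a uniform 0.1 h grid after the burn-in,
#' finds maxima with prominence at least 10% of the post-burn-in amplitude,
#' and returns the mean inter-peak interval. Returns `NA` (absent) if fewer
#' than 3 peaks are found or if the post-burn-in peak-to-trough amplitude is
#' below 5% of the trajectory's global amplitude, or if the final third of
#' the assessment window has lost that amplitude (damped or arrested
#' dynamics).
#'
#' @param sim A `g2m_sim`, or a tibble/data.frame with a `time` column and
#'   the named species column (e.g. a synthetic trajectory).
#' @param species Quantity whose peaks define the cycle (default Cyclin B,
#'   whose maxima mark mitosis together with MPF).
#' @param burn_in Hours discarded before period estimation.
#' @param grid Resampling step (h).
#' @return Period in hours, or `NA_real_` if no sustained oscillation.
#' @export
estimate_period <- function(sim, species = "CyclinB", burn_in = 100,
                            grid = 0.1) {
  if (inherits(sim, "g2m_sim")) {
    traj <- sim$trajectories
  } else {
    traj <- sim
  }
  if (!species %in% names(traj)) {
    reg <- species_registry()
    if (inherits(sim, "g2m_sim") && species %in% reg$derived) {
      tt <- traj$time
      x <- interp_quantity(sim, species, tt)
      traj <- tibble::tibble(time = tt, value = x)
      names(traj)[2] <- species
    } else {
      stop("unknown species: ", species, call. = FALSE)
    }
  }
  t_max <- max(traj$time)
  if (t_max <= burn_in) stop("trajectory shorter than burn_in", call. = FALSE)
  tt <- seq(burn_in, t_max, by = grid)
  x <- stats::approx(traj$time, traj[[species]], xout = tt, rule = 2)$y
  global_amp <- diff(range(traj[[species]]))
  amp <- diff(range(x))
  if (!is.finite(amp) || global_amp == 0 || amp < 0.05 * global_amp) {
    return(NA_real_)
  }
  # damped ringing is not an oscillation: the final third of the assessment
  # window must still carry amplitude comparable to the floor
  tail_sel <- tt >= t_max - (t_max - burn_in) / 3
  if (diff(range(x[tail_sel])) < 0.05 * global_amp) return(NA_real_)
  pk <- find_peaks(x, min_prominence = 0.1 * amp)
  if (length(pk) < 3) return(NA_real_)
  mean(diff(tt[pk]))
}

.g2m_env <- new.env(parent = emptyenv())

#' Wild-type reference (memoised)
#'
#' Simulates the unperturbed model once per session and caches its period
#' and MPF peak, used as the reference for phenotype classification.
#'
#' @param params A `param_set`.
#' @return List with `period` and `mpf_peak`.
#' @export
wt_reference <- function(params = default_parameters()) {
  key <- paste(format(as.numeric(params), digits = 10), collapse = ",")
  hit <- .g2m_env$wt_ref
  if (!is.null(hit) && identical(hit$key, key)) return(hit$value)
  sim <- simulate_cycle(params, t_end = 400)
  per <- estimate_period(sim)
  traj <- sim$trajectories
  val <- list(period = per,
              mpf_peak = max(traj$MPF[traj$time >= 100]))
  .g2m_env$wt_ref <- list(key = key, value = val)
  val
}

#' Classify the phenotype of a simulation
#'
#' A cell is viable iff a sustained oscillation is detected
#' ([estimate_period()] returns a value) in the assessment window and the
#' arrest indicator stays off: a mean Mad2:Cdc20P above the damage-signal
#' activation threshold (0.36) over the assessment window marks the cell
#' arrested even when small-amplitude checkpoint ringing would register as
#' residual "peaks" (the sustained-high mitotic checkpoint complex is the
#' model's arrest read-out). Inviable runs are classified as M-phase arrest
#' with high MPF when the terminal MPF mean exceeds half the wild-type MPF
#' peak, else as early arrest with low MPF.
#'
#' @param sim A `g2m_sim` covering at least `burn_in + 96` h.
#' @param reference_period Reference (unperturbed) cycle period in hours
#'   used for the mutant-to-reference ratio.
#' @param burn_in Hours discarded before assessment (default 100).
#' @param species Period species (default Cyclin B).
#' @param wt_mpf_peak Wild-type MPF peak; defaults to the memoised
#'   wild-type reference for the default parameters.
#' @return A `phenotype_call`: one-row tibble with columns `viable`,
#'   `period_h`, `tm_over_t`, `arrest_class`, `mad2cdc20p_mean`.
#' @export
classify_phenotype <- function(sim, reference_period,
                               burn_in = 100, species = "CyclinB",
                               wt_mpf_peak = NULL) {
  if (reference_period <= 0) {
    stop("reference_period must be > 0", call. = FALSE)
  }
  if (max(sim$trajectories$time) < burn_in + 96) {
    stop("simulation must cover at least burn_in + 96 h", call. = FALSE)
  }
  if (is.null(wt_mpf_peak)) wt_mpf_peak <- wt_reference()$mpf_peak
  per <- estimate_period(sim, species = species, burn_in = burn_in)
  traj <- sim$trajectories
  tail_win <- traj$time >= max(traj$time) - 24
  assess <- traj$time >= burn_in
  mcc_mean <- mean(traj[["Mad2:Cdc20P"]][assess])
  viable <- is.finite(per) && mcc_mean <= dds_constants()[["activation_threshold"]]
  arrest_class <- if (viable) {
    "none"
  } else if (mean(traj$MPF[tail_win]) > 0.5 * wt_mpf_peak) {
    "M-phase-high-MPF"
  } else {
    "early-low-MPF"
  }
  out <- tibble::tibble(
    viable = viable,
    period_h = if (viable) per else NA_real_,
    tm_over_t = if (viable) per / reference_period else NA_real_,
    arrest_class = arrest_class,
    mad2cdc20p_mean = mcc_mean)
  class(out) <- c("phenotype_call", class(out))
  out
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat("<phenotype_call> ",
      if (x$viable) sprintf("viable, period %.1f h (Tm/T = %.2f)",
                            x$period_h, x$tm_over_t)
      else sprintf("inviable, %s", x$arrest_class),
      sprintf("; mean Mad2:Cdc20P %.3f\n", x$mad2cdc20p_mean), sep = "")
  invisible(x)
}
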