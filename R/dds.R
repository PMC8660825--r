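#' DNA-damage-signal constants
#'
#' Fixed constants of the damage-signal rule: piecewise-linear gain 200 on
#' the Mad2:Cdc20P scale, activation threshold 0.36, arrest threshold 0.6,
#' and signal decay rate 1e-8 per hour. As printed, the signal strength drops
#' discontinuously at the 0.6 arrest boundary (the arrest branch restarts
#' from zero); it is continuous at 0.36 from above.
#'
#' @return Named numeric vector.
#' @export
dds_constants <- function() {
  c(gain = 200, activation_threshold = 0.36, arrest_threshold = 0.6,
    decay_rate = 1e-8)
}

#' DNA damage signal from the mitotic checkpoint complex level
#'
#' The damage signal DDS is a piecewise-linear function of the Mad2:Cdc20P
#' concentration: zero below 0.36; `200 * (x - 0.36)` between 0.36 and 0.6
#' (activation branch); `200 * (x - 0.6)` above 0.6, where additionally the
#' cell-cycle-arrest condition is met (the integrator resets Cdc20 to zero
#' at the upward crossing of 0.6). The signal entering the ATM/ATR equation
#' is `Sig = DDS * exp(-1e-8 * t)`.
#'
#' @param mad2cdc20p Mad2:Cdc20P concentration(s), relative scale (>= 0).
#' @param t Time in hours (>= 0). Recycled against `mad2cdc20p`.
#' @param prior Optional previous state (a one-row result of this function);
#'   used only to carry the sticky `arrest_triggered` flag forward.
#' @return A tibble with columns `dds`, `sig`, `arrest_triggered`.
#' @export
dds_signal <- function(mad2cdc20p, t = 0, prior = NULL) {
  if (any(mad2cdc20p < 0)) stop("mad2cdc20p must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  k <- dds_constants()
  dds <- ifelse(mad2cdc20p < k[["activation_threshold"]], 0,
         ifelse(mad2cdc20p <= k[["arrest_threshold"]],
                k[["gain"]] * (mad2cdc20p - k[["activation_threshold"]]),
                k[["gain"]] * (mad2cdc20p - k[["arrest_threshold"]])))
  arrest <- mad2cdc20p > k[["arrest_threshold"]]
  if (!is.null(prior) && isTRUE(any(prior$arrest_triggered))) arrest <- arrest | TRUE
  tibble::tibble(dds = dds,
                 sig = dds * exp(-k[["decay_rate"]] * t),
                 arrest_triggered = arrest)
}

# scalar fast path used by the reference RHS
dds_sig_scalar <- function(mc, t) {
  if (mc < 0.36) return(0)
  if (mc <= 0.6) return(200 * (mc - 0.36) * exp(-1e-8 * t))
  200 * (mc - 0.6) * exp(-1e-8 * t)
}
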