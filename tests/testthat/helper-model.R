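# Shared fixtures, computed once per test run.
.fix <- new.env()

wt_sim <- function() {
  if (is.null(.fix$wt_sim)) .fix$wt_sim <- simulate_cycle(t_end = 400)
  .fix$wt_sim
}

wt_period <- function() {
  if (is.null(.fix$wt_period)) .fix$wt_period <- estimate_period(wt_sim())
  .fix$wt_period
}

wt_mpf_peak <- function() {
  tr <- wt_sim()$trajectories
  max(tr$MPF[tr$time >= 100])
}

p53null_state <- function() {
  y <- default_initial_state()
  y["p53"] <- 0
  y
}

# phenotype call for a parameter edit applied to a background
call_mutant <- function(edits = list(), p53 = "wt", t_end = 400) {
  p <- default_parameters()
  init <- default_initial_state()
  if (p53 == "null") {
    p["k_s28"] <- 0
    init <- p53null_state()
  }
  for (nm in names(edits)) p[nm] <- edits[[nm]]
  sim <- simulate_cycle(p, init = init, t_end = t_end)
  classify_phenotype(sim, wt_period(), wt_mpf_peak = wt_mpf_peak())
}

# standalone checkpoint-module period (p53 trace)
module_period <- function(params = default_parameters(), damage_on = TRUE,
                          k_d27.1 = NULL, t_end = 150) {
  p <- params
  if (!is.null(k_d27.1)) p["k_d27.1"] <- k_d27.1
  f <- function(t, y, parms) list(rhs_p53_module(t, y, p,
                                                 damage_on = damage_on))
  o <- suppressWarnings(deSolve::ode(
    c(0.1, 0.05, 0.05, 0.1, 0.05), seq(0, t_end, 0.05), f, NULL,
    method = "lsoda", rtol = 1e-8, atol = 1e-10))
  sel <- o[, 1] > t_end - 60
  x <- o[sel, 3]; tt <- o[sel, 1]
  amp <- diff(range(x))
  if (!is.finite(amp) || amp < 0.005) return(list(period = NA_real_,
                                                  amplitude = amp))
  n <- length(x)
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  pk <- pk[x[pk] > min(x) + 0.5 * amp]
  if (length(pk) < 4) return(list(period = NA_real_, amplitude = amp))
  list(period = mean(diff(tt[pk])), amplitude = amp)
}
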