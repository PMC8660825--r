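#' Partial rank correlation coefficients
#'
#' PRCC of each column of `X` (sampled parameters) against each column of
#' `Y` (model outputs): Spearman-type partial correlation computed on ranks,
#' controlling for all other columns of `X`. Implemented through the
#' precision matrix of the rank-transformed `[X, y]` block; columns of `X`
#' or `Y` with zero variance yield `NA` (flagged, not an error).
#'
#' @param X Numeric matrix `n x p` of inputs.
#' @param Y Numeric matrix (or vector) of outputs.
#' @return List with matrices `prcc` and `p_value` (`p x q`), and the
#'   degrees of freedom used (`n - 2 - (p - 1)`).
#' @export
prcc <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(Y) == n)
  rx <- apply(X, 2, rank)
  ry <- apply(Y, 2, rank)
  const_x <- apply(rx, 2, stats::var) < .Machine$double.eps
  const_y <- apply(ry, 2, stats::var) < .Machine$double.eps
  df <- n - 2 - (p - 1)
  out <- matrix(NA_real_, p, q, dimnames = list(colnames(X), colnames(Y)))
  pv <- out
  for (j in seq_len(q)) {
    if (const_y[j]) next
    keep <- which(!const_x)
    if (length(keep) == 0) next
    m <- cbind(rx[, keep, drop = FALSE], ry[, j])
    cm <- stats::cor(m)
    om <- tryCatch(solve(cm), error = function(e) MASS_ginv(cm))
    k <- length(keep)
    r <- -om[seq_len(k), k + 1] / sqrt(diag(om)[seq_len(k)] * om[k + 1, k + 1])
    r <- pmin(1, pmax(-1, r))
    out[keep, j] <- r
    tstat <- r * sqrt(pmax(df, 1) / pmax(1 - r^2, .Machine$double.eps))
    pv[keep, j] <- 2 * stats::pt(-abs(tstat), df = pmax(df, 1))
  }
  list(prcc = out, p_value = pv, df = df)
}

# Moore-Penrose fallback for near-singular rank-correlation matrices
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Global PRCC sensitivity analysis
#'
#' Draws Latin-hypercube samples of all (non-zero) kinetic parameters within
#' a +/-1% box around their nominal values, integrates the model for each
#' sample, computes the 50 time-averaged reported quantities, and returns
#' the PRCC of each quantity against each parameter with two-sided p-values.
#' The +/-1% statement is taken as the primary (bounded) specification and
#' sampled uniformly by default; a truncated-normal option (sd such that the
#' +/-1% bound is 3 sd) is available.
#'
#' @param params Scenario `param_set`.
#' @param n_samples Latin-hypercube sample count (default 1000). With
#'   `n <= n_parameters + 2` the partial correlations are rank-deficient and
#'   the report is flagged unreliable.
#' @param perturbation Relative half-width of the sampling box (default
#'   0.01).
#' @param seed Integer seed.
#' @param quantities Reported quantities (default all 50).
#' @param parameters Parameters to perturb (default all 137; zero-valued
#'   parameters are excluded and recorded).
#' @param distribution `"uniform"` (default) or `"normal"` (truncated).
#' @param init Scenario initial state.
#' @param t_end,t0,dt,T Integration/averaging settings (see
#'   [average_concentration()]).
#' @param scenario Label stored in the report.
#' @return A `prcc_report`: list with `prcc` and `p_value` tibbles (long
#'   format), `excluded`, `n_failed`, and `settings`.
#' @export
prcc_analysis <- function(params, n_samples = 1000, perturbation = 0.01,
                          seed = 1,
                          quantities = species_registry()$reported,
                          parameters = setdiff(param_symbols(), "tau"),
                          distribution = c("uniform", "normal"),
                          init = default_initial_state(),
                          t_end = 96, t0 = 0, dt = 1, T = 96,
                          scenario = "") {
  distribution <- match.arg(distribution)
  excluded <- parameters[params[parameters] == 0]
  vary <- setdiff(parameters, excluded)
  k <- length(vary)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  U <- lhs::randomLHS(n_samples, k)
  if (distribution == "normal") {
    z <- stats::qnorm(U * (stats::pnorm(3) - stats::pnorm(-3)) +
                        stats::pnorm(-3))
    frac <- z / 3
  } else {
    frac <- 2 * U - 1
  }
  nominal <- as.numeric(params[vary])
  samples <- sweep(1 + perturbation * frac, 2, nominal, `*`)
  colnames(samples) <- vary
  Ys <- matrix(NA_real_, n_samples, length(quantities),
               dimnames = list(NULL, quantities))
  failed <- 0L
  for (i in seq_len(n_samples)) {
    p <- params
    p[vary] <- samples[i, ]
    res <- tryCatch({
      sim <- simulate_cycle(p, init = init, t_end = t_end)
      average_all(sim, t0, dt, T)[quantities]
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else Ys[i, ] <- res
  }
  if (failed > 0.1 * n_samples) {
    stop("more than 10% of PRCC sample integrations failed", call. = FALSE)
  }
  ok <- stats::complete.cases(Ys)
  res <- prcc(samples[ok, , drop = FALSE], Ys[ok, , drop = FALSE])
  long <- function(m, col) {
    tibble::tibble(parameter = rep(rownames(m), times = ncol(m)),
                   quantity = rep(colnames(m), each = nrow(m)),
                   "{col}" := as.numeric(m))
  }
  structure(
    list(prcc = long(res$prcc, "prcc"),
         p_value = long(res$p_value, "p_value"),
         excluded = excluded, n_failed = failed,
         settings = list(n_samples = n_samples, perturbation = perturbation,
                         seed = seed, distribution = distribution,
                         df = res$df, scenario = scenario,
                         unreliable = n_samples <= k + 2)),
    class = "prcc_report")
}

#' @export
print.prcc_report <- function(x, ...) {
  cat("<prcc_report> ", x$settings$n_samples, " LHS samples, ",
      length(unique(x$prcc$parameter)), " parameters x ",
      length(unique(x$prcc$quantity)), " quantities",
      if (isTRUE(x$settings$unreliable)) " [n <= p + 2: unreliable]",
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.prcc_report <- function(x, ...) {
  dplyr::left_join(x$prcc, x$p_value, by = c("parameter", "quantity"))
}

#' @importFrom rlang :=
NULL
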