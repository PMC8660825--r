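#' Right-hand side of the full 34-ODE model (reference implementation)
#'
#' Pure-R reference implementation of the model derivatives. The compiled
#' version registered with deSolve (`"g2m_derivs"`) is the one used by
#' [simulate_cycle()]; this function defines the equations readably and is
#' cross-checked against the compiled code in the test suite.
#'
#' Conventions: the timescale enters as `dX/dt = tau * f(X)` (so `tau`
#' rescales time only); the damage signal is recomputed from the
#' instantaneous Mad2:Cdc20P value inside every call; concentrations are
#' dimensionless relative to total CDK1 = 1 and free CDK1 is the
#' conservation closure `1 - MPF - preMPF - p21:MPF`.
#'
#' @param t Time in hours.
#' @param state Named numeric vector of the 34 dynamic species (registry
#'   order).
#' @param params A `param_set`.
#' @param dds Optional externally supplied damage signal `Sig`; by default
#'   it is recomputed from `state` and `t`.
#' @return Named numeric vector of 34 derivatives (h^-1).
#' @export
rhs_full <- function(t, state, params, dds = NULL) {
  if (length(state) != 34) stop("state must have 34 entries", call. = FALSE)
  if (!all(is.finite(state))) {
    stop("non-finite state entry: ",
         paste(which(!is.finite(state)), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(params))) {
    stop("non-finite parameter: ",
         paste(names(params)[!is.finite(params)], collapse = ", "),
         call. = FALSE)
  }
  p <- as.list(params)
  names(p) <- gsub("[.']", "_", names(p))
  y <- as.numeric(state)

  CB <- y[1]; MPF <- y[2]; pMPF <- y[3]; p21MPF <- y[4]; p21 <- y[5]
  C25P <- y[6]; W1P <- y[7]; C25 <- y[8]; W1 <- y[9]
  PPP <- y[10]; PLP <- y[11]; PL <- y[12]; PP <- y[13]
  EM <- y[14]; AP <- y[15]; APP <- y[16]; C20 <- y[17]; C20P <- y[18]
  APC20 <- y[19]; CH <- y[20]; CHP <- y[21]; APCH <- y[22]
  SEP <- y[23]; PT <- y[24]; PTSEP <- y[25]; EMP <- y[26]
  AT <- y[27]; P53 <- y[28]; P53P <- y[29]; P53PL <- y[30]
  MD <- y[31]; WIP <- y[32]; M2 <- y[33]; MC <- y[34]

  with(p, {
    CDK1f <- 1 - MPF - pMPF - p21MPF
    Sig <- if (is.null(dds)) dds_sig_scalar(MC, t) else dds
    mcd <- 1 + p21 / K_MCD + eps_MCD * PLP / K_MCD
    phiE <- K_Emi1^4 / (K_Emi1^4 + EM^4)

    v1   <- k_f1 * CB * CDK1f - k_r1 * MPF
    vW   <- (k_f2 * W1 + k_f2_1) * MPF
    vC   <- (k_r2 * C25P + k_r2_1) * pMPF
    v3   <- k_f3 * C25
    v3r  <- k_r3 * C25P / (K_Cdc25P1 + C25P)
    v4   <- k_f4 * MPF * W1 / (K_Wee1f + W1)
    v4r  <- (k_r4 * PP + k_r4_1) * W1P / (K_Wee1P + W1P)
    v5   <- k_r5 * MPF * p21^3 - k_f5 * p21MPF
    v6   <- k_f6p * PL * MPF * K_A1 / (K_A1 + AT)
    v6r  <- k_r6 * PLP / (K_Plk1P1 + PLP)
    v7   <- k_f7 * MPF * PP - k_r7 * PPP
    v8   <- k_f8 * PLP * EM - k_r8 * EMP
    v9   <- k_r9 * C20
    v9r  <- k_f9 * C20P / (K_Cdc20P1 + C20P)
    v10  <- k_f10 * MPF * AP / (K_APC + AP) -
            (k_r10 * PP + k_r10_1) * APP / (K_APP + APP)
    v11  <- k_f11 * APP * C20 * phiE
    v11r <- (k_r9 + k_r11) * APC20
    v12  <- k_f12 * MPF * CH / (K_Cdh1 + CH) -
            (k_r12 * PP + k_r12_1 + k_r12_2 * SEP / (K_Sep + SEP)) *
              CHP / (K_Cdh1P + CHP)
    v13  <- k_f13 * AP * CH - k_r13 * APCH
    v14  <- k_f14 * PT * SEP - k_r14 * PTSEP
    v16  <- k_f16 * P53 - k_r16 * P53P
    v17  <- k_f17 * P53P * PLP - k_r17 * P53PL
    v18  <- k_f18 * M2 * C20P - k_r18p * mcd * MC
    v19  <- k_f19 * MPF * APCH / (K_APCH + APCH)
    vPTS <- k_d25_2 * APC20 * PTSEP / (K_PtSep + PTSEP)

    d <- numeric(34)
    d[1] <- k_s1 - v1 -
      (k_d1 + k_d1_2 * APC20 / (K_CycB1 + CB) +
         k_d1_3 * APCH / (K_CycB2 + CB)) * CB
    d[2] <- v1 - vW + vC - v5 - k_d2_2 * APC20 * MPF / (K_MPF + MPF)
    d[3] <- vW - vC - k_d3_2 * APC20 * pMPF / (K_preMPF + pMPF)
    d[4] <- v5 - k_d4_2 * APC20 * p21MPF / (K_p21MPF + p21MPF)
    d[5] <- k_s5 * (1 + P53 / K_p53) +
      3 * (k_f5 * p21MPF - k_r5 * MPF * p21^3) - k_d5 * p21
    d[6] <- v3 - v3r - (k_d6_1 + k_d6_3 * APCH / (K_Cdc25P2 + C25P)) * C25P
    d[7] <- v4 - v4r - k_d7_1 * W1P
    d[8] <- k_s8 * K_A2 / (K_A2 + AT) - v3 + v3r -
      (k_d8_1 + k_d8_3 * APCH / (K_Cdc25 + C25)) * C25
    d[9] <- k_s9 - v4 + v4r - (k_d9_1 + k_d9_3 * APCH / (K_Wee1 + W1)) * W1
    d[10] <- v7 - k_d10 * PPP
    d[11] <- v6 - v6r - (k_d11_1 + k_d11_3 * APCH / (K_Plk1P2 + PLP)) * PLP -
      k_f17 * P53P * PLP + k_r17 * P53PL
    d[12] <- k_s12 - v6 + v6r - (k_d12 + k_d12_3 * APCH / (K_Plk1 + PL)) * PL
    d[13] <- k_s13 - v7 - k_d13 * PP
    d[14] <- -v8
    d[15] <- k_s15 - v10 - v13 + v19 - k_d15 * AP
    d[16] <- v10 - v11 + v11r
    d[17] <- k_s17 - v9 + v9r - v11 -
      (k_d17_1 + k_d17_3 * APCH / (K_Cdc20 + C20)) * C20
    d[18] <- v9 - v9r + k_r9 * APC20 - k_f18 * M2 * C20P +
      k_r18p * mcd * MC -
      (k_d18_1 + k_d18_3 * APCH / (K_Cdc20P2 + C20P)) * C20P
    d[19] <- v11 - v11r - k_d19_3 * APCH * APC20 / (K_APC20 + APC20)
    d[20] <- k_s20 - v12 - v13 - k_d20 * CH
    d[21] <- v12 + v19 - k_d21 * CHP
    d[22] <- v13 - v19
    d[23] <- -v14 + vPTS
    d[24] <- k_s24 - v14 - (k_d24_1 + k_d24_2 * APC20 / (K_Pttg1 + PT)) * PT
    d[25] <- v14 - vPTS
    d[26] <- v8
    d[27] <- k_s27 * (1 + K_DDS * Sig) -
      k_d27_1 * AT * WIP^4 / (K_Wip1^4 + WIP^4) - k_d27 * AT
    d[28] <- k_s28 * (1 + AT / K_A3) - v16 - k_d28_1 * P53 * MD - k_d28 * P53
    d[29] <- v16 - v17 - k_d29_1 * P53P * MD - k_d29 * P53P
    d[30] <- v17 - k_d30_1 * MD * P53PL
    d[31] <- k_s31 + k_s31_1 * P53P - k_d31_1 * AT * MD - k_d31 * MD
    d[32] <- k_s32 + k_s32_1 * P53P - k_d32 * WIP
    d[33] <- k_s33 - k_f18 * M2 * C20P + k_r18p * mcd * MC - k_d33 * M2
    d[34] <- v18

    stats::setNames(tau * d, species_registry()$dynamic)
  })
}

#' Right-hand side of the standalone p53--Mdm2--Wip1 checkpoint module
#'
#' The checkpoint oscillator in isolation: the five species ATM/ATR, p53,
#' p53P, Mdm2 and Wip1 with the cell-cycle couplings held at zero (no
#' Plk1P, so no p53P:Plk1P exchange). With `damage_on`, the damage input
#' `Sig` is held at a constant positive value (default `Sig = 30 / K_DDS`,
#' a 31-fold increase of ATM/ATR synthesis; the calibrated sustained-damage
#' stimulus, see the vignette).
#'
#' @param t Time in hours.
#' @param state Named or unnamed numeric vector of length 5:
#'   (ATM/ATR, p53, p53P, Mdm2, Wip1).
#' @param params A `param_set`.
#' @param damage_on Logical; hold the damage input at a constant level.
#' @param sig Constant damage input used when `damage_on` (default
#'   `30 / K_DDS`).
#' @return Numeric vector of 5 derivatives (h^-1).
#' @export
rhs_p53_module <- function(t, state, params, damage_on = FALSE, sig = NULL) {
  if (length(state) != 5) stop("state must have 5 entries", call. = FALSE)
  p <- as.list(params)
  names(p) <- gsub("[.']", "_", names(p))
  AT <- state[[1]]; P53 <- state[[2]]; P53P <- state[[3]]
  MD <- state[[4]]; WIP <- state[[5]]
  with(p, {
    Sig <- if (damage_on) (if (is.null(sig)) 30 / K_DDS else sig) else 0
    v16 <- k_f16 * P53 - k_r16 * P53P
    d <- numeric(5)
    d[1] <- k_s27 * (1 + K_DDS * Sig) -
      k_d27_1 * AT * WIP^4 / (K_Wip1^4 + WIP^4) - k_d27 * AT
    d[2] <- k_s28 * (1 + AT / K_A3) - v16 - k_d28_1 * P53 * MD - k_d28 * P53
    d[3] <- v16 - k_d29_1 * P53P * MD - k_d29 * P53P
    d[4] <- k_s31 + k_s31_1 * P53P - k_d31_1 * AT * MD - k_d31 * MD
    d[5] <- k_s32 + k_s32_1 * P53P - k_d32 * WIP
    stats::setNames(tau * d, c("ATM/ATR", "p53", "p53P", "Mdm2", "Wip1"))
  })
}
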