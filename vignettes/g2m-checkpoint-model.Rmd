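---
title: "The coupled mitotic-cycle / G2/M checkpoint model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled mitotic-cycle / G2/M checkpoint model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`g2mcycle` implements a deterministic ODE model of the mammalian mitotic
cell cycle coupled to the G2/M DNA damage checkpoint. The state is a vector
of 34 dimensionless concentrations, normalized so that total CDK1 equals 1;
sixteen further reported quantities (pool totals and the free-CDK1 closure)
are defined by conservation laws, giving 50 reported quantities in all.
Kinetics are a hybrid of mass action and Michaelis--Menten forms with 137
rate constants plus the dimensionless timescale `tau`; the timescale enters
as `dX/dt = tau * f(X)`, so `tau` rescales time only and `period * tau` is
exactly conserved (this is tested). With the bundled defaults,
`tau = 1.65` yields a 48 h wild-type cycle.

The mitotic core is a relaxation oscillator: Cyclin B is synthesized,
binds free CDK1, and is held inactive as Tyr-phosphorylated pre-MPF by
Wee1; Cdc25P reverses that phosphorylation and its accumulation acts as
the G2 timer; active MPF inactivates Wee1 and PP2A (zero-order,
ultrasensitive switches), phosphorylates APC/C and activates Plk1; Plk1P
phosphorylates Emi1, relieving a cooperative (Hill-4) inhibition of
APC/CP:Cdc20 assembly; APC/CP:Cdc20 degrades cyclin, MPF falls, PP2A and
Cdh1 recover, and APC/CT:Cdh1 clears the mitotic regulators to reset G1.

The checkpoint layer follows the printed formulation of the damage
response: p53 is synthesized under ATM/ATR control, exchanges with its
phosphorylated form, and is degraded by Mdm2; p53P induces Mdm2 and Wip1;
Wip1 inhibits ATM/ATR through a fourth-order Hill term; p21 (induced by
p53) binds MPF as a trimer (the cubic binding term) and, together with
Plk1P, accelerates disassembly of the mitotic checkpoint complex
Mad2:Cdc20P through the shared weighting factor
`(1 + [p21]/K_MCD + eps*[Plk1P]/K_MCD)`.

### The damage signal and the arrest event

The damage-signal strength is a piecewise-linear function of the
instantaneous Mad2:Cdc20P level: zero below 0.36, `200*(x - 0.36)` on the
activation branch, and `200*(x - 0.6)` above the arrest boundary, decaying
as `exp(-1e-8 t)`. As printed, the signal is continuous at 0.36 and drops
discontinuously at 0.6; we implement it exactly as printed and flag the
discontinuity here. The signal is recomputed inside every right-hand-side
call (no delay state). The arrest condition is handled as a solver event:
an upward crossing of Mad2:Cdc20P through 0.6 stops the integrator
(`lsodar` root finding), Cdc20 is reset to zero, and integration restarts.
The reset fires once per upward crossing and re-arms only after the signal
falls below 0.6 again, which prevents event chattering; arrested cells can
legitimately accumulate many reset events as the complex rings around the
boundary.

## Provenance of the equations and parameter values

The checkpoint equations (the p21, Cdc25, Plk1P, Cdc20P, ATM/ATR, p53,
p53P, p53P:Plk1P, Mdm2, Wip1, Mad2 and Mad2:Cdc20P balances) are typed
directly from their published in-text formulation. The remaining 22
mitotic-core equations and the full table of default parameter values are a
**synthetic reconstruction**: the original model's complete species,
reaction and parameter tables are not redistributed here, so the core was
re-derived from the described reaction network, and the bundled tables
(`parameters_synthetic.csv`, `conservation_synthetic.csv`,
`initial_state_synthetic.csv`) are labelled accordingly.

The reconstruction's free constants were calibrated against the published
reference behaviors, in this order: (1) a stable wild-type limit cycle
with a 48 h period at `tau = 1.65` (an exact uniform rescaling of all rate
constants pins the period; Michaelis constants are scale-free);
(2) the standalone p53--Mdm2--Wip1 module oscillating at 5 h under
sustained damage, with the oscillation abolished when the Wip1-to-ATM/ATR
inhibition is removed; (3) the single-gene deletion viability pattern,
including the two arrest classes (Cdc20 loss arrests in M with high MPF,
Cdc25 loss arrests early with low MPF); (4) the Plk1-depletion arrest
thresholds -- first arrest at 60% synthesis reduction in p53-null cells and
at 80% in p53-wild-type cells. Because the table is calibrated to these
published observables, checks of those same observables validate the
calibration, not an independent transcription; this is stated openly.

Design choices made where the published description is silent or where the
reconstruction forced a decision:

* **Emi1 gate.** Emi1 inhibition of APC/CP:Cdc20 assembly is a Hill-4
  function of free Emi1. A first-order gate cannot simultaneously make
  complete PLK1 loss lethal in p53-wild-type cells and keep mild depletion
  viable; the cooperative form gives the required dynamic range.
* **Standalone module stimulus.** The sustained damage input of the
  isolated checkpoint module defaults to `Sig = 30/K_DDS` (a 31-fold
  increase of ATM/ATR synthesis). A weaker stimulus does not cross the
  module's Hopf point.
* **Arrest read-out.** A run is called arrested not only when no
  qualifying oscillation is detected but also when the assessment-window
  mean of Mad2:Cdc20P exceeds 0.36: the sustained-high checkpoint complex
  is the model's arrest indicator, and arrested cells can carry
  small-amplitude checkpoint ringing that a pure peak detector would
  miscount as cycling. Similarly, `estimate_period()` rejects trajectories
  whose final third of the assessment window has lost the 5% amplitude
  floor (damped ringing).
* **Knockout conventions.** Deletion or CRISPR loss of a uniquely mapped
  gene zeroes its synthesis constant; losing one paralog of a lumped
  family (CCNB1/2, CDC25A/B, ATM/ATR) scales the shared constant by 0.5
  per lost paralog, while losing the whole family zeroes it; any APC/C
  subunit knockout zeroes the APC/C synthesis rate (complex disruption).
  TP53 loss additionally starts p53 at zero. Cell-line mutation profiles
  zero nonessential genes and reduce essential genes to 70% of nominal so
  modelled lines keep cycling.
* **Initial conditions.** The bundled initial state is the wild-type
  limit-cycle point reached after a 300 h burn-in from a documented
  G1-like seed (`seed_state()`); phenotype calls are insensitive to the
  starting point for viable cells because the limit cycle is attracting.

## Tunable parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `tau` | global timescale; `period * tau` exactly constant | 1.65 | -- |
| `k_s1` | Cyclin B synthesis; sets the loading phase | ~0.011 | h^-1 |
| `k_s8` | Cdc25 synthesis; the G2 timer's source, gated by ATM/ATR | ~0.085 | h^-1 |
| `k_s12` | Plk1 synthesis; depletion scales this constant | ~0.047 | h^-1 |
| `k_s5`, `K_p53` | p21 synthesis and its p53 induction threshold | ~0.00095, ~0.02 | h^-1, rel. conc. |
| `K_MCD`, `eps_MCD` | Mad2:Cdc20P disassembly weights of p21 and Plk1P | ~0.02, 3 | rel. conc., -- |
| `K_DDS` | damage-signal coupling into ATM/ATR synthesis | ~2 | -- |
| `K_Wip1`, `k_d27.1` | Wip1-mediated ATM/ATR clearance (Hill-4) | ~0.08, ~0.45 | rel. conc., h^-1 |

Solver settings default to `rtol = 1e-6`, `atol = 1e-9` with dense output
resampled at 0.1 h; halving the tolerances moves a 150 h endpoint state by
less than 0.1% (tested). Period detection uses a 100 h burn-in, a 0.1 h
resampling grid, a 10% prominence floor and a 5% amplitude floor.

## What the synthetic cell-line fixture emulates

`simulate_cell_lines()` draws independent per-gene mutations with marginal
rates shaped like a large cancer cell-line panel (TP53 by far the most
frequent, ATM and ATR next); groups are formed per mutated model gene plus
frequent co-mutation pairs. The fixture reproduces the *structure* of a
dependency screen -- group sizes, co-mutation counts within binomial
bounds, and the qualitative essential/nonessential knockout pattern -- but
none of the biology real mutation data carry: no mutation spectra, no
lineage or tissue structure, no co-occurrence correlations, and no
continuous dependency scores (essentiality here is the binary arrest call
of the model). Passing fixture-based tests therefore demonstrates the
pipeline and the model's knockout logic, not agreement with any real
screen.

## Sensitivity analyses

All three analyses work on time-averaged concentrations
`f_k = (1/N) sum_j X_k(t0 + j dt)` with `t0 = 0`, `dt = 1` h, `T = 96` h
(`N = 96`), a window long enough to cover the cycle even when depletion
roughly doubles the period.

* **Logarithmic intensities.** `S = (P/f) |f(P+h) - f(P-h)| / (2h)` with
  `h = 0.01 P`, evaluated from the scenario's standard initial state; the
  absolute value deliberately discards sign. Parameters that are zero in a
  scenario get `S = 0` and are excluded from the average
  `<S> = (1/137) sum_i S_i`. A step-halving check guards the
  central-difference convergence.
* **PRCC.** Latin-hypercube samples over a +/-1% box around nominal
  (uniform by default; a truncated-normal option maps the box to +/-3 sd),
  one 96 h integration per sample, then the partial rank correlation of
  each quantity against each parameter via the precision matrix of the
  rank-transformed block, with t-based two-sided p-values on
  `n - 2 - (p - 1)` degrees of freedom. The implementation is checked
  against the definitional residual-correlation construction to 1e-10.
* **Fuzzy alpha-cuts.** Each synthesis constant is a triangular fuzzy
  number with +/-1% support. The band at level alpha is the max-minus-min
  of the averaged quantity over the alpha-cut's endpoints, the nominal
  point, and the endpoints of all narrower cuts -- a grid refinement of
  the vertex method that makes the nesting property
  `band(alpha2) <= band(alpha1)` for `alpha2 > alpha1` hold by
  construction and the band at `alpha = 1` exactly zero. The shortcut is
  exact for responses monotone on the interval; a dense-grid comparison
  test guards it.

Problem sizes used by the test suite and the acceptance script: single
simulations of 400 h; depletion scans at 10% steps; the mutant panel of 23
mutants in four backgrounds; a 3x3x3 response-surface grid; sensitivity
averages over all 137 parameters (two 96 h integrations each); PRCC with a
few dozen samples in unit tests and configurable sample counts in the
pipeline.

## Known limitations

* The mitotic core is a reconstruction, not a transcription. Its
  qualitative wiring follows the described network, but individual rate
  constants are not comparable to the original deposit.
* Cdh1 loss is inviable in this reconstruction, whereas the published
  model predicts fast viable cycling (period ratio 0.3): the
  reconstruction's G1 reset leans on APC/CT:Cdh1, and no parameter change
  we found restores fast cycling without breaking PP2A essentiality or the
  depletion thresholds.
* Period stretch under moderate (30%) Plk1 depletion is weak (a few
  percent rather than the published 1.3-2.2x ratios); the depleted-column
  period ratios of the mutant panel are therefore not reproduced
  quantitatively, although the viability pattern largely is.
* The p21-overexpression loss threshold sits near `k_s5 = 0.0035` in the
  reconstruction versus the published 0.0073.
* Depletion-induced p53 oscillations in arrested cells run at 3.7-4.8 h
  here versus the published 1.1-2 h, and the trend with depletion depth is
  not reproduced.
* The limit-cycle window in `k_s8` extends further down (to at least 0.06)
  than the published lower endpoint between 0.07 and 0.08; the upper
  endpoint (between 0.3 and 0.5) is consistent.
* No spatial effects, no stochasticity, no cell-to-cell variability, no
  explicit apoptosis kinetics; arrest is a flag, not a fate decision.

## A worked example

```{r, eval = FALSE}
library(g2mcycle)

sim <- simulate_cycle(t_end = 400)
estimate_period(sim)            # ~48 h
autoplot(sim)

null_scan <- plk1_depletion_scan("p53-null")
arrest_threshold(null_scan)     # 0.6
wt_scan <- plk1_depletion_scan("p53-wt")
arrest_threshold(wt_scan)       # 0.8
autoplot(dplyr::bind_rows(null_scan, wt_scan))
```
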