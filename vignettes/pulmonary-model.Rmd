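---
title: "A pharmacometric pulmonary model: plasma PK with autoinduction and ELF/AC penetration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A pharmacometric pulmonary model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bronchoalveolar lavage (BAL) is the standard way to measure antibiotic
concentrations at the pulmonary site of action: the epithelial lining fluid
(ELF) covering the alveolar surface and the alveolar cells (AC, mostly
macrophages) recovered with it.  Because BAL is semi-invasive, most studies
obtain a *single* BAL sample per subject, typically at one late time point —
too little for a conventional compartmental description of lung
distribution.  This package implements a pharmacometric model built for
exactly that situation, using rifampicin as the reference compound: a
drug-specific plasma PK submodel coupled to drug-unspecific ELF and AC
effect compartments whose parameters are the *extent* (concentration
ratios) and *rate* (equilibration constants) of pulmonary distribution.

## The structural model

**Absorption.** Oral doses enter a chain of `N` transit compartments with
rate `ktr = (N + 1) / MTT` (the chain counts the terminal absorption
compartment), then reach the central compartment with first-order rate
`ka`.  The reference model fixes `MTT = 0.71` h and `N = 1`; `ka` is not
part of the published parameter table, so the package refuses to invent a
default — `rifampicin_params(ka = ...)` requires it, and the reference
configuration uses 2 1/h, i.e. absorption fast relative to elimination,
standing in for the fixed literature value of the prior plasma model.

**Disposition and autoinduction.** A one-compartment model with apparent
oral clearance `CL/F` and central volume `Vc/F` (bioavailability is
absorbed into the apparent parameters throughout).  Rifampicin induces its
own elimination: the plasma concentration `Cp` stimulates production of an
enzyme pool `E` (normalized to 1 at the pre-induced state),

    dE/dt = k_enz * [1 + Emax * Cp / (EC50 + Cp)] - k_enz * E,

and the momentary clearance is `CL(t) = TV(CL/F) * exp(eta) * E(t)`.
The turn-over rate `k_enz = 0.0036` 1/h implies a ~192 h enzyme half-life,
i.e. about 40 days (five half-lives) to induction steady state — which is
why a 5-day study cannot estimate the autoinduction parameters and the
reference model fixes `Emax = 1.04`, `EC50 = 0.0705` mg/L and `k_enz`.
With this multiplier form the induced clearance is bounded by
`1 + Emax = 2.04` times the pre-induced value.

**Allometry.** Typical values scale as
`TV(CL/F) = (CL/F)_STD * (MASS/70)^(3/4)` and
`TV(Vc/F) = (Vc/F)_STD * (MASS/70)^1`, where MASS is one of: total body
weight, fat-free mass (FFM), or normal fat mass (NFM).  FFM uses the
maximal-weight-height-squared form with sex-specific constants
(42.92/30.93 kg/m² in men, 37.99/35.98 in women); NFM interpolates between
FFM and total weight with estimable fat-fraction parameters (one for CL,
one for V, each in [0, 1], initialized at 0.5).
`compare_scaling_modes()` replays the size-descriptor selection: all four
modes are fitted and ranked by OFV, ties resolved in favor of fewer
parameters.  The reference model uses FFM.

**Pulmonary penetration.** ELF and AC are effect compartments driven by the
plasma concentration:

    dC_ELF/dt = k_ELF * (R_ELF/plasma * Cp - C_ELF)
    dC_AC/dt  = k_AC  * (R_AC/plasma  * Cp - C_AC)

They carry no drug mass (the lung sample volume is negligible), so the
plasma mass balance is untouched.  `k_ELF = k_AC = 41.58` 1/h corresponds
to an equilibration half-life of about one minute — effectively
instantaneous distribution, the appropriate assumption when every BAL
sample is drawn at a single late time at pseudo-steady-state.  With a
single BAL time the rate constants are structurally unidentifiable, and
`fit()` refuses to free them unless the design has at least two distinct
BAL times; the *extent* parameters `R_ELF/plasma` and `R_AC/plasma` remain
identifiable either way.  Unbound ratios are derived post hoc by dividing
the total ratios by the plasma unbound fraction (`fu = 0.2` for
rifampicin); protein binding inside ELF/AC is treated as negligible.
Note that `0.26 / 0.2 = 1.30` is the formula value of the unbound ELF
ratio — a published table that prints 1.28 has divided the *unrounded*
ratio estimate.

A practical consequence of the 1-minute equilibration: the effect
compartment tracks `R * Cp(t)` with a relative lag of roughly
`|Cp'(t)/Cp(t)| / k`.  That is below 0.2% in the elimination phase but can
reach a few percent during rapid absorption; the tests assert the sharp
bound rather than a blanket "instantaneous" claim.

An important kinetic fact about this parameter set: with an elimination
half-life of ~14 h, once-daily dosing *accumulates* — the uninduced day-5
AUC is ~41% above day 1.  Autoinduction therefore does not make day 5
lower than day 1; what it does is reduce exposure relative to the
`Emax = 0` model, increasingly so as the enzyme pool grows.  The invariant
tests encode this comparison.

## Units and dataset conventions

Milligrams, liters, hours; concentrations in mg/L.  Datasets are
long-format event tables (one row per dose or observation) with absolute
times in hours from the first study dose; "hours post dose" is always
derived, never stored.  Rows at a dose time report the pre-dose state.
Negative observed concentrations can occur under a proportional Gaussian
residual error at 35–40% CV and are retained — truncating them would break
the correspondence between the simulation model and the likelihood.

## Estimation

The single random effect is a lognormal between-subject variability on
CL/F (`eta ~ N(0, omega^2)`).  Each subject's conditional −2 log-likelihood
uses a proportional residual error per observation matrix with
*interaction*: the residual variance `f(eta)^2 * sigma_matrix^2` is
evaluated at the eta-conditional prediction.  The marginal likelihood is
approximated Laplace-style at the conditional mode: the mode is found by a
safeguarded Newton search on numerically differentiated `j(eta)` (the
problem is one-dimensional per subject), and the log-curvature term is
taken from the same finite differences.  On one-subject instances the
approximation agrees with adaptive quadrature over eta to well under 0.5
OFV units (tested).  The outer problem — typical values, penetration
ratios, omega and the three sigmas — runs Nelder–Mead on log-transformed
(positivity) or logit-transformed (fat fractions) parameters.  Standard
errors come from the numerically differentiated curvature of the objective
at the optimum (covariance `2 * H^{-1}` for a −2 log-likelihood),
delta-method back-transformed; a non-positive-definite curvature yields a
warning and no SEs, never an error.  OFV values carry the full Gaussian
normalizing constants but are only ever compared as differences
(`lrt()` uses the chi-squared threshold, 3.84 for one parameter at 5%).

Numerical choices worth knowing:

* ODE integration: `lsoda`, rtol 1e-8, atol 1e-10 — the system is stiff
  (k_ELF = 41.58 1/h vs k_enz = 0.0036 1/h spans four orders of
  magnitude); doses are bolus events into the transit chain with the
  integrator restarted at events.
* The estimator integrates the whole cohort as stacked independent copies
  of the system in a single banded-Jacobian `lsoda` call (the copies do not
  interact, so the Jacobian is block diagonal), and evaluates the inner
  Newton center and both finite-difference points in the same call.
* Inside the estimator the stiff ELF/AC states are not integrated at all:
  with a 1-minute equilibration half-life they satisfy
  `C = r (Cp - Cp'/k + Cp''/k²) + O(|Cp'''|/k³)` at the sampling times
  (relative error ~1e-5, verified against the full system in tests), so
  only the non-stiff plasma subsystem is solved and the step size is no
  longer throttled by the fast modes — a ~4-fold speedup.  Simulation and
  VPCs always use the full stiff system.
* Finite-difference steps: `h = 0.02` on eta and `5e-3` on the outer log
  scale — wide enough that difference quotients dominate solver noise at
  rtol 1e-8 (with `h = 1e-4` second differences are pure noise).
* The residual variance is floored at `(1e-10 mg/L)^2` so a zero
  prediction (a sample before the first dose) cannot produce an infinite
  likelihood term.
* eta is clamped to `±min(8, 6*omega + 1)`.

## The synthetic-study generator

`generate_study()` emulates the reference design: 40 adults (20 men, 20
women; an AIDS label carried as a pure grouping variable with no parameter
effect), 600 mg orally once daily for 5 days, plasma samples at ~2 and ~4 h
after the day-5 dose, one BAL-derived ELF and AC concentration at ~4 h, and
observation totals thinned completely at random to 76 plasma, 32 ELF and
36 AC records.  "Approximately" is implemented as uniform ±0.25 h jitter.
Covariate distributions (per-sex truncated normal weight and height) are
plausible adult values chosen once and documented as *not* derived from any
clinical dataset.  Each subject consumes a dedicated substream derived from
(seed, subject index), so datasets are bit-reproducible and independent of
cohort ordering.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: assay quantification limits (none reported for
the reference assay), informative missingness (the 76/32/36 totals are
assumed missing-completely-at-random), covariate effects on any parameter,
inter-occasion variability, and correlated random effects (the reference
model estimated variability only on CL/F).

## Recovery experiments and problem sizes

`simulation_reestimation()` runs the classic
stochastic-simulation-and-estimation loop: generate a study under the true
parameters, refit starting from the generating values (the standard SSE
convention), repeat over seeds.  The package's own calibration experiments
use a rich-BAL recovery design — one BAL sample per subject with BAL times
spread over 1, 4 and 8 h post dose so that both ratios are informed away
from a single time point.  Two scales are exercised: 50 subjects × 10
seeds for the headline recovery of `CL/F`, `Vc/F` and the two penetration
ratios (medians within 15% of truth), and 12 subjects × 20 replicates for
the coverage property of the Wald intervals (each free parameter's
empirical 95% CI coverage inside [0.80, 1.00]).  The smaller cohort keeps
the 20-replicate experiment affordable; cohort size is a design choice of
the experiment, not of the model.

```{r recovery-example}
library(pulmopk)
p <- rifampicin_params(ka = 2)
rec <- simulation_reestimation(p, n_subjects = 50, bal_times = c(1, 4, 8),
                               seeds = 1:10)
attr(rec, "medians")
```

## Visual predictive checks

`pcvpc()` implements the prediction-corrected VPC: observations and
simulated replicates are rescaled by the bin-median population prediction
over their own population prediction, then 5th/50th/95th percentiles of the
observed data are compared with 95% confidence bands of the same
percentiles across replicate simulations.  Binning is by observation matrix
and nominal time (rounded hour) — automatic data-driven binning is unstable
with two plasma times, and the classic single-4-h BAL design collapses the
ELF and AC panels to one bin each, which remains valid.  Bins with fewer
than three observations merge into their nearest same-matrix neighbor with
a message.  The default of 1000 replicates is configurable; the calibration
tests use 200.

## Known limitations

* The Laplace-type approximation shares FOCE's small-sample biases,
  visible mostly in omega and the sigmas at sparse designs; the structural
  parameters are recovered essentially unbiased in the packaged
  experiments.
* A single random effect: no IIV on the penetration ratios (would need
  multiple BAL samples per subject), no inter-occasion variability.
* The optimizer is derivative-free; for many-parameter extensions a
  gradient-based outer loop would be preferable.
* No bootstrap; SEs are curvature-based only.
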