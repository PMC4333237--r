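# pulmopk

Population-PK modeling of pulmonary drug distribution from
bronchoalveolar-lavage (BAL) studies, with rifampicin as the reference
compound.

## The problem

Antibiotic efficacy in pulmonary infection depends on the concentrations
reached at the site of action: the epithelial lining fluid (ELF) on the
alveolar surface for extracellular pathogens, and the alveolar cells (AC,
predominantly macrophages) for intracellular ones.  Both are sampled by
BAL — but BAL is semi-invasive, so most studies collect a *single* sample
per subject at one late time point.  Classic compartmental modeling of
lung distribution fails on such designs.

`pulmopk` implements a pharmacometric pulmonary model built for this
situation.  A drug-specific plasma submodel — transit-compartment
absorption (`ktr = (N+1)/MTT`), one-compartment disposition, and an enzyme
turn-over model of rifampicin's autoinduction,

    dE/dt = k_ENZ · [1 + Emax·Cp/(EC50 + Cp)] − k_ENZ · E,
    CL(t) = TV(CL/F) · e^η · E(t),       η ~ N(0, ω²)

with allometric scaling `TV(CL/F) = (CL/F)_STD (MASS/70)^{3/4}`,
`TV(Vc/F) = (Vc/F)_STD (MASS/70)^1` (MASS = body weight, fat-free mass or
normal fat mass) — drives two drug-unspecific effect compartments:

    dC_ELF/dt = k_ELF (R_ELF/plasma · Cp − C_ELF)
    dC_AC/dt  = k_AC  (R_AC/plasma  · Cp − C_AC)

`R_ELF/plasma` and `R_AC/plasma` are the pseudo-steady-state total
concentration ratios (the *extent* of distribution, estimable even from
one BAL sample per subject); `k_ELF`, `k_AC` are equilibration rate
constants (the *rate*, estimable only from designs with ≥ 2 distinct BAL
times — fixed to an ~1-minute half-life otherwise).  Unbound ratios follow
by dividing the total ratios by the plasma free fraction (0.2 for
rifampicin).

The package provides, as tested modules:

* `solve_model()` / `simulate_individual()` — stiff ODE simulation with
  bolus dose events (deSolve, compiled right-hand side);
* `generate_study()` — a synthetic-study generator emulating the classic
  40-subject sparse BAL design (600 mg daily × 5 days, plasma at ~2 and
  ~4 h on day 5, one BAL at ~4 h; 76/32/36 observations);
* `fit()` — a Laplace-type (FOCE-with-interaction flavor) approximate
  marginal-likelihood estimator with per-subject empirical-Bayes modes,
  `lrt()` nested-model testing and curvature-based standard errors;
* `compare_scaling_modes()` — size-descriptor selection across the four
  allometric variants;
* `pcvpc()` — prediction-corrected visual predictive checks;
* `simulation_reestimation()` — the stochastic-simulation-and-estimation
  loop used for parameter-recovery experiments.

## Worked example

```r
library(pulmopk)

params <- rifampicin_params(ka = 2)   # ka must be supplied explicitly
# the classic sparse design: 40 subjects, 76/32/36 observations
sparse <- generate_study(study_design_spec(), params, seed = 7)
table(sparse$matrix[sparse$evid == 0])
#>
#>     AC    ELF plasma
#>     36     32     76

# a rich-BAL estimation design: 50 subjects, BAL at 1, 4 or 8 h post dose
rich  <- study_design_spec(n_subjects = 50, n_male = 25,
                           bal_times = c(1, 4, 8), target_counts = NULL)
study <- generate_study(rich, params, seed = 1)
f <- fit(study, params)
print(f)
#> Pulmonary PK model fit (Laplace-type approximate ML)
#>   subjects: 50  observations: 200
#>   OFV: 1123.203   objective evaluations: 444   converged: TRUE
#>     parameter estimate      se rse_pct
#>        cl_std   3.9248 0.83755  21.340
#>        vc_std  73.6955 5.40158   7.330
#>  r_elf_plasma   0.2757 0.01791   6.497
#>   r_ac_plasma   1.0873 0.06760   6.218
#>      omega_cl   0.9108 0.10862  11.925
#>  sigma_plasma   0.3402 0.02905   8.537
#>     sigma_elf   0.3824 0.05154  13.479
#>      sigma_ac   0.3509 0.04759  13.564

# extent of distribution relative to unbound plasma drug
unbound_ratio(f$params$r_elf_plasma, f$params$fu_plasma)
#> [1] 1.378469
unbound_ratio(f$params$r_ac_plasma, f$params$fu_plasma)
#> [1] 5.436325

vpc <- pcvpc(study, f, n_sim = 500, seed = 2)
plot_vpc(vpc)           # ggplot; write_vpc() saves the numeric summary
```

Reading the output: this synthetic study was generated at a typical
pre-induced clearance of 3.85 L/h, a central volume of 76.6 L and total
ELF/plasma and AC/plasma ratios of 0.26 and 1.1; the fit recovers
3.92 L/h, 73.7 L, 0.276 and 1.087, each within about one standard error
of its truth (the 21% RSE on CL/F reflects the 88.8% between-subject
variability it must be separated from).  The unbound ratios above 1 say
that unbound drug concentrates in both ELF and AC even though the *total*
ELF concentration is below plasma.  On the classic single-4-h-BAL sparse
design the penetration ratios remain well determined but CL/F is weakly
identified — which is exactly why the equilibration rate constants are
fixed there and `fit()` refuses to free them.

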