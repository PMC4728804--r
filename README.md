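# chdfpk

Pharmacokinetic/pharmacodynamic analysis of the carbapenem antibiotic
**biapenem (BIPM)** in critically ill patients undergoing **continuous
hemodiafiltration (CHDF)**. CHDF removes small, poorly protein-bound drugs
in proportion to the effluent flow, so standard dosing guidance does not
carry over; this package implements the full modelling chain needed to pick
a regimen for such patients: compartmental and non-compartmental analysis
of paired plasma / filtrate-dialysate (FD) concentration curves, two-stage
population summaries, and Monte Carlo simulation of the probability of
target attainment (PTA) for the time-above-MIC efficacy target.

It is written for clinical pharmacologists and pharmacometricians; all
computation lives in package functions, with a set of numbered scripts
under `analysis/` that walk through the study workflow end to end.

## The model

Drug amounts in the central (X₁), peripheral (X₂) and hemofilter (X₃)
compartments follow the mass balances

    dX₁/dt = R_inf − (k₁₀ + k₁₂ + k₁₃)·X₁ + k₂₁·X₂
    dX₂/dt = k₁₂·X₁ − k₂₁·X₂
    dX₃/dt = k₁₃·X₁ − k₃₀·X₃

with infusion rate `R_inf = dose/T_inf` during infusions and zero
otherwise. The circuit ties two of the constants to the CHDF settings:
`k₁₃ = (Q_F + Q_D)·SC / V₁` and `k₃₀ = (Q_F + Q_D) / V₃`, where `Q_F`,
`Q_D` are the filtration and dialysate flows and `SC` is the membrane
sieving coefficient. Clearance splits into an extracorporeal part
`CL_CHDF = (Q_F + Q_D)·SC` and a non-CHDF part `CL_nonCHDF = k₁₀·V₁`.

At steady state under repeated infusions the plasma (C₁) and FD (C₃)
concentrations have closed forms in the hybrid rate constants α, β
(`α + β = k₁₂ + k₂₁ + k₁₀ + k₁₃`, `α·β = k₂₁·(k₁₀ + k₁₃)`); these are
implemented in `conc_central_ss()` / `conc_fd_ss()` and validated against
the ODE system (`simulate_ode()`), which serves as ground truth.

Efficacy is scored by **%T>MIC** — the percentage of a 24-h steady-state
period with plasma concentration at or above the MIC; carbapenems need
≥ 40 % for maximal kill (≥ 20 % for stasis). `sample_population()` draws
normal `(V₁, k₂₁, α, β)` vectors from two-stage moments (redrawing invalid
sets), `probability_target_attainment()` scores the 40 % target across
draws, and `pkpd_breakpoint()` reads the largest MIC with PTA ≥ 80 %
(Japanese convention; 90 % is also reported).

## Worked example

```r
library(chdfpk)

# cohort-mean parameters, standard circuit (Q_F + Q_D = 1.5 L/h, SC = 1)
m <- reference_mean_micro()
r <- regimen(300, tau = 6, tinf = 1)        # 300 mg q6h, 1-h infusion

percent_time_above_mic(m, r, mic = 4)       # 82.9  (% of 24 h >= 4 ug/mL)
percent_time_above_mic(m, r, mic = 8)       # 35.1
conc_central_ss(6, m, r)                    # 3.15  (steady-state trough, ug/mL)

# Monte Carlo PTA from the reference cohort's two-stage statistics
stats <- reference_population_stats()
draws <- sample_population(stats, 10000, seed = 1)
pta_curve(draws, r, mic_grid = c(0.25, 0.5, 1, 2, 4, 8, 16))
#>   mic  pta        breakpoint at >= 80%: 2 ug/mL
#>  0.25 99.5        breakpoint at >= 90%: 2 ug/mL
#>  ...
#>  2.00 92.8
#>  4.00 76.4
```

The `82.9` / `35.1` values say the mean patient holds the plasma level
above a susceptible-organism MIC (4 μg/mL) for ~83 % of the day on this
regimen — comfortably past the 40 % maximal-kill target — but only ~35 %
of the day for intermediate organisms (8 μg/mL). The PTA table folds in
between-patient variability: 92.8 % of simulated patients meet the target
at MIC 2 μg/mL, and 2 μg/mL is the largest two-fold MIC with PTA ≥ 80 %,
i.e. the PK/PD breakpoint for this regimen.

The `analysis/` scripts reproduce the study tables in order:
`01_reference_tables.R` (NCA summaries, two-stage statistics, the
clearance validation regression), `02_synthetic_cohort.R` /
`03_fit_synthetic.R` (synthetic cohort generation and parameter
recovery), `04_tmic_grid.R` (deterministic regimen exploration) and
`05_monte_carlo_pta.R` (PTA curves and breakpoints for all regimens).
Each writes its tables under `results/`.

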