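# tvclpk

Population pharmacokinetics with time-varying clearance for subcutaneous
antibody therapeutics.

`tvclpk` is an R package for pharmacometricians analyzing subcutaneously
dosed therapeutic proteins — the motivating case is envafolimab, an
anti-PD-L1 single-domain antibody-Fc fusion given to patients with advanced
solid tumors — whose apparent clearance declines over months of treatment.
It provides, end to end: the structural and covariate models, nonlinear
mixed-effects estimation, model diagnostics, dosing-regimen simulation, and
an exposure-response stage, together with a synthetic-trial generator that
reproduces the data structure of a mixed phase I/II oncology PK program.

## The model

A one-compartment model with first-order absorption from the injection-site
depot and first-order elimination whose clearance carries an Emax-type time
dependence:

    dAa/dt = -Ka * Aa
    (V/F) dCp/dt = Ka * Aa - CL/F(t) * Cp,   Cp(0) = 0
    CL/F(t) = theta_CL * (CRCL/95.14)^beta * f_country
              * exp(Emax * t / (24*T50 + t)) * exp(eta_CL)

with log-normal inter-individual variability on CL, V, Ka and proportional
residual error. Published typical values are pre-loaded: CL/F 0.0478 L/h,
V/F 15.5 L, Ka 0.0147 1/h, Emax -0.439, T50 34 days, CRCL exponent 0.475,
country multipliers 0.891 (US) and 0.740 (JP); a weight-incorporated variant
adds (WT/63)^0.155 on clearance and (WT/63)^0.623 on volume. Estimation uses
an approximate marginal likelihood (FOCE-with-interaction by default,
Laplace optionally) with empirical-Bayes individual estimates, stepwise
covariate selection (forward dOFV 6.63, backward 10.83), and a
subject-resampling bootstrap. Diagnostics include conditional weighted
residuals and dose-corrected visual predictive checks.

## A worked example

Simulate the three registrational dosing regimens for 20 weeks on a virtual
study population and compare steady-state exposure:

```r
library(tvclpk)

params <- final_model_parameters()
pop <- simulation_population(1000, params, mode = "covariate", seed = 1)

qw  <- simulate_regimen(pop, regimen_qw(150),  params)   # 150 mg weekly
q2w <- simulate_regimen(pop, regimen_q2w(300), params)   # 300 mg biweekly

round(c(r_auc_qw   = mean(qw$metrics$r_auc),
        r_cmax_q2w = mean(q2w$metrics$r_cmax),
        pct_above_5 = proportion_above_threshold(qw$metrics$cmin_ss, 5)), 2)
#>    r_auc_qw  r_cmax_q2w pct_above_5
#>        5.25        2.31      100.00
```

The weekly regimen accumulates about 5.2-fold in interval AUC by week 20
(the biweekly one only ~2.3-fold in peak concentration — the longer the
interval, the lower the accumulation), and every simulated subject holds a
steady-state trough above the 5 mg/L pharmacodynamic target. A typical
subject on either regimen shows near-identical steady-state exposure over a
common two-week window:

```r
typ <- tibble::tibble(id = 1, country = "chinese", wt = 60, crcl = 95.14,
                      eta_cl = 0, eta_v = 0, eta_ka = 0)
cmp <- compare_regimens(list(qw = regimen_qw(150), q2w = regimen_q2w(300)),
                        typ, params)
round(cmp$max_rel_diff_pct, 1)
#> [1] 8.6
```

Fitting works on event-record data (`ID, TIME, AMT, DV, EVID, MDV, WT,
CRCL, COUNTRY`); `generate_study_dataset()` creates a synthetic 182-subject
program (30 rich, 152 trough-only subjects, ~1810 concentrations) whose
generating truth is attached for recovery checks:

```r
ds  <- generate_study_dataset(params, seed = 7)
fit <- fit_population(ds, final_model_parameters(cl_pop = 0.06, v_pop = 12,
                        ka_pop = 0.01, emax = -0.25, t50 = 20,
                        beta_crcl = 0.3, omega_cl = 0.4, omega_v = 0.4,
                        omega_ka = 0.4, sigma_prop = 0.3),
                      fixed = c("frac_american", "frac_japanese"))
fit$estimates$cl_pop   # typical apparent clearance, L/h
```

A thin command-line wrapper for shell use lives at `inst/cli/tvclpk.R`
(`generate`, `fit`, `vpc`, `simulate`, `er`, `pipeline` subcommands), and
`run_pipeline()` chains the stages with a seed ledger and hashed manifest.

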