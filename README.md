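# gwgtraj

Gestational weight gain (GWG) is one of the few modifiable determinants of
pregnancy outcome, and the Institute of Medicine's 2009 recommendations
bound the *total* gain a woman should accrue by term as a function of her
pre-pregnancy BMI (ppBMI): 12.5–18 kg (underweight, BMI < 18.5), 11.5–16 kg
(normal, 18.5–24.9), 7–11.5 kg (overweight, 25–29.9), 5–9 kg (obese, ≥ 30).
gwgtraj is an R package for epidemiologists and perinatal researchers who
want to work with these recommendations mid-pregnancy and beyond:

* **Trimester-resolved IOM classification** — the recommended window is
  projected to the gestational age of each weighing (linear interpolation
  from the 0.5–2 kg first-trimester anchor at week 13 to the recommended
  total at week 40, or an IOM weekly-rate mode) and each woman is labelled
  `L`/`N`/`H` (below/within/above) in the second and third trimester, with
  T2→T3 transition tables.
* **Group-based trajectory modelling (GBTM)** — weight against gestational
  week is modelled as a finite Gaussian mixture of group-specific
  polynomial mean curves,
  `P(Y_i | t_i) = Σ_j π_j Π_t φ(y_it; β_j'x(t_it), σ)`, fitted by EM with
  k-means initialisation and restarts, with BIC order selection
  (`BIC = −2 logL + k log n`), posterior-membership adequacy diagnostics
  (Nagin's 0.70 floor), per-group slopes with Wald CIs, and `autoplot()`
  trajectory bands.
* **Relative risks** — modified Poisson regression (log-link Poisson GLM on
  the binary outcome, HC0 sandwich variance) returning RR with 95% CI per
  exposure level, outcome-specific adjustment-covariate policies, plus the
  closed-form Katz CI for 2×2 tables.
* **Table statistics** — signed Cochran–Armitage trend tests across ordered
  exposure categories, assumption-gated ANOVA/Tukey vs
  Kruskal–Wallis/Dunn comparisons, chi-squared/Fisher omnibus tests with
  the Marascuillo pairwise-proportion procedure.
* **A seeded synthetic cohort generator** — three latent trajectory groups
  with realistic ppBMI mixes and log-linear outcome risks, so the full
  pipeline is testable end to end with known ground truth.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()` and `glance()` methods.

## Worked example

```r
library(gwgtraj)
library(dplyr)

cohort <- simulate_cohort(sim_config(n_subjects = 2000, seed = 42))

# classify gains against the projected IOM windows and tabulate transitions
cls <- classify_gwg(cohort)
gwg_transitions(cls)
#> IOM T2 -> T3 transition table (n = 2000 )
#>
#>    T3
#> T2    L   N   H
#>   L 184 116   6
#>   N  93 361 130
#>   H   4 164 942
#>
#> Strata:
#>          stratum count row_total pct_of_row pct_of_total
#>        T2H & T3H   942      1110       84.9         47.1
#>  T2H & (T3N|T3L)   168      1110       15.1          8.4
#>  T2N & (T3N|T3L)   454       584       77.7         22.7
#>        T2N & T3H   130       584       22.3          6.5
```

So 1110 women were above the recommendations in the second trimester; 15.1%
of them had normalised by the third trimester, while 47.1% of the whole
cohort stayed above in both.

```r
# three weight-trajectory profiles
fit <- fit_gbtm(cohort_to_long(cohort), j = 3, seed = 42, n_starts = 3)
fit
#> GBTM fit: 3 group(s), order 1, shared variance
#>   n = 2000 subjects (8000 obs), logLik = -28705.14, BIC = 57478.69
#>   shares: 0.558 0.345 0.097
gbtm_adequacy(fit)
#> # A tibble: 3 × 6
#>   group n_assigned observed_share expected_share mean_posterior adequate
#> 1 G1          1119         0.560          0.558           0.978 TRUE
#> 2 G2           688         0.344          0.345           0.964 TRUE
#> 3 G3           193         0.0965         0.0966          0.981 TRUE
```

The three simulated profiles are recovered with shares close to the
generating (0.583, 0.324, 0.093) and mean posterior probabilities well
above the 0.70 adequacy floor; observed and posterior-expected shares
agree. `autoplot(fit)` draws the mean curves with 95% bands.

```r
# adjusted relative risk of gestational diabetes by ppBMI category
cohort$bmi_cat <- who_category(cohort$ppbmi)
fit_robust_poisson(cohort, "gdm", "bmi_cat",
  covariates = covariate_set("gdm"), reference = "normal"
) |>
  select(level, rr, conf.low, conf.high, p.value, n_used)
#> # A tibble: 3 × 6
#>   level          rr conf.low conf.high   p.value n_used
#> 1 underweight 0.452    0.143      1.43 0.175       2000
#> 2 overweight  1.51     0.983      2.33 0.0599      2000
#> 3 obese       2.53     1.67       3.85 0.0000136   2000
```

Obese women carry a 2.5-fold adjusted risk of gestational diabetes relative
to normal-BMI women in this simulated cohort — the kind of gradient the
generator builds in through its log-linear risk models.

`run_pipeline(pipeline_config(...))` chains all of the above (exclusion
accounting, classification, transition table, BIC-swept GBTM, risk tables
for four exposures, trend tests) into a single `study_report`, and
`write_report()` emits it as JSON plus per-table CSVs.

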