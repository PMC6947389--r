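---
title: "Modelling gestational weight gain: IOM classification, trajectory mixtures and perinatal risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gestational weight gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gwgtraj analyses maternal weight kinetics during pregnancy along three axes:
compliance of gestational weight gain (GWG) with the Institute of Medicine
(IOM) 2009 recommendations, resolved per trimester; latent weight-trajectory
profiles found by group-based trajectory modelling (GBTM); and relative risks
of maternal and neonatal complications across the resulting exposure
categories. A seeded synthetic cohort generator makes every stage testable
without clinical data. This vignette explains the models, the tunable
parameters, and the design decisions behind them.

## IOM classification

Women are categorised by pre-pregnancy BMI (ppBMI = weight/height², kg/m²)
into the WHO classes underweight (< 18.5), normal (18.5–24.9), overweight
(25–29.9) and obese (≥ 30); each boundary belongs to the heavier class. The
IOM 2009 recommended total gains at term are 12.5–18, 11.5–16, 7–11.5 and
5–9 kg for the four classes.

The recommendations bound *total* gain at delivery, but clinical interest is
in judging a weight measured mid-pregnancy. The package offers two
projections of the window to a gestational age *g* (weeks):

* **interpolation** (default): each bound is interpolated linearly between
  the standard first-trimester anchor (0.5–2 kg at week 13) and the
  recommended total at week 40,
  `bound(g) = t1 + (total − t1)·(g − 13)/27`. Its virtue is that it uses
  only published quantities and recovers the published totals exactly at
  term.
* **rate**: each bound grows from the anchor at the IOM second/third
  trimester weekly-rate ranges (e.g. 0.35–0.50 kg/week for normal ppBMI).

Both are documented projections, not claims about how any particular study
computed mid-pregnancy compliance; the mode used is recorded in every
output. A gain below the projected window is labelled `L`, above it `H`,
within it `N`. Bounds are **inclusive**: "within recommendations" is read as
a closed interval, so a gain exactly on a bound is `N`. Trimesters are
delimited at completed weeks: T1 ≤ 13, T2 14–27, T3 ≥ 28; when several
weights fall in one trimester the latest is classified, being closest to
the projection horizon. Women lacking a ppBMI or any usable trimester
weight are flagged and excluded with a reason rather than dropped silently.

The T2→T3 transition table cross-tabulates the two labels. Stratum
percentages are reported both against the stratum's row total (e.g. the
share of T2H women who normalised by T3) and against the grand total,
because both normalisations are in routine use and conflating them is a
common reading error.

## Group-based trajectory modelling

The trajectory model is a finite Gaussian mixture over subjects: conditional
on latent group *j* (probability π_j), subject *i*'s weights at their visit
times are independent Normals centred on a group polynomial,

y_it | group j ~ N(β_j' x(t_it), σ²),  x(t) = (1, t, …, t^order).

The observed-data log-likelihood is
Σ_i log Σ_j π_j Π_t φ(y_it; β_j'x(t_it), σ_j). By default the weight
variable is *absolute* weight (kg) against gestational week with the
pre-pregnancy weight anchored as a week-0 observation; this lets profiles
separate on starting weight (hence ppBMI) as well as gain rate. A gain-mode
switch models gain instead.

**Estimation.** EM: the E-step computes posterior group responsibilities;
the M-step solves a responsibility-weighted polynomial least squares per
group, sets π to mean responsibilities and σ from weighted residuals. The
likelihood is non-decreasing across iterations (asserted in the tests).
Initialisation is k-means (`nstart = 10`) on per-subject (level, slope)
summaries; `n_starts` restarts (default 10) jitter the initial partition,
and the best attained likelihood wins. An optional `polish = TRUE` runs a
BFGS quasi-Newton refinement on the free parameters and is kept only if it
improves the likelihood. Convergence is declared at a relative
log-likelihood change below `tol = 1e-8` (default), within `max_iter = 500`.
Shared σ is the default (`variance_mode = "shared"`) because per-group
variances invite degenerate spikes; `per_group` is available.

**Identifiability and selection.** Mixture likelihoods are invariant to
label permutation, so groups are relabelled to ascending fitted mean weight
at week 20, making output unique. Fits with an effectively empty group
(π_j < 1/n) are flagged degenerate and excluded from selection. Model order
is chosen by minimising BIC = −2 logL + k log(n_subjects) — the same ranking
as the maximised Schwarz form — over a grid of group counts and polynomial
degrees, with the full sweep table returned. Default degree is 1 (linear),
which is where per-group slopes are directly interpretable; degrees 0–3 are
supported.

**Adequacy.** Following the usual GBTM practice, each group reports the
mean posterior probability among its assigned members (flagged below the
conventional 0.70 floor) and the observed versus posterior-expected group
shares, which should agree closely in a trustworthy grouping.

**Wald inference.** Per-group slope CIs and the mean-curve bands use the
responsibility-weighted information σ²(XᵀWX)⁻¹ of the final M-step. This
conditions on the soft assignment and slightly understates uncertainty when
groups overlap; with the high posteriors (> 0.9) typical of well-separated
weight profiles the effect is negligible. Pairwise slope differences are
z-tests treating groups as independent. Slopes are reported per modelled
time unit (weeks by default); no equivalence to any other time coding is
claimed.

## Relative risks

Binary outcomes (gestational diabetes, hypertensive disorders, caesarean
delivery, macrosomia, SGA, LGA, neonatal hypoglycemia) are related to an
exposure factor (ppBMI class, T2 or T3 IOM label, or trajectory profile) by
the *modified Poisson* approach: a log-link Poisson GLM on the 0/1 outcome,
whose exponentiated coefficients are relative risks, with the HC0 sandwich
variance repairing the misspecified Poisson variance. HC0 is the standard
variant in this setting; the variant name is recorded in every output.
Unadjusted 2×2 estimates use the closed-form ratio with the Katz
log-scale CI, and a saturated robust-Poisson model reproduces that closed
form to numerical accuracy (a test asserts agreement to 1e-8). Adjustment
sets follow a fixed policy: age, parity, smoking, chronic hypertension,
diploma, family income and pre-existing diabetes, with pre-existing
diabetes dropped for the gestational-diabetes outcome. Missing data are
handled complete-case per model, with the retained `n_used` reported.
p-values are Wald on the log scale.

The gestational-diabetes screening rule is also provided as a decision
function: a 50 g glucose challenge ≥ 10.3 mmol/L is diagnostic; a value in
7.8–10.2 mmol/L triggers a 75 g OGTT, positive if any of the fasting/1 h/2 h
values reaches 5.3/10.6/9 mmol/L; an in-band challenge without OGTT values
returns an indeterminate `NA`, never a negative.

## Supporting table statistics

* **Trend across ordered categories**: Cochran–Armitage with equally spaced
  scores, reported as a signed z (positive when proportions rise along the
  given order) whose square equals the familiar chi-squared-for-trend. Equal
  spacing is an assumption, made explicit because table "continuity"
  columns rarely state their scores.
* **Continuous variables between groups**: Shapiro–Wilk (on residuals,
  subsampled at 5000) and Bartlett gates at α = 0.05 choose one-way ANOVA
  with Tukey–Kramer post-hoc, else Kruskal–Wallis with Dunn's rank z-tests
  (Bonferroni-adjusted by default). A constant-valued group, for which
  Bartlett is undefined, falls through to the rank branch with a flag. The
  α = 0.05 gate is a convention, not a claim of optimality.
* **Categorical tables**: Pearson chi-squared when all expected counts are
  ≥ 5, else Fisher's exact; pairwise proportions compared by the
  Marascuillo procedure, flagging |p̂_i − p̂_j| above
  √χ²_{k−1,0.95} · √(p̂_i(1−p̂_i)/n_i + p̂_j(1−p̂_j)/n_j).

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the data structure the analysis
expects: three latent trajectory groups with shares (0.583, 0.324, 0.093)
and per-group ppBMI distributions centred at 21.2 (SD 2.2), 26.3 (3.1) and
35.6 (5.0) kg/m² — a normal-weight majority, an overweight faster-gaining
group, and a smaller obese group. Each woman's weight at week *w* is her
pre-pregnancy weight plus her group's gain polynomial at *w*, plus a
per-woman random slope deviation (SD 0.08 kg/week) and visit-level noise
(SD 1.2 kg). The random-slope term is deliberate: without it the
between-woman gain spread is constant over gestation, and no single noise
level can reproduce a realistic compliance mix at both trimesters
(roughly 14% below / 57% above the recommendations at T2 and 13% / 54% at
T3, as large unselected cohorts report). The default gain quadratics were
set once to land the compliance mix in that range under the default visit
schedule — one weighing per trimester at weeks ~10, ~22 and ~34 with ±2
weeks of uniform jitter — and are not tuned thereafter.

Outcomes are generated from log-linear risk models,
P(event) = exp(β₀ + Σβx) clipped to [0, 1] with a warning, so generating
coefficients *are* log relative risks and parameter-recovery tests have an
exact truth. SGA/LGA derive from birth weight against the 10th/90th
percentile of a Normal reference (mean 3400 g at 40 weeks, 130 g per week
of gestational age, SD 450 g — only the percentile mechanism matters, no
clinical growth standard is claimed), and macrosomia is birth weight
strictly above 4000 g. Supplying an explicit model for one of these three
overrides the derivation, which is how cohorts with a prescribed true RR
for, say, LGA are built. Outcomes are independent given covariates; no
outcome–outcome dependence is modelled.

What passing tests on this generator do show: the classifier, mixture
estimator, and risk models recover known structure at realistic scale and
noise. What they do not show: behaviour under informative visit schedules,
missing-not-at-random weights, twin pregnancies, secular trends, or
clinically realistic joint distributions of complications.

A consequence worth knowing: the full default cohort is *not* a
three-component linear mixture — gains are quadratic and women deviate from
their group slope — so at n ≈ 6500 a BIC sweep of linear mixtures resolves
this extra structure and legitimately prefers four components, while data
generated from the three-group mixture itself yield a clean J = 3
selection. This mirrors the well-known sensitivity of mixture-order
selection to within-group heterogeneity in large samples.

## Numerical and reproducibility notes

* All stochastic functions take an explicit seed and restore the caller's
  RNG state; identical config + seed gives byte-identical output, including
  the written JSON report.
* Derived seeds are drawn with `sample.int()` from the master-seeded
  stream rather than by small arithmetic offsets: nearby Mersenne–Twister
  seeds produce correlated streams, which we observed inflating
  between-replicate variance in coverage simulations.
* Weighted least-squares systems fall back to a ridge-stabilised solve
  (1e-8 on the diagonal) on singular designs; σ is floored at 1e-6.
* Ties in modal assignment break to the lowest group index; the canonical
  group order is ascending fitted weight at week 20.
* Test problem sizes: the likelihood oracle runs on 3–5 subjects; recovery
  and selection suites use n = 500–2000 subjects with 4 visits; risk
  coverage uses 200 replicates of n = 400 and 20 replicates at n = 6551.

## Known limitations

* Single-outcome GBTM only: no joint multi-trajectory modelling, no
  covariates on group membership, no censored or zero-inflated variants.
* The Wald covariance conditions on the soft assignment (see above).
* The projection of IOM windows to mid-pregnancy is a documented
  convention; boundary-inclusive labelling likewise.
* Exact reproduction of any specific cohort's adjusted RRs is out of
  scope; the package's claims are correctness on known-truth simulations
  and exact reproduction of published count arithmetic.
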