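---
title: "Modelling 5 versus 10 years of adjuvant endocrine therapy"
author: "eetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 5 versus 10 years of adjuvant endocrine therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetsim)
```

## The question

Extending adjuvant endocrine therapy (tamoxifen, tamoxifen with ovarian
suppression, or an aromatase inhibitor) from 5 to 10 years is guideline care
for women with invasive ER-positive breast cancer. The absolute mortality
benefit of the second five years is small, it accrues over decades, and the
extra years of treatment carry their own toxicity burden. Whether a given
woman gains or loses from extension therefore depends on her age (through
competing, non-breast-cancer mortality and through the regimen she would
receive), her stage and nodal status (through her baseline risk of
breast-cancer death), and on how adverse events are valued.

`eetsim` is an individual-level, continuous-time microsimulation built to
put these pieces on one scale: for each simulated woman it realizes her life
history twice — once per treatment duration — under *common random numbers*
(CRN), and reports lifetime (or 15-year) breast-cancer mortality, life-years
(LYs), and quality-adjusted life-years (QALYs), undiscounted and discounted
at 3% per year.

## Model structure

### Cohort

A diagnosed cohort of women ages 25–79 (birth cohorts 1935–2009) with ER+
stage 1–3 cancers. Age at diagnosis is drawn from a normal distribution
(mean 61, SD 13) truncated to the configured age window — a synthetic,
approximately SEER-shaped default, not an estimate from any specific
registry; it is fully configurable. The stage mix defaults to
(0.45, 0.25, 0.18, 0.12) over stages (1, 2a, 2b, 3), again a configurable
synthetic default. Nodal status is a deterministic function of stage:
stages 1/2a node-negative, 2b/3 node-positive.

### Competing mortality

Other-cause death uses a Gompertz–Makeham hazard
$\mu(a) = \alpha + \beta e^{\gamma a}$ with closed-form cumulative hazard
$H(a) = \alpha a + (\beta/\gamma)(e^{\gamma a} - 1)$. The defaults
($\alpha = 5\times10^{-4}$, $\beta = 3\times10^{-5}$, $\gamma = 0.095$)
give a remaining life expectancy of about 39 years at age 40 and 14 years
at age 70, approximating U.S. women. This is a synthetic stand-in for
cohort life tables; a tabulated (age, annual hazard) CSV can be supplied
instead, and a multiplicative per-birth-decade shift hook exists (flat by
default). Death ages are drawn by inverse transform from the survival
conditional on being alive at diagnosis and capped at 120.

### Baseline breast-cancer mortality and calibration

Absent extended therapy, each stratum (age group × nodal status) carries a
lifetime cumulative breast-cancer-death hazard $\Lambda$ spread over the
first 25 years after diagnosis by a truncated-Weibull time shape $F(t)$;
no breast-cancer death occurs after year 25. Node-positive strata use
$\Lambda \times 2.5$ (a synthetic relative-risk default, configurable; the
published tables give no node-specific mortality, so nodal contrasts are
directional rather than calibrated).

Two calibrations pin the model to published outputs:

1. **Level.** $\Lambda$ is fitted by bisection — on a fixed set of draws,
   so the objective is monotone — until the simulated 5-year-arm lifetime
   probability of breast-cancer death (competing mortality on) matches its
   target (11.91% for ages 25–49, 10.20% for 50–79). The search starts at
   the closed-form no-competing-mortality solution
   $\Lambda = -\ln(1 - p)/\mathrm{HR}_5$.
2. **Shape.** The Weibull scale is fitted so that the share of the
   10-vs-5-year mortality difference accrued by year 15 matches the
   published 15-year/25-year ratio (2.13/2.63 ≈ 0.810 for ages 25–49,
   0.10/0.16 = 0.625 for 50–79). The share is evaluated by a deterministic
   quadrature of the breast-cancer death sub-density against the
   cohort-mean other-cause survival — i.e. *with* competing mortality
   folded in, because censoring by other-cause death shifts the realized
   share upward, visibly so at ages 50–79. The $k = 1$ truncated
   exponential is used when it can reach the target; for the 50–79 share it
   cannot (its achievable minimum is ≈ 0.67 once competing mortality is
   included), so `calibrate_model()` escalates the Weibull shape parameter
   ($k = 1.5$ suffices) to place the time-to-death mode later. The two
   fits alternate (shape, level, shape, level) since each affects the
   other weakly.

### Treatment effect

Strategy-level hazard ratios (strategy vs no endocrine therapy) come from
trial meta-analyses: ages 25–49 stage 1, 0.70/0.54 (5-/10-year strategy);
ages 25–49 stages 2–3, 0.66/0.50; ages 50–79, 0.55/0.54. The 10-year AI
value is derived from extension-trial death counts under an exponential
survival model: 46/1983 vs 47/1983 deaths give a hazard ratio of 0.978
independent of follow-up length, and $0.55 \times 0.978 \approx 0.54$
(`trial_counts_to_hazards()`, `extend_hr()`).

Strategy HRs are converted to piecewise hazard multipliers: both arms share
$m = \mathrm{HR}_5$ on years (0, 5] (the two strategies are the same
treatment there), and the 10-year arm's tail multiplier on (5, 25] solves

$$\mathrm{HR}_5\,\Lambda(5) + m_{\text{tail}}\,[\Lambda(25) - \Lambda(5)]
  = \mathrm{HR}_{10}\,\Lambda(25),$$

so the between-arm mortality difference is exactly zero through year 5 and
the lifetime effect reproduces the strategy-level HRs. Each woman carries a
latent standard-exponential draw $E$ shared by both arms; she dies of
breast cancer (absent competing death) iff $E$ falls below the arm's
lifetime cumulative hazard, at the time where the piecewise-scaled
cumulative hazard reaches $E$. This coupling is monotone: with the same
$E$, the arm with lower multipliers never dies earlier.

Partial completion scales the hazard reduction linearly,
$\mathrm{HR}_{\text{eff}} = 1 - c\,(1 - \mathrm{HR})$, with $c_1$ applied
to the shared early multiplier and $c_2$ to the 10-year arm's incremental
tail reduction; adverse-event probabilities scale by the same fractions
(the 0–5-year portion by $c_1$, the 5–10 increment by $c_2$). The linear
form on the $(1-\mathrm{HR})$ scale is this package's choice; the source
analyses state the direction of the adjustment but not its functional
form. The base case is 100% completion.

### Adverse events and QALYs

Each grade 3–4 event type (stroke, pulmonary embolus, new cardiac
condition, fracture, endometrial cancer, osteoporosis) is sampled
independently with the cumulative probability of the arm's duration column;
the pooled grade 1–2 row is one Bernoulli, and an affected woman receives
exactly two dated instances (grade 1 at utility 0.9 at the window start,
grade 2 at 0.85 at the midpoint, one year each by default). Occurrence and
onset draws are keyed by event type but not by arm: cases shared by both
arms occur at the *same* time in (0, 5] — the arms are the identical
regimen there — and only the 10-year arm's incremental cases fall in
(5, 10]. (Coupling onsets by rescaling one fraction to each arm's window
instead would slide shared events later in the 10-year arm and cancel most
of the between-arm toxicity burden; with window-consistent coupling the
ages 50–79 discounted QALY difference is about −0.04 rather than −0.004.)
The published column totals are treated as derived sums, never as inputs;
an expected count, not P(any event).

Duration semantics follow the published table: fixed spans (fracture 1 y at
0.8, pulmonary embolus 9 months at 0.65, grade 1–2 one year each),
onset-to-end-of-treatment-window (osteoporosis at 0.9 — the "treatment
duration" entry is read as *while the window lasts*, one of two defensible
readings), lifetime (new cardiac condition at 0.8), and first-year-then-
lifetime (stroke 0.7 then 0.85; endometrial cancer 0.85 then 0.9). Fatal
(grade 5) toxicity is *not* modelled: the source material notes events
could be life-threatening but publishes no excess-mortality rates, so
adverse events here affect quality of life only.

Utility at time $t$ is multiplicative — age-band utility at current age
(0.913 at 20–29 declining to 0.724 at 80+) × stage utility (0.9 stage 1 to
0.8 stage 3, applied for the full post-diagnosis lifetime, a deliberate
simplification with no cure-state recovery) × the product of active
toxicity multipliers. Multiplicative combination is the standard QALY
convention; the source describes the weights being "considered together"
without fixing an operator. Discounting is continuous from diagnosis,
$e^{-rt}$ at $r = 0.03$; an annual-step variant
$(1+r)^{-\lfloor t\rfloor}$ is available through
`config$discounting = "annual"` in the per-woman path
(`compute_outcomes()`) for comparison — the vectorized cohort integrator
implements the continuous form only. A 15-year horizon option clips both
the integration and the breast-cancer death attribution at $t = 15$.

### Common random numbers

One master seed spawns purpose-keyed substreams (latent breast-cancer
exponential, other-cause uniform, per-event occurrence and onset uniforms),
with draws indexed by woman id. Consequences: the two arms are exactly
paired; an arm's realization never depends on whether the other arm was
simulated; extending the cohort leaves earlier women untouched; and paired
Monte-Carlo standard errors of between-arm differences are one to two
orders of magnitude below the unpaired ones, which is what makes
differences of 0.16 percentage points resolvable at feasible cohort sizes.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config()
cfg$cohort$age_range <- c(25, 49)   # tamoxifen-based strata
calib <- calibrate_model(cfg)
cmp <- compare_durations(cfg, calib = calib, n = 1e6)
subset(cmp$summary, stratum == "all")
```

At one million paired women this reports (seed 1): a lifetime
breast-cancer mortality reduction of about 2.60 percentage points
(5-year arm calibrated to 11.91%), an undiscounted LY gain near 0.72,
and a discounted QALY gain near 0.18. The corresponding ages 50–79
aromatase-inhibitor run shows a mortality reduction near 0.16 percentage
points whose small survival benefit is outweighed by toxicity, a
discounted QALY difference of about −0.04.

## Sensitivity machinery

`one_way_sweep()` moves one parameter family across its published range
under identical seeds and the base-case calibration: adverse-event
utilities, durations (the grade 1–2 upper bound is the full treatment
duration, which flips the ages 25–49 gain to a loss), or probabilities
(components scaled proportionally so the column total tracks its published
range). `two_way_best_worst()` combines duration and utility extremes;
its worst ≤ base ≤ best ordering is by construction under CRN.
`completion_scenarios()` runs $(c_1, c_2)$ schedules, and
`tornado_table()` orders everything by absolute deviation from the base
increment. Probabilistic sensitivity analysis is deliberately out of
scope. Default sweep granularity is three points (low, base, high).

## Numerical choices

* Truncated-Weibull quantities use `log1p`-based closed forms; the Makeham
  cumulative hazard is inverted by safeguarded Newton iteration (the
  function is convex and increasing, initialized from the Gompertz term).
* Lifetime-hazard bisection runs on one fixed draw set (the objective is a
  monotone step function of $\Lambda$; 45 halvings reach the Monte-Carlo
  granularity), and the achieved value is reported with its binomial SE.
* The time-shape quadrature uses a 1001-point trapezoid on (0, 25] and a
  60-point age grid; both are deterministic, so shape calibration is
  bit-reproducible.
* QALY integration is exact piecewise-constant integration (event
  endpoints and age-band crossings as breakpoints), not time-stepping;
  the cohort path and the scalar per-woman path agree to 10⁻⁸ and are
  cross-checked in the test suite.
* Degenerate inputs: zero discount rate collapses discounted onto
  undiscounted outcomes exactly; `n_women = 0` cohorts are empty, not
  errors; an unattainable time-shape target raises an error listing the
  achievable interval.

## Problem sizes

Default runs in this package's own analyses use 10⁶ paired women for the
ages 25–49 strata and 5×10⁶ for ages 50–79 (where the between-arm
difference is an order of magnitude smaller), processed in 5×10⁵-woman
chunks. Paired SEs at those sizes are ≈0.006 LY and ≈0.0003 QALY —
comfortably below the effects of interest. Calibration uses 5×10⁵ women.

## What the synthetic cohort does and does not show

The generator reproduces the *structure* of the target population —
age-by-regimen assignment, stage/nodal mix, competing mortality of
plausible magnitude — but not any registry's empirical joint distribution:
there is no screening or incidence front-end (the simulator starts at
diagnosis), no molecular subtypes (chemotherapy/trastuzumab effects are
absorbed in the calibrated baseline and the stage utility), no second
contralateral cancers, no recurrence intermediate states, no
regimen-switching at menopause, and no costs. Absolute LY/QALY *levels*
therefore depend on the synthetic life table and should not be read as
registry estimates; the calibrated *between-arm differences* are the
quantities the model is built to reproduce, and passing tests demonstrate
internal consistency plus agreement with the published differences — not
external validity on real cohorts.
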