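# eetsim

Individual-level microsimulation of **extended adjuvant endocrine therapy
duration** — 5 versus 10 years — for women diagnosed with estrogen-receptor-
positive (ER+), non-metastatic breast cancer.

Extending endocrine therapy to 10 years is guideline care, but its absolute
benefit is small, accrues over decades, and is bought with five extra years
of treatment toxicity. Whether a given woman comes out ahead depends on her
age, regimen (tamoxifen ± ovarian suppression under 50, aromatase inhibitor
at 50+), nodal status, competing mortality, and how adverse events are
valued. `eetsim` puts these on one scale for decision-analytic use: each
simulated woman's life history is realized under *both* treatment durations
with common random numbers (CRN), and the package reports paired lifetime
differences in breast-cancer mortality, life-years (LYs) and
quality-adjusted life-years (QALYs), discounted at 3%/year.

## Model core

* **Baseline breast-cancer mortality.** Per stratum (age group × nodal
  status), a lifetime cumulative hazard Λ spread over the first 25 years
  post-diagnosis by a truncated-Weibull time shape F(t); no breast-cancer
  death occurs after year 25. Λ is **calibrated** by common-random-number
  bisection so the 5-year arm's lifetime P(BC death) matches its target
  (11.91% ages 25–49; 10.20% ages 50–79), starting from the closed form
  Λ = −ln(1 − p)/HR₅; the Weibull scale is calibrated so the share of the
  between-arm difference accrued by year 15 matches the published
  15-/25-year ratio.
* **Treatment effect.** Strategy-level hazard ratios HR₅/HR₁₀ (0.70/0.54
  stage 1 and 0.66/0.50 stages 2–3 at ages 25–49; 0.55/0.54 at 50–79)
  become piecewise hazard multipliers: both arms share HR₅ on (0, 5], and
  the 10-year arm's tail multiplier solves
  `HR₅·Λ(5) + m_tail·(Λ(25) − Λ(5)) = HR₁₀·Λ(25)`,
  so arms are identical through year 5 and reproduce the lifetime HRs. The
  10-year AI ratio itself derives from extension-trial death counts under
  an exponential survival model: 46/1983 vs 47/1983 deaths → hazard ratio
  0.978 (follow-up-independent), and 0.55 × 0.978 ≈ 0.54.
* **Competing mortality.** Gompertz–Makeham life table
  μ(a) = α + β·e^{γa} (synthetic defaults approximating U.S. women;
  tabulated CSV tables supported), sampled by inverse transform
  conditional on being alive at diagnosis.
* **Adverse events → QALYs.** Grade 3–4 events (stroke, pulmonary embolus,
  cardiac, fracture, endometrial cancer, osteoporosis) and a pooled
  grade 1–2 row, sampled per regimen/duration column with arm-shared
  draws; each instance becomes a dated multiplicative utility decrement
  (fixed span, treatment-window, lifetime, or first-year-then-lifetime
  semantics). Utility at time t = age-band utility × stage utility ×
  active toxicity multipliers, integrated with continuous discounting.
* **Sensitivity machinery.** One-way sweeps over adverse-event utilities,
  durations and probabilities (proportional column scaling), two-way
  best/worst cases, completion-rate schedules
  (HR_eff = 1 − c·(1 − HR)), and tornado-ordered output — all under
  identical seeds so the base case is bit-identical across sweeps.

## Worked example

```r
library(eetsim)

cfg <- default_config()
cfg$cohort$age_range <- c(25, 49)        # tamoxifen-based strata
calib <- calibrate_model(cfg)            # fit Λ and the time shape
cmp <- compare_durations(cfg, calib = calib, n = 200000)
subset(cmp$summary,
       stratum %in% c("all", "age2549_node_negative", "age2549_node_positive") &
       metric %in% c("bc_death", "ly", "qaly_disc"))
```

```
               stratum    metric mean_5y mean_10y    diff  se_diff
                   all  bc_death  0.1173   0.0918 -0.0256 0.000353
                   all        ly 33.2791  33.9854  0.7063 0.009420
                   all qaly_disc 13.7225  13.8997  0.1772 0.002838
 age2549_node_negative  bc_death  0.0866   0.0679 -0.0188 0.000362
 age2549_node_negative        ly 34.2698  34.7898  0.5200 0.009654
 age2549_node_negative qaly_disc 14.3216  14.4486  0.1270 0.003009
 age2549_node_positive  bc_death  0.1893   0.1478 -0.0415 0.000815
 age2549_node_positive        ly 30.9589  32.1014  1.1425 0.021804
 age2549_node_positive qaly_disc 12.3193  12.6139  0.2947 0.006323
```

Reading this: extending tamoxifen-based therapy in women diagnosed at ages
25–49 cuts lifetime breast-cancer mortality by ≈2.6 percentage points
(from the calibrated 11.9%), worth ≈0.71 undiscounted life-years and ≈0.18
discounted QALYs per woman after adverse events; node-positive women gain
roughly twice what node-negative women do (`diff` is always the 10-year
arm minus the 5-year arm, and `se_diff` is the paired Monte-Carlo SE,
20–50× smaller than the unpaired one thanks to CRN). The analogous
ages 50–79 aromatase-inhibitor run shows a 0.16-point mortality reduction
outweighed by toxicity: a *negative* discounted QALY difference of about
−0.04.

A thin CLI wraps the same functions
(`Rscript inst/cli/eetsim.R run --out out/ --seed 1 --n 100000`, with
`calibrate`, `sensitivity`, `fixtures` and `validate` subcommands), writing
the comparison tables, calibration report, event-log sample and a
reproducibility manifest.

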