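---
title: "Model and methods: simulating chemotherapy omission in node-positive, genomically low-risk breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the model addresses

Randomized evidence shows that postmenopausal women with hormone-receptor
positive, HER2-negative breast cancer, one to three positive axillary nodes,
and a 21-gene recurrence score (RS) of 25 or less can omit adjuvant
chemotherapy without loss of distant recurrence-free survival (DRFS), while
premenopausal women retain a benefit. Trials report five-year endpoints in a
selected population. `bcmicrosim` implements a discrete-event microsimulation
that extends such evidence to population scale and lifetime horizon: it
generates virtual diagnosed women from conditional covariate distributions,
assigns each to endocrine or chemo-endocrine therapy at random, samples
competing-risk event histories (distant recurrence, breast cancer death after
recurrence, other-cause death), and accounts outcomes as Kaplan-Meier DRFS at
5 and 10 years, lifetime life-years, and discounted quality-adjusted
life-years (QALYs), overall and by menopausal status and race/ethnicity.

## Population model

Profiles are sampled along a conditional chain: race/ethnicity, then age
within race (5-year bins, uniform within bin, capped at 100 at diagnosis —
an assumption, since no upper truncation is published), menopausal status
given age (a logistic in age with midpoint near 50; a zero scale degenerates
to the step function used by the age-50 proxy sensitivity analysis), tumor
grade given age band and race, ER/PR co-positivity given grade and race,
tumor size given grade, age band and race, and finally RS from a
proportional-odds model on 0–25 whose latent location shifts with grade,
size, hormone sensitivity, age band and race.

The shipped tables are synthetic stand-ins constrained to reproduce the
published population characteristics: overall median age 57.4, 28.6%
premenopausal, 27.0/57.8/15.2% grade mix, 85.4% ER-and-PR-positive, 53.2%
of tumors at 2 cm or below, median RS 17 overall (18 premenopausal, 17
postmenopausal), with the published race-specific mean ages and the
higher-grade, less hormone-sensitive tumor mix of non-Hispanic Black women.
The race mixture weights (0.83/0.07/0.10 White/Black/Hispanic) are not
published; they were solved from internal consistency — the race-stratified
"All" outcome rows must mix to the overall row, and the race-specific mean
ages must mix to the overall median. What a green population test
establishes is that the generator reproduces these *marginals*; it does not
establish that higher-order interactions (for example grade-by-size
dependence within race) match any registry.

## Event engine

Each patient carries a distant-recurrence hazard
`h(t) = h0_meno(t) * exp(sum log-sHR) * c_meno(t)`, a piecewise-constant
baseline per menopausal stratum on breaks (0, 5, 10, 20, 100] years,
proportional sub-hazard ratios for grade, size, hormone sensitivity, RS band
and race/ethnicity, and a menopause-specific chemotherapy hazard ratio
`c_meno(t)` applied in the chemo-endocrine arm. Event times are drawn by
inverting the cumulative hazard against an Exponential(1) deviate.
Other-cause death walks an annual life table upward from the continuous
diagnosis age (piecewise-exponential within year of age; the terminal age
carries probability 1, so every history is finite). If recurrence precedes
other-cause death, a lognormal post-recurrence survival time sets breast
cancer death; death occurs at the earlier of the two. Death with distant
recurrence as its first manifestation is the boundary case of a zero
post-recurrence draw — the DRFS event is at the recurrence time either way.
Grade 3–4 toxicity occurs with probability 0.175 (95% CI 0.17–0.20) in the
chemo-endocrine arm only; adherence is 100% by construction; chemotherapy
affects only the distant-recurrence hazard, so toxicity enters outcomes
through utilities alone.

Treatment-effect uncertainty uses an empirical-Bayes draw: each run draws
one lognormal deviation per menopausal stratum around the calibrated
chemotherapy effect (prior SD 0.02 on the log scale — a deliberately modest
value representing estimation error in the underlying trial effects; there
is no published value to adopt).

All randomness is keyed by (seed, stream, patient id), so results are
independent of iteration order and chunking, and sensitivity scenarios with
a shared seed are common-random-number comparisons.

## Outcome accounting

DRFS follows the standardized endpoint convention: distant recurrence (or
death with recurrence as first manifestation) is the event; other-cause
death without recurrence censors. The Kaplan-Meier estimator processes ties
events-before-censorings and is checked against an independent reference
implementation. Life-years are lifetime by default (the published life-year
tables are lifetime; DRFS is truncated at its stated horizons).

Utilities combine multiplicatively: an age-band utility (0.913 at 20–29
declining to 0.771 at 70–79, held constant outside that range — the
conservative choice for ages 80+, rather than inventing a decrement), the
invasive-breast-cancer utility 0.731 for life, chemotherapy 0.9 and grade
3–4 toxicity 0.7 each for their first six months, and distant recurrence
0.4 for three years (after which the pre-recurrence utility resumes; a
config switch applies it until death instead). The multiplicative rule is a
modeling choice — the source material says utilities were "adjusted" without
giving the rule. QALYs integrate this path against the annual-compounding
discount weight `(1+r)^(-t)` (default 3%; 1% and 5% in sensitivity). Because
the path is piecewise constant and the windows are known, the integral has a
closed form (inclusion–exclusion over the disutility windows); an explicit
segment-enumeration route is kept and the two are cross-checked to 1e-9 in
the tests.

A consequence worth stating plainly: with this discounting, the *discounted
QALY levels* printed in the source tables (for example 10.1 discounted vs
12.4 undiscounted over a 19.6-year mean survival) are not reachable — that
ratio implies a much milder effective discount than 3% per year, whichever
utility combination rule is used. The undiscounted levels and all
*incremental* quantities are internally consistent and are what the package
calibrates to and tests.

## Calibration

The baseline hazards, race sub-hazard ratios, chemotherapy effects,
post-recurrence survival and the other-cause life table are not published;
they are fitted in-repo and the shipped configs carry `generated_by`
provenance blocks so nobody mistakes them for published inputs. Two stages:

1. **Deterministic stage.** The population cell table gives the covariate
   mixture exactly, so the expected net DRFS
   `S(t) = sum_x p(x) exp(-H(t) m(x))` is computable without simulation.
   Baseline periods (0–5, 5–10), the Black and Hispanic sub-hazard ratios,
   and the trial-horizon chemotherapy effects are solved by
   one-dimensional root finding against the printed 5/10-year KM values.
2. **Stochastic stage.** The post-10-year baselines, the late
   postmenopausal chemotherapy effect, post-recurrence survival locations
   and the life-table scale factors are tuned by coordinate descent on log
   scale factors with common random numbers (`calibrate()`), against the
   life-year levels and the incremental life-year/QALY targets. Calibration
   simulates both arms for every patient (paired counterfactuals), which
   shrinks the Monte-Carlo noise of incremental targets an order of
   magnitude below the target tolerances; production analyses randomize
   1:1 as the protocol dictates.

Two deliberate deviations from the most parsimonious design: (a) the
postmenopausal chemotherapy effect is allowed to differ after year 10 — a
time-constant hazard ratio cannot produce both the printed ~2.3-point
10-year DRFS deficit and the printed 2.0 lifetime life-year loss (the
lifetime cumulative-incidence gap a constant ratio can generate is bounded
well below what 2.0 years requires); (b) the life table is calibrated
rather than taken from vital statistics — the printed race-specific
life-year levels (11.7 years for Black women at mean age 56) are far below
any U.S. life table and can only be met by a synthetic one, which is why
the shipped file is named `life_table_synthetic.csv`.

Identifiability: each free scale factor moves a distinct target block
(early baselines <-> 5/10-year DRFS per stratum and arm; late baselines and
post-recurrence survival <-> life-year levels; late chemotherapy effect <->
the postmenopausal life-year increment; life-table factors <-> race-level
life-year levels). The printed tables are themselves mutually inconsistent
in places (the race rows do not exactly mix to the overall row; the overall
life-year increment differs from the menopause-stratified mixture by ~0.2
years), so calibration is weighted least squares, not interpolation, and
lands within each printed value's test tolerance rather than on it.

## Virtual-trial validation

The validation harness emulates the randomized-trial protocol: the same
population generator with the premenopausal enrollment share fixed at 36.4%
(solved from consistency of the published validation rows; the trial's
characteristic tables are not in the main text), 1:1 randomization, a
trial-horizon chemotherapy effect set solved against the published 5-year
validation comparison, and a trial size from the standard two-proportion
power formula (control rate 0.93, detectable difference 2.5 points, 5%
two-sided alpha, 80% power — the published analysis states the power
specification without printing numbers). At that size a single virtual
trial carries percent-scale Monte-Carlo noise — exactly as the published
single run does, whose own rows are mutually inconsistent at that
magnitude — so the harness can average replicates and report the
Monte-Carlo SE per cell.

## Numerical choices and degenerate inputs

Ties in the KM estimator: events before censorings. Zero-width age bins,
zero menopause scale (step function), zero prior scale, zero hazards, zero
post-recurrence survival and zero discount rate are all exact special
cases, not limits, and are tested. A zero-tolerance calibration target
fails verification by construction under stochastic simulation. Patient
ages outside the life table raise errors rather than extrapolating.

## Known limitations

* The synthetic population matches published marginals, not registry
  microdata; subgroup results inherit whatever the conditional tables
  cannot express (no within-race grade-size interaction, for instance).
* The late (post-10-year) postmenopausal chemotherapy harm is a calibration
  artifact required by the printed lifetime losses; it should not be read
  as an estimated biological effect.
* Discounted QALY *levels* are reported as computed under
  `(1+r)^(-t)` discounting and intentionally do not match the printed
  levels (see above); increments do.
* No local/regional recurrence, second primaries, endocrine nonadherence or
  endocrine-therapy disutility; no cost accounting.
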