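---
title: "Screening young children for severe sleep disorders from 14-day sleep logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening young children for severe sleep disorders from 14-day sleep logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoscreen)
```

## The screening problem

Severe sleep disorders in infants and preschool children — sleep-onset
insomnia with onset after 22:30, fragmented sleep with more than three night
wakings, habitual sleep under 8 hours, or day-to-day schedule variation above
an hour — call for prompt intervention, but individual clinical assessment of
sleep diaries does not scale to population screening. `somnoscreen`
implements an automatic screener: ten summary variables are extracted from a
14-day parental sleep log and fed to a per-age-group pair of Fisher linear
classification functions; the child is judged 1 (no severe disorder) or 0
(severe disorder, refer for intervention). The package also re-implements the
full training pipeline so that classifier banks can be refitted on new
labeled cohorts, and ships a seeded synthetic cohort generator so every stage
is testable without clinical data.

## Data model

A log is a 14 × 288 grid of 5-minute epochs, 1 = awake, 0 = asleep. Each
logical day is anchored at 03:00 and covers decimal hours [3, 27), so the
wake-up window (3–10 h) and the bed window (18–26 h, i.e. 18:00–02:00) both
fall inside a single logical day; clock times after midnight live on the
extended scale (01:27 → 25.45). An epoch is asleep only when its half-open
5-minute window is fully covered by a recorded sleep interval — partial
coverage counts as awake, a deterministic and conservative rasterization.
Intervals may begin the evening before day 1 or run past the final 03:00
boundary; the out-of-span parts are truncated (the recorded nights, not the
window boundaries, define the data). A calendar day with neither an interval
nor a daily-flags row is a missing day; features average over non-missing
days, and by default a child with more than 3 missing days is excluded from
screening rather than imputed (the threshold is configurable; the source
study excluded incomplete records without stating a cut-off).

The nocturnal window of day *d* is 19:00–09:00, i.e. hours [19, 33) spilling
into day *d*+1. It is complete only for days 1–13 of a 14-day log, so
nocturnal statistics average over those 13 nights — no extrapolation beyond
the recorded span.

## The ten variables

Four of the ten variables come from sigmoid fits of the *sleep–wake rate
curve*: for each epoch in a window, the mean awake state over the observed
days. The model is

$$y = a + \frac{b - a}{1 + e^{(c - x)/d}}$$

where $c$ is the time at which sleep and wake are equally likely — the
estimated wake-up or bed time — and $d$ is the slope parameter. If the
schedule is perfectly regular the rate curve is a step function and $d \to
0$; the more the transition time varies from day to day, the larger $|d|$.
For a normal day-to-day spread with standard deviation $\sigma$, the rate
curve is approximately a normal CDF and the fitted logistic scale satisfies
$d \approx \sigma\sqrt{3}/\pi$, which the test suite checks directly. Wake
fits are rising ($d > 0$, window 3–10 h); bed fits are falling ($d < 0$,
window 18–26 h), so bed-time variation is reported as a negative number. One
note on the parameterization: in the formula above $a$ is the early-window
asymptote only when $d > 0$; with the falling convention $d < 0$ the roles
of $a$ and $b$ swap, and the package initializes and reports falling fits
with $b \approx 1$ (awake before bed) and $a \approx 0$.

The fit is nonlinear least squares on the averaged rate curve
(Levenberg–Marquardt via `minpack.lm`), which is the Gaussian
maximum-likelihood estimate for that curve. Nonlinear sigmoid fits are
sensitive to starting values, so the estimate is *jitter-averaged*: uniform
noise on [−`jitter_eps`, `jitter_eps`] (default 0.01) is added to every rate
value, the fit is repeated `n_repeats` times (default 100), and the final
estimate is the mean over converged repeats. A fit fails if fewer than half
the repeats converge. Starting values are data-driven: $c_0$ at the first
0.5-crossing of the curve, $|d_0| = 0.25$ h, asymptotes at 0 and 1, with box
bounds $a, b \in [-0.2, 1.2]$, $c$ inside the window, and $|d| \in
[10^{-4}, 2]$. The lower bound on $|d|$ keeps step-function inputs
well-posed; on constant-schedule logs the fitted $d$ lands below 0.003 with
$c$ within one epoch of the true time. With `n_repeats = 100` the
seed-to-seed standard deviation of $c$ is below 0.01 h.

The remaining six variables are direct summaries: total sleep duration
(asleep hours per [3, 27) day), nocturnal sleep duration (asleep hours per
19:00–09:00 night), night wakings, evening naps, and the breakfast and
self-awakening rates (means of daily binary flags). Two definitions were
genuinely open and were fixed as follows:

* **Night wakings** prefer the parent-reported counts when present for at
  least half the days (the source study's diary collected them; its low
  published mean of 0.14/night suggests reported counts). Otherwise they are
  counted from the grid as maximal awake runs strictly between sleep onset
  (first asleep epoch after 19:00) and final awakening (last asleep epoch
  before 09:00), so the tool remains self-contained.
* **Evening nap** is an episode count — the mean number of maximal asleep
  runs intersecting 15:00–19:00 per day — not an epoch fraction, because the
  published maximum of 1.62 exceeds what a fraction could reach.

## The classifier bank

The packaged bank holds the published Fisher classification function
coefficients for eight age groups (3–5, 6–9, 10–14, 15–18, 19–47, 48–59,
60–71, 72–83 months); the 0–2-month group had too small a sample for a
classifier, and such children are referred to clinical review. For a feature
vector $x$ the two scores are $y_g = \beta_g^\top x + \beta_{0g}$, $g \in
\{0, 1\}$, and the judgment is 1 iff $y_1 > y_0$. An exact tie (a
measure-zero event) is labeled 0, the safe screening default. Bed times are
fed to the classifiers on the extended 24-hour scale, consistent with the
published descriptive statistics being computed on a continuous scale. For
the 48–59-month group the published coefficient listing and the summary
table name *wake-up time variation* as a discriminant variable while the
accompanying prose mentions *bed time variation*; the bank follows the
tables.

The 3–5-month classifier uses bed time alone, which makes its decision rule
fully checkable by hand: the scores cross at bed time
$(492.019 - 391.015)/(41.685 - 37.154) \approx 22.292$ (≈ 22:18), with
judgment 1 strictly below and 0 strictly above. The acceptance suite
reproduces the published worked scores at bed times 21.0 and 23.0 exactly
and confirms the flip point by screening simulated deterministic sleepers.

## Training pipeline

Training is two-group linear discriminant analysis per age group with
stepwise variable selection minimizing Wilks' lambda
$\Lambda = \det W / \det T$ (pooled within-group over total scatter). At
each step the candidate minimizing $\Lambda$ enters if its partial
$F$-to-enter reaches `f_enter`; included variables with partial
$F$-to-remove below `f_remove` are then removed; the trace is capped at 20
actions. The source study names only the Wilks criterion and the 20-step
cap, so the thresholds default to the SPSS conventions `f_enter = 3.84`,
`f_remove = 2.71` (both configurable). Near-constant variables (pooled
within-group variance below 1e−12) are excluded up front to guard against
singular scatter.

From the selected set the canonical fit reports the discriminant eigenvalue
$\lambda$ (largest eigenvalue of $W^{-1}B$), which in the two-group case
satisfies $\Lambda = 1/(1+\lambda)$ and $R^2 = \lambda/(1+\lambda)$ for the
canonical correlation $R$; significance is Bartlett's
$\chi^2 = -(n - 1 - (p+2)/2)\ln\Lambda$ with $p$ degrees of freedom, where
$p$ is the number of selected variables. The packaged
`published_group_stats()` table reproduces these identities from its printed
eigenvalues to within 0.002 (absolute, on $\Lambda$ and $R$) and 0.2%
(relative, on $\chi^2$) — the residual is printed-precision rounding, e.g.
the 60–71-month $R$ rounds to 0.375 against a printed 0.376.

Fisher functions use the covariance form $\beta_g = S^{-1}\mu_g$,
$\beta_{0g} = -\tfrac12 \mu_g^\top S^{-1}\mu_g + \log \pi_g$ with $S$ the
pooled within-group covariance. Priors default to equal (the SPSS default;
configurable to group-size priors). Validation is leave-one-out: the
functions are refitted on $n-1$ cases and the held-out case classified.
Because the original clinical cohort is unavailable, retraining is
procedure-faithful, not coefficient-faithful: retrained constants will not
numerically match the packaged bank.

The tests tie every piece to an independent oracle: $\Lambda$ against
`manova`'s Wilks statistic on a thousand random data sets (agreement to
1e−10), Fisher-rule classification against Mahalanobis nearest-centroid
classification with prior offsets (exact agreement), leave-one-out against
`MASS::lda(CV = TRUE)` (exact agreement), stepwise selections against
same-size exhaustive-search Wilks optima (the only non-degenerate reading of
"best subset", since $\Lambda$ is monotone non-increasing in the variable
set), and LOO accuracy against the analytic two-class Bayes accuracy
$\Phi(\Delta/2\sigma)$ for a known one-variable shift.

## Synthetic cohorts

The generator encodes severity at the generative-parameter level, so labels
are noiseless class indicators (an optional label-noise rate can be set).
Each child draws a nightly schedule — sleep onset and wake time normal with
per-class means and day-to-day SDs, clipped to the bed and wake windows —
plus Poisson night wakings placed uniformly within the night, optional
afternoon and evening naps, and Bernoulli daily flags. Day-level draws are
independent (no autocorrelation): the variation parameter $d$ measures only
the marginal day-to-day spread, so this is the simplest structure matching
what the features measure. The night before day 1 is generated too, so
first-morning data are covered.

Non-severe defaults are anchored to the published cohort descriptive
statistics (wake 6.84 h, bed 21.44 h for the dominant 19–47-month group,
day-to-day SDs of about 0.45–0.47 h so that fitted variations center near
the published 0.26/−0.27), with age trends following the developmental
narrative: younger children sleep earlier, nap more, and wake more at night.
Severe profiles violate the clinical criteria by construction: mean sleep
onset 23:00 (after the 22:30 threshold), day-to-day SD 1.1 h (> 60-minute
variation), and an elevated night-waking rate (> 3/night). Between-child
heterogeneity — personal mean offsets (SD 0.45/0.55 h), per-child day-to-day
SD spread, gamma-distributed waking rates, and beta-distributed flag
probabilities — is calibrated so cohort-level feature SDs have the published
orders of magnitude (the strong skews of the published night-waking and
breakfast distributions emerge naturally from the gamma/beta shapes). For
controlled experiments `group_profile()` defaults all heterogeneity to zero.

What the generator does *not* emulate: weekend/weekday structure, seasonal
or developmental drift within the 14 days, autocorrelated schedules,
age-specific waking durations, or the original study's class prevalence
(548/7008). Passing end-to-end tests therefore demonstrates that the
machinery recovers planted structure under realistic magnitudes, not that
the packaged bank's published accuracies transfer to any particular
population.

## Validation problem sizes

The shipped tests and the acceptance script use: exact-logistic and
step-function fits on the 84-epoch wake grid; 500 simulated days for the
spread-recovery checks; 1,000 random small data sets (p ≤ 3, n ≤ 50) for
the Wilks/Mahalanobis oracles; 200 replicates (p = 4, n = 60) for
stepwise-vs-exhaustive; and a 400 + 400 19–47-month cohort at
`n_repeats = 100` for the end-to-end experiment, whose classes differ only
in mean sleep onset (21.4 vs 23.0, day SD 0.5). On the extracted 14-day
feature scale that separation is $\Delta = 1.6$ h against a feature SD of
about $0.5/\sqrt{14} \approx 0.13$ h, giving an analytic Bayes accuracy of
effectively 1; bed time enters the stepwise trace first with an $F$
statistic three to four orders of magnitude above any later entry, and
leave-one-out accuracy matches the Bayes reference within 5 points. With ten
candidate features and ~800 cases, conditionally uninformative variables
occasionally clear the default `f_enter` after bed time enters — the
familiar type-I behavior of stepwise selection, which is why the end-to-end
checks assert the identity and dominance of the first-entered variable
rather than an exact selected set.

## Limitations

* The screener applies published coefficients; it cannot be recalibrated to
  the original cohort, which is not publicly downloadable.
* Sleep logs are parent-reported; the rasterization trusts the diary.
* The sigmoid model assumes a single dominant sleep-wake transition per
  window; polyphasic schedules (common under 6 months) can fail the wake-fit
  preconditions, and such children are reported as extraction failures
  rather than silently mislabeled.
* Judgments are binary; the original four clinical grades are collapsed
  (A/B/C → 1, D → 0) by design.
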