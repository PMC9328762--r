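---
title: "Methods: tachometric analysis of urgent saccadic choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tachometric analysis of urgent saccadic choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tachorace)
```

This vignette records the methodological conventions implemented by the
package: how tachometric curves are estimated, how the analytic
psychometric functions are fitted, how two curves are compared by an
optimal time shift, how the race model is specified and calibrated, and
how uncertainty is quantified. It is the reference for every numeric
convention a reader might need to re-derive a result.

## Task structure and raw processing time

Each trial presents a go signal and, after a gap of `gap_ms`
milliseconds, a visual cue on the left or right. Prosaccade trials
require a saccade toward the cue; antisaccade trials away from it. With
a positive gap the movement must be prepared before the cue appears
(urgent regime), so the cue-viewing time that could inform the choice is
the raw processing time

$$\mathrm{rPT} = \mathrm{RT} - \mathrm{gap},$$

computed by `compute_rpt()`. Negative rPTs (movement committed before
any cue information arrived) are legitimate guesses. `filter_urgent()`
retains completed trials with `gap_ms >= 0`; aborted trials (no scored
choice) are flagged, not dropped, so abort rates and history labels
remain computable.

## Tachometric curve estimation

`tachometric()` slides a 21 ms bin along the rPT axis in 1 ms steps.
Bins are half-open intervals $[c - w/2,\, c + w/2)$ so that adjacent
non-overlapping bins never double-count a trial. Each defined grid
point reports the fraction of correct trials among those in its bin;
points with fewer than `min_bin_n` trials (default 10) are undefined
(`NA`) rather than extrapolated. Confidence intervals are exact
Clopper–Pearson binomial intervals via beta quantiles, which remain
defined at observed fractions of 0 and 1. For model-predicted curves
(`predicted_tachometric()`, 50,000 simulated trials by default) the
threshold is raised to `min_bin_n = 1000` because the curve represents a
model expectation and only well-populated bins are meaningful.

Downstream consumers interpolate linearly between adjacent *defined*
grid points only; gaps and regions outside the grid stay undefined
(`NA`) and are dropped from averages, never imputed.

## Psychometric functions and landmarks

Prosaccade curves are fitted with a rising sigmoid

$$s(x) = B + \frac{A - B}{1 + e^{-(x - C)/D}},$$

where $B$ is the chance baseline, $A$ the asymptote, $C$ the rise point
and $D$ the slope scale. Antisaccade curves are fitted with the
pointwise maximum of a falling and a rising limb,

$$v(x) = \max\{s_L(x),\, s_R(x),\, 0\},$$

with $s_L$ descending from the chance plateau $A_L$ to the shared
minimum $B_{LR}$ around the drop point $C_L$, and $s_R$ climbing from
$B_{LR}$ to the asymptote $A_R$ around the rise point $C_R$. The drop
point is where accuracy is halfway from chance to the capture minimum;
the rise point is halfway from the minimum to the asymptote.

Fitting minimizes the mean absolute error (MAE) over the defined grid
points, equally weighted. MAE is robust to the occasional ragged bin
and matches the accuracy scale of the data, but it is non-smooth, so
minimization uses the derivative-free Nelder–Mead simplex restarted
from several jittered versions of moment-based initial values (10
restarts by default, fixed internal seed; the caller's RNG stream is
saved and restored). Three structural constraints keep the problem
identified:

* $C_R = C_L + e^{\theta}$, so the drop always precedes the rise;
* with the chance parameter free, $A_L = B_{LR} + (1 - B_{LR})
  \cdot \mathrm{logistic}(\theta)$, so the falling limb always descends
  — without this the optimizer can flatten or invert the limb and the
  fitted chance level becomes meaningless;
* soft box penalties keep $C$ (or $C_L, C_R$) inside the measured rPT
  range and the slope scales below a quarter of its span, excluding
  the degenerate solution in which a limb becomes an arbitrary
  constant far outside the data.

Fits whose dynamic range (asymptote minus baseline for the sigmoid,
chance minus minimum for the drop limb) is below 0.05 are flagged
degenerate and their landmark is reported as `NA`. By default the
chance parameter is frozen at 0.5; history- or bias-conditioned curves
are fitted with it free (`fix_chance = FALSE`), since measuring the
displaced guessing baseline is the point of those analyses.

## Optimal time-shift comparison

`optimal_shift(f1, f2, window_ms)` transforms the test curve $f_2$ by a
baseline offset $\Delta b$, gain $g$ and time shift $\Delta x$, and
minimizes the mean absolute residual

$$E = \left\langle\, \big|\, g\,(\Delta b + f_2(x + \Delta x)) -
f_1(x) \,\big| \,\right\rangle$$

over the stated rPT window. $\Delta x$ is searched exhaustively on a
1 ms grid (±60 ms by default) — making the estimate global in the
parameter of interest — with a Nelder–Mead inner minimization over
$(\Delta b, g)$ at each shift and a final quadratic refinement of
$\Delta x$ to sub-millisecond resolution. Window points where either
curve is undefined are dropped; fewer than `min_points` (default 30)
usable points is a coverage error, not a silent answer. Setting
`allow_gain`/`allow_baseline` to `FALSE` yields a pure time-shift
comparison.

`pro_anti_shift()` applies the convention for comparing the two tasks'
exogenous responses: the prosaccade curve is inverted about chance
($f \mapsto 1 - f$), so its capture-driven early *rise* becomes an
early *drop*, and it is aligned against the antisaccade curve over the
early departure-from-chance window (55–105 ms). If the exogenous
response is identical in the two tasks, the optimal shift is zero.

## Race model

`simulate_session()` integrates a two-plan race to threshold in 1 ms
Euler steps. Each trial draws buildup rates for the cue-directed and
anti plans from a bivariate normal (floored at zero); the larger rate
goes to the cue-directed plan with probability $0.5 + \mathrm{bias}$.
Plans start ramping after a Gaussian go-latency. Cue onset triggers,
after an afferent delay (`exo_latency_ms`), the exogenous response
interval (ERI, `eri_duration_ms`): the cue-directed plan is halted for
`halt_ms` and then accelerated by `exo_accel` per ms, while the anti
plan is halted throughout. After the ERI the endogenous signal
accelerates the task-appropriate plan (`endo_accel`) and decelerates
the other (`endo_decel`). **The antisaccade and prosaccade variants
differ only in which plan the endogenous signal favors**; all exogenous
dynamics are shared, which is why their early curve segments align at
zero shift. The first plan to reach threshold triggers the saccade
after a fixed efferent delay; simultaneous crossings are resolved by
the larger overshoot, exact ties at random. Decelerated rates may go
negative (the plan shrinks) but activity is floored at zero, and
integration is capped at `timeout_ms` (such trials are returned as
aborted).

Default parameters are frozen in the versioned configuration
`inst/extdata/race_params_default.json`. They were calibrated once, by
hand, to reproduce the qualitative signatures of the urgent tasks —
antisaccade accuracy collapsing toward zero at rPTs of roughly
90–140 ms and recovering above 90% beyond ~220 ms; a monotone rising
prosaccade curve bounded away from zero; near-zero pro-vs-anti shift;
and bias sensitivity concentrated in the antisaccade rise point — and
are not adjusted per analysis. The `"low"` luminance preset delays and
weakens the exogenous response (`exo_latency_ms` 112 vs 80 ms,
`exo_accel` 0.8 vs 1.2), shifting both curves rightward by ~30 ms, as a
dimmer cue does.

## Target-history conditioning

`label_history()` conditions on the history of *target* locations (where
the response should have gone), not on cues or on the participant's
choices. At depth $d$ a trial is a *repeat* (pattern AA, AAA, AAAA)
when the $d$ preceding targets in the same participant-and-block run
all equal its own target, and a *switch* (AB, AAB, AAAB) when they
agree with each other but differ from its own. Missing, non-contiguous
or aborted predecessors leave a trial unlabeled. `conditioned_analysis()`
builds each condition's tachometric curve and fits it with the chance
parameter free, reporting the fitted chance level and rise point;
conditions with fewer than 500 trials are flagged unstable.

`rise_vs_chance_slope()` expresses the central trade-off — a guessing
bias toward the upcoming target raises the chance plateau *and* buys an
earlier rise — as a positive "ms of earlier rise per unit of chance"
slope: the exact ratio of differences for two conditions, a
least-absolute-deviations line for more. `model_bias_sweep()` produces
the model-side counterpart by simulating sessions across lateral-bias
values and fitting each with chance free; in the antisaccade model the
rise point falls as chance rises, while the prosaccade rise point is
nearly flat.

## Resampling

`bootstrap_stat()` resamples *trials* with replacement — the same unit
the curves are estimated from — recomputes the statistic per resample,
and reports the percentile interval. Iterations draw from a
prefix-stable seed stream: increasing `n_iter` extends the sequence
without changing earlier resamples, so precision can be raised without
invalidating previous runs. Failed refits are recorded as `NA`; more
than 20% failures marks the result unreliable rather than silently
narrowing the interval.

`permutation_correlation()` tests a cross-participant Pearson
correlation by re-pairing the second variable at random. The two-sided
p value uses add-one smoothing, $p = (1 + \#\{|\rho_{\pi}| \ge
|\rho_{\mathrm{obs}}|\})/(n_{\mathrm{perm}} + 1)$, so it is never
exactly zero.

## Synthetic ground truth

`generate_trials()` draws trials directly from a stated accuracy
function of rPT, an RT distribution (truncated normal, mean 230 ms, sd
60, support [80, 600] ms) and the design gap set — independently of the
race model — so that binning, fitting, shift and history analyses can
be validated against known truth. Below the guessing cutoff (80 ms
rPT) choices follow a lateral/previous-target bias whose strength can
grow with the length of the preceding target-repeat run (capped);
above it, correctness is Bernoulli with probability given by the truth
curve. This separation lets each pipeline stage be tested for exact
recovery before it ever touches model output.

```{r example}
params <- race_params()
curve <- predicted_tachometric(params, "anti", n_trials = 20000,
                               seed = 1, min_bin_n = 500)
fit <- fit_anti(curve)
fit
```
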