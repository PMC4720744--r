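---
title: "Analysing two-phase single-case data with scedab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing two-phase single-case data with scedab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedab)
```

## The setting and the data model

An AB design records one behavioural measure over consecutive sessions: a
baseline phase of `n_pre` sessions before an intervention, then `n_post`
sessions after it. There is no within-study replication, so nothing here can
establish a causal intervention effect; the package's narrative labels
therefore speak of *behavioural change* only. The data object,
`two_phase_series()`, is a tibble of (time, score, phase) rows with the
improvement direction (`aim`) attached: whether lower or higher scores are
better flips every directional inequality in the package, once, at the data
level. Sessions are 1-based consecutive integers derived from row position;
the long-CSV `Time` column is validated against that but never stored.
Missing scores are rejected outright rather than imputed — every method
below assumes a complete, equally spaced series, and silently imputing into
a 15-point series would dominate the result.

## NAP

`nap()` compares all `n_pre * n_post` ordered (baseline, intervention)
pairs by exhaustive enumeration: a pair counts as improving when the
intervention value beats the baseline value in the aim direction, and ties
count half. The index is the improving fraction, reported both as a
proportion and as a percentage (two decimals in reports). It is ordinal —
invariant under any strictly increasing rescaling of the scores — and equals
the nonparametric probability of superiority, which the test suite verifies
against an independent rank-sum (Mann–Whitney, midrank ties) computation on
a thousand random series. Under an i.i.d. no-change null its expectation is
0.5; `null_nap_calibration()` checks that by simulation.

Two conventions are deliberate. Ties are exact floating-point equality by
default, with an optional absolute `tie_tol` for instrument-rounded data,
because half-weighting should not silently absorb near-misses. The
interpretive bands are closed on their upper ends with "small" reaching 65%
— only that boundary is fixed by the convention the package follows; the
medium/large split at 92% comes from the non-overlap literature and both are
configurable through `nap_bands()`.

## SLC

`slc()` estimates the baseline trend as the mean of the baseline first
differences (algebraically `(last − first)/(n_pre − 1)`, a telescoping
identity the tests assert), removes it positionally from the whole series
(`y*_t = y_t − (t − 1)·trend`, first session unmoved), estimates the slope
change as the mean first difference of the corrected intervention phase,
removes that within the intervention phase (`y**_j = y*_{n_pre+j} −
(j − 1)·slope_change`, first intervention session unmoved), and reports the
net level change as the difference of corrected phase means. The positional
origins — global first session for detrending, first intervention session
for slope-change removal — are a design choice: each correction leaves its
own first point untouched, which keeps the corrected series interpretable on
the raw scale. Outputs are deliberately unstandardised: a slope change of
−2.33 on a T-score scale reads directly as 2.33 T-score points per session.

Both trend estimates need at least two points in their phase; a baseline of
fewer than five sessions is flagged in the report (the usual design
standard) but never blocks the computation. Any series lying on a single
straight line across both phases yields slope change and level change of
exactly zero, and for a noiseless generated series the estimator returns the
generating triple to machine precision — the recovery property that ties the
estimator to the generator below.

## Visual aids

`range_lines()` and `phase_descriptives()` supply the per-phase extremes,
means and medians behind the simplest overlays (standard deviations use the
sample n−1 convention by default — the wider, more conservative choice for
bands — with a population switch).

`sd_band()` draws baseline mean ± k·SD (k = 2 by default, mean replaceable
by the median) and projects it across the intervention phase. "Outside" is
strict inequality; a point exactly on a limit counts as inside, favouring
the no-change reading. The familiar rationale — under normality fewer than
5% of points should escape a 2-SD band when nothing changed — is an
asymptotic statement: with a baseline of `n` points the escape probability
of an independent normal observation is `P(|t_{n−1}| > 2/sqrt(1 + 1/n))`,
which is about 14% at n = 5, still 6.6% at n = 20, and only drops below 5%
for baselines of several hundred points. `sd_band_null_calibration()`
therefore defaults to a 500-session baseline — where the theoretical value
is 4.6% — to probe the long-run property, and the short-baseline inflation
is the reason the band is offered as a visual aid, never a test.

`split_middle()` fits the resistant trend line through the (median session,
median score) points of the two half-phases. For odd lengths the middle
observation belongs to both halves by default (`middle = "drop"` gives the
alternative); for a phase lying exactly on a line, both rules recover slope
and intercept exactly, both parities, which the tests assert. `ols_trend()`
provides the least-squares counterpart used for per-phase plotting.

`stability_envelope()` projects the baseline split-middle trend across the
intervention phase inside an envelope of half-width 0.25 × baseline median
(both the fraction and the 80% criterion are configurable). Two containment
fractions are computed because the 80% rule is ambiguous about which points
it governs: the baseline's own containment (is the baseline trend-stable
enough to project at all?) and the intervention phase's containment under
the projection (did the behaviour leave the continued trend?). The `stable`
verdict applies the criterion to the intervention containment; the baseline
fraction is reported alongside and drives the `unstable-baseline` warning.
Enlarging the fraction can never shrink either containment (a monotonicity
the tests check). Projection is unbounded in time, so with a trending
baseline the envelope can leave the plausible measurement range —
`analyze(..., scale_range = )` flags that, since a projection into
impossible values should not be read literally.

`immediacy()` contrasts the mean of the first `window` intervention sessions
with the mean of the last `window` baseline sessions (default 3, clamped by
`analyze()` to the shorter phase).

## The synthetic generator

`simulate_ab()` generates `y_t = mu_t + e_t` with a deterministic part that
mirrors the SLC decomposition — baseline level and linear trend, plus an
additive level change and an extra per-session slope change in the
intervention phase — and AR(1) noise `e_t = phi·e_{t−1} + innovation`,
normal innovations of SD `noise_sd`, 100 burn-in steps. `noise_sd`
parameterises the *innovation*, not the marginal noise SD (which is
`noise_sd/sqrt(1 − phi²)`); this is documented rather than rescaled so that
`phi` can be varied without silently changing the innovation scale. Because
the mean structure matches the estimator, noiseless recovery is exact, and
the default null calibrations (`n_pre = 5`, `n_post = 10`, the common
short-design sizes) use i.i.d. noise with every effect at zero.

What the generator does *not* emulate: bounded or discrete measurement
scales, floor/ceiling compression, non-normal innovations, cycles, or
reactivity at the phase change. Passing tests on generated data show the
estimators are internally coherent under the model they assume — linear
trends and AR(1) dependence — not that real behavioural series satisfy that
model.

## The composed report

`analyze()` is a pure function of the series and its configuration: the
same input always yields a byte-identical JSON report (stable key order,
floats at 4 decimals, percentages at 2). Each numeric field comes from
exactly one of the operations above; module errors propagate with the
originating module named. Warnings follow three documented rules: baseline
shorter than 5 sessions, baseline containment below the stability criterion,
projected envelope leaving a configured `scale_range`. The cut-off
assessment uses strict inequality (a score exactly at the cut-off is not in
the functional range) and reports whether the final `final_k` (default 3)
intervention sessions all qualify.

The report intentionally has no aggregate verdict. The three assessment
components answer different questions — ordinal overlap, trend-corrected
magnitudes, clinical meaning — and with delayed effects or unstable
baselines they genuinely disagree; the report exposes the per-component
statements plus a disagreement flag and leaves adjudication to the analyst.
Sign conflicts (say, a positive net level change next to intervention points
escaping the band downwards) are surfaced, not resolved.

## Problem sizes and numerical choices

The test-suite simulations use sizes chosen to make their Monte Carlo error
small relative to the property checked: 10,000 replicates for the NAP
chance-level calibration (standard error ≈ 0.0013 at lengths 5/10), 10,000
series for the band calibration, 1,000 random series for the oracle and
telescoping identities, a 5×5×5 parameter grid for noiseless recovery, and
5,000-point series for the AR(1) autocorrelation check. Exact identities are
asserted at machine precision; stochastic checks at 3 Monte Carlo standard
errors or documented theoretical bounds.

## Known limitations

Only two-phase AB series: no ABAB, multiple-baseline or multi-case
containers, and no meta-analytic pooling. All statistics are descriptive —
no p-values or confidence intervals for NAP (their basis is unclear under
autocorrelation), no GLS/multilevel/ARIMA modelling, no randomisation tests.
NAP is insensitive to an improving baseline trend (use SLC alongside it);
SLC's baseline trend is fragile below five baseline points; the 2-SD band
and the projected envelope both inherit the short-baseline fragility
discussed above.
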