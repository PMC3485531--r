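---
title: "Segmental time-volume loss: model, numerical choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental time-volume loss: model, numerical choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stvloss)
```

## The model

One echo study is a set of 16 segmental time-volume curves on a common
grid: time in percent of the RR-interval (t = 0 at QRS onset, one curve
spans exactly one cycle, [0, 100] %RR), volume in ml. The global LV curve
is the pointwise sum of the 16 segments; global end-systole `t_ES` is the
time of its minimum, and each segment's end-systole `t_s` is the time of
its own minimal volume `V_{s,min}`. In a dyssynchronous ventricle the
`t_s` scatter around `t_ES`.

Three families of indices are computed from these quantities.

* Timing-only: `SDI = sd(t_1, …, t_16)` and `L-E = max(t_s) − min(t_s)`,
  both in %RR.
* Volume-weighted: the per-segment systolic time-volume loss
  `STV_s = ∫ max(V_s(t) − V_{s,min}, 0) dt` over the interval between
  `t_s` and `t_ES`, in ml × %RR. A segment whose minimum precedes `t_ES`
  is already relaxing — re-expanding — at global end-systole, so the curve
  sits above its own minimum over the interval and the enclosed area grows
  with both the timing offset and the displaced volume. Pre-STV sums the
  early (`t_s < t_ES`) segments, Post-STV the late ones, total STV both.
* Global function: EDV and ESV are the maximum and minimum of the global
  curve, EF = 100 (EDV − ESV)/EDV.

Two structural properties follow directly from the definition and are what
the package's validation leans on. First, scaling one segment's excursion
`V_s(t) − V_{s,min}` by a factor k scales its STV contribution by exactly
k while leaving SDI and L-E unchanged (timing indices are amplitude-blind).
Second, as a delayed segment's amplitude goes to zero its STV contribution
vanishes while its timing offset still moves SDI and L-E — the
hypokinetic-segment dissociation that motivates volume weighting. Because
basal segments hold more volume than mid and apical ones, they also weigh
more in STV, unlike in any timing-only index.

## Numerical choices

* **Shared grid.** All curves are linearly interpolated onto a uniform
  grid before analysis; the default is 201 points (0.5 %RR). This makes
  every `t_s` and `t_ES` a grid point, so the trapezoidal area has no
  partial intervals, and it fixes the timing resolution at a documented
  value. Bare resampling accepts any grid of 3 or more points; analysis
  requires at least 8.
* **Minimum detection.** Discrete argmin on the grid, no sub-sample
  refinement. Exact ties break to the earliest time — deterministic, and
  biased toward the pre-systolic class; with 201 points and smooth curves
  ties are essentially confined to constructed inputs.
* **Integration.** Trapezoidal rule on the shared grid, exact for the
  piecewise-linear curve model. The integrand is clamped at zero so
  numerical noise below the stored minimum cannot produce negative areas.
  Tests hold the trapezoid against a 10^4-subinterval Riemann sum.
* **SDI divisor.** Sample SD (N − 1) by default; the population form is a
  switch, since the convention of the clinical analysis software is not
  published.
* **Synchronous segments** (`t_s` exactly `t_ES` on the grid) form their
  own class with zero area and are counted in neither sum; no wrap of
  late events across the cycle boundary is attempted, as events around
  end-diastole are outside the model.
* **Degenerate inputs.** A zero-EDV study is rejected; fewer than 16
  segments is an error unless explicitly allowed, in which case indices
  are computed over the available N with a warning; curves not spanning
  [0, 100] are clamped at the boundary with a warning.

On the evaluation side, the ROC AUC is the Mann–Whitney concordant-pair
fraction (ties counted one half), which equals the trapezoidal area under
the empirical curve; its CI uses the Hanley–McNeil standard error, paired
AUC differences the DeLong covariance, and the reported cutoff maximises
the Youden index with ties broken toward higher sensitivity. None of these
rules is canonical in the clinical literature that prints cutoffs and
predictive values without stating them; all are therefore explicit,
documented choices here, and the marker direction (higher = positive for
Pre-STV, SDI, L-E) is never flipped automatically — an inverted marker is
reported with its sub-0.5 AUC. The group test is the pooled-variance
Student t by default (Welch as a switch), matching conventional reporting
in this field.

## What the synthetic generator emulates

`simulate_study()` builds each segment as
`V(t) = v_min + A · w((t − d) mod 100)` plus optional Gaussian noise,
where `w` is a raised cosine with minimum at the reference end-systolic
time (40 %RR by default, a typical systolic fraction) and value 1 at QRS
onset; an asymmetric variant with faster early descent is available. The
delay `d` shifts the segment's end-systole exactly, giving ground truth
for parameter recovery: at zero noise the analyser recovers each injected
delay to within one grid step and the SDI of the recovered times tracks
the SD of the injected delays.

`simulate_cohort()` layers a CRT trial on top. Per patient it draws EDV
and EF from heart-failure distributions (EDV ≈ 195 ± 45 ml responders /
176 ± 60 non-responders, EF ≈ 19 ± 8 %), splits volume across segments
with basal > mid > apical weights, and injects a dyssynchrony pattern:
responders carry 3–6 early-contracting segments (delay magnitude
26 ± 9 %RR) that mostly keep their inward motion, non-responders carry
3–5 delayed segments (14 ± 6 %RR) that are mostly hypokinetic (amplitude
× 0.1). A per-patient log-normal contractility multiplier on the
preserved delayed segments reproduces the strong right skew of clinical
STV values, whose group SDs are of the same order as the means — a skew
symmetric per-segment draws cannot generate. Follow-up studies shrink
responder delays by the homogenization factor (0.8 by default; CRT
homogenises contraction timing) and impose a drawn ESV change
(responders −29 ± 8 %, truncated to [−55, −12]; non-responders +3 ± 5 %,
truncated to [−8, +15]); the follow-up curves are rescaled
multiplicatively so the analysed ESV matches the drawn change exactly.
The truncation bounds deliberately exclude the ±10 % response boundary,
so the stored ground-truth labels are exactly recoverable by
`classify_response()` — boundary behaviour itself is tested separately
with degenerate distributions.

### What it does not emulate, and calibration limits

Measurement noise is additive white Gaussian per sample (default
0.02 ml), with no temporal or inter-segment correlation; real
border-detection output is smoothed, and the discrete argmin is quite
sensitive to white noise near a flat minimum, so large `noise_sd` values
inflate STV through end-systole jitter rather than emulating tracing
error. Re-tracing by a second observer is better modelled as smooth
per-segment offset/scale perturbations, which is what the acceptance
script does. There is no hemodynamics, no valve timing, no mitral
regurgitation and no scar model.

Against the clinical group statistics used as calibration targets, the
default cohort reproduces the non-responder Pre-STV (≈ 4.6 ± 3 vs
5.2 ± 6.8 ml%), SDI in both groups (≈ 12.9/7.3 vs 12.6/7.4 %RR), L-E, and
the volumes well. Responder Pre-STV reaches ≈ 37 ± 22 ml% against a
clinical 51 ± 51: with delays bounded so that segmental minima stay
inside the cycle (early shifts ≤ ~34 %RR), and EDV/EF drawn
independently, still-larger early-segment amplitudes stop helping —
they drag the global minimum toward the early cluster and cancel the very
separation being integrated. The extreme clinical tail therefore lies
outside what this mechanistic model produces, and passing cohort-level
tests show correct *ordering and discrimination* (Pre-STV AUC ≈ 1 on
default cohorts), not that real Pre-STV magnitudes above ~100 ml% are
reproduced.

## Problem sizes used in validation

The test suite runs the partition and integration checks on 100 and 50
randomly parameterised studies, parameter recovery on 50, the AUC oracle
on 200 small score sets against exhaustive pair counting, type-I-error
calibration of the t-test and the DeLong comparison on 1000 null
simulations each (n = 20 + 20 and 200 + 200), and the end-to-end cohort
check on 100 seeds of the default 20 + 8 cohort. These sizes keep every
Monte-Carlo estimate's standard error well inside the asserted bands
while remaining quick to run.

## Known limitations

* Timing resolution is the analysis grid (0.5 %RR by default); sub-frame
  end-systole estimation is deliberately not attempted.
* Post-STV never wraps across the cycle boundary; late events near
  end-diastole are truncated by construction.
* The ROC cutoff and CI conventions (Youden, Hanley–McNeil, DeLong) are
  reasonable defaults, not reconstructions of any particular clinical
  software.
* Clinical Pre-/Post-STV distributions are matched in location and
  ordering but not in their extreme right tail (see above).
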