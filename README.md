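# stvloss

Quantification of left-ventricular (LV) mechanical dyssynchrony from
16-segment time-volume curves, as produced by real-time three-dimensional
echocardiography (3DE) with semi-automated endocardial border detection.

## The problem and the method

Roughly one third of heart-failure patients who receive cardiac
resynchronisation therapy (CRT) do not improve. Most echocardiographic
selection indices summarise only the *timing* of segmental contraction:

- **SDI** (systolic dyssynchrony index): the standard deviation of the 16
  segmental times from QRS onset to minimal segmental volume, in % of the
  RR-interval;
- **L-E**: the delay between the latest and the earliest segment to reach
  minimal volume, in %RR.

Timing-only indices treat a severely hypokinetic segment — one that barely
moves — exactly like a well-contracting one. The *segmental time-volume
loss* (STV) family corrects for this by weighting each segment's timing
offset by the volume it displaces. With `V_s(t)` the volume trace of
segment `s`, `t_s` its time of minimal volume `V_s,min`, and `t_ES` the
global end-systolic time (minimum of the summed LV curve),

```
STV_s  =  ∫ max(V_s(t) − V_s,min, 0) dt     over [min(t_s, t_ES), max(t_s, t_ES)]
```

in units of ml × %RR ("ml%"). **Pre-STV** is the sum of `STV_s` over
segments reaching their minimum *before* global end-systole, **Post-STV**
over segments reaching it *after*, and total STV their sum. A delayed but
akinetic segment contributes nothing to STV while still inflating SDI and
L-E — the dissociation that motivates the method.

The package also implements the evaluation pipeline for such markers:
responder classification (≥ 10 % reduction of end-systolic volume at
follow-up), empirical ROC curves with Mann–Whitney AUC, Hanley–McNeil
confidence intervals and Youden cutoffs, DeLong paired AUC comparison,
Student/Welch group comparisons, Pearson correlation with reverse
remodelling, and Bland–Altman reproducibility — plus a synthetic generator
of segmental curves and paired baseline/follow-up CRT cohorts so that the
entire pipeline can be exercised and validated without patient data.

## Worked example

```r
library(stvloss)

# a ventricle with four early, well-contracting segments
st <- simulate_study(study_params(delays = c(rep(-24, 4), rep(0, 12)),
                                  seed = 1L))
analyze_study(st)
#> LV dyssynchrony analysis: study 'synthetic' (201-point grid)
#>   EDV 184.51 ml  ESV 149.97 ml  EF 18.7%
#>   SDI 10.73 %RR  L-E 24.00 %RR
#>   Pre-STV 27.06 ml%  Post-STV 0.67 ml%  total STV 27.73 ml%

# the same timing pattern in hypokinetic segments: SDI persists, STV collapses
amp <- 2.8 * segment_size_weights(); amp[1:4] <- amp[1:4] * 0.1
analyze_study(simulate_study(study_params(delays = c(rep(-24, 4), rep(0, 12)),
                                          amplitude = amp, seed = 1L)))
#>   SDI 10.73 %RR  L-E 24.00 %RR
#>   Pre-STV 4.00 ml%  Post-STV 0.00 ml%  total STV 4.01 ml%

# a full synthetic CRT cohort, evaluated end to end
coh <- simulate_cohort(cohort_params(seed = 7L))
evaluate_cohort(coh)
#> CRT response evaluation: 20 responders / 8 non-responders
#>   pre_stv   AUC 1.00 (1.00-1.00)  cutoff  12.19  sens 100.0%  spec 100.0%  r(dESV) -0.53 (p=0.00373)
#>   post_stv  AUC 0.79 (0.62-0.96)  cutoff   1.12  sens  70.0%  spec  87.5%  r(dESV) -0.34 (p=0.0732)
#>   sdi       AUC 1.00 (1.00-1.00)  cutoff  11.01  sens 100.0%  spec 100.0%  r(dESV) -0.79 (p=6.54e-07)
#>   le        AUC 0.93 (0.84-1.00)  cutoff  32.50  sens  95.0%  spec  87.5%  r(dESV) -0.56 (p=0.00196)
#>   Pre-STV vs SDI AUC: 1.00 vs 1.00, DeLong p = 1
```

The first run shows a dyssynchronous ventricle whose early segments
contract well: SDI 10.7 %RR and Pre-STV 27.1 ml% are both elevated. Making
those same segments hypokinetic leaves SDI and L-E untouched but reduces
Pre-STV roughly sevenfold — the volume weighting at work. The cohort evaluation
reports, per marker, the ROC AUC with its 95 % CI, the Youden-optimal
cutoff with sensitivity/specificity, and the correlation with the percent
ESV change at follow-up.

A command-line interface is installed with the package
(`inst/exec/stvloss`): `stvloss metrics|cohort|repro|simulate`.

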