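---
title: "Simulating subject-independent fMRI neurofeedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating subject-independent fMRI neurofeedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Conventional real-time fMRI neurofeedback (rt-fMRI NF) trains a person to
modulate their *own* brain activity. When the disorder itself distorts the
network being trained — as depression distorts the emotional network —
feedback computed from the patient's own activity may reinforce the
dysfunctional pattern. The alternative studied here is *subject-independent*
feedback: a linear support vector machine (SVM) is trained to distinguish two
whole-brain states (happy autobiographical imagery versus motor imagery) in a
healthy "tutor", and patients are then rewarded, volume by volume, for
producing activity that the tutor's classifier labels as the target state.

`rtnf` implements that entire loop as a desk-scale simulation: a synthetic
BOLD generator, the offline classifier construction with cross-validation,
an abbreviated online preprocessing path, the per-TR thermometer/reward
loop, and the small-sample statistics used to analyse learning and clinical
change. Everything runs from seeds; no scanner data is required anywhere.

## The block paradigm

A run is 7 minutes: 20 s rest, then 4 repetitions of (40 s happy imagery,
40 s motor imagery, 20 s rest), i.e. 420 s = 210 volumes at TR = 2 s, with
80 HAPPY, 80 MOTOR and 50 REST volumes. Only this arrangement is consistent
with the stated run length, block lengths and block counts, so it is the
default; `build_paradigm()` accepts any contiguous scheme whose block
durations are multiples of the TR.

## The BOLD generator

`simulate_run()` produces a run as

$$Y_v(t) = B_v\Big(1 + \textstyle\sum_c \tfrac{P_{c,v}}{100}\,(x_c \ast h)(t)\Big)
  + d_v(t) + \varepsilon_v(t)$$

* $B$ — baseline field: 100 (arbitrary units) inside an ellipsoidal brain
  support, 0 outside. The default grid is 20 × 24 × 20 voxels at a nominal
  3 mm; any grid is accepted.
* $P_c$ — condition pattern in percent of baseline.
* $x_c \ast h$ — the block boxcar convolved with a canonical double-gamma
  HRF (peak 6 s, undershoot 16 s, ratio 1/6), sampled by upsampling to
  0.1 s. The kernel is normalised to unit time-integral, so a sustained
  block plateaus at exactly the pattern amplitude; this makes "a 1 %
  amplitude" mean a 1 % steady-state signal change.
* $d$ — per-voxel linear drift; slopes are Gaussian with standard
  deviation `drift_amplitude` (percent of baseline over the run,
  default 0.5).
* $\varepsilon$ — AR(1) noise with marginal standard deviation
  `noise_sigma` (percent of baseline, default 1) and lag-1 coefficient
  `ar1_coefficient` (default 0.3), initialised at stationarity. These are
  field-typical values for 3 mm voxels, and linear detrending — the only
  trend removal the pipeline applies — matches the linear drift model.

Identical seed and inputs give bit-identical output; the caller's RNG
state is saved and restored.

### Tutor template and pattern fidelity

`tutor_template()` defines two deterministic spatial patterns (schematic
"emotional" and "motor" cluster sets), mean-centred over the support,
mutually orthogonalised and scaled to unit L2 norm. The tutor's profile
uses them at amplitude 30 (in the percent-scaled unit-norm convention this
puts the strongest voxels near a 1 % BOLD effect, and yields
cross-validated tutor accuracy around 0.9 on the default grid — the level
typical of two-class whole-brain emotion decoding).

A patient is parameterised by *pattern fidelity* $f \in [0,1]$: during each
task block their instantaneous pattern is

$$P_b = a\,(f\,T + \sqrt{1-f^2}\,R_b)$$

with $T$ the template pattern and $R_b$ a random field orthogonal to both
template patterns, so the spatial correlation between the realised pattern
and the template is exactly $f$.

**Why $R_b$ is re-drawn every block.** An early design kept one stable
orthogonal field per subject. That version fails a basic sanity
requirement: a fidelity-0 subject should classify at chance against the
tutor model, but any *stable* pattern pair — however orthogonal to the
template over the whole brain — still projects consistently onto the SVM
weight vector restricted to the selected voxels, and multivoxel
aggregation amplifies that stable projection into far-above-chance (or
far-below-chance) accuracy. Re-drawing the orthogonal component per block
models the non-template part of activity as fluctuating, task-unrelated
cognitive state; it preserves the fidelity-correlation contract and makes
fidelity 0 behave as chance. The cost is that the simulator has no stable
individual "signature" map — a known limitation, stated below.

**Learning** is modelled as a per-session fidelity increment
(`learning_rate`, default 0.1 per session, capped at 1), starting from
`pattern_fidelity` 0.3. This is a phenomenological stand-in chosen to
produce rising accuracy over a 4-session protocol for recovery testing; it
claims no neural mechanism.

## Preprocessing

Offline (classifier construction): discard the first 10 volumes
(gradient-stabilisation window), rigid realignment to volume 1,
slice-timing correction, affine normalisation to a template grid, Gaussian
smoothing (default 8 mm FWHM offline).

* **Realignment** estimates 6 rigid parameters per volume by Nelder-Mead
  plus a BFGS polish on the masked mean-squared difference under trilinear
  resampling, comparing only voxels whose transformed coordinates stay
  inside the moving volume (otherwise content lost at the field-of-view
  edge biases the fit). Both a zero start and a warm start from the
  previous volume are tried and the better kept.
* **Slice timing** uses Fourier phase shifting (exact for band-limited
  series); the default order is interleaved ascending for 34 slices,
  configurable.
* **Normalisation** replaces segmentation-based template registration with
  a 12-parameter world-space affine (translation, rotation, log-scale,
  shear) estimated from the *mean of a 1-minute dummy run* (30 volumes at
  TR 2 s) by staged Nelder-Mead (translation → rigid → full affine) on
  1 − spatial correlation. This preserves the architecture of the online
  system — parameters estimated once, reused per volume — at desk scale.
* **Online path** per volume: resample to the template grid through the
  stored affine, smooth (default 6 mm). It is the same operation the
  offline path applies per volume, so the two agree to numerical
  precision by construction. On one CPU at the default grid the measured
  per-volume cost is far below the 2 s TR (it is logged per run in
  `nf_run()` results).
* The 10-volume discard applies to classifier-training runs only; online
  feedback runs keep all 210 volumes because the run-accuracy denominator
  is fixed at 210. This asymmetry is deliberate.

## The classifier

Features are masked voxel time series (intensity mask: mean intensity
above 0.5 × the grand mean of positive voxels), linearly detrended per
voxel per run, with task volumes as samples (one volume = one sample; the
online loop must decide per volume, and training mirrors that). Labels can
optionally be shifted by a hemodynamic delay of k TRs; the default is 0,
keeping the literal 210-volume bookkeeping.

Training pipeline (applied in full inside every cross-validation fold):

1. standardise each voxel with training statistics only;
2. linear SVM (cost 1) over the whole mask — `e1071::svm`;
3. effect map $e_j = w_j(\bar{x}_j^{H} - \bar{x}_j^{M})$, the SVM weight
   times the class-mean difference. The effect-mapping literature this
   follows does not print its formula, so this weight-times-activation
   form is a documented package decision, validated by a Monte-Carlo
   recovery test (the single informative voxel among hundreds of noise
   voxels is found by $\arg\max |e|$ in ≥ 95 % of replicates), and kept
   behind its own interface so an alternative formula can be swapped in;
4. keep the top 5 % of mask voxels by $|e|$;
5. retrain the SVM on the selected voxels — these weights and bias are
   the online decision rule.

Leave-one-run-out cross-validation over 4 runs reports per-fold accuracy,
sensitivity and specificity with HAPPY as the positive class (the printed
report never states which class anchors sensitivity; HAPPY is our
documented choice). Averages are arithmetic fold means, printed rounded to
two decimals half-away-from-zero; a mean of exactly 0.925 therefore prints
as 0.93 where the original table shows 0.92 — both lie inside the ±0.005
band that the report's rounding implies, and the test suite asserts the
band, not one convention. Among several candidate classifiers the one with
the highest mean accuracy wins; ties break by higher mean sensitivity,
then lowest index.

## The closed loop

`nf_run()` streams a (simulated) run through the online path, classifies
every volume — decision value $w \cdot z + b$; exactly 0 classifies as
HAPPY, a documented deterministic tie rule — and drives a 10-bar
thermometer clamped to [0, 10]:

* task volume: +1 bar if the prediction matches the block's condition,
  −1 otherwise;
* entering a rest block: the bar resets to the rounded mean of the
  previous task block's bar trajectory (R's round: half to even, so a
  mean of 2.5 resets to 2 — the documented convention); at session start
  the bar sits at the midpoint (5).

Online detrending is a causal per-voxel running linear fit (the residual
of volume *t* under the least-squares line through volumes 1..*t*),
the real-time analogue of the offline detrending.

Run accuracy follows the fixed-denominator formula
$100 \times \#\text{correct}/210$, under which rest volumes can never be
correct and the attainable ceiling is $100 \times 160/210 = 76.19$.
An alternative `task_only` scoring (denominator 160) is also computed and
reported alongside. Monetary reward is 1.5 USD at accuracy ≤ 50 %, plus
2 USD for every started 5-point step above 50 (3.5 for 51–55, 5.5 for
56–60, …, 21.5 at 100) — a non-decreasing step function.

Note one intrinsic property of per-volume scoring against instantaneous
block labels with label shift 0: the BOLD response lags each block switch
by several volumes, so even a noiseless tutor replay scores in the
mid-80s (task denominator), not 100. This is the hemodynamic ramp, not a
defect; shifting labels by 2–3 TRs trades this against the literal
bookkeeping and is exposed as an option.

## Statistics

* **Exact one-sample Wilcoxon signed-rank test** versus zero: zeros are
  dropped (Wilcoxon's original procedure), absolute differences are
  mid-ranked, and the null distribution of $W$ is computed over all $2^n$
  equiprobable sign assignments of the observed ranks — implemented by
  iterative convolution on a half-integer grid, which is mathematically
  identical to explicit enumeration and practical to n = 25; beyond that
  a tagged normal approximation takes over. Two-sided p-values sum the
  probability of all $W$ at least as far from $n(n+1)/4$ as observed.
  The test suite checks the implementation against a literal
  $2^n$-loop oracle across hundreds of seeded datasets with ties and
  zeros.
* **One-sample z-test**: $z = (\bar{x} - \mu_0)/(s/\sqrt{n})$, normal
  tail. The day-4 group comparison against 50 % uses the *upper
  one-tailed* p: with the printed group mean, SD and n, only that
  sidedness reproduces the printed p-value.
* **Learning**: per-participant deltas Run16 − Run1,
  (Run15 + Run16 − Run1 − Run2)/2 and mean(Day 4) − mean(Day 1), each fed
  to the exact Wilcoxon test; OLS slopes of accuracy against run and
  session index.
* **Clinical change**: per participant and instrument, contrasts between
  the three evaluations (before training, after training, 10-day
  follow-up), reported as *earlier minus later* score so that positive
  values mean improvement on symptom scales; group exact Wilcoxon on each
  contrast, with all-zero contrasts reported untested (a zero-difference
  signed-rank test is undefined). No multiple-testing correction is
  applied, matching the analysis this mirrors; that is a faithful
  reproduction, not an endorsement.
* **Screening**: eligible iff 10 ≤ BDI-II ≤ 29 and suicidality item < 2
  and Okasha < 5 (risk exclusion takes precedence). Severity bands:
  none < 10, mild 10–19, moderate 20–29, severe > 29; the 19/20 split
  inside the eligible range is our documented choice — the screening
  rules fix only 10 and 29.

## Problem sizes and numerical choices

The test suite exercises unit behaviour on a 10 × 12 × 10 grid with a
one-repetition (60-volume) paradigm, and the cohort-level properties at
the full default conditions: 20 × 24 × 20 grid, 210-volume runs, 4 tutor
training runs, 7 patients, 4 days × 4 runs. The end-to-end recovery
property uses 10 seeded cohort replicates; the fidelity sweep uses 5
fidelity levels × 6 seeded subjects; Wilcoxon equivalence uses 500 seeded
datasets at n ≤ 12. These sizes were chosen so the whole suite completes
comfortably on a single CPU while keeping every group test at the study's
n = 7.

Other numerical conventions: standard-deviation floors of 1e−12 in
standardisation; trilinear interpolation samples outside the source grid
as 0; registration costs ignore voxels mapping outside the moving volume
and fail loudly when fewer than half remain or the residual correlation
stays below 0.5; optimisations are deterministic (Nelder-Mead/BFGS with
fixed starts), so all preprocessing is reproducible without seeds.

## Known limitations

* No stable subject-specific activation signature (see the per-block
  redraw rationale); consequently the simulator cannot express a patient
  whose idiosyncratic-but-stable pattern is systematically confusable
  with one tutor class.
* Noise is AR(1) + linear drift only: no physiological (cardiac or
  respiratory) components, no motion unless injected, no spatial noise
  correlation beyond smoothing.
* Normalisation is affine; nonlinear warps and tissue segmentation are
  out of scope.
* Passing recovery tests on this generator shows the pipeline's logic is
  sound under its assumptions; it does not certify performance on real
  scanner data, whose artefact structure is far richer.
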