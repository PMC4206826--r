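---
title: "Methods: from calcium movies to conditioning inference"
author: "calpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from calcium movies to conditioning inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`calpop` analyses population calcium imaging of a cortical area that
receives both a fast sensory input and a slow neuromodulatory (dopaminergic)
input, in experiments where the two are paired during a conditioning phase
and the sensory response is re-measured at several later time points. This
vignette documents the models, the parameters that matter, the synthetic
data the package tests itself against, and the numerical conventions.

## The signal model

Raw fluorescence of a cell is modelled (and simulated) as

```
F(t) = F0 · (1 + drift(t) + Σ_i a_i · k_i(t − t_i)) + ε(t)
```

with `F0` the baseline in arbitrary units, `a_i` the dF/F amplitude of the
transient evoked by stimulus `i`, `k_i` a unit-peak kernel, `drift` a slow
multiplicative sinusoid and `ε` white Gaussian noise with SD `noise_sd · F0`.
Because every term scales with `F0`, all downstream dF/F quantities are
invariant to the baseline scale — only ratios carry meaning, and the test
suite asserts this invariance explicitly.

Two kernel shapes reflect the two stereotyped responses in this
preparation: a **short** kernel (peak ≤ 1.5 s, support ≤ 5 s; default peak
0.5 s, τ 1.5 s) for direct sensory drive, and a **long** kernel (peak 6–7 s
after the stimulus, support 20–30 s; default peak 6.5 s, τ 8 s) for phasic
dopaminergic drive. The rise is a saturating exponential calibrated to hit
exactly 1 at the sample nearest the requested peak time; after the peak the
kernel is exactly `exp(−(t − t_peak)/τ)`. Pinning the post-peak segment to a
pure exponential makes decay-constant recovery well-posed: the fitted τ has
a known truth. (A difference-of-exponentials rise with a free decay mixture
would look marginally more biophysical but would make the "true τ" of a
simulated transient ambiguous.)

## Baseline and dF/F

`dF/F(t) = (F1(t) − F0(t))/F0(t)` with `F0(t)` the **median** of the raw
samples within `t ± W`. Two half-window conventions are used, chosen by the
response kinetics under analysis:

* `W = 40 s` for slow dopaminergic transients (the transient occupies well
  under half the window, so the median is unbiased);
* `W = 2.5 s` for fast sensory transients (tracks residual slow drift).

Windows **truncate** at the recording boundaries — no padding, reflection or
extrapolation; this is the simplest convention with an unambiguous oracle,
and the implementation (an exact running median for interior samples,
direct medians at the truncated edges) is tested bit-for-bit against a
naive per-sample sort-and-pick oracle on both dialects. A zero baseline is
a hard error naming the offending sample, since dF/F is undefined there.

With `W = 2.5 s` the window is only ~5× the width of a fast transient, so
the median is slightly elevated during the response and single-cell peak
dF/F is mildly underestimated. This bias is shared across conditions and
cancels in every comparative statistic; for absolute amplitude recovery the
40 s dialect is the right tool (the generator tests recover injected
amplitudes within 2% there).

## Transient metrics

* **Peak**: maximum dF/F on a half-open window `[start, end)`, ties broken
  by the earliest sample. Frame `k` (0-based) has timestamp `k / fps`.
* **Summed response**: sum of the dF/F samples on `[start, end)` — a sum of
  samples, not a time integral, so the value scales with the frame rate; a
  trapezoidal integral is available behind a flag for rate-independent
  units.
* **Decay constant**: `dF/F(t) = dF/F_max · e^(−t/τ)` with `dF/F_max`
  pinned to the observed peak, leaving τ as the single free parameter,
  estimated by golden-section least squares on τ ∈ [0.5/fps, 1000] s with
  tolerance 1e-9. The default fit window runs from the peak to the first
  sample below 5% of the peak, capped at 40 s. A log-linear fit through the
  fixed intercept `log(dF/F_max)` (positive samples only) is exposed both
  as a user option and as the independent closed-form oracle in the tests.
  Degenerate windows — fewer than 3 samples (2 for log-linear), peak ≤ 0,
  or an all-non-positive decay segment — are hard errors.
* **Occurrence**: a transient occurred when the post-stimulus peak (5 s
  window) exceeds `k_sd = 3` standard deviations of the dF/F over the 5 s
  preceding the stimulus. No criterion is canonical in the literature, so
  both the multiplier and the windows are configuration. At 2.3 Hz this
  rule inspects ~11 samples against an 11-sample SD estimate; Monte Carlo
  places its false-positive rate on pure Gaussian noise near 6%, and the
  test suite asserts that computed bound rather than a smaller nominal
  figure.

## Population statistics

The **response vector** of one stimulus repetition is the N-cell vector of
peak dF/F within 5 s of stimulus onset (mean-over-window is offered as an
alternative summary; both are tested). Cell order is fixed across
repetitions. **Pattern similarity** of a time point is the mean of the
three pairwise cosine similarities between the repetitions' vectors.
Zero-norm vectors raise an error rather than contributing a silent 0 — an
all-zero repetition has no direction, and substituting any number would
bias the three-pair average; callers may drop such repetitions explicitly.
Negative dF/F values are kept (cosines may be negative).

**Occurrence reliability** is Cronbach's α with repetitions as items and
cells as subjects, computed on the binary occurrence matrix by default
(graded dF/F matrices are equally accepted). The 95% CI is Feldt's
F-interval with `(n−1)` and `(n−1)(k−1)` df — a method choice the package
makes explicitly since plotted CIs rarely name one. α is undefined (error)
for one repetition or zero total-score variance.

**Distribution comparisons** use the responder fraction above dF/F = 0.2
plus a two-sample Kolmogorov–Smirnov test: `D` is the exact ECDF supremum;
the p-value uses the asymptotic Kolmogorov series at effective sample size
`nm/(n+m)`, adequate at the 50–80 cells per animal this package targets
(tests verify `D` against a brute-force oracle for all n, m ≤ 20 and the
p-value against the reference implementation).

## Inference layer

The conditioning design is **split-plot**: each animal experiences one
paradigm (between factor) and all four test time points (within factor).
`mixed_anova()` computes the classical balanced decomposition — paradigm
tested against subjects-within-groups, time and the interaction against
the subject × time residual — giving df `(3, 28)`, `(3, 84)`, `(9, 84)` for
the 4 × 8 × 4 design. Unbalanced or incomplete data are a hard error: the
closed-form sums of squares assume balance, and imputation is out of scope.
When all values are equal the 0/0 F-ratios are guarded to 0 and flagged
(`zero_ss`). No sphericity correction is applied by default;
Greenhouse–Geisser is available behind a flag. The implementation is
verified against `aov()` error strata on random designs to 1e-8.

**Ryan's post hoc** uses the sequential-rejective nominal levels
`α_r = 2α/(k(r−1))` for a pair spanning `r` of the `k` ordered means
(reducing to `α` at `k = 2`), with closure: a pair is tested only when
every enclosing span has been rejected, so no isolated rejection can sit
inside a retained span. "Ryan's test" is not a single procedure across
literatures; this variant was chosen because it is the common
sequential-rejective reading, its rejections provably sit between
Bonferroni-all-pairs and unadjusted t tests (asserted on every tested
dataset), and its familywise error under a complete null simulates at or
below α. Pairwise t statistics use the ANOVA error mean square; within-
factor comparisons therefore borrow the residual stratum.

**Paired t with Holm** guards the all-differences-zero case to
`t = 0, p = 1` instead of erroring, and delegates the step-down adjustment
to `p.adjust`.

## The synthetic-data generator

The generator is first-class, tested code — it defines the conditions under
which the pipeline is validated. Per animal it draws once: which cells
respond (`responder_fraction = 0.6`), their base amplitudes
(`max(0, N(0.15, 0.05))` dF/F — below the 0.2 responder criterion at
baseline, as in the conditioning design), and a cells × repetitions matrix
of perturbation draws `ε`. The injected amplitude of cell *i* on repetition
*r* at a time point with gain *g* and similarity coupling *c* is

```
a_{i,r} = g · max(0, a_i + (1 − c) · rep_jitter_sd · ε_{i,r})
```

Sharing `a` and `ε` across time points has three useful consequences, each
asserted by tests: all-unity effects give bit-identical responses at every
time point; a pure gain change scales the mean injected amplitude exactly;
and raising the coupling shrinks inter-repetition scatter so expected
pairwise cosine similarity increases monotonically in `c`. The default
effect structure gives only the T1 paradigm (sensory 0.5 s before the
dopamine burst) a conditioning effect — gain ramping to 1.5 and coupling to
0.8 at 2 hr, with intermediate values at 1 hr — while the temporal-
separation control T2 and the single-site controls stay at unity. Defaults
elsewhere: 8 animals per paradigm, 50–80 cells per animal (uniform), 2.3 Hz
frames, 190 s recordings with sensory repetitions at 30/90/150 s,
`noise_sd = 0.02`, `drift_amplitude = 0.01`, `rep_jitter_sd = 0.1` (chosen
comparable to the amplitude scale so the coupling parameter spans a wide
similarity range). Inter-animal variance components are deliberately free
parameters, not asserted facts.

The movie generator renders neuron somata as disks whose pixels carry the
raw trace value (so a mean-over-ROI readout is exact in the noise-free
case), astrocytes as static disks bright in the red counterstain channel,
Gaussian pixel noise at a stated contrast-to-noise ratio, and optional
integer rigid drift applied to both channels.

What the generator does **not** emulate — and hence what green tests do not
certify on real data: neuropil contamination, photobleaching beyond slow
sinusoidal drift, scanning/photon-shot noise statistics, overlapping or
non-disk somata, sub-pixel or rotational motion, and any biological
correlation structure between cells beyond the shared latent vector.

## Imaging front end

Registration is translation-only by FFT cross-correlation against a
reference frame, reporting integer corrective shifts and filling exposed
borders with the frame median — deliberately minimal plumbing whose
known-shift recovery is exactly checkable, not a general motion corrector.
Detection smooths the mean image (Gaussian, σ = `min_radius/2`), takes
strict 8-neighbour local maxima above an intensity percentile, and keeps
them greedily by brightness subject to non-overlap of the fixed-radius
disks; supplying seed points bypasses detection entirely (the
"semi-automatic" path, one ROI per seed). Astrocyte exclusion labels an ROI
astrocyte when its mean red intensity exceeds the stated percentile of
ROI-wise red intensities; with an all-zero red channel nothing is excluded.
Coordinates are 0-based `(x, y)`; disk membership is centre distance ≤ r.

## Pipeline and reproducibility

`run_pipeline()` chains generator → dF/F → per-cell metrics → per-animal
aggregation (mean peak dF/F across cells and repetitions; pattern
similarity; occurrence α) → split-plot ANOVA and Ryan post hoc tables →
CSV outputs plus a JSON manifest (config MD5, seed, package version, file
inventory). All randomness flows from one seed; re-running a configuration
reproduces byte-identical tables, which the tests assert via file hashes.
The first 10 s of each recording are excluded from displays (onset
artifacts in this preparation); stimulus timestamps are carried in the data
files, never inferred from the traces.

Problem sizes: the full validation runs the study-scale design (4 paradigms
× 8 animals × 60 cells × 4 time points) for 20 effect and 20 null
replicates, 200 noisy decay fits, 2000-replicate familywise-error
simulation, and 50-trace baseline-oracle comparisons — sizes at which each
check is stable yet the whole suite completes in minutes on one core.

## Known limitations

* Balanced designs only in the ANOVA layer; use mixed-effects software for
  missing cells.
* The KS p-value is asymptotic; below ~20 observations per sample use an
  exact test.
* Registration is integer-translation only.
* The occurrence criterion is a convention (3 SD, 5 s windows), not an
  optimised detector; its false-positive rate under Gaussian noise is ~6%,
  not the per-sample tail of 0.13%.
* Sums of samples (not integrals) make summed responses frame-rate
  dependent; compare only within a fixed acquisition rate or switch to the
  integral option.
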