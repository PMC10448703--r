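---
title: "Discovering TOI/ROI condition effects in fNIRS with tensor decompositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering TOI/ROI condition effects in fNIRS with tensor decompositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirstensor)
```

## The problem

Infant fNIRS studies of event perception typically compare oxygenated-
hemoglobin (HbO) responses across the cells of a 2x2 design — for example
entity type (human/mechanical) crossed with action sequence — recorded from
20 channels (10 per hemisphere) over temporal and temporal-occipital cortex.
The standard *grand averaging* analysis collapses each subject's
trial-averaged hemodynamic response function (HRF) over a predefined time
window of interest (TOI) and channel region of interest (ROI) before running
an ANOVA. That requires committing to a TOI and ROI in advance and discards
the temporal and spatial structure of the response, so effects outside the
predefined window are invisible.

`nirstensor` implements the alternative: assemble all subjects' HRFs into a
tensor, decompose it, test each component's subject-mode scores with the
same 2x2 ANOVA, and read the *discovered* TOI and ROI off the summed
profiles of the significant components. The grand-averaging baseline is
included (`grand_average()`, `grandavg_test()`) so both analyses can be run
head-to-head on the same data.

## Data model

An epoch spans 2 s of pre-onset baseline, the stimulus presentation
(12-15 s depending on paradigm), and 10 s after stimulus offset; time 0 is
the onset and windows are half-open. `build_hrf()` extracts one epoch per
trial, subtracts each trial's per-channel baseline mean (toggleable via
`baseline_correct`; correction makes response magnitudes interpretable and
removes slow offsets), and averages trials arithmetically within subject and
condition. Recordings at lower rates are upsampled with linear
interpolation (`resample_hrf()`; polyphase filtering available via
`method = "polyphase"`). Channels are split into left/right hemisphere sets
before tensorisation; channels 1-10 are left and 11-20 right by default.

## Tensor construction

Two tensors are built per hemisphere:

* **4-way, for nonnegative CPD** — each HRF channel is transformed with a
  short-time Fourier transform and the coefficient *magnitudes* at positive
  frequencies are stacked into a (time-frame x frequency x channel x
  subject) array. Magnitude is the minimal nonnegative reduction of the
  complex coefficients, which the nonnegativity constraint requires; the DC
  bin is dropped along with the negative frequencies (baseline correction
  removes most DC anyway). The STFT window defaults to 10 s with 75%
  overlap: long enough to resolve the sub-0.1 Hz hemodynamic band over a
  24-27 s epoch, short enough to leave several frames for temporal
  localisation. Both are configurable (`stft_window_s`, `stft_overlap`).
* **3-way, for orthogonal Tucker** — the signed HRF matrices stacked into
  (time x channel x subject).

For a mixed design each subject contributes one subject-mode slot per
within-subject level (36 subjects -> 72 slots); slots are ordered
deterministically by subject id and level.

## Decompositions

**Nonnegative CPD.** `nn_cpd()` fits
$X \approx \sum_{r=1}^{R} \lambda_r\, u_r^{(t)} \circ u_r^{(f)} \circ
u_r^{(c)} \circ u_r^{(s)}$ with all factors nonnegative, by HALS-style
block-coordinate nonnegative least squares (one exact column update at a
time), which is monotone in the objective and considerably faster than
multiplicative updates. Factors are initialised from the absolute leading
singular vectors of each unfolding with seeded multiplicative jitter, so
independent restarts explore different basins while starting in a sensible
region; a tiny ridge (1e-12) keeps the update defined if a column collapses.
Columns are normalised to unit L2 norm on return with magnitudes collected
in `lambda` — the decomposition itself fixes scale only up to permutation
and scaling, and the screening thresholds below are defined on unit-norm
components. Defaults: `tol = 1e-8` on the relative change of the squared
residual, `max_iter = 500`.

Because the CPD is not unique, `run_cpd_ensemble()` reruns it (ten times by
default) from seeds derived deterministically from the master seed;
cross-run consensus (below) then keeps only components that recur.

**Rank selection.** `select_rank_cpd()` fits ranks `1..r_max` from a fixed
audit seed (distinct from the ensemble seeds, so selection is reproducible
regardless of `n_runs`) and returns the smallest rank whose relative
Frobenius reconstruction error falls below 10%. The full error curve is
returned for inspection — the "knee" of that curve is informative when the
threshold rule is not attainable, in which case the scan cap is used and a
warning flag is set. On noise-dominated desk-scale simulations the 10%
level is often unreachable; the cap then plays the role of the operating
rank and is reported as such.

**Orthogonal Tucker.** `orthogonal_tucker()` fits
$Y \approx G \times_1 A^{(t)} \times_2 A^{(c)} \times_3 A^{(s)}$ with
orthonormal temporal and channel factors. The subject mode is *not*
compressed: $A^{(s)}$ is the identity, so each subject keeps one row of
core scores per (temporal, spatial) component pair and the component-wise
ANOVA remains possible. Fitting is truncated HOSVD followed by higher-order
orthogonal iteration; the fit is nondecreasing per sweep and factors are
orthonormal to 1e-10. `select_ranks_td()` estimates errors for all rank
pairs from the discarded singular values of the sequentially truncated
HOSVD and picks the smallest pair under the threshold, ordering by
`Rt + Rc` first and then smaller `Rt` (temporal parsimony is preferred
because the TOI is read from temporal components).

## Component screening

Screening mirrors what a physiologist would discard by eye and applies
objective cutoffs:

* **Temporal**: a unit-L2-normalised temporal component is excluded when its
  mean absolute value from 2 s after onset to the end of stimulus
  presentation is below 0.01 — such components carry their mass in the
  baseline and do not reflect a stimulus-locked response. The threshold is
  normalisation-dependent, which is why the package fixes the unit-norm
  convention and exposes `temporal_threshold`.
* **Spectral** (CPD only): a component whose argmax-magnitude frequency
  exceeds 0.1 Hz is excluded; hemodynamic responses for paradigms of this
  length live below that. Ties resolve to the lowest frequency, and a
  spectral-centroid variant is available (`spectral_method = "centroid"`).
  Longer/shorter paradigms or adult data warrant a different cutoff
  (`spectral_cutoff_hz`).
* **Cross-run consensus** (CPD only): components from different runs are
  linked when both their temporal and their spatial vectors correlate with
  r > 0.5 at p < 0.05 (t transform with n-2 df); connected components of
  this graph that span at least two runs become consensus components,
  weighted by the fraction of runs they appear in. Connected components
  (rather than cliques) implement the "consistently emerged" reading
  simply, at a documented risk of chaining; requiring *both* modes to match
  is the stricter of the two readings, and `consensus_mode = "either"` is
  available. Single-run orphans are never promoted. Tucker components skip
  this stage — the orthogonal decomposition is unique up to sign, and it is
  run once.

## Component-wise inference and TOI/ROI

Subject scores (CPD: $\lambda_r$ times the subject-mode column; Tucker: the
core fiber $G[r_t, r_c, \cdot]$) are tested with a 2 (factor A) x
2 (factor B) ANOVA: Type III sums of squares with sum-to-zero contrasts for
the between-subjects design (valid under unbalanced cells), and the
classical mixed-model partitioning when one factor is within-subjects (the
between effect tested against the subject-within-group mean square, the
within effect and interaction against the within-subject error). Per-test
alpha is 0.05 with no multiplicity correction by default, mirroring the
original component-wise procedure; a Benjamini-Hochberg flag (`fdr`) is
provided and is used in this package's own synthetic validation, where
planted effects are strong enough that the distinction between a genuinely
loaded component and a 5% false positive is exactly what matters.

For every effect with significant components the absolute temporal,
spatial (and spectral) vectors are summed, weighted by consensus occurrence
(weight 1 for Tucker), into nonnegative profiles. The TOI peak is the
profile's argmax restricted to the stimulus presentation; a profile whose
global maximum lies post-stimulus yields no TOI unless a within-stimulus
value reaches half of it (`toi_post_peak_frac`). The reported TOI window is
the peak +/- 1 s — matching the follow-up averaging window — and the ROI is
the set of channels reaching half of the spatial profile's maximum
(`roi_fraction`); both the half-width and the prominence fraction are
reported with every result, since the underlying procedure leaves them
open. Ties resolve to the earlier peak and the lower channel index by
construction.

Follow-up contrasts average HbO over the TOI extended by 1 s on each side
and the ROI channels, and compare the implicated cells with JZS Bayes
factors (Cauchy prior scale 0.707, the convention of the common Bayesian
t-test software; `bf_rscale` to change), paired by subject for
within-subject factors and two-sample otherwise. The integral over the
prior's mixing variable is computed on a shifted log scale so large t does
not underflow.

## The synthetic-data generator

`simulate_dataset()` emulates the target study conditions: a 2x2 design
(between or mixed) with 18 subjects per cell by default, 20 channels, 12
trials per subject (blocked by within-level in mixed designs), epochs of
2 s baseline / 15 s stimulus / 10 s post-stimulus at 50 Hz. Each trial's
signal is the sum of the planted effect waveforms — a nonnegative
double-gamma bump placed in the effect's channels and window, scaled by the
cell's amplitude multiplier — plus a slow sinusoidal drift (~30 s period,
random phase per subject and channel) standing in for systemic physiology,
and white Gaussian sample noise. One master seed drives per-subject
substreams at fixed offsets, so enlarging the design leaves existing
subjects' data untouched. An optional condition-independent shared response
(`base_amp`, default 0) can be added; note that a strong perfectly coherent
shared response changes the analysis regime, because planted group
differences then leak into the shared component's scores in every
decomposition — useful as a hard-mode demonstration, not part of the
default conditions.

The generator deliberately omits realistic optics (partial volume, scalp
interference), cardiac and respiratory spectral peaks, and motion
artifacts: passing recovery tests on this generator shows the pipeline's
statistical machinery works, not that preprocessing of raw optical data is
solved (that is upstream of this package).

## Validation choices and problem sizes

The package's own validation (see `tests/testthat/test-acceptance.R`) runs
at desk scale, chosen to exercise every stage in minutes: rank selection on
a 135 x 16 x 10 x 40 rank-4 tensor with 5% noise; 200 null simulations
(10 subjects/cell, 8 channels, 4 Hz) for type-I calibration of the
component-wise ANOVA; and 20-seed end-to-end recovery of a planted
2-channel, 4-8 s main effect (20 subjects/cell, 20 channels, 5 Hz,
amplitude 1.5x the trial noise SD) for both branches, with the BH flag on
and solver budgets of 200 HALS iterations at `tol = 1e-6` for the CPD
ensemble. The planted-recovery bar is the correct ROI channel set and a TOI
peak within +/-2 s of the planted center in at least 90% of seeds.

## Known limitations

* SNIRF/HDF5 I/O is not provided; the interchange format is the long CSV +
  JSON sidecar pair written by `write_recording()`.
* Consensus clustering by connected components can chain distinct
  components through intermediates when run-to-run variability is high.
* The `<10%` rank rule is a convention; on low-SNR data it is unattainable
  and the scan cap becomes the operating rank (flagged in the result).
* Profile summation weights Tucker combinations equally; a strongly
  significant and a barely significant combination contribute alike, which
  is why the BH flag matters for saturated synthetic effects.
* Only 2x2 designs with at most one within-subjects factor are supported.
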