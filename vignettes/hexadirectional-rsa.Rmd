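---
title: "Detecting six-fold and one-fold directional codes in multi-voxel patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting six-fold and one-fold directional codes in multi-voxel patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexadir)
library(dplyr)
```

## The scientific problem

Entorhinal grid cells fire on a hexagonal lattice of spatial fields, so the
population response is periodic in movement (or imagined) direction with a
period of 60°. Head-direction cells, by contrast, are tuned to a single
preferred direction (360° period). `hexadir` implements a multivariate test
for both codes in volumetric brain-imaging data from a direction-imagination
task: participants stand (mentally) at a start landmark and imagine facing a
target landmark, and the multi-voxel activity patterns evoked by different
imagined directions are compared pairwise.

The logic is representational: if a population carries a 60°-periodic code,
two trials whose imagined directions differ by a multiple of 60° sample the
periodic response at the same phase, and their activity patterns should be
more similar than those of two trials whose directions differ by 30° modulo
60°. The test statistic is the difference in mean pattern similarity between
those two pair conditions. Crucially, no per-subject grid orientation needs
to be estimated: whatever the orientation, direction pairs 0 mod 60 apart
agree in phase and pairs 30 mod 60 apart do not.

## The task geometry

Everything downstream conditions on the task's combinatorial geometry, so the
package derives it from scratch rather than hard-coding counts. Eighteen
buildings sit at the vertices of equilateral triangles arranged in a hexagon:
six inner buildings at unit lattice radius on the main axes (these are the
start locations), six outer ones at radius 2 on the same axes, and six outer
ones at radius \(\sqrt 3\) on the 30°-offset axes. From each start, exactly
ten of the twelve 30°-spaced directions are reachable along lattice vectors
(all six main-axis directions, and four of the six offset directions), giving
60 start–target combinations:

```{r geometry}
layout <- build_city_layout()
combos <- enumerate_combinations(layout)
table(table(combos$direction_deg))
```

When a start has both an inner and an outer building on the same direction,
the outer target is used. This rule is forced by two facts the design must
reproduce: inner-ring targets then occur only on 30°-mod-60 directions, so
two inner-target trials always differ by a multiple of 60°, and such pairs
make up 276/2256 = 12.23% of the 0-mod-60 condition while never appearing in
the 30-mod-60 condition.

Main-axis directions are reachable from all six starts and would be
oversampled, so `apply_exclusions()` removes two combinations per main-axis
direction under the constraint of two removals per start (a union of two
disjoint start-to-direction matchings, drawn by rejection). The remaining 48
combinations sample every direction exactly four times. `generate_design()`
then fills four 24-trial blocks: the 48 combinations are split into two
direction- and start-balanced halves for blocks 1–2 and again, independently,
for blocks 3–4, so every combination occurs exactly twice and never twice in
the same half. The balanced split uses greedy weighted sampling over
directions with retry; pure rejection needs several hundred attempts per
split, the greedy draw succeeds in a handful. Each block carries three catch
trials (never first; the probe view is correct in half of all catch trials).
Catch trials keep their direction labels and stay in the analysis: they are
ordinary imagination trials up to the probe, and removing them would break
the per-block balance.

Pairs with a direction difference of 0° are members of the 0-mod-60 (and
one-fold "similar") condition; this inclusion is what makes the 12.23%
inner-ring fraction come out exactly.

## Similarity, contrasts and controls

Pattern similarity is the Pearson correlation across voxels for every
unordered trial pair, Fisher-z transformed (`atanh`) before averaging.
Condition means are unweighted means over included pairs. Four schemes are
built in: `onefold` (Δ ≤ 30° vs Δ ≥ 60°), `mod60` (the grid contrast),
`mod90` (a biologically implausible four-fold control), and `cardinal`
(pairs of cardinal-direction trials vs the rest). The exclusion controls
(same start, same target, same combination, same block, inner-ring targets,
north–south street) are pair filters applied before averaging, and the three
distance controls regress z on a pair-distance measure — mean vector length,
absolute length difference, or the mean distance among all four buildings —
and re-form the contrast on the residuals (continuous or median-split
binary).

Two numerical choices matter. Noiseless synthetic patterns reach r = ±1
exactly, where `atanh` diverges; z is capped at `atanh(1 - 1e-15)` and the
pair flagged. Pairs involving a zero-variance pattern are flagged invalid
and dropped, not zero-filled. One documented consequence of unweighted
averaging: the 0-mod-60 condition weights Δ = 0 and Δ = 180 pairs as 336 and
384 of 2256, so a pure one-fold cosine similarity profile leaks into the
mod-60 contrast with expectation −48/2256 of the similarity amplitude —
slightly *negative*, i.e. conservative for detecting grid codes. The
acceptance checks verify the sign over 100 seeds.

## The synthetic cohort

The generator exists so that every stage is testable without real data. It
emulates: per-subject independent design realizations (own exclusion and
order randomization); voxel populations with grid (`baseline_v + A_v
cos 6(θ − ψ)`, one orientation ψ per subject-region, per-voxel amplitudes
`A_v ~ N(0, amplitude_sd)`), head-direction (von Mises or pure cosine tuning
at per-voxel preferred directions), or null tuning, plus i.i.d. Gaussian
trial noise; optional embedding of the patterns into a 4-D run (boxcar over
the 2 s cue + 10 s imagination, convolved with a canonical double-gamma
hemodynamic response, sampled at TR = 1.8 s) with cosine drift, AR(1) noise
and random-walk motion courses loading onto voxels; and behavioral responses
drawn von Mises around the true direction with a uniform lapse component.

What it does not emulate: spatial autocorrelation of fMRI noise,
physiological confounds, registration error, or any dependence of the
hemodynamic response on content. Passing tests therefore demonstrate that
the *analysis* is correct and calibrated, not that real data would show the
effects.

Key defaults and why:

* `n_subjects = 24` — matches the group size the method targets (group
  t-tests with 23 degrees of freedom).
* `behavior_kappa = 2.6` (`calibrate_kappa(33.68)`) — puts the mean absolute
  angular error in the mid-30s-degrees regime of trained participants;
  `lapse = 0.03` adds rare uniform guesses.
* Grid `amplitude_sd = 0.045` with unit baseline spread and unit noise at
  100 voxels — calibrated once, by simulating the d-versus-amplitude curve
  (1200 subjects per point), so that the group effect size of the planted
  pmEC-like signal is Cohen's d ≈ 0.55. This targets the weak-effect d ≈ 0.5
  regime in which group-level grid codes are typically reported; within that
  regime we chose the smallest amplitude whose expected one-tailed,
  Bonferroni-corrected rejection rate at n = 24 clears the 70% recovery bar
  used by the verification suite (exact power at d = 0.50 is 0.65, at 0.55
  is 0.73). The orientation ψ is redrawn uniformly per subject, so some
  subjects carry almost no detectable signal (ψ near 15° puts all sampled
  directions at the same response level) — heterogeneity the real method
  also faces.

## Pattern extraction

The time-series path mirrors the standard preprocessing contract: per-voxel
least-squares residualization against the six motion regressors (plus
intercept; residuals are exactly orthogonal to the regressors and the
operation is idempotent), an optional discrete-cosine high-pass at 100 s
(on by default only in time-series mode — directly simulated patterns need
no drift removal), and trial-window averaging of the volume during which the
10 s imagination period ended plus the two following volumes. Volume k
(0-based) is taken to cover acquisition time `[k·TR, (k+1)·TR)`, so the
window anchor is `floor(end_time / TR)`; a cue-locked variant is available
because the timing origin of the window is a genuine convention choice. tSNR is the
mean of the region-mean time course divided by its temporal standard
deviation (a voxelwise variant is offered); zero temporal variance reports
`NA`, never infinity.

## Searchlight and smoothing

Searchlight spheres have a 7-voxel diameter (123 integer offsets within
radius 3); every volume voxel may be a centre, the sphere content is
restricted to gray matter, and spheres with 30 or fewer gray voxels are
skipped ("more than 30" read strictly as ≥ 31). Each defined map voxel
equals the ROI contrast computed on its sphere — an equivalence the tests
check exactly. Maps are smoothed with a 4 mm FWHM Gaussian implemented as
normalized convolution, so undefined (NaN) voxels neither spread nor dilute
their neighbours. The sphere is defined by voxel count, not millimetres, so
it adapts with the voxel size.

## Inference

Subject-level significance uses label shuffling: a permutation reassigns the
trial metadata across trials, every pair is relabelled consistently (pair
(i, j) inherits the labels of (π(i), π(j)), so conditions, filters and
distances move together), and the contrast is recomputed on the unchanged
correlation matrix. p uses the add-one estimator `(1 + #[perm ≥ obs]) /
(n_perm + 1)` — never exactly zero, so the signed z = Φ⁻¹(1 − p) is always
finite. Group-level inference is a one-sample t against zero (one-tailed for
directional predictions, Bonferroni-multiplied for left/right region pairs)
or a sign-flipping permutation t. Small-volume random-field correction is
out of scope; Bonferroni over mask voxels or max-statistic permutation are
the offered substitutes. The calibration harness
(`calibration_experiment()`) repeats cohort → pipeline → group test and
reports rejection rates; under null models these sit at the nominal level
(checked against the binomial band over 200 cohorts), and subject-level
permutation p-values are uniform (Kolmogorov–Smirnov).

## Behavioral and visual controls

Behavioral accuracy is the absolute wrapped angular error; the chance
criterion is a one-sided Wilcoxon signed-rank test of a subject's errors
against the 90° median of a uniform responder. The behavioral 60°-modulation
control multiplies the two errors of every trial pair and contrasts the
mod-60 conditions. One honest caveat, documented because the acceptance
checks measure it: although this contrast has exactly zero expectation under
direction-independent errors (per-trial leverage cancels, 47/2256 against
48/2304), its distribution is strongly right-skewed — all within-direction
pair products fall in the 0-mod-60 condition — so the parametric t at n = 24
rejects a true null in roughly 9–10% of cohorts at a nominal 5%. That is a
property of the error-product statistic itself, and a reason to prefer the
sign-flip permutation variant when using this control in anger.

The visual-similarity control computes, per image, the 2-D FFT magnitude and
phase of the luminance channel and the CIELAB L/a/b channels (D65 reference
white), correlates each dimension across image pairs, and compares similar
against dissimilar direction pairs (different starts only) with two-sample
t-tests, Bonferroni-corrected for 24 comparisons (the correction count is
taken as given and configurable). The "views" fed to it are procedural
scenes — direction-dependent sky gradient plus distance-scaled building
rectangles — sufficient to exercise the feature pipeline, with no claim of
visual realism.

## Problem sizes and reproducibility

The packaged checks use 100-voxel regions, cohorts of 24 subjects, 50
cohorts for recovery, 200 for calibration, and 1000-permutation
subject-level tests — sizes chosen so the whole verification pipeline runs
on a laptop in minutes while keeping binomial and KS bands tight enough to
be meaningful. Every stochastic step takes an explicit seed; cohort and
calibration runs derive per-subject seeds from a single master seed, and the
pipeline manifest records config hash, seeds and file checksums so identical
configs reproduce identical artifacts.

## Known limitations

* The generator's noise is white across voxels; searchlight maps on real
  data have spatially correlated noise and their smoothness is not emulated.
* The mod-90 "B" condition pools remainders 30 and 60, following the
  four-fold control's construction; other poolings are not offered.
* Condition averaging pools all pairs across runs; a
  within-run-then-average variant is not offered (the same-block exclusion
  filter covers the temporal-autocorrelation concern instead).
* The north–south street is identified by a configurable lattice column
  (default: the column through the two inner buildings at x = 0.5).
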