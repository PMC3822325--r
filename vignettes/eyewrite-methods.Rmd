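---
title: "Methods: via-point featurization and Bayesian recognition of eye writing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: via-point featurization and Bayesian recognition of eye writing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyewrite)
```

## The problem

Cursive eye writing asks a user to trace letter shapes with smooth-pursuit
eye movements. The resulting gaze records differ from pen trajectories in
three ways that drive every design choice in this package: movement
initiation and release are contaminated by small ballistic saccades (the
pursuit loop needs a "burn-in" to lock on); there is no spatial reference
frame, so only *relative* geometry is meaningful; and the signal carries
physiological components — ocular microtremor, undetected saccades, pupil
dynamics — that are noise for recognition but signal for assessing motor
control.

## Deterministic front end

**Smoothing.** Positions and the finite-difference velocities are both
filtered with a binomial kernel of order 20 (the normalized row of
Pascal's triangle, a cheap discrete Gaussian). Boundaries are handled by
mirror reflection about the end samples, which gives DC gain exactly 1:
constants pass through unchanged, so the filter cannot create artificial
extrema (and hence spurious via-points) at trajectory ends.

**Saccade trimming.** Acceleration is measured in px/sample², the natural
unit at a fixed 75 Hz rate. Within the first 30 samples, everything up to
the *last* sample exceeding 0.4 px/sample² is deleted; within the last 5
samples, everything from the *first* offending sample on. The standard
rule states the deletion only for the leading window; we mirror it for the
trailing one, since end-of-trajectory contamination is described
symmetrically. The rule is single-pass; if trimming would leave fewer than
two samples the trajectory is returned untouched with a
`eyewrite_degenerate_trajectory` warning rather than an error, so batch
pipelines survive pathological records.

**Via-points.** Candidates are the samples where ẋ or ẏ changes sign (or
is exactly zero); on the discrete signal the crossing between samples i
and i+1 is attributed to the sample with the smaller absolute velocity.
Since discrete zero-crossing detection is not fully determined by the
continuous description, this tie-break is our choice; it lands on the
sample nearest the true zero for a locally linear velocity. A geometric
constraint rejects a candidate when *both* its x and y distances to the
previously kept via-point are below `min_sep` (default 2 px) — this prunes
the candidate bursts that noise produces along horizontal or vertical
plateaus, where one velocity component hovers around zero. This threshold
has no canonical value; 2 px is slightly below the
pursuit-noise scale and is configurable. The first and last samples are
always via-points; at most 15 are kept, earliest first.

**Auxiliary features.** Width and height are the bounding box of the
smoothed trajectory. The spectral energy A sums the discrete power spectra
of ẋ and ẏ over all frequency bins above f₀ = 2.6 Hz, with the
normalization `sum(|fft(v)|²)/n² = mean(v²)`, so a sinusoidal velocity of
amplitude a above the split contributes a²/2 per axis (this is the
Parseval identity the unit tests check). Whether the two axes should be
combined by summation or replaced by a single speed signal is not
determined by the method's description; summation keeps the feature
invariant under axis reflection. μₚ and σₚ are the mean and standard
deviation of the pupil series. We read the pupil "variability" as a
standard deviation rather than a variance: its domain (0..5 in
steps of 0.1) matches the SD scale of plausible pupil series, and the
symbol σ conventionally denotes an SD.

## Discrete domains and discretization

Relative displacements live on −40..40 (81 bins plus a termination
marker), velocities on −10..10 (21 bins plus marker) after division by 30
(px/s per bin). The displacement scale is an open choice; we use 2.5 px per
bin, which maps the generator's 100 px letter box onto roughly ±40, and
apply the same scale to the size features (domain 0..50). The
spectral-energy scale is likewise ours: 150 (px/s)² per bin, chosen from
the magnitudes the default generator produces so that the strongest
impairment tremor stays within the 0..30 domain rather than saturating its
top bin. The pupil grids are −1..1 (step 0.01) and 0..5 (step 0.1).

The **termination marker** ("probability well") is an extra domain value,
off the numeric scale, taken by all four via-point dimensions
simultaneously for slots beyond a trajectory's end. It lets a fixed
15-slot model represent variable-length trajectories without a length
variable: short trajectories concentrate transition mass on
marker→marker, which at inference time strongly favors symbols of the
right length. First-via-point terms keep the marker in their domain for
uniformity of table shapes, although a first via-point always exists — the
marker simply receives its Laplace floor there.

## Learning

Chain terms are Laplace succession laws with α = 10⁻⁷: essentially
empirical frequencies, with every value strictly positive so that a single
surprising bin cannot zero out a whole product. Tables are then smoothed
along their *target* axis with a truncated discrete Gaussian (support 15
bins, variance 2 bins² for displacements; 7 and 1 for velocities). This
smearing simulates the shape variability of a larger exemplar database; we
read the kernel "order" as the support length. The marker entry
is excluded from smearing — termination is a structural fact, not a
geometric one — and the numeric part is renormalized to the remaining
mass. Reflection at the domain boundary makes the uniform distribution an
exact fixed point of the smoother, which is why cells without exemplars
(left at the Laplace uniform prior, with a logged message) can skip the
smoothing pass unchanged.

Size and energy terms per (L, H) cell, and pupil terms per H, are
truncated discrete normals: sample mean and SD, density evaluated on the
grid, renormalized (values off the domain get zero). The SD is floored at
half a grid step so single-exemplar cells keep a usable density. All terms
conditioned on the unknown symbol `"$"` are uniform over their full
domain, including the marker — this keeps `"$"` agnostic about trajectory
length, which is what an unknown-length unknown-shape background class
should be. Raw counts and normal-fit sufficient statistics are stored in
the model object, so confirmed trajectories can be added later without
re-reading the original database.

Priors over symbols and disability levels are uniform; language priors or
word-level prediction are out of scope.

## Inference

All posteriors are computed in log space; the marginalization over H (or
over L, for disability assessment) uses log-sum-exp. On 15-slot products
of bounded-below tables this is not strictly necessary in double
precision, but it makes the "no underflow for 15 via-points" contract
independent of domain sizes and α. Probabilities are floored at 1e-300
before taking logs so that a fully truncated normal tail cannot produce
NaNs. The incremental posterior after k via-points simply omits the terms
for slots beyond k — for a chain, marginalizing the future is exactly
dropping its factors, an identity the enumeration oracle in the test suite
verifies. The final posterior pads short trajectories with the termination
marker (the final-inference product runs over all 15 slots) and adds the
size and energy terms inside the H-sum; pupil terms cancel for letter
recognition because they are independent of L.

Novelty is decided on the geometric posterior *before* auxiliary
variables: sizes and energies vary little across an alphabet, so their
likelihoods pull any trajectory toward the known classes and mask novelty.
The decision is the plain argmax rule (flag when `"$"` wins); a minimum
P("$") threshold is available but off by default. Ties in `classify()` are
broken by domain order and flagged.

Entropy is reported in natural log units (the choice of base is a convention; we fix it here); the uniform prior over 36 symbols gives ln 36 ≈ 3.58 nats.

## The synthetic test bed

The original nine-alphabet eye-written database is not deposited, so the
generator stands in for it. It emulates the statistical structure the
model assumes: smooth strokes traced at pursuit speeds (~150–250 px/s in a
100 px box, so scaled velocities fill the −10..10 domain), white pursuit
noise (SD 1 px), a faint 6 Hz microtremor (0.3 px), an optional
high-acceleration initiation saccade (probability 0.25, 25 px) that
exercises the trimming stage, and a slow pupil random walk (baseline +0.1,
step SD 0.02). Ten stylized strokes (loops, waves, arcs, serpentines,
spirals, ...) form the template library; symbol identity is arbitrary.
The shapes are designed to be mutually distinguishable at the model's
resolution — two early candidates (a Gaussian bump next to the half-circle
arc, and an upward serpentine next to the rightward wave) were close
enough in coarse via-point geometry to absorb each other's trajectories
and were replaced; a library of near-duplicate shapes would misstate
novelty detection the same way visually confusable letters do. Requesting
more symbols than base shapes derives new templates by deterministic
rotation. Allograph variants (mirrored forms) can be mixed in at a
configurable rate.

The impairment manipulation is: spatial
scaling by 4/5 (level 2) and 1/2 (level 3) about the trajectory centroid
(the scaling origin is irrelevant to the model, which only sees relative
displacements), an added 6 Hz sinusoid, and a pupil-mean shift with
reduced variability. The sinusoid amplitudes ("small" and "medium") and
pupil shifts have no canonical values; we declare 2
px / 5 px, +0.1 / +0.2, and SD factors 0.7 / 0.4. These defaults are the
study conditions of the test suite, not fitted quantities.

What the generator does *not* emulate: the oculomotor plant (saccade
dynamics are a 4-sample linear jump, tremor is a pure sinusoid),
blink artifacts, drift of the illusory-motion percept, allograph diversity
beyond mirroring, and writer-specific style. Passing tests therefore show
that the pipeline and model recover the structure they assume — parameter
recovery, not field performance on human data.

## Experiment sizes

The test suite and `scripts/acceptance.R` use problem sizes chosen to
exercise the method's characteristic experimental structure: 35 symbols × 9 alphabets
(315 leave-one-alphabet-out trials) for the trial-count experiment; 10
symbols × 9 alphabets for recognition and entropy tracking; and the
disability experiment trains on a level-1 database of 10 symbols × 8
alphabets plus its manipulated level-2/3 copies. The novelty experiment
trains 3 of 8 symbol classes on 20 alphabets and tests the other five
classes for novelty and 10 held-out alphabets of the known classes for
retention: with many fewer training exemplars per class, retention becomes
unstable, because the model has no via-point insertion/deletion mechanism
and a held-out exemplar with an unseen via-point count collapses onto the
background class. Twenty exemplars per class cover the count variants the
generator produces. Miniature models for the enumeration oracle use 3
symbols, 2 disability levels, ±2 domains with marker, and 3 via-point
slots, small enough for exhaustive enumeration of all unobserved
via-point configurations.

## Known limitations

* No insertion/deletion model for via-points: recognition is sensitive to
  spurious or missing via-points near trajectory starts, and this is the
  dominant error source in both recognition and known-class retention.
* Recognition robustness and novelty sensitivity trade off through the
  smoothing kernels: wide smearing (needed with few exemplars) makes the
  recognizer forgiving and the novelty detector lenient.
* The disability score depends entirely on how separated the simulated
  impairment levels are; it is a measurement-tool demonstration, not a
  clinical claim.
* The H-marginalization floors every trained symbol's evidence at its
  untrained-level uniform slices, capping how decisively the background
  class can win; novelty detection therefore leans on observed-context
  mismatches and trajectory length.
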