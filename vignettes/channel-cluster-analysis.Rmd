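---
title: "Models and methods: channel clustering, sparklet coupling, and current scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: channel clustering, sparklet coupling, and current scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvclust)
```

## Scientific background

In arterial smooth muscle, voltage-gated KV2.1 and CaV1.2 channels do not
sit in the membrane as isolated proteins: they self-assemble into clusters,
and the degree of clustering carries function. KV2.1 forms micro-clusters
that can coalesce into large macro-clusters when a C-terminal serine in its
clustering domain is phosphorylated; macro-clustering is more extensive in
female than male myocytes, and it promotes the clustering and cooperative
gating of neighboring CaV1.2 channels — hence sex-specific Ca²⁺ influx —
while leaving KV2.1's own conductive function essentially untouched (only
on the order of 1% of membrane KV2.1 channels conduct).

`kvclust` implements the computational core of that style of study as a
reusable, tested pipeline over synthetic data with known ground truth:

1. a stochastic lattice model of cluster self-assembly
   (nucleation/growth/removal) whose steady states show the exponential
   cluster-size law seen in imaging data;
2. segmentation of 3D confocal stacks and 2D localization maps into cluster
   tables, exponential size-distribution fits, and a macro/micro
   classification;
3. quantal analysis of Ca²⁺ sparklet traces: idealization, site activity
   (nPs), and coupling-coefficient (κ) inference under a coupled Markov
   chain;
4. linear scaling of whole-cell current density with the fraction of
   functional channels, plus blocker-subtraction IV analysis;
5. generators for every input the pipeline consumes.

All empirical statements below are computed by the test suite
(`tests/testthat/`), the analysis drivers (`analysis/`), or
`scripts/acceptance.R`; nothing is quoted from external data.

## The lattice self-assembly model

The membrane is a periodic `rows × cols` lattice of sites, each empty or
occupied by a channel. One synchronous step, with all events sampled from
the state at the start of the step:

* an occupied site is vacated with probability `p_removal` (removal acts on
  any occupied site, not only cluster edges);
* an empty site with at least one occupied 4-neighbor becomes occupied with
  probability `p_growth`;
* an empty site with no occupied neighbor nucleates with probability
  `p_nucleation`.

A site eligible for growth uses `p_growth` only — growth and nucleation are
not compounded at the same site. Clusters are 4-connected components under
periodic boundaries. These conventions (4-neighborhood, periodic wrap,
synchronous update, growth precedence) are this package's choices; the
qualitative behavior — exponential steady-state size distributions in the
low-density regime — does not depend on them, but exact small-grid
enumeration does, and the test suite pins the update rule against an
independent 512-state transition-matrix enumeration on a 3×3 lattice.

**Steady-state detection.** Total occupancy is averaged over 500-step
blocks; the run is declared stationary when consecutive block means change
by less than `rel_tol` for `consecutive` blocks in a row. The defaults are
`rel_tol = 0.02` and `consecutive = 3`: at the occupancies this model
reaches on grids up to 512² (a few hundred to a few thousand occupied
sites), stationary block means fluctuate by 1–3%, so a much tighter band
sits below the stationary noise floor and would never trigger; 2% sits just
above it while still rejecting the initial filling transient, which changes
occupancy by tens of percent per block. Non-convergence within `max_steps`
is a flagged result, not an error.

**Parameter fitting** (`fit_params()`) is a deliberate grid search: each
candidate is simulated with ≥3 replicate seeds (fixed 1500-step burn-in on a
128² grid by default), relative-frequency distributions are averaged, and
the distance to the observed distribution is the sum of squared frequency
differences over the union of the supports (absent sizes count as zero, so
missing tail mass is penalized). Relative frequencies make different grid
and cell sizes comparable. At a few hundred observed clusters the growth
probability is recovered exactly on a coarse grid while nucleation is only
weakly identified — the fit surface is much flatter along that axis — so
self-consistency is asserted on the growth axis and on the generating point
beating all points with a different growth probability.

## Segmentation and cluster metrics

3D stacks are thresholded at a fixed absolute level, labeled with
26-connectivity, and filtered by the standard spot rules: components must
exceed two voxels (`min_voxels = 3`) and span at least 100 nm laterally and
150 nm axially. Volumes are voxel counts × voxel volume; the default axial
step is 0.13 µm. 2D maps use 8-connectivity. Maximal connectivity matches
the region-growing behavior of the interactive tools this replaces; the
choice matters only for marginally touching components.

**Macro/micro threshold.** The lower volume limit of a macro-cluster is the
mean cluster volume minus two standard deviations of the per-cell means —
with the canonical inputs (mean 0.12 µm³, SD 0.03 µm³) that is 0.06 µm³ —
and classification is strict: a cluster is macro iff its volume exceeds the
threshold. For an exponential population with mean µ the expected macro
fraction has the closed form `exp(-0.06/µ)` (≈ 0.42 at µ = 0.07 µm³,
≈ 0.65 at µ = 0.14 µm³), which the tests verify by simulation. Note the
threshold is a population-level constant derived from per-cell *mean*
volumes; applying mean − 2·SD to a single cell's pooled, near-exponential
volume sample would give a negative number (SD ≈ mean for an exponential),
which the software warns about rather than silently clipping.

**Sphere-equivalent diameter.** Reported as `d = (6V/π)^(1/3)`: 0.06 µm³ ↔
486 nm and 0.12 µm³ ↔ 612 nm. Published figures quoting ~193 nm and ~278 nm
for these volumes are not consistent with the sphere formula (they are
closer to what a volume in µm³ misread as a diameter heuristic would give);
this package reports the formula value and documents the discrepancy rather
than matching those prints.

**Membrane occupancy** is reported as the summed sphere-equivalent
cross-sections, `π r²` with `r = (3V/4π)^(1/3)`, of membrane-restricted
clusters over the membrane area — the simplest geometry-consistent
definition, since the measurement is usually reported without a formula.

**Localization maps.** Blink movies are processed per frame: above-threshold
pixels are grouped (8-connectivity), each spot is fit with a 2D Gaussian
(intensity-weighted moments as start and fallback), localizations below a
photon threshold are discarded, and accepted centroids are rendered as a
count histogram at 20 nm/pixel. Coordinates are zero-based with half-open
bins: a point at 100 nm lands in pixel 5 at 20 nm/pixel. The
confocal-emulating Gaussian blur replaces each pixel by a weighted average
of its neighbors within a 200 nm radius (σ = radius/2, kernel truncated at
the radius); convolution is circular, so integrated intensity is conserved
exactly and the operation is translation invariant. Two point clusters
150 nm apart merge into one connected blob after the blur — the mechanism by
which groups of micro-clusters appear as single macro-clusters at confocal
resolution.

## Quantal sparklet analysis

A sparklet site with `N` channels produces a fluorescence trace sampled at
100 Hz. Idealization assigns each frame the nearest integer multiple of the
quantal amplitude (half-amplitude thresholds), clamped to `[0, max_levels]`.
The quantal amplitude is supplied, or calibrated from the amplitude
histogram as the spacing of a mixture of equally spaced Gaussians
(`fit_quantal_amplitude()`). At an SNR (quantal amplitude over noise SD) of
5, frame-level agreement with the generating ground truth exceeds 95%
(measured ≈ 99%).

**Site activity.** nPs is implemented as the time-weighted mean open-channel
count, `nPs = Σ_k k·T_k / T` — the standard nP_open analogue, with `n` the
number of quantal levels reached and `P_s` the occupancy-weighted
probability of sparklet occurrence. This is this package's operational
definition (the measure is usually defined only verbally) and is consistent
with the magnitudes conventionally reported: low-activity sites around
0.05–0.1, high-activity sites around 0.25–0.35. Sites are classed high iff
`nPs > 0.2`, strict at the boundary. Cell-level summaries include silent
cells as nPs = 0 so that population means are not conditioned on observing
activity.

**Coupled Markov chain and κ.** Each channel alone is a two-state chain with
stationary open probability `p` and mean open dwell time of 2 frames
(configurable); the closing probability per frame is `1/mean_open` and the
opening probability `p/(mean_open(1-p))`, which bounds admissible `p` below
`mean_open/(mean_open+1)`. The joint transition kernel is the mixture

    P = (1 − κ) · P_indep + κ · P_sync

where `P_indep` steps every channel independently and `P_sync` picks one
channel uniformly at random as leader, steps it, and sets all channels to
the leader's new state. κ = 0 is independent gating; κ = 1 confines the
site to the all-closed/all-open levels — exactly the stated endpoints of the
coupling coefficient. Because channels are exchangeable under both kernels,
the aggregate open-channel count is itself Markov, and the likelihood of an
idealized record is evaluated exactly from its transition counts,
conditional on the first frame. `estimate_kappa()` maximizes over
`(κ, p) ∈ [0,1] × (0, p_max)` by bounded quasi-Newton search from a small
grid of starts. For `N = 1` the two kernels coincide, κ is structurally
unidentifiable, and the estimate is returned as `NA` with a flag rather
than a number.

Recovery under the study conditions (N = 3, p = 0.1, 2000 frames, 20
replicate sites): mean κ̂ ≤ 0.01 when κ = 0, ≥ 0.97 when κ = 1, and within
±0.02 of 0.4 when κ = 0.4; the RMSE decreases monotonically with record
length (checked at 500/2000/8000 frames). The exact estimator used on real
recordings in the literature is typically custom unpublished code, so these
definitions are validated by simulation recovery, not against per-cell
published values.

## Current-density scaling

Whole-cell current density is linear in the number of conducting channels,
so the prediction layer is a single multiplication: a fraction `f` of
functional channels scales the 100%-functional reference density at every
voltage by `f`. The built-in references are the model-derived densities at
+50 mV, 7006 pA/pF (male) and 17293 pA/pF (female). Report-time rounding
follows the printed precision convention — nearest integer at ≥ 100 pA/pF,
one decimal below — giving 3503 and 701 (male, 50%/10%), 8646 and 1729
(female), and 70.1 / 173 at 1%. Rounding is applied only at report time;
`predicted_density` stays exact, so scaling composes multiplicatively.
Published 0.1%-functional values are *not* linear in `f` (they derive from
the interior of a full myocyte electrophysiology model that is out of scope
here), so this package deliberately does not reproduce them and the full
kinetic model is not reimplemented. The liquid-junction-potential
correction (13 mV for K⁺ solutions, 9.4 mV for Ba²⁺) is available as an
explicit voltage-axis offset and is off by default.

Drug subtraction (`drug_subtraction()`) computes the blocker-sensitive
component as pre-drug minus post-drug traces under an exactly matched
protocol; `build_iv()` summarizes each step over a measurement window
(default: mean of the final 50 ms) normalized by capacitance.

## Synthetic data: what it does and does not emulate

The generators produce exponential cluster volumes on a box-shell
"membrane", Gaussian-blob renders with Poisson shot noise and Gaussian read
noise, blink movies with per-frame Bernoulli emitters and Gaussian
localization jitter, and coupled-gating traces drawn from the same kernel
the estimator assumes. They emulate the *statistics* the analyses consume —
size laws, spot shapes, noise floors, gating correlations — and none of the
biology that produces them: no cell morphology, no antibody labeling
density, no photophysics beyond Bernoulli blinking, no ER-junction
tethering. Passing recovery tests therefore demonstrates that the inference
chain is correct and well-calibrated on data satisfying its assumptions; it
does not certify performance on real images or recordings, where model
mismatch (non-exponential tails, structured background, non-Markov gating)
is the dominant risk. Every generator takes one seed and is bit-reproducible
under it; the pipeline derives per-stage seeds from a single global seed
(`derive_seed()`), so stages can be rerun in isolation.

## Numerical choices and problem sizes

* Segmentation thresholds are fixed absolute levels (no adaptive
  thresholding), matching fixed-threshold spot assignment.
* Exponential fits use Levenberg–Marquardt least squares on binned counts
  (`count = A·exp(−size/τ)`), started from a log-linear regression; default
  bin widths are 0.02 µm³ for volumes and 500 nm² for areas (the analyses
  that consume areas pass widths explicitly).
* Degenerate inputs are rejected with messages (fewer than 3 non-empty
  bins; non-uniform sampling; records under 100 frames for κ; mismatched
  protocols), never silently coerced.
* Default run sizes keep every analysis on one CPU in minutes: 512² lattice
  for the steady-state tail (≈1 min), 128² for fitting grids, 2000-frame
  traces for κ, 10⁴ clusters for size-law recovery. They are the scales at
  which the statistical assertions above are calibrated; all are arguments,
  not constants.

## Known limitations

* The lattice model is on-lattice and single-species; it does not model
  explicit tether proteins or continuous-space aggregation.
* The κ estimator assumes the mixture kernel above with a fixed mean open
  time; real channels with strongly voltage- or Ca²⁺-dependent kinetics
  violate that, and κ then measures effective synchrony under the assumed
  clock.
* Membrane occupancy depends on the sphere-equivalent footprint convention;
  alternative conventions rescale it by a shape factor.
* The current-scaling layer is exactly linear by construction and is not a
  kinetic model; it cannot reproduce sub-linear behavior at very small
  functional fractions.
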