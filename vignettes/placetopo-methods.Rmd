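---
title: "Methods: testing anatomical topography in place-cell populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing anatomical topography in place-cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(placetopo)
```

placetopo asks one question of a calcium-imaging recording from hippocampal
CA1: are place cells that sit close together in the imaging plane more
similar in their spatial tuning than place cells picked at random? The
package implements the full chain needed to answer it — event-rate tuning
maps, place-cell classification, a battery of spatial-clustering statistics
with resampling nulls, cross-environment remapping comparisons, Bayesian
position decoding, and object-vector cell analysis — together with a
synthetic-data generator whose topography can be switched on and off, so
every stage can be verified against a known ground truth.

This vignette records the package's methodological choices: the generative
model, the estimators, the null constructions, the defaults and why they
were chosen, and what the synthetic validation does and does not establish
about real recordings.

## The synthetic population model

**Trajectory.** Free foraging in a square arena (default 80 cm, 50 cm walls
as metadata) is modelled as a smoothed random walk: each velocity component
is an Ornstein–Uhlenbeck process with correlation time `tau = 2` s, with
specular reflection at the walls, sampled at 15 Hz. The per-axis stationary
SD is set so the mean running speed equals `mean_speed` (default 8 cm/s,
a typical active-foraging speed for a mouse). These values are not taken
from any dataset; they were chosen once so that a 35-minute session visits
essentially every 2.5 cm bin of the arena (coverage is above 99% in
simulation, and the generator contract demands at least 95%), which is the
regime the downstream analyses assume.

**Cells.** Somata are placed uniformly in a 350 µm × 350 µm field of view
by dart-throwing with a 10 µm minimum spacing, so the 15 µm
overlapping-pair exclusion used by the pair statistics is genuinely
exercised. Each cell carries one Gaussian place field (two with probability
0.2), field width σ ~ U(4.5, 7.5) cm — about a 20 cm field diameter at the
30% contour — peak event rate ~ U(0.5, 1.5) events/s, and an active flag
drawn at `active_fraction` (default 0.35, the fraction of active place
cells typically estimated for arenas of this size). Silent cells emit only
uniform noise events (0.01 events/s), which keeps them below the 40-event
inclusion threshold in a 35-minute session.

**Events and ΔF/F.** Given a trajectory, events are an inhomogeneous
Poisson process with intensity = sum of the cell's Gaussian bumps evaluated
at the animal's position, plus the uniform noise rate. Amplitudes are
gamma(2, 0.5) (mean 1). The surrogate ΔF/F convolves the amplitude-weighted
impulse train with a single-exponential calcium kernel (τ = 1.5 s, a
GCaMP6s-like decay; gain 0.6) and adds white noise (SD 0.13). With these
defaults the population mean SNR lands mid-way in the 3–8 range that
characterizes good in vivo recordings.

**Injected topography.** The alternative hypothesis the battery must
detect is *local clusters of similarly tuned cells*. `clustering_config()`
implements it as a cluster-patch process: circular anatomical patches of
diameter `cluster_scale` (default 150 µm) are scattered to cover a
`coverage` fraction of the FOV (default 0.8); each patch owns a field
anchor drawn uniformly in the arena; a member cell's field centroid is
`λ·(anchor + jitter)` + `(1−λ)·uniform` with 4 cm jitter, while cells
outside every patch stay uniform. At `λ = 0` anatomy and tuning are
statistically independent — the null the package is calibrated on. This
patchy form was a deliberate choice over a smooth anatomical gradient: a
smooth gradient raises within-bin similarity *homogeneously* across the
FOV, which the binned Moran statistic — a measure of spatial heterogeneity
of bin values — cannot see, whereas discrete patches are exactly the
configuration the prior literature proposed and the binned analysis is
built to detect. The model satisfies the generator contract that expected
field distance increases with anatomical distance up to `cluster_scale`,
and at strong coupling the median nearest-neighbour field distance falls
below half the random-pair median.

**Remapping and objects.** `generate_remapping_pair()` either redraws all
field centroids and active flags independently (`"orthogonal"`, modelling
exposure to a different arena) or returns the identical layout
(`"preserved"`, modelling re-exposure, where only event noise differs).
`assign_object_vectors()` gives a fraction of cells (default 0.10) a
preferred distance (log-normal, median 15 cm — matching the observed
median distance of real object fields — truncated at 35 cm) and a uniform
preferred angle; in object sessions these cells gain an additive Gaussian
bump (σ = 5 cm, amplitude 1.5× their peak rate) at object position +
vector, reused when the object moves.

## Tuning maps

Maps divide the arena into 2.5 cm bins (an 80 cm arena gives 32 × 32),
sum deconvolved event *amplitudes* per bin — amplitudes, not counts,
because the deconvolved amplitude is the activity currency — and divide by
the seconds spent in the bin. Both occupancy and events are speed-filtered
first (default v_min = 2 cm/s on a boxcar-smoothed speed; the threshold is
config-exposed because published values vary).

Smoothing is a Gaussian kernel with σ = 2.5 *bins* (6.25 cm) by default;
σ in cm is available via `sigma_units` since conventions differ. Two
implementation details matter:

* **Mask handling.** Unvisited bins are flagged, never imputed, and must
  not dilute their neighbours. Smoothing is therefore normalized
  convolution: smooth rate×mask and mask separately and divide.
* **Boundaries.** The 1-D smoothing operators use reflecting boundaries,
  which makes them symmetric and doubly stochastic — constants are fixed
  points and total rate mass is conserved exactly on fully visited grids
  (the test suite checks both to 1e-6 or better).

Object-tuning maps use the same normalization on a (distance × angle) grid
(2 cm, 6° bins; angle origin = arena east, counter-clockwise, allocentric)
with circular wrapping of the angle axis. Because polar bins subtend
wildly unequal arena areas, bins whose kernel-pooled occupancy falls below
0.5 s carry no estimate; without this, the nearly empty bins next to the
object produce spurious rate peaks.

Place fields are 4-connected components of bins at or above 30% of the map
peak, at least 4 bins and at most half the arena in area; the centroid is
the rate-weighted mean of the component's bin centres, and the main field
is the highest-peaked one (ties: larger area, then lowest (row, col) of
the peak bin). These thresholds are conventional, not prescribed, and are
config-exposed. Spatial information uses the standard bits-per-event form
`SI = Σ p_i (λ_i/λ̄) log2(λ_i/λ̄)`.

## Signal quality and classification

SNR is signal/noise with signal = mean over significant transients of each
transient's 90th-percentile ΔF/F and noise = mean absolute frame-to-frame
ΔF/F difference outside transients. A *signed* mean of differences would
be ≈ 0 by construction, so the absolute form is the only usable reading.
Transients are epochs above median + 3 robust (MAD) SDs lasting ≥ 0.5 s,
with sub-0.2 s gaps bridged — conventional values, config-exposed.
Inclusion requires SNR strictly above 3 and at least 40 events per
environment.

A cell is a place cell iff (1) its SI exceeds the 95th percentile of 1,000
circular event-time shuffles (shift uniform in [30 s, duration − 30 s],
preserving inter-event structure), (2) split-half stability — maps from
interleaved odd/even 1-minute blocks — exceeds r = 0.3, and (3) at least
one place field is detected. The shuffle count, shift floor, percentile
and r threshold are defaults standing in for values the underlying
methodology leaves to its references; all are arguments.

## The clustering battery

All pairwise statistics (anatomical distance, main-field distance, map
correlation over jointly visited bins) live in a pair table; pairs closer
than 15 µm are flagged for exclusion where somatic overlap could leak
signal, i.e. in within-bin statistics, but not in the global pair table.

**Binned Moran's I.** Cells are assigned to an 8 × 8 grid of ~45 µm
anatomical bins (FOV/8 per axis, anchored at the FOV corner). Bins with at
least 3 place cells get the mean pairwise map correlation of their members
(sub-15 µm pairs excluded). Global Moran's I,
`I = (n/S0) · (zᵀWz)/(zᵀz)`, uses row-standardized inverse-distance
weights with a cutoff at twice the bin size (the weight specification is
not canonical; queen contiguity is provided as an alternative and the
choice is reported in the result object). Significance compares I to the
95th percentile of 1,000 random reassignments of the bin values. Local
Moran's I decomposes the global statistic per bin with conditional
permutation p-values, Bonferroni-corrected by default. Size-matched
controls redraw, 200 times, random cell sets of each bin's size from the
session roster and recompute the same statistic.

**Profiles.** Expanding-circle profiles pool the pairwise statistic over
all pairs within radius r of a reference cell (radii 15–60 µm in 5 µm
steps; a neighbour exactly on the circle is included), report the median
with a percentile-bootstrap CI (10,000 resamples, 99% by default), and
compare it to the median of 200 size-matched draws from pairs at all
distances. The field-space profile swaps the roles of the two spaces
(radii 5–50 cm over field distance, statistic = anatomical distance).
Effect sizes between the smallest- and largest-radius groups use Cliff's
delta, computed by rank counting and verified against exhaustive pair
counting.

**Nearest neighbours.** Each cell is paired with its anatomically nearest
place cell (ties to the lowest index) and with a random partner. Moran's I
on the per-cell NN statistic needs care: mutual nearest neighbours carry
*identical* derived values, so permuting the derived values produces a
grossly anti-conservative null (~90% false rejection in simulation). The
null instead reassigns cell identities — rows and columns of the pair
statistic matrix — over the anatomical positions and recomputes the NN
statistic, which is exchangeable under the no-topography null (measured
type-I ≈ 5%) while leaving the duplication structure intact. Note that
this Moran variant detects spatial *heterogeneity* of local similarity;
a coupling that elevates similarity uniformly is caught by the
observed-vs-random-partner comparison and the profiles instead.

**Mutual information.** Continuous pairwise MI uses the
Kraskov–Stögbauer–Grassberger kNN estimator (algorithm 1, Chebyshev
metric, k = 3, tiny jitter against ties; negative estimates clamped to 0
with the raw value kept as an attribute). An equal-frequency binned
plug-in estimator is included as an independent cross-check. On bivariate
Gaussians at n = 10,000 the estimator is unbiased to within 0.003 nats of
`−½ ln(1−ρ²)` with single-draw SD ≈ 0.012 at ρ = 0.9.

## Remapping

For cells that are place cells in both environments, the package computes
per-cell map correlations and centre-of-mass shifts for A–A′ and A–B
against 100 random-pairing controls, a rotation control (A against the
four right-angle rotations of B, reported as the rotation taking A to B),
and per-pair signed changes in field distance `Δd`. Density summaries use
the signed value, profile medians use |Δd|, and the three groups A–A′,
A–B, A–RandomA′ (A′ cell identities shuffled) are compared with the
Brown–Forsythe (median-centred Levene) variance test via `car`.
Multi-field cells contribute only their main field.

## Decoding

The Bayesian decoder alternates 0.5 s temporal bins between training and
test. Per-cell expected rates per spatial bin come from tuning maps fit on
training frames only (rates floored at 1e-3 events/s); the prior is the
training occupancy (a flat prior is available). Amplitude-summed event
"counts" enter a Poisson log-likelihood through the continuous extension
`k·log(λΔt) − λΔt` (the factorial term is argmax-invariant and dropped);
decoding is the posterior argmax bin centre, ties to the lowest
(row, col). Immobility is excluded from training and test alike. The
log-domain argmax is verified against a direct-product posterior on small
instances. Local-versus-random comparisons decode from all cells within a
radius of a reference cell against size-matched random subsets from the
same session; the similar-tuned control takes the k cells whose main
fields are closest to a random arena anchor.

## Object-vector cells

A cell is object-tuned iff it expresses a prominent new field at a
consistent object-referenced location in both object sessions. Preferred
vectors are extracted from the baseline-subtracted *spatial* maps
(object-session rate − baseline rate, floored at zero; peak refined to the
rate-weighted centroid of bins ≥ 60% of peak within 10 cm) and then
expressed as (distance, angle) from the object. Two considerations drove
this choice over reading the (distance × angle) map peak directly: the
subtraction cancels pre-existing place fields, which otherwise capture the
argmax — it is the map-level form of the "new field" requirement — and the
arena-space extraction avoids the polar grid's distortions (tiny
near-object bins, angular over-smoothing far out). The polar
`ObjectTuningMap` remains the descriptive map type and the fallback route
when no baseline session exists.

Consistency requires the two session vectors to agree: distance within 10
cm and angle within 45°, or Cartesian endpoints within 10 cm — the latter
generalizes the inclusion of cells firing *at* the object, where direction
is undefined and small positional noise subtends large angles. Novelty
additionally requires the baseline spatial rate at the implied arena
locations to stay below 50% of the object-session rate there, and the
subtracted peak must exceed 0.12 events/s. On synthetic protocols with 10%
injected object cells these defaults recover over 90% of true cells with
under 1% false positives. Circular uniformity of preferred angles is
tested with the Rayleigh statistic `Z = n·R̄²` and its standard series
p-value approximation.

## Calibration, problem sizes, and limitations

The package ships a calibration harness (`calibration_suite()`) that runs
many synthetic sessions through the binned Moran test and the
expanding-circle profile. Calibration sessions use the *noiseless expected
tuning maps* of the generative model rather than simulated event trains:
under the no-topography null the spatial arrangement of map similarities —
the only thing the battery tests — is identical in distribution either
way, and the analytic maps make 500-session replication practical. Event-
level realism is exercised separately (classification, decoding, remapping
and object analyses all run on simulated events). The suite's standard
problem sizes are 500 null sessions and 100 strongly coupled sessions of
300 place cells each, with 500 Moran permutations, 2,000 bootstrap
resamples and 200 size-matched iterations per session; at these sizes the
measured null rejection rate is 5.0% and joint detection under strong
coupling exceeds 90%.

What passing these suites shows is that the statistics are calibrated and
powered *under the generative model*. Real data differ in ways the model
deliberately omits: neuropil contamination and imperfect source
separation (approximated only by the 15 µm exclusion), non-Poisson burst
dynamics, behavioural inhomogeneity of coverage, drift across a session,
and imaging artifacts. A null result on real data is therefore evidence
against topography only insofar as those omissions do not mask it; the
power analysis quantifies sensitivity to the patch alternative, not to
every conceivable form of clustering.

Numerical conventions collected in one place: ties in field detection
break by area then lowest (row, col); the decoder breaks posterior ties by
lowest (row, col); nearest-neighbour ties break by lowest cell index;
profile circles are closed (boundary included); all resampling takes
explicit seeds, and session-level seeds derive from a master seed by a
stable arithmetic hash (`derive_seed()`).
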