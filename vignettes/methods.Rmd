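---
title: "Detecting and validating transient calcium-signaling communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating transient calcium-signaling communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell populations that communicate through gap junctions — the motivating
system is the blood-progenitor pool of the *Drosophila* larval lymph gland,
imaged live with the Ca²⁺ indicator GCaMP6f — exchange information locally:
a Ca²⁺ transient in one cell can trigger transients in its neighbors within
about two cell diameters. `cacomm` turns per-cell fluorescence traces plus
static 2-D centroids into four kinds of statements:

1. **Transient communities** (collective events): groups of ≥ 3 cells whose
   activations co-occur within 14 µm and ≤ 15 s of one another.
2. **Spatial significance**: whether the observed number of communities
   depends on where the cells actually are, assessed by a position-shuffle
   permutation test on the mean events per cell (MEC).
3. **Hotspots**: connected groups of cells that participate in communities
   far more often than the population, validated by an activity-matched
   trace-swap bootstrap that separates *recurrence due to coupling* from
   *recurrence due to being more active*.
4. **Hotspot–environment flow**: how often hotspot communities involve
   outside cells, who initiates them, and the speed at which activation
   propagates between neighbors.

All four stages run from `analyze_recording()`; `run_study()` repeats them
over a manifest and adds condition-level comparisons (Fisher's exact test on
counts of spatially significant recordings; Kruskal–Wallis on magnitudes,
speeds and rates — both chosen for small, unbalanced, non-normal samples).

## From fluorescence to activity

Each cell's raw trace F is min–max normalized, F' = (F − Fmin)/(Fmax −
Fmin), making thresholds comparable across cells with different indicator
expression. A constant trace cannot be scaled: it is set to zero, flagged,
excluded from spike calling, but kept in the roster — it still occupies
space, counts for local density, and participates in shuffles.

Binarization is a two-stage running-median scheme with four tunables:

| parameter | default | role |
|---|---|---|
| `smooth_k` | 3 frames | short median that removes single-frame noise |
| `bias_k` | 25 frames | long median estimating the slow baseline |
| `bin_thr` | 0.4 | frame-level activity threshold after rescaling |
| `peak_thr` | 0.3 | minimum peak for a candidate run to survive |

The smoothed trace minus its long-median baseline, clipped at zero and
rescaled by its own maximum, is compared against `bin_thr`; maximal
above-threshold runs are the cell's activations and their first frames its
onsets. Running-median windows must be odd (even values are bumped up,
over-long windows truncated, with warnings). R's Tukey end-rule for
`runmed` means a monotone drift leaves an exactly zero residual, so slow
trends produce no spurious activations.

Two consequences of the *per-cell* rescaling are worth knowing. First, a
cell that never spikes has only noise to rescale, so its noise spans [0, 1]
and can cross `bin_thr`: silent-but-noisy cells produce spurious short
runs. The motivating recordings select ROIs on visible GCaMP activity, so
every analyzed cell spikes; for other data a minimum-amplitude pre-filter
is advisable. Second, two true spikes closer together than the indicator
decay merge into one run and cannot be counted twice; onset counts are
counts of resolvable transients, not of underlying firing events.

## Linking activations into communities

Two activations belong to the same community when their cells lie within
`eps` = 14 µm (about two cell diameters) and their timing differs by at
most `max_lag` = 15 s, converted to frames as `ceiling(max_lag /
frame_interval)`. Per frame, co-active cells within `eps` cluster by
single linkage; a cluster joins any community with a member active during
the preceding lag window within `eps`, clusters bridging several
communities merge them, and a community closes after a full lag window of
silence. Events with fewer than `min_total_event_size` = 3 distinct
participants, or shorter than `min_duration` = 1 frame, are discarded.
`min_cluster_size` = 1 allows communities that grow by one cell per frame.

`detect_events()` implements this as a single online sweep over
activation-run starts with union–find merging. Because the spatiotemporal
relation is symmetric, the result equals the connected components of the
graph whose nodes are (cell, activation run) pairs and whose edges join
runs within `eps` and `max_lag` — `brute_force_events()` builds exactly
that graph by exhaustive pairwise enumeration and serves as the
independent oracle; the suite asserts exact equivalence (participants and
per-frame membership) on hundreds of random instances.

Per-event propagation speed is the mean of distance/|Δt| over participant
pairs within `eps` whose first activations fall on different frames;
simultaneous pairs are excluded and an event with no sequential adjacent
pair has speed 0 by convention. All sequential adjacent pairs are used,
not only consecutive ones — with events of 3–8 cells the difference is
small, and the choice is symmetric with the transmission-direction
statistic. When speeds are pooled across recordings, only recordings with
frame intervals in 2.32–4 s enter, to avoid confounding by temporal
resolution.

## The spatial-shuffle test

Stochastic coincidence and local density gradients can both produce
apparent communities. The shuffle test quantifies how much of the observed
MEC depends on the actual trace-to-position assignment: each permutation
reassigns traces to positions uniformly at random, re-detects events, and
records the permuted MEC. The p-value is the fraction of permutations with
MEC ≥ observed (ties count as extreme), and the magnitude is observed MEC
divided by the mean permuted MEC — 1 means no spatial structure.
Binarization is strictly per cell, so permuting binarized rows equals
re-binarizing permuted traces; the implementation exploits this for speed
and the suite asserts the commutation. Under an uncoupled homogeneous
null the observed assignment is exchangeable with the permuted ones, so
the test is calibrated by construction; the acceptance suite measures the
realized type-I error over 200 synthetic null recordings and checks the
mean magnitude is within 0.05 of 1.

## Hotspots and the trace-swap bootstrap

Participation counts (distinct events per cell) define hotspot candidates:
cells with counts ≥ max(5, LGmax/2) — LGmax being the recording's maximal
count, the threshold kept as a real number — are marked, and connected
components of marked cells in the 14 µm neighborhood graph with ≥ 3
members become candidates with their convex hulls. The same `eps` as event
detection is used for the neighborhood graph (configurable); a 1–2 cell
component is not a community, hence the minimum of 3.

High counts could simply reflect more active cells in a dense spot. The
bootstrap controls exactly that: each iteration matches hotspot cells —
uniformly at random, without replacement — to non-hotspot cells with *at
least as many* activations, is valid when ≥ 50% of members are matched,
swaps the traces of matched pairs, re-detects events, and records the MEC
over the hotspot member positions. With at least 100 valid iterations, a
candidate is validated when the fraction of iterations reaching the
observed hotspot MEC is ≤ 0.05; fewer than 100 valid iterations give
`insufficient_data`. Because matched partners are at least as active as
the members they replace, the permuted MEC is, if anything, biased upward
— the test errs conservative. The suite verifies both directions:
coupling-driven planted hotspots are validated with power ≥ 0.8, and
pseudo-hotspots planted through elevated firing alone are rejected at the
nominal rate.

Hotspot–environment statistics all operate on "hotspot communities"
(events containing ≥ 1 member): the interaction probability is the
fraction also containing an outside cell; the initiation fraction is the
share of mixed communities whose first frame contains only member cells
(first frames mixing both are ambiguous and excluded); the transmission
probability is the fraction of member/non-member pairs within `eps` and
with distinct activation frames where the member fired first; and the
expected initiator probability — the reference point for the initiation
fraction under random activation order — is the mean proportion of member
cells across hotspot communities.

## The synthetic-data generator

`simulate_recording()` produces recordings with known ground truth: cells
placed uniformly, clustered (Thomas process) or manually; per-cell Poisson
source spikes; each spike propagating independently to neighbors within
the coupling radius with per-link probability `p_t` after a delay of
distance/speed with ±20% uniform jitter; a no-reactivation guard bounding
each cascade; and fluorescence rendered as baseline + Gaussian noise + a
sum of instant-rise exponential-decay kernels, capped at a saturation
level. Defaults are chosen to emulate the motivating recordings: 50 cells
in 150 × 150 µm, 3 s frames, 7.5 min, baseline 100 ± 5 with spike
amplitude 50 (SNR 10), λ = 1 spike/min, coupling radius 14 µm, speed
1.6 µm/s.

Three rendering choices deserve justification:

* **Kernel decay τ = 8 s.** At 2.3–6.7 s frame intervals a much faster
  kernel would decay between samples and make spikes undetectable by
  construction; the system's transients persist over tens of seconds
  (communities live ~25 s), and τ = 8 s yields 2–4-frame activations.
* **Saturation at 1× amplitude.** GCaMP-class indicators saturate;
  unbounded kernel summation would let overlapping transients inflate a
  cell's fluorescence range 1.5–2×, pushing its ordinary spikes below the
  relative binarization threshold. The cap keeps every resolvable spike
  near full scale.
* **Rate heterogeneity and pacing as options.** `rate_cv` draws per-cell
  source rates from a Gamma distribution (real populations are
  heterogeneous; the default 0 keeps the calibration null homogeneous),
  and a hotspot's `renewal_shape` replaces Poisson sourcing with a
  Gamma-renewal process — regular, pacemaker-like recurrence, the
  behavior hotspots are hypothesized to exhibit. Both default to the
  plain Poisson model.

The planted-hotspot semantics: a region multiplies the source rate of the
cells inside it (`rate_mult`) and the transmission probability of links
whose *both* endpoints are inside (`pt_mult`) — coupling strength is a
property of the cell–cell interface, so a hotspot is a patch of enhanced
mutual coupling, not a beacon that broadcasts further.

Canonical presets freeze the study conditions used by the test suite:
`null_config()` (uncoupled, unstructured; type-I error and magnitude
calibration), `chain_config()` (12 cells in a 10 µm-spaced line, `p_t` =
1, 2.5 s frames; speed recovery), `strong_coupling_config()` (one
six-cell hotspot with near-certain intra-links, paced at 0.9 cascades/min
total over 12.5 min in a CV-0.8 background) and `confounded_config()`
(the same disc at 1.6× firing with no coupling). The strong-coupling
preset is deliberately tuned so the planted effect is unambiguous: sources
are paced (shape 6) so successive community activations stay separated
instead of fusing through the 15 s linking lag, and member activation
counts stay inside the background distribution so activity-matched
partners exist. Under these conditions the suite requires Jaccard ≥ 0.5
recovery and ≥ 0.8 validation power.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis relies on — baseline
noise, transient kernels, distance-limited probabilistic propagation with
realistic delays, localized recurrence, rate heterogeneity, an uncoupled
high-activity mode — but not photobleaching, focal drift, segmentation
errors, z-projection crosstalk between overlapping cells, or biophysical
Ca²⁺ dynamics (IP₃, store depletion, refractoriness beyond the per-cascade
guard). Passing tests therefore certify the *inference machinery* under
the model's assumptions, not performance on any particular microscope's
artifacts.

## Numerical choices and degenerate inputs

* Time-based `max_lag` converts to frames by `ceiling`, so 15 s at 3
  s/frame is 5 frames; frame-based windows (`smooth_k`, `bias_k`,
  `min_duration`) stay in frames.
* Close/far pair classification uses close ≤ 14 µm < far, resolving the
  boundary double-count in favor of "close".
* Permutation p-values count ties as extreme; magnitudes with a zero
  permuted mean report `Inf` (flagged) and 1 when observed and permuted
  are both zero.
* Pearson p-values use the t approximation on full-length traces with no
  autocorrelation correction, and the pair table is not multiplicity
  corrected — both deliberate matches to the analysis the pipeline
  replicates, and both documented limitations.
* Zero-variance traces make Pearson r undefined: flagged `NA`, excluded.
* Event merging keeps the union of memberships; event ids are assigned by
  start frame after detection, so no ordering artifact survives.
* `validate_hotspot` matching randomizes order each iteration; duplicate
  matchings are allowed (iterations are exchangeable draws).

## Problem sizes in the test suite

The suites run at sizes chosen to estimate each property with useful
precision while staying lightweight: 200 null recordings × 200
permutations for the type-I/magnitude calibration, 200 random instances
for oracle equivalence, 10 strong-coupling and 20 confounded simulations
for the bootstrap's power and specificity, and 10 chain simulations for
speed recovery. `scripts/acceptance.R` re-runs the null calibration from
scratch at the same size.

## Known limitations

* The per-cell relative threshold misbehaves on cells that never spike
  (see above); a pre-filter on raw dynamic range is advisable for
  unsupervised ROI sets.
* The swap bootstrap's conservativeness rests on partners being at least
  as active as members. When a candidate's members are far more active
  than every potential partner the test returns `insufficient_data`
  rather than guessing; and because candidates are selected as upper
  tails of chance co-activation, validation of candidates whose members
  sit exactly at the population's activity ceiling can lose its
  conservative margin — the confounded preset measures this regime.
* Coordinates are static 2-D projections; drift and z-motion are assumed
  corrected upstream.
* The transmission probability is sensitive to density asymmetry, not only
  to rate or coupling asymmetry: a patch of cells denser than its
  surroundings amplifies cascades internally and exits them through many
  links, so mixed communities tend to start inside it and the statistic
  rises above 0.5 even with homogeneous rates and coupling. Values near
  0.5 for a real hotspot therefore indicate no *net* directional bias
  beyond geometry; comparisons across hotspots of similar density are the
  safer use.
* MEC treats all events equally regardless of size or duration.
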