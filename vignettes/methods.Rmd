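---
title: "Models and methods behind hippocampr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hippocampr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hippocampr analyses population calcium imaging from dorsal CA1 recorded
across an item-place learning design: a habituation session (`HA`) without
objects, two object sessions with a fixed configuration (`S1`, `S2`), and a
recall session (`S3`) in which one object is displaced. This vignette
documents the models, the parameters that matter, the numerical conventions,
and the design decisions that were genuinely open — in enough detail that a
reader could re-derive every number the package produces.

## Coordinate frame and binning

The arena (default 40 × 40 cm) has its origin at the lower-left corner, x
rightwards, y upwards, in cm. The spatial grid (default 10 × 10, so ~4 cm
bins) assigns a point to bin `(i, j)` when it falls in the half-open square
`[(i−1)w, iw) × [(j−1)h, jh)`; the far arena edges are closed so that every
in-arena point, including one exactly on the top or right wall, belongs to
exactly one bin. This removes any ambiguity at bin boundaries.

## Behavioural scoring

Only a single tracked point per sample is modelled. A sample "explores"
object k when it lies within `object_radius_cm` (default 2 cm) of the
object's position; each sample contributes the interval to the next sample
as dwell time (the final sample contributes the median interval).
"Total exploration time" is read as total tracked session time by default;
`exclude_immobile = TRUE` offers the alternative reading that discounts
samples slower than a speed cutoff (default 2 cm/s), since the convention is
not fixed in the field. Posture-dependent exclusions (climbing, sitting on
the object) cannot be expressed with point tracking and are out of scope.
The discrimination index `(t_d − t_s)/(t_d + t_s)` is the standard
difference-over-sum form bounded in [−1, 1]; it is undefined (NA, with a
warning) when both times are zero.

## Ensembles and reactivation

The longitudinal registration map (habituation as reference) is consumed,
not computed. A cell is *active* in a session when it appears in that
session's registration column and — when event counts are supplied — has at
least `min_events` (default 1) events. Session ensemble sizes are expressed
as a percentage of the habituation count (which may exceed 100);
reactivation between sessions is `100·|A∩B|/|A|` with the *earlier* session
as denominator, computed for the successive pairs HA→S1, S1→S2, S2→S3.

## Population bursts

Each cell's ΔF/F trace is z-scored, traces are averaged per frame across
cells, and the population mean is z-scored again. Zero-variance traces carry
no signal and are dropped with a warning before averaging. Bursts are
maximal runs of frames with population z *strictly above* `z_threshold`
(default 2; "exceeding" is read as strict), discarded when shorter than
`min_duration_s` (default 0.05 s). Conventions: a run of `n` frames at rate
`fps` has onset at its first frame time and duration `n/fps`, so a 1.0 s
square pulse at 20 fps yields exactly 1.0 s; burst *magnitude* is the mean z
over the run (the peak z is reported separately). No splitting of prolonged
detections into sub-bursts is attempted, since no principled rule exists for
calcium signals at this bandwidth. Speed analyses interpolate the tracked
speed onto the imaging frame clock; the activity–speed relation uses
Spearman correlation, and burst-triggered speed profiles average speed in a
±2.5 s or ±5 s window around burst peaks (bursts whose window leaves the
session are skipped), with a contrast defined as speed at the peak bin minus
the mean of the two window-edge bins.

## Rate maps and place-cell-like classification

Positions are averaged within 0.5 s windows; each event is assigned to the
spatial bin of its window. Occupancy per bin is 0.5 s times the number of
windows; total occupancy therefore reconstructs the session duration to
within one window. Events falling in windows without tracking samples are
dropped with a warning.

Skaggs information, `I = Σᵢ pᵢ (λᵢ/λ̄) log₂(λᵢ/λ̄)` bits/event, is computed
on the **raw** (unsmoothed) map: this keeps the analytic identities exact —
a cell firing only in 1 of k equally occupied bins carries exactly log₂(k)
bits/event, and uniform firing carries 0 — and avoids the smoothing kernel
leaking information across bins before the shuffle test. The smoothed path
is available via `use_smoothed = TRUE`.

Significance uses a circular shuffle: the entire event train is rotated by
a random offset modulo the session duration while the behavioural record
stays fixed, and the information is recomputed (default 500 times). Offsets
are drawn uniformly from `[min_shift_s, T − min_shift_s]` with
`min_shift_s = 10` s, so no shuffle is a near-identity rotation (the value
is a convention; any choice well above the temporal autocorrelation of
behaviour works). The empirical p is the proportion of shuffled scores that
equal or exceed the observed score. A cell is place-cell-like only if
`p < 0.05` (strict) *and* it fired ≥ 20 events; cells below the event
criterion skip the shuffle test entirely since they can never classify.
This two-part criterion controls both chance-level information and
undersampled maps. Under the null (events independent of position) the
realized significant fraction at α = 0.05 concentrates near 0.05 with
binomial noise — with 200 cells its standard deviation is ~0.015, a scale
worth remembering when reading small-sample false-positive fractions.

Rate-map smoothing convolves *both* the event histogram and the occupancy
histogram with an isotropic Gaussian ("width 1" is read as σ = 1 bin,
truncated at 3σ) and takes their ratio; edge bins are thereby implicitly
renormalised, and a constant map is exactly preserved. Fields are the
4-connected components of bins at or above 20 % of the peak smoothed rate
(threshold inclusive; 4-connectivity is the conservative choice for field
separation — both were open conventions), with occupancy-unweighted
centroids and size = bin count × bin area (16 cm² per bin at defaults).
Spatial coherence correlates each visited bin's raw rate with the box-car
mean of its visited 3 × 3 neighbours (centre excluded, a classic
construction; the kernel size was unstated), then applies Fisher's
z-transform, clipped at `atanh(1 − 10⁻¹²)` to stay finite; a constant map
raises an error rather than returning an arbitrary value. Object scores
intersect the pooled field bins of a cell with a mask extending 2 bins
beyond each object's centroid bin in every direction (5 × 5 per object,
clipped at walls); pooling across a cell's fields is the default, a
per-field mean is available (the aggregation for multi-field cells was an
open choice).

## Functional networks

Edges come from pairwise Spearman correlations between full-rate ΔF/F
traces (no down-sampling). P-values use the large-sample t approximation on
rank-transformed traces, which is the regime these sessions live in
(≥ thousands of frames); Bonferroni adjustment by the number of tested pairs
is applied, and edges require adjusted `p < 0.001` *and* `r > 0`. Applying
the threshold to adjusted rather than raw p-values is the stricter of the
two possible readings and is the default (`correction = "none"` gives the
other). Constant traces remain as nodes but form no edges.

Centralities are those a weighted-graph analysis in igraph would produce:
degree = edge count / (n − 1); the Barrat weighted local clustering
coefficient (nodes with fewer than two neighbours score 0); and closeness =
1 / mean shortest-path distance to the other nodes *of the node's connected
component*, with edge length 1/r so stronger correlation means closer
(`distance = "one_minus"` gives the 1 − r alternative). Closeness on a
disconnected graph is undefined in general; the component-wise rule with
isolated nodes scoring 0 is this package's convention. Session-level means
are expressed as a percentage of the habituation session; a zero or missing
baseline is an error by default and NA in the pipeline.

## Statistics

Cellular metrics are analysed at the cell level; animal-level metrics
(bursts, centralities, reactivation) aggregate per animal first. The
within-group family is Friedman (paired complete designs, detected
automatically) or Kruskal–Wallis, followed by paired signed-rank or
rank-sum Wilcoxon tests with Holm adjustment; between-group comparisons are
two-sided Mann–Whitney U. Exactness of Wilcoxon p-values follows
`stats::wilcox.test`'s standard rule (exact for small tie-free samples,
normal approximation with tie correction otherwise). Fully tied data make
rank statistics 0/0; the degenerate outcome is reported explicitly as
statistic 0, p = 1.

## The synthetic-data generator

`simulate_study()` emulates the study design — four sessions at 20 fps,
600 s, a 40 × 40 cm arena with two objects from S1 on and one object
displaced in S3 — for one animal at a time, with all ground truth returned:

- **Trajectory**: velocity follows a mean-reverting (OU) process (τ = 1 s,
  per-axis sd 4.8 cm/s, i.e. mean speed ~6 cm/s — a plausible mouse
  open-field regime), integrated and reflected at walls.
- **Events**: inhomogeneous Poisson per cell. Base rates are log-normal
  around 0.1 Hz (typical deconvolved calcium event rates). Place-tuned
  cells multiply the base rate by a Gaussian spatial gain
  `peak_gain·exp(−d²/2w²)` (defaults: gain 6, width 5 cm), so firing
  concentrates in the field and decays to near zero away from it, as real
  place fields do. Object-tuned cells are place-tuned on an object location
  with a session-dependent gain factor (rising into S3 under the
  vehicle-like preset; flat under the antagonist-like one) and are untuned
  during the object-free habituation.
- **Bursts**: planted at times ≥ 10 s apart, default 0.3 s duration, gain 8
  applied to a 70 % participant subset.
- **Correlated blocks**: a shared slow log-normal latent modulation
  (AR(1), τ = 2 s, σ = 0.8) multiplies the rate of block members.
- **Traces**: per-frame event counts convolved with a
  difference-of-exponentials calcium kernel (rise 0.05 s, decay 0.6 s —
  approximating fast GCaMP indicators; configurable since no single kernel
  is canonical) plus white Gaussian noise (sd 0.15).
- **Ensemble dynamics**: every registered cell is active in the reference
  session; later membership follows directional Bernoulli overlap (fraction
  of the earlier session's active set re-active later). The vehicle-like
  preset uses 0.75 / 0.80 / 0.40 for HA→S1 / S1→S2 / S2→S3 with 10 %
  recruitment of inactive cells; the antagonist-like preset lowers
  reactivation (0.60 / 0.50 / 0.35), halves burst count and gain, and
  flattens object tuning.

What the generator does *not* emulate: biophysical calcium dynamics,
imaging/photon noise, motion artefacts, cell-extraction errors, spatial
footprint overlap, theta-timescale spike organisation, or behavioural
states beyond a homogeneous random walk. Tests passing on synthetic data
therefore demonstrate the *algorithmic* correctness and statistical
calibration of every stage under the planted generative model — not
robustness to the full noise structure of real miniscope recordings.

## Numerical conventions and degenerate inputs

- Events exactly at the session end clamp into the last temporal window.
- The Fisher transform is clipped to `±atanh(1 − 10⁻¹²)`.
- Spearman p-values for |r| = 1 are reported as 0.
- Empty burst lists yield count 0 with NA means; empty field sets and
  both-zero discrimination times are errors/NA with warnings, never silent
  zeros.
- All seeds are integers below 2³¹; every stochastic function takes an
  explicit seed and the pipeline derives per-cell shuffle seeds
  deterministically from the configuration seed, so reruns are
  byte-identical.

## Verification scale

The test-suite fixtures are sized for a desk machine: null-calibration runs
use 200 simulated cells at 500 shuffles and 100 noise networks of 50 cells ×
12,000 frames; recovery runs use 100 cells over a 600 s session; oracle
comparisons use 500 random graphs of ≤ 6 nodes and 1,000 random rate maps;
the end-to-end determinism check uses a 30-cell, 120 s study. These sizes
were chosen so the full suite exercises every claim in minutes while
keeping the statistical bands meaningful at their stated n.

## Known limitations

- Single tracked body point; no head-direction or nose-contact refinement
  of object exploration.
- The pipeline processes one animal per study tree; cohort-level statistics
  operate on tidy metric tables combined by the caller.
- No position decoding, remapping correlations across sessions, community
  detection, or small-world statistics — deliberately out of scope.
- The registration map is trusted as given; registration errors propagate
  directly into reactivation estimates.
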