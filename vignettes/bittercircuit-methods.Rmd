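---
title: "Models and methods behind BitterCircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind BitterCircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BitterCircuit)
```

BitterCircuit quantifies how bitter-taste activation shapes fly behavior
and how that information propagates through downstream synaptic circuitry.
This vignette explains the models each stage implements, the parameters
that matter, what the built-in simulators do and do not emulate, and the
numerical conventions chosen where the underlying procedures leave room.

## Locomotor and preference quantification

Tracked arena trials arrive as per-frame tables (position in mm,
arena-centred; forward velocity in mm/s; angular velocity in deg/s) at a
nominal 30 frames/s. All analyses treat the *trial* as the statistical
unit: flies are averaged within a trial before any window statistics, so
downstream tests operate on per-trial values.

Window conventions, all configurable but defaulted to the standard assay
design:

- kinematic traces are averaged in 0.33 s bins (10 frames); a trailing
  partial bin is dropped, and bin width 1 is the identity;
- the onset response is the mean velocity over the first 1 s of light
  minus the baseline mean over the 4 s preceding onset;
- the offset response is the mean forward velocity over the 5 s after
  light offset minus the same pre-onset baseline;
- the preference index is computed in 1 s bins from the fly counts in the
  positive-role quadrants, sampling each fly's position at the bin
  midpoint frame, and an epoch is summarized by the mean of its last five
  bins ("final PI").

Choices the assay description leaves open, fixed here: quadrants partition
the arena by coordinate signs with boundary points assigned to the
lower-indexed quadrant (a measure-zero set, so the PI is insensitive);
bin occupancy uses the midpoint frame rather than a majority vote; frames
with lost tracks are excluded from window means, and a window with more
than 50% missing frames raises a quality error rather than returning a
silently unstable mean.

Learned preference is measured over exactly two test epochs whose CS+
quadrant assignments are swapped; the reported value is the mean of the
two final PIs. For any fly whose occupancy is time-invariant and
odor-independent the two tests contribute equal and opposite counts, so a
pure spatial bias cancels identically — this is an algebraic property of
the counterbalanced design, and the suite asserts it exactly.

## Feeding microstructure

Interaction intervals from a two-channel closed-loop feeding assay are
segmented hierarchically: every interval is a sip (after discarding
contacts shorter than 30 ms as sensor noise); consecutive sips whose gap
is at most `intra_burst_gap` share a burst; sips whose gap is at most
`inter_bout_gap` share a bout. The default thresholds (0.5 s and 2 s) are
package defaults exposed for configuration — the assay's published
analyses take their values from dedicated methods work, so these defaults
should not be read as canonical. Segmentation sorts the interactions
first, making it independent of input order, and is monotone: raising
either threshold can only merge, never split, bursts or bouts. Sips are
nested in bursts and bursts in bouts by construction; bout durations
include their internal gaps, so duration sums are not ordered across
levels and the package asserts the interval-nesting property instead.

Closed-loop light epochs are reconstructed as 1.5 s windows from each
interaction onset on the stimulated channel, merged when overlapping and
truncated at session end. Summaries are computed per channel up to a
horizon (default 1 hr), with sips straddling the horizon truncated; when
both a control and a stimulated channel are named, the control-minus-opto
difference of each feeding parameter is reported, and a named channel
with no surviving sips contributes an all-zero row so full suppression
yields a defined difference.

The PER suppression index is `1 - with/without`; a zero baseline makes it
undefined and returns `NA` rather than raising, since zero-PER conditions
occur in real screens.

## Calcium response metrics

ΔF/F uses the mean of the 20 frames preceding stimulus onset as the
baseline B: `(f - B) / B`. Construction guarantees a zero baseline-window
mean and invariance to gain changes of the raw fluorescence. Traces with
fewer than 20 pre-stimulus frames or a non-positive baseline are rejected.

ON amplitude is the peak ΔF/F in the stimulus window (default 5 s); OFF
amplitude is the post-offset peak (5 s window) *referenced to the ΔF/F
level at offset* and floored at zero, so a sustained ON plateau does not
masquerade as an OFF transient. Peaks are taken on a 3-frame moving
average to suppress single-frame noise; the offset reference is the mean
of the three raw frames ending at offset. These window lengths and the
smoothed-peak statistic are this package's choices — trace shapes, not
peak formulas, are what the source experiments report.

Habituation profiles normalize each component to trial 1 and report the
final-to-first ratio; a zero first-trial amplitude yields `NA` for that
component. Both trial-level metrics and any fly-level averaging are left
to the caller, since either unit can be appropriate.

## Effect-strength classification

For each behavior and experimental genotype the pipeline runs a one-way
ANOVA over all genotype-by-intensity cells (experimental plus both
controls) as the gate — mirroring the question "is there an effect at any
light intensity". The factor structure (one ANOVA over all cells) is the
default; per-intensity gating can be assembled from the same primitives.
Fully degenerate data (zero variance everywhere) returns p = 1 by
convention. Dunnett's many-to-one comparisons share the pooled error term
across all groups and compute two-sided family-wise adjusted p-values
from the multivariate-t distribution of the maximum statistic
(`mvtnorm::pmvt` with the standard shared-control correlation structure);
with a single control this reduces exactly to a pooled t-test. Adjusted
p-values are never smaller than raw ones.

The effect size is the smaller of the two mean differences against the
controls, signed by their common direction; when the controls straddle
the experimental mean the effect is zero (consistent directions are an
assumption of this screen design). The maximal effect over intensities is
normalized by the reference genotype's maximal effect, making the
classification invariant to common rescaling, and classified with
α = 0.05: gate failure ⇒ none; ≥ 0.8 ⇒ strong; ≥ 0.4 ⇒ moderate;
otherwise weak. Thresholds are inclusive ("at least 80% or 40%").

## Connectome tracing

The circuit container is a directed graph with positive integer synapse
weights, at most one edge per ordered pair (duplicates are aggregated on
construction), and per-cell annotations: cell type, optional seed-subtype
label, output regions (tokens like `SMP`, with `(C)` marking the
contralateral hemisphere), and optional total input-synapse counts.

Layer expansion admits a cell if it receives **at least `edge_min`
synapses from at least one** source cell (default 3) — a per-edge rule,
not a population sum. A member's reported total then sums its qualifying
edges only; whether sub-threshold edges from additional source cells
should count is genuinely ambiguous in printed summaries, so
`include_subthreshold_in_total` exposes both conventions (default
`FALSE`). Source cells admitted by lateral or feedback edges are retained
and flagged rather than dropped, since lateral connectivity within the
seed population is itself a finding of interest. Top-target selection
offers the population-threshold rule (total ≥ k after excluding, e.g.,
the seeds) and top-n ranking with ties broken by ascending cell id for
determinism. Percent input is reported only when total input counts are
available — it is never estimated.

The interconnection motif matrix aggregates qualifying edges (default
≥ 5 synapses) between seed subtypes in either count or summed-weight
mode; both are provided because published connectivity diagrams are
ambiguous about which quantity their line weights encode. Region
fractions count a member once per region under the chosen laterality
rule (`ipsi_only` by default, since printed region lists mark only
contralateral targets specially). Path search enumerates simple paths
(no revisits — reported hop counts imply simple paths) from any seed to
a target cell or cell type, bounded by the number of intermediate nodes,
over edges meeting the weight threshold, ranked by weakest edge then
total weight.

The two packaged summary tables describe the mlSEZt circuit's third- and
fourth-order layers. They are transcribed from printed sources, so the
parser tolerates their typographic quirks (double and trailing commas in
region lists), and an md5 checksum test guards against transcription
drift. Cell ids exceed 32-bit integer range and are handled as strings
throughout.

## The simulators: what they emulate, and what they do not

Each simulator draws from one seeded generator per call (the caller's RNG
state is restored afterwards) and records every planted value in a ground
truth object, so recovery can be asserted rather than assumed.

**Arena** (`simulateArenaTrial`): forward velocity is baseline
(4 mm/s) plus the onset boost (4 mm/s) during light plus Gaussian noise;
angular speed likewise (baseline 20 deg/s, boost 60 deg/s). After each
light offset a Bernoulli subset of flies (probability 0.5) freezes for 30
s, velocity drawn from |N(0, 0.1·baseline)| — the freeze duration is a
configurable default because its distribution is only qualitatively
characterized ("nearly a minute"). Positions follow a biased random walk
with a drift toward (positive coefficient) or away from (negative) the
centroid of the nearest lit quadrant; the underlying assays report no
movement model, so this is the simplest process with a controllable
steady-state preference. Positions and velocity channels are generated as
separate tracker outputs: the simulator does not enforce kinematic
consistency between them, does not model fly-fly interactions, wall
following, or identity swaps, so passing recovery tests says nothing
about tracker artifacts in real data.

**Feeding** (`simulateFeedingSession`): sips within bursts within bouts,
with exponential inter-event gaps at three scales — truncated to the
disjoint ranges delimited by the segmentation thresholds ((0, 0.5),
(0.5, 2), (2, ∞) s). The truncation is an identifiability choice: it
makes the planted hierarchy exactly recoverable by segmentation, which
the suite requires; untruncated exponentials would overlap across scales
and make exact recovery impossible for any threshold. Counts per level
are shifted-Poisson (means 5 sips/burst, 3 bursts/bout); sip durations
average 0.15 s; bouts recur every ~30 s. Optogenetic suppression keeps
the first contact on the stimulated channel (the sip that first triggers
light) and thins later sips with retention probability equal to the
suppression factor (default 0.1, near-complete suppression). Real
capacitance data additionally contain positional artifacts and drift the
simulator does not model.

**Calcium** (`simulateCalciumTrials`): ON and OFF transients hold their
peak for 3 frames and decay exponentially (τ = 1.5 s), with per-trial
geometric habituation (ON factor 0.6, OFF 0.9 — ON habituates much more
strongly). The residual ON level is held flat across the frames
bracketing offset so the offset-referenced OFF measurement is exact in
the noise-free case; this is a deliberate alignment between generator and
metric, which is why the suite also checks the metrics on hand-built
traces that do not share the generator's shape. Default frame rate 6.5
frames/s matches repeated-stimulation scanning; noise is white Gaussian
at 2% of baseline, with no bleaching or motion artifacts.

**Circuit** (`simulateCircuit`): 21 seed cells in three subtypes (6/5/10),
32 planted second-layer and 30 planted third-layer cells — the scale of
the real traced circuit — plus decoy cells reachable only through
sub-threshold (weight 1–2) edges, a planted subtype motif with strong
(≥ 5) edges, and feedback edges from a fraction of layer-2 cells back
onto seeds. Planted edge weights are uniform on 5–30 so every planted
edge passes both the layer (3) and motif (5) thresholds, keeping planted
membership exactly recoverable.

## Numerical conventions and problem sizes

Interval merging treats touching intervals as one epoch; floating-point
comparisons against window boundaries use a 1e-9 tolerance. Dunnett
p-values integrate the multivariate t with absolute error 1e-5, and a
numerical guard enforces monotonicity against raw p-values. The
determinism contract is bitwise: identical parameters and seed give
identical outputs, and the pipeline runner's provenance sidecar contains
no timestamps so reruns are byte-identical.

The test suite exercises recovery with 100 simulated trials per planted
effect (12 flies per arena trial, 400 s feeding sessions), null
calibration of the gate statistics with 10,000 replicates of three groups
of ten, and brute-force oracle equivalence of every tracing operation on
200 random graphs of up to 50 nodes — sizes chosen to give tight Monte
Carlo error at interactive runtimes.

## Known limitations

Upstream processing is out of scope: video tracking, capacitance signal
extraction, image registration and ROI drawing are assumed done. The
statistics are fixed-effects throughout; nesting of trials within flies
or sets of flies is left to the caller's choice of unit. The tracing
module analyses whatever graph it is given — it does not query a live
connectome service, and the packaged tables cover only the two printed
downstream layers, not the full volume, so population-wide counts (e.g.
all third-order cells at threshold 3) require an external edge list via
the `edge_list` dialect.
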