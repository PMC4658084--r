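---
title: "Methods: echogram segmentation and fish-finder cross-calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: echogram segmentation and fish-finder cross-calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echofish)
```

## The problem

Recreational fish-finders (RFFs) display echo intensity as screen colours on
a sequential numeric scale with no dB reference, saturate dense targets
because of their narrow dynamic range, and ship with no data-processing
software. Scientific echo-sounders (SESs) provide calibrated volume
backscattering but at a cost that excludes most ecological field programmes.
`echofish` implements the processing chain that makes RFF output
quantitative: image-domain segmentation of fish schools, a colour-to-dB
mapping cross-calibrated against an SES run from the same vessel, a
regression correction for saturation, and echo-integration into
relative-abundance transects. Absolute density and biomass are explicitly
out of scope: without a calibration sphere and a known target strength the
RFF can only support *relative* comparisons.

## Data model

A frame is a matrix of colour indices (row 1 = shallowest sample, column 1 =
oldest ping) with a displayed depth range and per-column time/position.
Vertical scale is forced by the display: `metres_per_row = (depth_max -
depth_min) / rows`. The horizontal scale has no on-screen anchor, so it is
reconciled from the sidecar log: vessel speed between consecutive frame
fixes (great-circle) times the ping interval, the ping interval itself being
inferred from the unique-ping count revealed by overlap de-duplication.
Pixel-centre depth convention: row *r* sits at `depth_min + (r - 0.5) *
metres_per_row`.

Sidecar format (one CSV row per frame: file, ISO-8601 time, lat/lon, depth
range) is this package's own convention — how position and time reach the
processing stage is implementation-defined, and a one-row-per-frame log is
what a GPS-synchronised capture script naturally produces. Frames are
quantised against a declared palette by nearest-colour match (screen
captures may be RGB); a pixel further than `quantise_tol` from every palette
colour is an error rather than a silent snap.

## Seabed tracing

Everything below the seabed is spurious signal. The seabed is found in two
steps. First, upper edges: pixel `(r, c)` is marked when it reaches the edge
threshold (default: any echo) and the pixel above does not. Second, the
bottom line is the path `d(1..N)`, one row per column, maximising

    sum_i edge(d(i), i)  -  lambda * sum_i |d(i+1) - d(i)|,
    subject to |d(i+1) - d(i)| <= P

solved exactly by a Viterbi-style dynamic programme over all (row, column)
states, cost `O(R N (2P+1))`. `P = 2` bounds the seabed slope per ping;
`lambda` (default 0.5 per pixel of vertical transition) is the tunable
anti-vertical penalty — at 0 the path chases every edge, large values
straighten it. Score ties are broken toward the deeper path, then the
straighter one, so a flat seabed under a school is not traced through the
school; an all-empty edge map yields the deepest row plus a `no_evidence`
flag. The full DP is used rather than a greedy per-column scan because it
dominates it in score at negligible cost on frame-sized inputs, and it is
what makes the trace robust to gaps punched into the seabed edge by noise.
A consequence worth knowing: an echo blob *resting directly on* the seabed
line is absorbed into it (the trace rides over it); objects at least one
row above the line are left alone, which is precisely the boundary the
0.5 m altitude exclusion rule then polices.

## Noise suppression

*Speckle* is removed by a `3 x 3` median filter (symmetric-reflected
borders), implemented by counting-threshold search over the colour alphabet.
The filter clears isolated salt pixels and may smooth within-school colour
texture; it must not erode school membership — the shipped tests assert
≤ 2 % membership erosion at 1 % salt density.

*Interference columns* (a full-height saturated ping) are peaks in the
per-column echo sum. A column is cleared when its sum exceeds the median by
`z_threshold` (default 5) scale units, where the scale is the **wider** of
the MAD and the standard deviation. Pure median/MAD was the first design
here, but echogram ping sums are zero-inflated: with any speckle present the
MAD tracks the speckle floor and flags legitimate dense school pings
(observed z ≈ 17 versus interference z ≈ 42), and with no speckle the MAD is
exactly zero. Requiring a column to be extreme under both scales keeps
interference far above threshold and schools far below it in either regime.
Processing order is edges → seabed → mask → despeckle → columns; the order
between despeckling and masking is immaterial whenever the seabed margin
covers the kernel radius (a tested property), and running the column filter
last lets it operate on seabed-free sums.

## School detection and measurement

The mask is simply "colour > 0" after the steps above. Candidates are
8-connected components (echo traces step diagonally at ping boundaries);
each gets metric extents from the pixel scales. Exclusions follow the survey
protocol: top depth < 3 m (transducer nearfield), altitude above the traced
seabed < 0.5 m (bathymetric anomalies), length or height < 1 m
(non-schooling fish), mean S_v < −65 dB. Each rejection is logged with its
rule. The optional exclusion-list mechanism (clear declared rectangles
before detection) replaces an interactive review pass with a reproducible,
diffable artefact.

Candidates merge when the nearest gap between their pixel sets fits inside
the linking ellipse. The stated `10 x 2 m (L x H)` is read as *full axis
lengths*: the gap `(dx, dz)` (measured between pixel edges, in metres)
merges when `(dx/5)^2 + (dz/1)^2 <= 1`, and merging closes transitively via
union-find. Aggregates smaller than `10 x 5 m (L x H)` are discarded.
Merging is order-independent (tested by permutation).

Descriptors per school: pixel-mean depth, extreme-row depths, metric
bounding box, seabed depth (`BotDepth`) as the deepest traced seabed under
the school's column span — the variant that keeps the depth-ordering
invariants on sloped seabeds, where the seabed-at-centroid alternative can
sit above the school's deepest pixel — altitudes as seabed minus depth,
`Area` of the hole-filled mask versus `AreaLV` of the raw mask ("less
vacuoles": the names imply the raw area is the smaller, vacuole-free one),
outer perimeter by Moore boundary tracing with true diagonal step lengths
(≈ 5 % high on digitised disks, within the 8 % isoperimetric budget),
maximum Feret diameter over the convex hull of pixel corners with the
perpendicular extent and the orientation in `[0°, 180°)` from the ping
axis, and the colour histogram. Schools touching the frame edge carry a
`Truncated` flag (an internal column, not part of the CSV schema).

## Colour calibration

The mapping is affine over *retained* colours: background (index 0) never
enters any mean, and the weakest retained colour (index 1) anchors
`start_db`, so `S_v(c) = start_db + step_db (c - 1)`. School means are
always taken in the linear domain. Scenario schools are chosen by pixel
skewness `g1 = m3 / m2^{3/2}` (the moment estimator; the small-sample
adjusted variant would change nothing material at school pixel counts):
minimum, closest to zero, maximum, ties resolved by earlier survey time.
Fully saturated schools (zero colour variance) have undefined skewness and
are excluded from the ranking with a warning; if fewer than three distinct
scenario schools remain, selection fails loudly rather than silently
duplicating.

The grid search evaluates `|S_v,SES - S_v,RFF(start, step)|` over starts
−70…−60 dB (0.5 dB) × steps 0.1…2 dB (0.1 dB); the absolute difference is
used (the sign carries no information about optimality) and each scenario is
optimised separately, with the headline step reported at the −65 dB baseline
start — the same minimum the SES analysis uses, which makes the two systems'
thresholds comparable. The saturation correction is OLS of `log10(s_v,SES)`
on *linear* `s_v,RFF` (the compression is exponential in the linear
variable, so the log transform belongs on the response), with corrected
values `10^{β0 + β1 s_v,RFF}` — always positive by construction. Comparisons
use 4 dB bins anchored at −68 dB (half-open `[edge, edge+4)`), the Wilcoxon
signed-rank test (exact distribution when untied and n ≤ 50, otherwise the
tie- and continuity-corrected normal approximation), and a depth regression
of `log10(s_v)` per system as the time-varied-gain check.

## Relative abundance

Schools are assigned to 500 m elementary distance sampling units by the
along-track distance of their centroid (great-circle accumulation over the
track; off-track schools snap to the nearest along-track point with a
warning beyond 1 km). Units are half-open; a final partial unit is kept when
≥ 250 m, else merged into its neighbour — the protocol leaves the partial
convention open, so unit *counts* should never be compared across
implementations, only unit *contents*. Per unit,

    s_a = sum_i s_v,i * H_i * W_i / L,      s_A = 4 * pi * 1852^2 * s_a

with `H`, `W` the school height and width in metres and `L` the unit length
— the range interval is the height of all schools weighted by their
lengths, for schooling targets only. Binning conserves the school total
exactly (a tested invariant). Detection concordance is the 2×2
presence/absence table with a Wald test on the log odds ratio (equivalent to
a binary-predictor logistic regression) and the Haldane 0.5 correction on
zero cells. Scale dependence uses true rolling sums (stride one unit) at 18
scales 0.5, 1.5, …, 17.5 km, each divided by the scale length and
transformed `log(x + 0.1)` (the offset accommodates empty units) before the
between-system R² is computed; rolling sums are plain cumulative-sum
arithmetic.

## The synthetic world

The generator emulates the inter-calibration survey rather than arbitrary
data: 7 kn vessel speed, a 0–50 m display window at 100 rows, 2 pings/s
(1.8 m per ping column), frames of 160 pings overlapping by 10, a seabed
random walk at 32–46 m with slope within the tracer's `P`, ten schools of
15–40 m × 6–12 m at 10–24 m depth with mean S_v −52…−42 dB and 3 dB
lognormal within-school spread, 1 % salt speckle, 0.5 % interference pings,
and a 16-colour display quantising through the −65 dB / 1.3 dB mapping with
hard clipping at the top colour. Choices that need justification:

* **16 colours.** The RFF palette size is device configuration; under a
  ~1.3 dB step an 8-colour display would top out near −57 dB and every
  realistic school would collapse to a single colour, which contradicts the
  observed raw fish-finder dynamic range (medians near −48 dB with a
  compressed but nonzero spread). Sixteen steps put the ceiling near
  −45 dB, reproducing partial saturation instead of total loss.
* **Median-invariant stencils.** Planted schools are rectangles with the
  four corner pixels clipped — the shape family invariant under the 3×3
  median — so planted pixel counts remain the correct reference after
  despeckling. Real schools are not median-invariant; a green recovery test
  therefore establishes the pipeline's bookkeeping, not robustness to
  arbitrary school morphology.
* **Interference placement.** Noise columns are injected only ≥ 2 pings
  away from any school: a saturated ping inside or adjacent to a school is
  physically possible but makes the planted ground truth ill-defined (even
  a human reviewer could not apportion those pixels), so it is excluded
  from the stated world rather than scored arbitrarily.
* **Matched-pair modes.** The *physical* mode draws per-pixel S_v normally
  in dB around a school mean in −54…−31 dB, gives the SES the exact linear
  mean and the RFF the quantised, ceiling-clipped histogram — this
  reproduces saturation and yields depth agreement near R² ≈ 0.99 and
  log-area agreement near 0.74 under the default noise, i.e. the regime the
  method targets. The *truth* mode inverts a prescribed correction relation
  and mixes two adjacent colours so the histogram mean equals the intended
  `s_v,RFF` exactly, enabling 5 %-level parameter-recovery tests that the
  physical mode (whose "true" coefficients are emergent) cannot support.
* **Spatial structure.** The rolling-scale property (R² growing with
  scale) is tested on an AR(1) log-density field with independent
  per-system detection dropout: with an i.i.d. school field the property is
  mathematically absent — window sums of i.i.d. pairs correlate no better
  than the units — so patchiness at survey scale is part of the stated
  world, as it is in any real bay transect.

## Numerical choices and degenerate inputs

Score ties in the tracer are compared with exact floating-point equality;
the shipped tests use dyadic `lambda` values so DP and the exhaustive oracle
agree bit-for-bit. Overlap detection demands exact column equality (screen
shifts are pixel-aligned; a lossy capture chain would need a tolerance and
would first break the palette quantisation anyway). An empty school list
writes a header-only CSV; an empty histogram makes the mean S_v an error at
the calibration surface but merely a `-Inf` (hence an S_v-threshold
rejection) inside candidate filtering. `apply_correction` output is
mathematically positive; extreme inputs can still underflow to zero in
double precision. EDSU boundaries are half-open, so a school exactly on a
boundary belongs to the later unit.

## Known limitations

The linking-ellipse gap is measured between axis-aligned pixel-edge
distances, a rasterised approximation of true Euclidean clearance. The
perimeter estimator inherits chain-code bias (up to ~5 % on smooth shapes).
Column georeferencing assumes piecewise-linear vessel motion between frame
fixes. The pixel histograms of extracted schools are taken after
despeckling, so heavy speckle inside a school biases its colour histogram
slightly toward the local median. None of the supplied tests exercise real
device captures; palette tables for specific devices are user
configuration.
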