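---
title: "Quantifying corneal nerve degeneration and epithelial integrity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying corneal nerve degeneration and epithelial integrity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneametrics)
```

## The measurement problem

The corneal sub-basal nerve plexus converges centripetally into a central
swirl of thin βIII-tubulin–positive fibers, which turn anteriorly and end as
punctate terminals between apical epithelial cells. Desiccation stress (as in
dry eye disease) degrades this bed: fibers fragment, terminals drop out,
coverage shrinks, and the overlying epithelium loses its regular pattern of
DAPI-bright nuclei. `corneametrics` turns whole-mount confocal stacks and
simple physiology records into numbers that track this process:

1. a **tiled standard-deviation z-projection** that flattens the curved
   cornea into separate sub-basal and epithelial-terminal binary images;
2. a **flood-fill fragmentation index** (fragments per unit nerve coverage);
3. **first-derivative statistics of DAPI intensity line profiles**
   (transition delta, AUC, AUC per transition) as epithelial-integrity
   readouts;
4. **tear-wick and blink-threshold endpoints** with a normality-gated group
   comparison;
5. **synthetic generators** with planted ground truth for all of the above.

## Tiled projection of a curved stack

Because the flattened cornea is curved, one 800 × 800 px field holds
sub-basal fibers and epithelial terminals at z-planes that drift across the
image. The stack is split into a 3 × 3 grid (`tile_grid()`; tile edges differ
by at most 1 px, larger tiles first, row-major order, 1-based closed
rectangles as in the Bioconductor range conventions). Each tile is flattened
over its own inclusive plane window by standard-deviation projection:

$$P(y,x) = \sqrt{\tfrac{1}{n}\sum_{z=z_0}^{z_1}\big(I(z,y,x) - \bar I(y,x)\big)^2}$$

with the *population* convention (divide by $n$), matching the standard
ImageJ "Standard Deviation" projection; the convention is recorded in the
output provenance. SD projection highlights thin, high-contrast structure:
a pixel crossed by a fiber varies strongly across the window, a background
pixel does not.

Plane windows are intended to be chosen manually per tile (the interactive
workflow); `zbounds = "auto"` provides an unattended stand-in: the brightest
`window`-plane interval is taken as the main band — the sub-basal plexus
whenever fibers are present, since it dominates total intensity — and for the
epithelial layer the search repeats strictly above that band, skipping one
plane of bleed-through. If the bright band already sits in the upper planes
the tile is treated as single-band. This heuristic is deliberately simple; it
is validated on synthetic stacks and is not a substitute for manual bounds on
unusual real data.

Binarization is by supplied threshold (`manual`/`fixed`) or Otsu. The default
for unattended runs computes one Otsu threshold from the stitched projection
(`threshold_scope = "global"`), because per-tile histograms of empty corner
tiles would otherwise binarize pure noise; `threshold_scope = "tile"` mirrors
the per-tile interactive workflow. Stitching copies pixels with no blending,
so split → stitch is exactly the identity and fragment counts are seam-free.

## Fragmentation index

`label_fragments()` assigns every foreground pixel to a contiguous fragment
with an iterative (explicit-stack) flood fill written in C++ — an explicit
stack is a contract, not an optimization, because an intact nerve swirl is a
single component of tens of thousands of pixels and recursion would overflow.
Connectivity is 8 by default so 1-px diagonal fiber segments remain
contiguous; 4-connectivity is available by flag. Labeling order is a
deterministic column-major raster scan. `pseudo_color()` draws each fragment
in a distinct random RGB color (sampled without replacement, background
black), so the number of distinct colors equals the fragment count.

The degeneration readout is coverage-normalized:

$$\text{fragmentation index} = \frac{K}{\text{coverage (px)}}$$

reported both per foreground pixel and per 1000 px (and per µm² when a pixel
size is supplied). An empty mask yields all-zero metrics with an `empty`
flag. No minimum-fragment-size filter is applied by default; `min_size` is
available for noisy masks. Whether coverage should be a pixel count or a
calibrated area is left to the caller via `pixel_size_um`; the index uses
pixel count.

## Epithelial integrity from DAPI line profiles

`preprocess_dapi()` linearly rescales each image to the 8-bit range (minimum
to 0, maximum to 255; a constant image maps to zero) and applies a Gaussian
filter (default σ = 1 px) to reduce speckle noise. `extract_profiles()` reads
5 column profiles at evenly spaced x-coordinates and 5 row profiles at evenly
spaced y-coordinates (at fractions 1/6 … 5/6 of each axis, so borders are
excluded; a 600-px axis gives coordinates 100–500).

The first derivative uses central differences at interior points and
one-sided differences at the ends. On the derivative, a peak is a transition
into higher fluorescence (background → nucleus) and a trough the transition
out (nucleus edge). `detect_transitions()` keeps local maxima above
`+min_prominence` and minima below `−min_prominence` (default 5% of the
derivative's maximum absolute value, in the spirit of peak-ignore settings in
interactive curve-analysis software), resolves plateaus to their leftmost
index, and enforces peak/trough alternation by dropping the less extreme of
two same-sign consecutive extrema.

Metrics:

* **transition delta** — mean |peak − trough| over adjacent (peak, next
  trough) pairs; an unpaired extremum at the end of a profile is dropped;
* **AUC** — each retained extremum owns a lobe; the profile is partitioned at
  midpoints between consecutive retained extrema and each lobe integrates
  |derivative| over its cell by the trapezoidal rule (outermost lobes end at
  their own zero crossing). Summed, this is the total variation of the
  profile across the detected-transition span — the summed amplitude of its
  intensity transitions. Bounding lobes at raw zero crossings of the
  derivative was rejected: speckle noise creates spurious zero crossings that
  chop sharp transitions into fragments and undercount precisely the
  sharpest, healthiest images;
* **AUC per transition** — AUC / n, 0 with a flag when no transitions exist.

By default the raw profiles are **averaged before differentiation**
(`pool = "average"`), the classical order for this measurement, which also
suppresses uncorrelated speckle by ≈ √(number of profiles); profiles are
averaged within equal-length sets (rows vs columns of a non-square image).
`pool = "profile"` computes per-profile metrics and pools them (counts and
areas summed, deltas averaged over all pairs); it is more conservative when
profiles are few but lets noise-extremum composition effects dilute
degradation contrast, which is why it is not the default.

All metrics are invariant to adding a constant to the raw intensities (the
rescale removes it) and to transposition (the profile sets swap).

## Physiology endpoints

**Blink threshold.** A Cochet-Bonnet filament length is positive when blinks
occur on at least 3 of 6 taps. Longer filaments exert lower force, so the
sensitivity threshold is the *longest* tested length (of 3.5, 2.5, 2, 1.5, 1,
0.5 mm) with a positive response, and 0 when no length qualifies. Scanning
all lengths and taking the maximum is equivalent to the descending
stop-at-first-positive protocol whenever response is monotone in force, and
is what `sensitivity_threshold()` implements; the equivalence is tested
exhaustively against a descending-scan oracle. Lengths are millimetres
throughout.

**Tear wick.** `wick_summary()` reports per-group per-day mean ± SEM
(SEM = sample SD/√n) and percent change of the group mean from its
baseline-day mean; a zero baseline flags the percent change as undefined
rather than failing.

**Group comparison.** `group_compare()` implements the dispatch rule used
throughout: Shapiro–Wilk per group at α = 0.05; all groups pass → Student's
t-test (two groups; Welch available via `var_equal = FALSE`) or one-way
ANOVA; any failure → Mann–Whitney or Kruskal–Wallis. Groups too small
(n < 3) or degenerate for normality testing route to the nonparametric
branch with a warning; fully constant data is flagged degenerate. The named
tests are delegated to the standard R routines — the dispatch logic is the
module's content. No multiple-testing correction is applied by default,
matching the unadjusted pairwise reporting convention; `p.adjust` can be
applied downstream. Simulations in the test suite verify the dispatched
pipeline keeps its nominal type-I error (within [0.03, 0.07] at α = 0.05)
and routes skewed data nonparametrically in ≥ 90% of replicates.

## Synthetic data: what it emulates, and what it does not

**Nerve stacks.** Sub-basal fibers are streamlines of a logarithmic-spiral
field about the image center (`swirl_turns` revolutions from r ≈ 4 px to
48% of the short axis, with small multiplicative wobble), rendered at
`fiber_width_px` into a low-z band; terminals are 2 × 2 px puncta in a higher
band; both bands drift linearly by `curvature_tilt` planes between opposite
corners, emulating residual curvature of the flattened cornea, with a dim
(0.35×) bleed into the two neighbouring planes. Degradation is applied to
the geometry in a fixed, documented order — whole-fiber removal
(`coverage_loss`), fiber breakage (`break_rate` per candidate break point,
cutting a gap ≥ 3 fiber widths so binarization cannot re-bridge it),
terminal dropout — and additive Gaussian noise (clipped to [0, 1]) comes
last. Truth records the noiseless 2D coverage mask and its exact component
count under the configured connectivity. `non_touching = TRUE` lays fibers
as short spiral-aligned arcs in disjoint cells with guard margins, giving a
deterministic guarantee that planted fragments never touch, so planted
counts are exact by construction (rejection sampling was rejected: it cannot
guarantee termination at high fragment counts). Quantitative morphology of
the naive mouse cornea (fiber density per mm², terminal counts) is not
published; defaults (24 fibers, 0.5 terminals/1000 px², 20 planes, tilt 4)
were chosen once for testability and visual plausibility, not biological
calibration.

**Epithelium.** Nuclei sit on a square lattice (pitch 24 px, first
row/column half a pitch from the border), jittered by ±2 px, rendered as
flat-topped smooth discs of radius 9 px over a dim background — densely
packed, as epithelial nuclei are, with per-nucleus brightness drawn from
U(0.55, 0.95) to emulate chromatin-state variation. Degradation order is
fixed: dropout → Gaussian blur → contrast flattening (affine shrink toward
the mean) → additive noise. Two generator design points matter for the
metrics' behaviour and are deliberate: dense packing creates confluent
bright plateaus, and brightness heterogeneity adds low-frequency structure;
together they anchor the image's dynamic range under blur. A sparse lattice
of identical nuclei is nearly a single-frequency pattern, and a uniform blur
then attenuates its oscillation and its global range at the same rate — the
per-image min→max 8-bit rescale would cancel the blur almost exactly and
"blur" would not disrupt the measured quantities at all.

**Cohorts.** Three groups (naive / desiccation+vehicle / desiccation+CMP,
n = 13/11/11) measured at days 0, 5, 7, 10, 14. Wick lengths are Gaussian
about group-by-day means (SD 0.8 mm), truncated at 0; the default means
start at a 5 mm baseline and encode a 43% reduction by day 5 and 60% by
day 7, persisting under vehicle and partially recovering under CMP.
Blink tables draw, per animal-day, a latent threshold
t ~ N(group-day mean, 0.45 mm) — anchored at a 2.65 mm baseline falling to
1.08 mm after 7 days of desiccation — and positives ~ Binomial(6, p) with
p = logistic((t − length)/0.25 mm), monotone non-increasing in filament
length. The baseline wick length is a design choice (absolute values are
rarely reported; only relative changes are), as are the vehicle/CMP
recovery trajectories.

Not emulated: optical sectioning physics (PSF convolution, Poisson photon
noise, bleaching), fluorescein surface imaging, nerve branching morphology,
spatially heterogeneous ("patchy") epithelial damage, and longitudinal
within-animal correlation in the cohorts. Passing tests therefore
demonstrate the *algorithms* recover planted structure and directional
effects under controlled degradation — not that the defaults reproduce any
particular biological magnitude.

## Numerical choices and degenerate inputs

* SD projection: population convention; single-plane windows yield zero with
  a warning rather than failing.
* Auto plane-window ties (equal-intensity windows) resolve to the leftmost
  window, robust to floating-point round-off in the running sums.
* Otsu on a constant image is undefined: an empty mask plus a warning.
* Flood-fill seeds scan in column-major order; labels are dense 1..K.
* Pseudo-colors are sampled without replacement from the 24-bit palette
  (excluding black), so color collisions are impossible.
* Plateau extrema take the leftmost index; alternation drops the less
  extreme of same-sign neighbours (ties keep the leftmost).
* Zero transitions: delta and AUC/transition report 0 with
  `no_transitions = TRUE`.
* Empty cohorts, empty groups, zero baselines and constant groups are
  flagged or warned about, never silent errors.
* Generators are pure functions of (parameters, seed); they save and restore
  the caller's RNG state.

## Problem sizes used by the test suite

The suite validates at desk scale, chosen to keep the full run around two
minutes: 256 × 256 synthetic nerve stacks (12 fibers, 20 seeds per
degradation level; 50 planted fragments × 10 seeds for exact-recovery), the
generator's default 512 × 512 epithelium (20 seeds per blur/flattening
level), ≥ 200 random 64 × 64 masks against a breadth-first-search oracle,
10,000 sampled blink tables against the descending-scan oracle, and 2000
null-cohort simulations for the type-I check. Tiling and round-trip
identities are exercised at the full 800 × 800 acquisition size.

## Known limitations

* The auto plane-bound heuristic assumes at most two intensity bands per
  tile; stacks with three or more structures in z need manual bounds.
* Otsu assumes a bimodal histogram; faint structure over dominant background
  may need a manual threshold (the interactive workflow's choice).
* The fragmentation index is resolution-dependent (it normalizes by pixel
  count); compare only images of equal magnification, or calibrate with
  `pixel_size_um`.
* Derivative metrics assume roughly isotropic nuclear texture; strongly
  anisotropic damage would be diluted by pooling row and column profiles.
* The dispatch rule tests normality per group independently; it does not
  model heteroscedasticity beyond offering Welch's test.
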