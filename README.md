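# corneametrics

Quantification of corneal nerve-bed degeneration and epithelial integrity for
mouse models of ocular surface desiccation (dry eye disease).

The cornea's sub-basal nerve plexus — a central swirl of sensory fibers whose
terminals ramify between apical epithelial cells — degrades under desiccation
stress, and that degradation is the structural readout behind falling tear
production and corneal sensitivity. `corneametrics` implements the full
quantitative workflow used to measure this in whole-mount confocal imaging and
in-cage physiology, for researchers analyzing βIII-tubulin–labeled corneal
nerve images, DAPI-stained epithelium, tear-wick records and Cochet-Bonnet
aesthesiometry tables.

## What it computes

**Tiled z-stack flattening.** The flattened cornea is curved, so one field's
sub-basal fibers and epithelial terminals lie in different z-planes across the
image. Stacks are split into a 3 × 3 grid of tiles, each tile is flattened
over its own plane window by standard-deviation projection (population
convention: each output pixel is `sd(I(z)) = sqrt(mean((I - mean(I))^2))` over
the window), binarized (manual threshold or Otsu), and re-stitched seamlessly.

**Fragmentation index.** Contiguous nerve fragments in the binary image are
counted by an iterative flood fill (8-connected by default) and pseudo-colored
for inspection. Degeneration is quantified as

```
fragmentation_index = n_fragments / coverage_px
```

fragments per pixel of nerve coverage (also reported per 1000 px). Intact
nerves form few long fragments; degenerating axons disassemble into many
short ones, raising the index while coverage falls.

**Epithelial integrity from DAPI line profiles.** Images are converted to
8-bit, Gaussian filtered, and sampled along 5 fixed column + 5 fixed row
profiles. On the first derivative of the (averaged) profiles, a peak marks a
transition into a nucleus and a trough the transition back out. Reported
statistics: the transition delta (mean |peak − trough| amplitude difference),
the combined unsigned area of derivative peak/trough lobes (AUC), and AUC per
transition. All three fall as nuclear definition is lost.

**Physiology endpoints.** Tear-wick summaries (mean ± SEM, percent change
from baseline) and Cochet-Bonnet sensitivity thresholds — the longest
filament length eliciting blinks on ≥ 3 of 6 taps (longer filament = lower
force = higher sensitivity; no response at any length scores 0). Group
comparisons are normality-gated: Shapiro–Wilk per group at α = 0.05, then
Student's t / one-way ANOVA, or Mann–Whitney / Kruskal–Wallis.

**Synthetic data with planted truth.** Generators for spiral nerve-swirl
stacks (with controllable fiber breakage, terminal dropout, coverage loss and
corneal-curvature plane drift), periodic DAPI nucleus fields (dropout, blur,
contrast flattening, noise), and three-group cohort time series
(naive / vehicle / CMP-treated) — each carrying exact ground truth so every
pipeline stage is testable without microscope data.

## Worked example

```r
library(corneametrics)

# a desiccated-cornea-like stack: broken fibers, dropped terminals
p <- nerve_params(image_size_px = c(256, 256), n_planes = 12, n_fibers = 12,
                  curvature_tilt = 3, break_rate = 0.5, coverage_loss = 0.3,
                  terminal_dropout = 0.4, seed = 7)
g <- generate_nerve_stack(p)
res <- analyze_nerve_stack(g$stack)
attr(res, "metrics")
#>        layer fragment_count coverage_px coverage_fraction fragmentation_index fragments_per_1000px
#> 1  sub_basal             38        7239       0.110458374         0.005249344             5.249344
#> 2 epithelial             21          84       0.001281738         0.250000000           250.000000
```

The sub-basal layer flattens to 38 fragments over ~11% coverage — an index of
5.2 fragments per 1000 foreground px, an order of magnitude above an intact
swirl (which is a single fragment, index < 0.2). The epithelial layer retains
21 of the planted terminals, each an isolated punctum.

```r
co <- generate_cohort(cohort_spec(seed = 7))
ep <- analyze_endpoints(co)
subset(ep$wick_summary, group == "vehicle")
#>      group day  n mean_mm sem_mm baseline_undefined pct_change
#> 11 vehicle   0 11    4.86  0.164              FALSE        0.0
#> 14 vehicle   5 11    2.58  0.217              FALSE      -47.0
#> 13 vehicle   7 11    1.94  0.208              FALSE      -60.1
ep$tests$day7$wick
#> <group_comparison> one-way ANOVA (parametric): statistic = 82.93, p = 2.192e-13
#>   cmp: n = 11, mean = 2.29 +/- 0.18 (SEM)
#>   naive: n = 13, mean = 4.78 +/- 0.139 (SEM)
#>   vehicle: n = 11, mean = 1.94 +/- 0.208 (SEM)
```

Tear production in desiccated groups falls ~47% by day 5 and ~60% by day 7
relative to baseline, and the day-7 group difference is detected by the
parametric branch of the dispatch. Sensitivity thresholds route through the
rank-based branch (they live on the discrete filament-length scale).

A thin command-line front end over the same functions is installed at
`inst/cli/corneametrics.R` (subcommands `simulate`, `project`, `fragment`,
`epithelium`, `endpoints`).

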