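---
title: "Quantifying hyphal shape and tip-associated fluorescence in budding bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyphal shape and tip-associated fluorescence in budding bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyphometry)
```

## The measurement problem

Budding bacteria of the Hyphomicrobiaceae reproduce through a thin polar
hypha: the mother cell extends a tube a few tenths of a micrometre wide and
several micrometres long, and the daughter cell forms by swelling of the
hyphal tip. Cytoskeletal mutants of these organisms keep making hyphae, but
the hyphae are kinked and buckled instead of straight. Classical shape
metrics (sinuosity, curvature, angularity) average away exactly the feature
of interest — a small number of localized, sharp direction changes — so
this package implements a purpose-built statistic, the **hyphal deformity
score** `d_h`:

$$ d_h = \frac{1}{N}\left( \sin\theta_J + \sum_{i=1}^{N-1} \sin\alpha_i \right) $$

where the $\alpha_i$ are the deflection angles of the kinks along the
hypha, $\theta_J$ is the emergence (junction) angle between the mother
cell's long axis and the initial hyphal direction, and $N$ counts all
measured angles including the junction. The sine maps both conventions for
reading an angle (interior vs. turn) onto the same value
($\sin(180^\circ - \alpha) = \sin\alpha$), is 0 for a straight, collinearly
emerging hypha, and saturates at 1 for right-angle turns. A kink-free hypha
has $N = 1$ and $d_h = \sin\theta_J$.

Only cells with initiated or finished bud formation and exactly one
unbranched hypha are scored: bud formation marks the end of hyphal
elongation, and branched or multi-hyphal cells make the per-hypha score
ambiguous. Every other cell is carried through the pipeline with an
explicit exclusion reason — counts of measured plus excluded cells always
equal the input count.

## From mask to geometry

Segmentation is deliberately out of scope; the pipeline consumes a labelled
binary mask (any segmenter, or hand tracing, can produce one) together with
optional intensity channels. Per label:

1. **Skeletonization** — iterative two-subiteration (Zhang–Suen) thinning
   of the component; local width at every skeleton pixel is twice the
   Euclidean distance transform. Side spurs shorter than `prune_len_um`
   (default 0.2 µm) are removed.
2. **Main path** — the longest geodesic through the skeleton, found by a
   BFS double sweep (the tree-diameter heuristic). This is robust against
   the spurious 3-neighbour pixels that 8-connected thinned staircases
   produce, which defeat junction-counting approaches.
3. **Partition** — on the width profile along the path, the longest run
   with width ≥ `body_width_ratio` (0.6) × maximum width is the cell body;
   thin terminal runs at least `min_hypha_um` (0.3 µm) long are hyphae; a
   terminal run at a hypha's distal end with width ≥ `bud_width_ratio`
   (0.5) × body width is a nascent bud. These criteria are this package's
   construction: the visual stage definitions they operationalize
   (no hypha / hypha without bud / budding) are standard, but no published
   numeric thresholds exist for them.
4. **Boundary refinement** — the width-threshold crossing sits inside the
   wide compartment's polar cap, not at the attachment point, so each
   boundary is walked toward the thin side until the local half-width
   reaches ~1.2× the hyphal tube half-width (estimated as the median over
   the tail). Terminal skeleton retraction, which thinning causes at every
   blunt end, is compensated by extending each path end by its local
   half-width. Without these two corrections hyphal length is biased by
   roughly one body radius (~10 % at typical geometry); with them the
   mean absolute length error on synthetic data is below 4 %.
5. **Branch handling** — skeleton structures off the main path longer than
   the local width are real: attached in the thin region they mark a
   branched hypha, attached at the body a second appendage; either way the
   cell is excluded from deformity scoring (with its reason), matching the
   inclusion rule. Shorter structures are thinning artifacts and ignored.

Cells touching the image border and topologically ambiguous cells (two
near-equal wide regions) are excluded with reasons, never silently dropped.

## Angle measurement on traced paths

Raw skeleton paths carry pixel-staircase jitter, so kink detection runs on
a smoothed (5-pixel moving average), Ramer–Douglas–Peucker-simplified
polyline (`simplify_tol_um`, default 0.05 µm ≈ 1 pixel at 100×
magnification) and counts vertices whose deflection exceeds `min_kink_deg`
(default 10°). Two refinements matter for image-derived traces, and both
are exact no-ops on clean polylines:

* **Corner clustering** (`merge_radius_um`, default 0.2 µm in the core
  API, 0.3 µm in the image-pipeline configuration): digitization rounds a
  sharp corner over a length scale of roughly the tube radius plus the
  smoothing window, so one physical kink surfaces as a short run of
  same-direction sub-turns. Simplified vertices closer than the merge
  radius are clustered and their *signed* deflections summed — the sum
  telescopes to the direction change between the flanking straight
  segments, so the full kink angle is recovered rather than split into
  sub-threshold fragments. The generator's minimum kink spacing (0.4 µm)
  exceeds the radius, so distinct kinks are never merged.
* **Junction chord** (`junction_chord_um`, 0 in the core API, 0.4 µm in
  the image pipeline, with a 0.15 µm skip): inside the body's polar cap the
  medial axis bends smoothly from the body axis toward the hypha, so the
  first simplified segment underestimates the emergence angle by several
  degrees. Measuring the initial direction over the chord from 0.15 µm to
  0.55 µm of hyphal arc length skips the cap-rounded zone; on synthetic
  data this reduces the junction bias from about −4° to about −1°.

The two defaults express the two use cases: hand-digitized or analytic
polylines are measured with the literal first-segment/per-vertex
convention; skeleton-derived traces use the rounding-aware settings, which
`run_config()` applies by default.

## Demographs and peak-to-tip distances

Fluorescence profiles are sampled along the concatenated medial path
(non-hyphal pole → body → hypha → bud) at `sample_step_um` (0.05 µm) with
bilinear interpolation, averaged over a 3-pixel window perpendicular to the
path. Demographs stack per-cell min–max-normalized profiles (constant
profiles map to zeros — the only choice that keeps the normalized range in
[0, 1] without inventing contrast), pole-aligned at column 0 and sorted
ascending by cell length. Pole alignment, rather than mid-cell centering,
makes tip-associated signals trace the cell-length diagonal, which is the
pattern of interest; a centered variant was considered and rejected as the
default because it halves the visual resolution of tip proximity.

The peak-to-tip distance restricts the profile to the hypha (+ bud)
segment, smooths with a `peak_window_um` = 0.15 µm moving average (raw
argmax is noise-brittle at realistic SNR), takes the argmax with ties
broken toward the tip, and reports tip arc position minus peak arc
position. Between-channel comparisons are paired per cell, so tip-position
errors — the largest single error source — cancel exactly in the offset.

## Group statistics

Per-cell scores are compared with the tie-corrected Kruskal–Wallis rank
test (`stats::kruskal.test`); ties are real here because straight hyphae
score exactly 0. Normality is assessed with the D'Agostino–Pearson omnibus
K² test (skewness z via the Johnson SU transformation, kurtosis z via the
Anscombe–Glynn cube root; K² ~ χ²(2)), implemented in the package because
no installed R package provides this particular omnibus form; it is
validated against an independent reference implementation. Significance
labels default to `****` < 0.0001, `***` < 0.001, `**` < 0.01, `*` < 0.1,
`n.s.` otherwise. The source convention this mirrors leaves the interval
between 0.1 and 0.9999 unlabelled; everything at or above 0.1 is reported
here as `n.s.`. For more than two groups, pairwise two-group rank tests
with Bonferroni correction are appended — a pragmatic follow-up choice,
clearly labelled as such in the output.

## The synthetic-data generator

Because the measurements this package automates are conventionally done by
hand on micrographs, validation uses a fully ground-truthed generator
(`phenotype_spec()`, `generate_cells()`, `rasterize_cells()`):

* **Kink model** — kink count ~ Poisson(`kink_count_mean` = 2); kink and
  emergence deflections |N(0, σ)| truncated below 180°, with random turn
  direction; kink positions partition the hyphal length with a 0.4 µm
  minimum segment. The half-normal is this package's construction: it has
  a single interpretable spread parameter σ that maps straight phenotypes
  to a few degrees and buckled ones to tens of degrees.
* **Geometry defaults** — body 2.2 × 1.2 µm, hypha length N(5, 0.8) µm and
  width 0.25 µm, bud diameter 0.9 µm, pixel size 0.065 µm: typical values
  for a 100× objective and for micrographs of hyphal budding bacteria with
  1 µm scale bars.
* **Truth convention** — the analytic score counts the emergence angle and
  the drawn kinks at or above the 10° visibility threshold; sub-threshold
  draws bend the polyline but are, by definition, not kinks. This makes
  the truth equal `compute_deformity()` on the noiseless generating
  polyline (asserted in the tests) and keeps truth and measurement
  estimands identical.
* **Rendering** — tubes and the bud disc are drawn on the pixel grid (the
  body capsule's surface passes through the axis poles, so hyphal-length
  truth is the visible length), per-channel Gaussian spots are placed at
  the true arc offsets from the tip, the field is convolved with a
  Gaussian PSF (σ 0.1 µm), and Poisson shot noise plus additive Gaussian
  read noise are applied. The label mask is the noiseless tube support.
  Placement is rejection-sampled with a margin; the field grows if a cell
  cannot be placed.

What the generator does *not* emulate: segmentation errors (masks are
perfect), uneven illumination, autofluorescence, out-of-focus light,
overlapping or touching cells, multicellular arrays, and time-lapse
dynamics. Passing round-trip tests therefore demonstrates correctness of
the geometry and measurement chain given a good mask, not robustness to
poor segmentation.

## Numerical choices and degenerate inputs

Angles are computed via `atan2(|u × v|, u · v)`, stable near 0° and 180°;
polyline simplification is the recursive maximum-perpendicular-deviation
method implemented iteratively. Hyphae shorter than twice the
simplification tolerance are rejected as unmeasurable rather than scored 0.
Constant demograph rows map to zeros; equal-height profile peaks resolve
toward the tip; identical samples in the rank test return H = 0, p = 1
rather than failing. All generator randomness flows from the spec seed, and
rasterization derives its placement/noise stream from the same seed, so
identical configurations replay byte-identically.

## Problem sizes used in validation

The validation suite measures: formula equivalence on 60 small polylines
against an independently coded evaluation; invariance under rigid motion,
reflection, scaling and angle supplements on 1000 random angle sets and 250
random cells; an image round trip of 100 cells per σ ∈ {5°, 20°, 40°}
(Pearson r between analytic and re-measured scores > 0.9, mean hyphal
length error ≤ 5 %, stage classification ≥ 95 %); detection power for the
σ = 5° vs σ = 40° contrast at n = 100 cells per group over 100 replicates
(p < 10⁻⁴ in ≥ 95 %) with the type-I error of the same comparison held at
0.05 ± 0.02 over 1000 replicates; and paired peak-offset recovery (0 vs
0.2 µm, 200 cells, SNR 5) to within one 0.05 µm sampling step. These sizes
match the study design the statistic is meant for — population plots of
~100 hand-measured cells per strain — while keeping the suite quick to run.

## Known limitations

* Geometry is strictly 2D, matching projected epifluorescence/DIC
  measurements; no 3D correction is attempted.
* Strongly buckled hyphae that fold back onto themselves merge into a
  single mask blob; the tracer flags these as branched and excludes them,
  which slightly censors the extreme tail of the deformity distribution —
  the same censoring a human tracer faces with an unresolvable tangle.
* Kinks closer together than the corner-rounding scale (~0.3 µm at default
  settings) cannot be separated in image-derived traces.
* The bud/hypha boundary is a width-threshold construction; where the
  nascent bud widens very gradually, a few hundredths of a micrometre of
  arc length can migrate between hypha and bud.
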