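---
title: "Quantifying dendritic arbors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendritic arbors: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

dendromorph quantifies single-neuron dendritic arbors of the kind imaged in
*Drosophila* class IV dendritic arborization (c4da) sensory neurons: a
central soma with a planar, radially branching, self-avoiding arbor of tens
to hundreds of terminal tips. The package covers five stages:

1. **Synthetic arbors** (`synthetic_spec`, `generate_arbor`, `evolve_arbor`,
   `render_arbor`, `make_dataset`) — oracle-labeled inputs for every other
   stage.
2. **Segmentation** (`segment_classical`, `train_segmenter`,
   `segment_trained`, `binarize_and_clean`, `dice`,
   `validate_against_truth`) — raw image to cleaned binary dendrite mask.
3. **Morphometry** (`skeletonize`, `total_length`, `count_tips`,
   `territory_coverage`, `sholl`, `quantify`) — the four standard morphology
   parameters.
4. **Dynamics** (`align_skeletons`, `transition_arbor`, `dynamics_record`,
   `survival_rate`) — two-time-point stable/eliminated/added accounting.
5. **Statistics and pipeline** (`compare_groups`, `summarize_records`,
   `run_pipeline`, the `dendromorph` CLI).

# The synthetic arbor model

`generate_arbor` grows a rooted tree by iterating growth cones from the
soma. Each cone elongates in segments whose length is Gaussian
(`seg_len_mean_um` = 6 µm, SD 2 µm, floored at 4 µm) with per-segment
heading noise (`angle_jitter_deg` = 18°) and a weak outward tropism, and
bifurcates with probability `branch_prob` = 0.35 per segment. Three
termination routes create tips: stochastic interior termination
(`term_prob` = 0.05 per segment), the field border, and **contact
inhibition** — like real da dendrites, which tile their receptive territory
without crossing, a cone stops when its path would come within ~5 px of an
existing branch. When a terminal-tip target is set, branching is gated so
the projected tip count never overshoots, branching pressure adapts to the
remaining deficit, and — when frontal growth stalls before the target —
new cones sprout interstitially from existing internal nodes, which is also
how real c4da arbors add branches. A shortfall beyond 10% of the target is
an error, never a silent truncation.

Geometric floors matter for measurement fidelity and are deliberate:
segments are at least 4 µm, a terminated stub shorter than 9 px is
discarded (the cone's base becomes the tip), and primary dendrites clear
the soma region before they may terminate. These floors guarantee that
every terminal branch survives skeletonization, which is what makes exact
tip-count recovery on noiseless renders possible (acceptance criterion 2).

**Rendering.** Branch diameters taper from 2 px at the soma to 1 px at deep
terminal branches (2 px/µm scale, so 0.5–1 µm — the realistic range).
Terminal branches are drawn as true 1-px digital (Bresenham) lines; such
lines are invariant under the thinning algorithm, whereas 2-px staircase
ends unravel one pixel per thinning iteration and would silently shorten
terminal branches. Terminal branches are rendered at 0.55 of backbone
intensity (real terminal branches are relatively faint and are the known
failure mode of automatic segmentation), then PSF blur (σ = 1 px), a
constant background (0.1), additive Gaussian noise (SD 0.05 on a 0–1
scale), and debris are applied. Debris — detached fragments of degenerated
branches that persist after engulfment — is drawn as ≤4 px bright
fragments displaced ≥3 px from any true branch; debris appears **only** in
the image, never in the ground-truth mask, so a good segmenter is trained
and evaluated on suppressing it.

The ground-truth mask is the **visible support**: the PSF-convolved
noiseless signal above a fraction (0.22 × faint-terminal contrast) of the
faintest branch peak. This is what a human annotator traces on a blurred
image. With `psf_sigma_px = 0` the mask reduces exactly to the rendered
support, which keeps the noiseless oracle tests sharp.

**Evolution.** `evolve_arbor` removes whole terminal branches (tip back to
the nearest branch point; a removal is skipped if it would turn the
attachment node into a new, unlabeled tip), grows unbranched new terminal
branches at internal nodes so that added/T2 ≈ `p_add`, scales about the
soma, and translates. Every tip carries a ground-truth label
(stable/eliminated/added) and the label sets partition both tip sets
exactly — the oracle for the dynamics stage.

# Segmentation

Two backends produce per-pixel dendrite probability maps.

The **classical baseline** needs no training: a multiscale Hessian ridge
filter (largest negative eigenvalue, scale-normalized, σ ∈ {1, 1.5, 2.5})
is combined geometrically with a local background-subtracted intensity
term, normalized by a high quantile of the positive response, and
gamma-compressed (γ = 0.25) so faint terminals clear the default 0.5
threshold. The map is invariant to constant offsets and to contrast scaling
by construction.

The **trainable backend** stands in for the U-Net-style model that a
GPU-equipped stack would use; the pre-installed environment has no deep
learning runtime, so the package ships a compact convolutional segmenter:
a fixed multiscale convolutional encoder (normalized intensity, Gaussian
pyramid σ ∈ {1, 2, 4}, Hessian ridge *and* blob channels at σ ∈ {1, 1.5,
2.5}, a fine local-contrast channel, and a background-subtracted channel —
12 features) feeding a one-hidden-layer nonlinear decoder trained by
minibatch SGD on pixelwise cross-entropy plus a soft-Dice overlap term.
Pixels are sampled per training image: one third foreground, one quarter
from the 4-px ring around the structure, one eighth from the brightest
background pixels (hard negatives — debris and noise spikes), the rest
uniform background. The blob channel (sign-flipped largest Hessian
eigenvalue) is what lets the decoder discriminate compact bright debris
from elongated faint terminals. Training is deterministic given the seed
and takes seconds on one CPU; the model serializes to JSON.

Image-level normalization divides by the 99.95% intensity quantile above
the median, floored at 6× the robust noise level (MAD) — without the floor
a sparse arbor in a large field normalizes to its noise and the map
explodes with false positives.

**Postprocessing** follows threshold → close → size-filter. Closing uses a
square (Chebyshev) element of radius `gap_close_px` because a square
element actually bridges a 2·r px gap between 1-px lines, which a Euclidean
disk of the same radius does not. The default radius is 1 (not 2): the
generator's self-avoidance leaves ~3 px of background between a terminal
tip and the neighboring branch, and a radius-2 closing would weld tips onto
neighbors and destroy tip counts, while radius 1 still heals the 1–2 px
breaks that noise causes along faint branches. Components smaller than
`min_fragment_px` = 30 are removed — this is what eliminates detached
debris — but the component containing the soma (deepest erosion depth) is
always kept, so a heavily degenerated neuron is never deleted outright; an
empty cleaned mask is flagged dead and feeds the survival table.

# Morphometry

`skeletonize` thins the mask (vectorized two-subiteration Zhang–Suen),
builds an 8-connected pixel graph (diagonal steps that duplicate an
orthogonal two-step path are dropped), prunes terminal spurs shorter than
3 px (thinning artifacts on wide branches), and — important for length —
collapses every degree-2 pixel chain into a Douglas–Peucker polyline with
1 px tolerance. Raw step-count length (1 per orthogonal, √2 per diagonal
step) overestimates true curve length by up to ~20% at unlucky angles
because thinned chains staircase; after simplification the Euclidean
edge-length sum is within ~1–2% of the generating SWC ground truth. The
soma is the pixel with the deepest erosion depth, ties broken toward the
mask centroid.

* **Total length**: Euclidean sum over edges ÷ px/µm (identical to the
  step rule on raw pixel chains).
* **Tips**: degree-1 nodes outside the soma exclusion radius (soma radius
  + 2 px). Cycles contribute no tips and are tolerated.
* **Territory coverage**: a grid of `cell_px` = 20 px cells; territory =
  cells whose centers fall in the convex hull of the skeleton; coverage =
  % of territory cells containing skeleton. A degenerate (collinear) hull
  scores 100 by convention. Note the denominator shrinks with the hull, so
  purely peripheral loss can nudge coverage up by a fraction of a point —
  interior loss, the signal of degeneration, decreases it.
* **Sholl**: per concentric circle (step 10 µm), the number of
  edge–circle intersections computed analytically per straight edge. For
  unit pixel edges this equals the classic "endpoint distances straddle r"
  rule, but it stays exact for long simplified edges that can cross a
  circle twice.

Known asymmetry: thinning is not exactly rotation-symmetric, so measured
length changes by <0.1% under a 90° rotation (tips remain exact);
translation invariance is exact.

# Dynamics

Two time points of the same neuron are aligned by exhaustive search over
integer translations (±10 px), scoring twice the exact raster overlap plus
the overlap within a 2-px dilation — the exact term keeps the optimum from
sliding along the dilation plateau, the dilated term breaks ties. The
**transition-state arbor** is the t1 backbone restricted to nodes within
`match_tol_px` = 3 of the t2 skeleton.

A t1 tip is **stable** when ≥ `cover_frac` = 0.7 of its terminal branch
(sampled at 1-px steps) lies within the dilated t2 skeleton; coverage of a
branch rather than tip-to-tip distance tolerates growth-induced tip
displacement. Eliminated and added counts follow by subtraction — E = T1 −
S, A = T2 − S — so the conservation identities S+E=T1 and S+A=T2 hold *by
construction* on every record (the t2-side coverage count is kept as a
diagnostic). A neuron with an empty cleaned mask at t2 yields S=0, E=T1,
A=0 and is flagged dead; `survival_rate` tabulates per-condition survival
percentages from those flags.

Alignment is translation-only; larval body-wall growth between time points
is absorbed by the coverage tolerance, not by similarity registration. The
parameter-recovery acceptance grid therefore evolves arbors without
growth scaling; an upgrade path (uniform scaling about the soma) exists in
`transform_skeleton`.

# Statistics

`compare_groups` wraps the standard formulations: one-way ANOVA with Tukey
HSD, Kruskal–Wallis with Dunn's tie-corrected z tests adjusted by
Benjamini–Hochberg, the two-way ANOVA interaction term, and Student's
pooled-variance t (Welch off, matching the reported methodology; two
identical groups return t = 0, p = 1 rather than an error). Dunn
comparisons are two-sided. `summarize_records` reports mean ± SEM and n
per condition; single-value groups emit SEM = NA. Under the null the
one-way ANOVA's type-I error is verified to sit in [0.03, 0.07] at α=0.05
over 1,000 simulations.

# What a green test does and does not establish

The generator emulates: radial self-avoiding planar arbors, faint terminal
branches, PSF blur, additive noise, detached debris, rigid inter-session
offsets, and tip-level elimination/addition. It does **not** emulate:
uneven illumination, muscle autofluorescence and other structured
background, depth-dependent blur, dendrite blebbing/fragmentation
intermediates, partial branch retraction (modeled only as whole-branch
elimination), multi-neuron fields, or tracking across more than two time
points. Accuracy numbers (e.g. the R² fidelity targets) therefore certify
the computational pipeline against its own stated world, not performance
on real micrographs; biological effect sizes observed in live animals are
not reproducible computationally and are not claimed.

# Numerical choices

* Determinism: every stochastic routine draws from a private RNG stream
  seeded from its argument (`spec$seed`, `seed`, `cfg$seed`), so identical
  inputs give byte-identical outputs and the caller's RNG state is never
  touched.
* FFT convolution is circular; arbors keep a ≥10 px margin so wrap-around
  never reaches structure.
* The spur-pruning threshold (3 px), Sholl step (10 µm), territory cell
  (20 px), and cleaning defaults are exposed parameters; defaults are
  package choices, not values from the source study, and sensitivity to
  them is the user's to explore.
* Images are PGM (portable graymap, 16-bit binary for intensities, 8-bit
  for masks): the only grayscale format that needs no external imaging
  dependency; skeletons are standard 7-column SWC in micrometers.
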