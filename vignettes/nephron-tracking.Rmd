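---
title: "Tracking nephron tubules through serial histological sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking nephron tubules through serial histological sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephtrack)
```

## The problem

A nephron is a single convoluted epithelial tubule, beginning at a glomerulus
in the renal cortex, descending through the medulla as the loop of Henle and
returning to the cortex. Serial sectioning of a rodent kidney (2.5 µm
sections, ~1000 slices for a mouse, ~4000 for a rat) turns each nephron into
a long chain of small lumen cross sections scattered across the image stack,
densely interleaved with hundreds of other nephrons, blood vessels and
interstitial tissue. Tracing one nephron by hand means following thousands of
cross sections and takes hours; `nephtrack` automates the trace from a single
seed point, with a non-interactive correction hook where automation fails.

The pipeline has three stages — image preprocessing, feature extraction, and
graph-based tracking guarded by a rule base and an optional machine-learned
move validator — plus a synthetic phantom generator that provides ground
truth for every stage, since the original animal datasets are not
distributable.

## Preprocessing

Each slice passes through grayscale conversion, background removal, global
and local contrast-limited adaptive equalisation, thresholding, erode/dilate
cycles and component size filtering, producing a binary image in which each
4-connected component is (ideally) one tubule lumen cross section.

Choices worth knowing about:

* **Polarity.** Lumens are taken to be bright against dark-stained walls
  (the toluidine-blue convention after grayscale conversion). The `invert`
  flag in `preprocess_params()` flips this for other stains.
* **Background handling.** The background mask (largest bright component,
  closed with a disk kernel, padded so closing cannot erode at the image
  border) is multiplied onto the image, making background *exactly* zero.
  The equalisation passes exclude exact zeros from their histograms and pin
  them to zero, otherwise the large background area would dominate the
  intensity ranks and lift the tissue above any fixed threshold.
* **Equalisation.** Both passes are tile-based contrast-limited adaptive
  histogram equalisation with bilinear blending of the per-tile mappings;
  the "global" pass simply uses a window at least as large as the image.
  The clip limit (`eq_clip`, default 4 times the uniform bin count) keeps
  single-intensity regions from being stretched into full-range noise.
* **Size filtering.** Components under 10 px² or over 100000 px² are
  confidently not lumens and are removed; these two bounds are the only
  preprocessing constants treated as fixed working-range values rather than
  calibration parameters.
* **Threshold default.** After equalisation the lumen/tissue split sits
  around rank 0.6–0.7 on the synthetic intensity model, so
  `binary_threshold` defaults to 0.65. Like every other preprocessing value
  it is a calibration default, exposed in `preprocess_params()`.

**The sigmoid schedule.** At the outer-medullary transition zone the thick
descending limb (≈60 µm diameter) narrows abruptly to a 10–15 µm thin limb,
and most preprocessing parameters need different values above and below that
depth. Any parameter may therefore be scheduled as

\[ v(z) = v_\mathrm{med} + (v_\mathrm{cor} - v_\mathrm{med})\,
   \sigma(-s\,(z - z_0)) \]

with \(\sigma\) the logistic function, inflection \(z_0\) at the transition
slice and steepness \(s\) in 1/slices: near-constant in the cortex and the
medulla, smooth in between. The logistic reparameterisation by its two
asymptotes, inflection and steepness is this package's concrete choice of
sigmoid.

**Defective slices** (auto-detected when the slice mean deviates more than 3
robust standard deviations from the stack median, or listed explicitly) are
replaced by a copy of the nearest intact slice — preferring the slice above
on ties — so slice numbering is preserved.

## Feature extraction

Each binary component becomes a `cross_section` carrying:

* **Nodes.** K-means over the component's pixels, with K grown from 1 until
  the mean distance between adjacent nodes (adjacency = consecutive along a
  nearest-neighbour chain started from the most extreme node) falls below
  the spacing target (default 30 px). A component compact enough that twice
  its RMS radius is within the target keeps a single centroid node. Runs are
  seeded deterministically (fixed seed plus K, three restarts), and
  centroids that fall outside a bent component are snapped to the nearest
  component pixel.
* **Shape factors.** Circularity \(4\pi A / P^2\), eccentricity and axis
  lengths from the moment-equivalent ellipse (with the 1/12 pixel-extent
  correction), solidity \(A/A_\mathrm{hull}\) and aspect ratio, plus area
  and minor axis length as absolute descriptors. The perimeter uses
  corrected chain weights (0.948 axial, 1.343 diagonal) because a raw
  √2-weighted chain biases the circularity of smooth shapes about 10% low;
  tiny components (<10 px) use the exposed-edge count. The convex hull is
  taken over pixel corners, not centres, so thin shapes cannot report
  solidity above 1.
* **Shape profile.** 24 radii at 15° increments measured from each node to
  the component boundary. Where the boundary is multivalued in angle, the
  profile keeps the *first* crossing along increasing radius; this is
  implemented by marching a ray outward over the component mask in 0.25 px
  steps, which realises that unwinding rule exactly and, unlike binning
  traced boundary points into 15° sectors, has no systematic bias at the
  diagonal angles of square-ish shapes. Profiles are computed on the binary
  mask boundary.

Angles are measured from the +x axis towards +y (the row direction);
coordinates are 0-based with x = column, y = row, z = slice index.

## Tracking

From a seed node the tracker grows a parent/child graph with open/closed
lists, A*-style. A popped node proposes at most one **vertical** candidate
per direction — the nearest node on the adjacent slice, strictly within the
tracking radius `r_track` — and chains the remaining nodes of its own cross
section through **horizontal** edges. Before a vertical link is accepted it
must pass, in increasing order of computational cost:

1. **Distance rule**: the x–y distance must be strictly less than the sum of
   the two nodes' radii (half the minor axis each), optionally scaled by a
   coefficient (default 1).
2. **Skip rule** (skipping moves only): at most 2 slices skipped, and each
   of the six shape descriptors must change by no more than
   `shape_change_limit` percent (default 30). The reference value is floored
   per factor (1 for the dimensionless ones, 10 px² for area, 2 px for the
   minor axis): eccentricity of a near-circular lumen hovers near zero and a
   raw relative change would reject nearly every skip.
3. **Bidirectional rule**: the reverse search from the candidate must select
   the original node.
4. **ML validation** (when a classifier is configured; see below).

**Registration.** Neighbouring slices are locally registered around the
current node by exhaustive normalised cross-correlation over integer shifts
(default window half-width 16 px, range ±8 px); candidate positions are
corrected by the offset for the distance computations and the offset is
reversed once the link is committed, so stored coordinates stay in each
slice's own frame and offsets never accumulate. Flat windows return a zero
offset flagged with zero confidence.

**Skipping.** Dead ends may be bridged by skipping 1–2 slices, but only when
the direction buffer (last 5 vertical move directions, ≥60% agreement with
the attempted direction) shows consistent motion and at least
`refractory_period` (default 10) accepted moves have passed since the last
skip — skipping from every dead end would be the fastest way onto the wrong
nephron.

**r_track default.** When not set explicitly it is derived as 1.5× the mean
nearest-neighbour spacing between cross sections, with a 25 px fallback for
sparse stacks where no slice holds two cross sections.

**Reconstruction.** The tracked path is the longest root-to-leaf chain of
the parent map (ties broken towards the deepest terminal slice, then the
lowest node id); shorter branches are discarded as probable interstitial
links. Each point carries half its cross section's minor axis as a radius
and a provenance flag. `evaluate_against_truth()` computes per-slice
residuals and reports **α** (fraction of tracked points within the residual
threshold of the truth on the same slice — accuracy) and **β** (fraction of
truth points matched — extent). The default threshold is 15 px, the scale
below which residuals concentrate for correctly tracked tubules; it is
configurable.

**Manual correction.** When the open list empties, an optional
`correction_provider` callback is shown the deepest dead end and may return
a bridge coordinate; the bridged node is marked `manual` in the output.
This realises manual intervention non-interactively: tests drive it from
phantom ground truth, a CLI could drive it from user input.

## Machine-learned move validation

A move between two cross sections is described by 66 features: the 6
shape-factor means and 6 differences, the x–y distance, the relative z
position in the stack, the image difference (1, or 2–3 across skips), the
registration offset (dx, dy), both 24-point shape profiles, and the Pearson
correlation of the profiles. Five output classes are used: (1) a normal
move between circular cross sections, (2) a normal move involving elongated
cross sections, (3) an abnormal move (interstitial tissue or vessel), (4) a
glomerulus move, and (5) an inner-medulla move. Argmax voting over five
one-vs-all learners yields the decision: classes 1–2 accept the move, 3
rejects it, 4 terminates the branch (the glomerulus has been reached), and 5
is a *region signal* that switches tracking to unidirectional mode for the
inner medulla (it is not a validity verdict, and is excluded from
valid/invalid accuracy summaries).

Two families are implemented from scratch (no R ML package is assumed):

* a feed-forward **neural network** with one hidden layer (default 20
  logistic units) trained by L-BFGS on penalised cross-entropy; a winning
  valid class is accepted only if its score reaches the threshold (default
  0.3), and raising the threshold monotonically tightens invalid-move
  rejection;
* an **SVM with RBF kernel** (default width 5, cost 10) trained by a
  compact SMO solver in C++. The kernel width plays the same sensitivity
  role as the network threshold.

Features are z-scored with parameters fitted on the training split only;
the split defaults to 0.7 : 0.15 : 0.15. Training-example capture runs the
tracker in capture mode, which records every candidate within the tracking
radius (not only the nearest): the plausible-but-wrong moves are exactly
what the classifier must learn to reject, and without them classes 3–4
would be starved — the feedback loop between tracking and training.

## The phantom generator

`generate_phantom()` renders tubes as dark wall annuli around bright lumens
on a mid-intensity tissue background surrounded by bright glass, and records
every centerline, per-slice shift and per-pixel label as ground truth. The
stated world and its defaults:

* **Geometry**: a 160×160 px, 200-slice stack; lumen radius 12 px in the
  cortex narrowing to 4 px at a transition at slice 120 via the same sigmoid
  used by the parameter schedule; 3 px walls; centerlines are smoothed
  random walks (per-slice step SD 1.2 px, 9-slice moving average), which
  reproduces tortuosity qualitatively.
* **Nuisance processes**: Gaussian intensity noise (SD 0.02), per-slice
  integer translational misalignment drawn from N(0, sd²) — 2 px SD in the
  standard test world, 4 px when emulating the residual misalignment of
  registered real stacks — thin bright clutter bars (area well under the
  lumen working range, never touching each other), optional smeared
  rectangular artefacts, optional blanked slices, and an optional large
  high-solidity glomerulus surrogate blob at the tube origin.
* **Intensity model**: three levels (background 0.95, tissue 0.45, lumen
  0.85, wall 0.18, clutter 0.8) plus noise. Real toluidine-blue texture,
  internally segmented glomeruli and stain variability are *not* emulated,
  so a green phantom test establishes algorithmic correctness on well-posed
  geometry, not segmentation robustness on real histology.

Everything is reproducible from the spec's seed, and the generator restores
the caller's RNG state.

## Numerical and design notes

* Strict inequalities follow the tracking-radius and distance-rule
  definitions everywhere; boundary candidates at exactly `r_track` are
  rejected.
* Component labels follow raster-scan order of first occurrence, so
  segmentation output is deterministic.
* The move-validation order (distance → skip → bidirectional → ML) follows
  computational cost; a reporting mode (`record_all_rules`) evaluates every
  rule per rejected move so overlap between rules can be tallied.
* Degenerate inputs have defined answers: single-pixel components get
  eccentricity 0, aspect ratio 1, minor axis 1; flat registration windows
  return zero offset with zero confidence; an empty graph reconstructs to an
  empty path; α is an error (and β zero) for an empty path.
* The environment provides no R image-IO package, so stacks are exchanged
  as ASCII PGM directories with a JSON sidecar; binary stacks round-trip
  exactly.

## Limitations

The tracker is greedy and local: a single wrong link can carry the path onto
another structure, and such errors are not detectable without ground truth.
Whole-stack rigid/non-rigid registration, interactive correction, watershed
segmentation (rejected for over-segmenting elongated lumens) and
photorealistic phantom rendering are out of scope. Classifier accuracies
quoted by the tests describe the synthetic move distribution; they do not
transfer to real histology without retraining on captured, hand-labelled
moves.
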