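---
title: "Methods: dynamic contour evolution and graph-based cell tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic contour evolution and graph-based cell tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dpetrack)
```

# Scope and model overview

`dpetrack` quantifies single-cell behavior in grayscale time-lapse
microscopy through two coupled stages. The segmentation stage represents
each cell as an explicit closed polygon ("contour") that is evolved from a
coarse initialization to the cell boundary; the tracking stage links the
per-frame instances into identity-stable trajectories with a bipartite
graph whose edges carry multi-feature similarities. Downstream modules turn
tracks into morphometry (perimeter, area, circularity, aspect ratio) and
migration statistics (origin-normalized trajectories, path lengths, cohort
comparisons).

Everything is implemented as explicit matrix computations in R. There is no
GPU or deep-learning framework underneath: the learnable layers (the
Fourier-KAN convolutions, the detection and offset heads, the graph message
passing and edge readout) are small enough that analytic gradients and
full-batch descent on the trained heads suffice at the desk scale this
package targets. The convolutional backbone stays at its seeded random
initialization (a random-features regime) while the linear heads on top of
it are trained; this keeps every training run deterministic, seconds-fast
and fully reproducible, at the cost of the representational ceiling a
fine-tuned backbone would have. The package is a faithful, testable,
desk-scale formulation of the approach, not a GPU-scale training harness.

# Segmentation

## FT-KAN backbone

The feature extractor is a two-block convolutional stem (3x3 kernels,
stride 2, tanh nonlinearities) followed by two Fourier-KAN convolutions,
giving a three-level pyramid at strides 4/8/16 with 16/32/64 channels. In a
KAN-style convolution every scalar weight is replaced by a learnable
univariate function; here that function is a truncated Fourier series

phi(x) = sum_{k=1..G} a_k cos(k s x) + b_k sin(k s x),

with G = 3 harmonics by default. Because the basis is fixed, a whole FT-KAN
convolution reduces to cos/sin feature expansion followed by an ordinary
im2col matrix product, which is why it runs comfortably on one CPU (a
256x256 frame passes in well under a second). The tanh stem keeps features
in (-1, 1); the angular input scale s = pi/3 then maps arguments well
inside one period, so the Fourier activations cannot alias. Where the
trained-network literature leaves the placement of such blocks open, we put
them after the stem with fixed 3x3 windows; "dynamic receptive field"
behavior comes from the learnable per-tap activation shape, not from
deformable sampling.

## Detection and initial contours

Detection is a center-heatmap head: a 1x1 linear map on the stride-4 level
produces a sigmoid peak map, decoded by 3x3 local maxima above `score_thr`
(default 0.4) with greedy box-IoU non-maximum suppression (default 0.5). A
second linear head regresses log box sizes at the peak. Each detection
seeds an ellipse inscribed in its box with `n_vertices` = 128 equally
angle-spaced vertices, positively oriented.

## Boundary Feature Enhancement and MLP offsets

Two sequential per-vertex offset heads refine the ellipse before the
landmark stage (the two-head reading of the pipeline is a design choice;
the alternative single-head reading collapses them into one map):

* **BFE** concatenates the bilinearly sampled stride-4 feature vector at
  each vertex with a one-hot encoding of the local Freeman chain-code
  direction (8 directions) and maps it linearly to a 2-D offset.
* **MLP offsets** mix the per-vertex features with a circular kernel-3 1-D
  convolution along the contour and a tanh MLP, for a configurable number
  of passes.

Both heads bound their output through tanh x `r_max` (default 4 px), and
both are zero-initialized, so an untrained segmenter degrades gracefully to
the plain ellipse pipeline — the ablation identity the test suite checks.

## Landmarks

The landmark extractor is deliberately classical so the refinement loop is
testable without any training. Within a margin around the instance:

1. the patch is denoised (1-px Gaussian), and boundary saliency points are
   taken as the gradient-magnitude ridge — Canny-style non-maximum
   suppression along the quantized gradient direction, thresholded at 30%
   of the patch maximum, with sub-pixel refinement by a parabola fit along
   the gradient;
2. ridge points are restricted to a slightly dilated connected component
   of the thresholded patch around the instance centroid, which excludes
   boundaries of neighboring cells that fall inside the window;
3. protrusion-tip candidates are angular local maxima of the radial
   distance of that component's boundary from the centroid, up-weighted
   (weight 2 vs at most 1 for ridge points) because tips carry the
   thin-protrusion signal that plain ridge pulls tend to under-serve.

A flat patch falls back to the current contour vertices, so the stage never
fails on empty input.

## Dynamic Profile Evolution

DPE iteratively stretches or contracts contour vertices toward the
landmark field until convergence. Per iteration:

* every vertex takes a step toward its nearest landmark — the full capped
  pull `alpha * w * min(|pull|, capture_radius)` along the landmark
  direction, weighted by normalized saliency `w`;
* every landmark additionally attracts its nearest vertex (a reverse,
  Chamfer-style term); without it, elongated cell ends whose boundary is
  far from all vertices would never be covered, because the forward term
  only ever consults the nearest landmark of each vertex;
* top-saliency anchors (the protrusion tips) each pull one dedicated
  vertex, so thin protrusions are entered rather than bridged;
* the step field is smoothed along the contour (circular 3-point average),
  geometrically damped by `damping^(iteration-1)`, and trust-region capped
  so the mean displacement never increases from one iteration to the next;
* vertices are redistributed by arc length between iterations.

Iteration stops when the mean vertex displacement drops below `tol`
(default 0.05 px) or after `max_iter` iterations. Defaults are alpha = 0.7,
`max_iter` = 80, damping = 0.97, capture radius 12 px: a smaller step size
(0.5) with a 50-iteration budget systematically under-reached the concave
regions between protrusions on the star benchmark, which is why the larger
step with explicit damping and the monotone trust region is the default —
the damping and cap restore the stability a small step would otherwise
provide. An optional learned residual head (`beta`) can displace vertices
from backbone features; it is zero-initialized and off by default, making
the documented attraction rule the entire default behavior. Should the
final polygon self-intersect, vertices are reprojected by angular sorting
about the centroid (an exact repair for star-shaped regions, a controlled
approximation otherwise); the property suite checks simplicity across
hundreds of seeded fixtures.

## Postprocessing and training

Postprocessing smooths each contour with a circular moving average (window
5), drops instances under `min_area` (30 px^2) and deduplicates pairs with
IoU above 0.8, keeping the higher score. The trainer optimizes the
detection head (penalty-reduced focal-style BCE against Gaussian center
heatmaps), the size head (L2 on log sizes, with the step clipped by the
feature Gram trace so the quadratic objective cannot diverge), and the BFE
head (smooth-L1 through the tanh bound against arc-length-aligned ground
truth polygons; alignment picks the cyclic vertex rotation with least total
distance to the ellipse initialization). Feature dropout at probability
`dropout_p` regularizes all heads. The learning-rate schedule is the
stepped decay L_{i+1} = L_i * gamma applied every `decay_every` epochs
(closed form L0 * gamma^floor(epoch/decay_every)); 1e-5 with gamma 0.1
every 50 epochs is the reference configuration for full-scale training,
while the desk-scale trainer defaults to larger rates appropriate for its
linear heads.

# Tracking

## Graph construction

For consecutive frames, the Top-K highest-score instances per frame (ties
broken by larger area, then list order; K applied per frame) become the two
node sets of a bipartite graph. Pairs whose centroids are closer than the
gate radius (3x the mean equivalent cell diameter by default) receive a
directed edge pair. The initial edge feature is a fully connected layer on
the 3-vector (polygon IoU, appearance cosine similarity, bounded contour
similarity), plus a +-1 direction flag that keeps e_ij and e_ji distinct;
with identity weights the first three dimensions are the similarities
themselves.

Contour similarity is 1 - dH/(dH + D): dH the symmetric Hausdorff distance
between centroid-aligned boundary samples and D the mean semi-major axis of
the two minimum-area rotated rectangles. Alignment happens before the
Hausdorff computation, making the measure translation-invariant — the
unaligned alternative would conflate displacement with shape change, which
is exactly what the separate IoU term already measures. Shape similarity is
the sum of three bounded terms (area ratio, aspect-ratio agreement, contour
similarity), so it lives in [0, 3].

## Mahalanobis weighting

Edge updates are conditioned on the Mahalanobis distance
((v_i - v_j)' M (v_i - v_j))^(1/2) between node appearance features. The
printed form of this distance in the source method places the covariance
Sigma itself, not its inverse, inside the quadratic form; the standard
definition uses the inverse. The package defaults to the statistically
conventional choice — the inverse of the (diagonal, ridge-stabilized)
empirical feature covariance of the two frames — and exposes
`mhd_matrix = "literal_sigma"` to reproduce the literal printed form, plus
`"identity"` (in which case the distance is exactly Euclidean). The
discrepancy is surfaced as configuration rather than silently resolved.

## Message passing and Edge CLAS

Each of T rounds (default 3) updates every directed edge as
e^t = e^0 + tanh(W_e [e^0; e^{t-1}; v_i; v_j; MhD; shape]) — a residual
form, so the raw similarities stay visible to the readout — and then every
node by a learned map of its incident edge features, summed, through a
residual tanh update. The node-update rule and the handling of the two edge
directions are this package's design (the method source leaves them
unstated): messages use a shared linear map, and the Edge CLAS confidence
is the mean of the two per-direction sigmoid readouts of
[e^T; e^0; MhD; shape], which makes S_sim symmetric by construction and
equal to 0.5 for an untrained (zero) readout.

Training fits only the logistic readout (binary cross-entropy on edges
labeled by ground-truth identity agreement) over features produced by the
seeded, fixed message-passing weights — the same random-features stance as
the segmenter, chosen for determinism and speed.

## Matching and lifecycle

S_sim is thresholded at S_tau (default 0.5) and the surviving edges enter
an optimal one-to-one assignment (Hungarian algorithm, maximizing total
S_sim). The threshold rule alone would permit many-to-one matchings; the
assignment resolves them optimally, and on graphs small enough to
enumerate, the test suite verifies equality with brute force. Unmatched
new-frame instances become births; unmatched old-frame tracks enter an
occluded state and re-enter the next graph with their last-seen contour and
features for up to `max_gap` frames (default 3) before terminating. No
motion extrapolation is applied by default: at the frame rates targeted
here cells move a fraction of a diameter per frame, so last-seen geometry
gates correctly; a constant-velocity predictor would be the natural
extension where that assumption fails. Track ids are assigned in creation
order and never reused.

# Metrics

Detection quality follows the COCO conventions: greedy score-ordered
matching per IoU threshold over 0.50:0.05:0.95, 101-point interpolated AP,
AR as the mean best recall over thresholds, area classes small/mid/large at
32^2 and 96^2 px^2 (the threshold set over which AR averages, and the area
cutoffs, are unstated in the source; COCO's are adopted). Tracking follows
CLEAR-MOT: per-frame correspondence at IoU >= 0.5 (gated centroid distance
when only point tracks are available), identity persistence before optimal
per-frame assignment, MOTA = 1 - (FN + FP + IDS)/GT, and IDF1 from a global
optimal identity matching on co-occurrence counts.

# The synthetic generator

The generator is the package's study system, and its defaults are the
emulation target, not tuning knobs: moderately elongated spindle-like cells
(base ellipse, axis ratio 0.55, mean radius 16 px with s.d. 2) bearing 2-5
thin protrusions (Gaussian angular bumps, mean length 8 px, angular width
0.25 rad, placed at jittered regular angles so spikes never merge), with
per-cell perimeters concentrating around 90-120 px — about 70-95 um at the
default 0.8 um/px. Acquisition follows 10-minute frame intervals over 20 h,
i.e. 121 frames per sequence. Motion is a persistent random walk
(gamma-distributed steps with mean 0.65 px/frame, wrapped-normal heading
changes with s.d. 0.6 rad, slow body rotation), calibrated so control
cohorts accumulate path lengths of roughly 60 um over the full acquisition;
the "stress" condition multiplies step lengths by a motility factor
(0.5 in the bundled analyses), emulating reduced motility under oxidative
stress. Occlusion has two faces: detection drops (per-frame probability,
capped run length, ground truth untouched) and genuine overlap events
(paired cells steered within a diameter of each other). Rendering is filled
polygons with a 1-px Gaussian soft edge and additive Gaussian noise
(s.d. 8 counts on an 8-bit range), quantized to 8 bits.

Protrusion tips are reported at the exact local maxima of the radial shape
model (the ellipse slope shifts each bump peak slightly off its nominal
angle, so tips are located by continuous maximization; a spike whose
maximum degenerates to its window edge yields no tip). Cells are seeded at
least 2.2 mean radii apart — overlap then arises through motion, not at
initialization.

What the generator does **not** emulate: lensless shadow-image optics and
its contrast transfer, intensity heterogeneity within cells, shape
remodeling beyond rigid rotation, division and lineage, photobleaching,
drift, and dense colony growth. Tests passing on these scenes therefore
demonstrate algorithmic correctness and calibrated behavior under the
stated conditions — not segmentation accuracy on real HT22/BV2 recordings,
which are not distributed with their source publication.

# Numerical choices and degenerate inputs

* Polygon IoU is exact clipping, not rasterization: polygon A is fanned
  into signed triangles about its centroid and B is Sutherland-Hodgman
  clipped against each (convex) triangle; signed areas sum to the exact
  intersection area for simple polygons. Degenerate (near-zero-area)
  triangles are skipped; disjoint bounding boxes short-circuit to 0.
* Contours are normalized at construction to positive shoelace
  orientation; fewer than 3 vertices, or any non-finite coordinate, is an
  error.
* `resample_contour` iterates its equal-arc-length pass to a fixed point
  (equal chord spacing), which makes resampling idempotent to machine-level
  tolerance rather than only approximately.
* The minimum-area rectangle comes from rotating calipers on the convex
  hull; zero-extent polygons are errors for aspect ratio.
* Mahalanobis weighting matrices must be symmetric PSD (checked); the
  empirical covariance is used diagonally with a 1e-6 ridge because at
  typical per-frame instance counts a full covariance would be singular.
* Hungarian assignment runs on a square-padded matrix; forbidden or
  sub-threshold pairs contribute zero and are stripped from the result, so
  the optimum over admissible matchings is preserved.
* Ties in Top-K break by larger area then list position; ties in greedy AP
  matching break toward the higher IoU.
* The polynomial config hash and all seeds stay below 2^31.

# Problem sizes

The bundled analyses and checks run, by design, at desk scale: segmenter
training on 200 synthetic 96x96 frames (3 cells each) for 30 epochs with 50
held-out frames; tracker training on 8 sequences of 8 cells x 10 frames;
the occlusion benchmark on 20 cells over 50 frames of a 320x320 scene with
10% detection drops of 1-2 frames; motility cohorts of 200 cells per
condition over the full 121-frame acquisition (ground-truth-only
simulation); geometry oracles on 100 seeded polygon pairs at 8x
supersampling. These sizes are the package's reference configuration —
large enough to exercise every code path and small enough that a full run
completes in minutes on one CPU.

# Known limitations

* The random-features training regime bounds achievable accuracy on real,
  low-contrast data; the architecture supports, but the package does not
  ship, full backbone optimization.
* The landmark extractor assumes cells are locally the dominant intensity
  structure; heavily textured backgrounds would need a learned saliency
  source (the `beta` residual head is the hook for it).
* Self-intersection repair is exact only for star-shaped regions.
* Heavily overlapping cells segment as merged components until they
  separate; identity continuity across such events is the tracker's job,
  and detection drops emulate the resulting gaps.
* The CLEAR-MOT implementation counts IDS per GT-track reassignment under
  identity persistence; conventions differ across published toolkits in
  edge cases (e.g. re-acquisition after long gaps).
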