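# dpetrack

Contour-based instance segmentation and identity-stable tracking of cells
in grayscale time-lapse microscopy, with the downstream morphometry and
migration analyses that long-term live-cell monitoring needs. The package
targets the regime where classical pixel labeling struggles: moderately
elongated cells with thin protrusions, low-contrast soft edges, and
transient partial occlusion that fragments naive trackers' identities.

It is written for quantitative cell biologists and image-analysis
developers who want a fully scriptable, deterministic, CPU-only toolchain:
every stage is an exported R function, every learnable part trains in
seconds from a seed, and a synthetic scene generator with complete ground
truth makes every claim testable.

## The model in brief

**Segmentation** represents each cell as an explicit polygon evolved to the
boundary:

1. An FT-KAN convolutional backbone extracts a 3-level feature pyramid
   (strides 4/8/16). In a Kolmogorov-Arnold (KAN) convolution each scalar
   weight is a learnable univariate function; here a truncated Fourier
   series `phi(x) = sum_k a_k cos(k s x) + b_k sin(k s x)`, so the layer
   reduces to cos/sin expansion plus an ordinary convolution.
2. A center-heatmap head detects cells; an ellipse inscribed in each box
   (128 vertices) seeds the contour.
3. Boundary Feature Enhancement (BFE) predicts bounded per-vertex offsets
   from sampled features concatenated with the local Freeman chain-code
   direction; a circular-convolution MLP head refines further.
4. Dynamic Profile Evolution (DPE) extracts landmarks — the sub-pixel
   gradient-magnitude ridge plus protrusion-tip candidates (angular radial
   maxima) — and iteratively stretches or contracts vertices toward them
   (damped, trust-region capped) until the mean displacement falls below
   tolerance. Smoothing, noise removal and IoU deduplication finish the
   instance set.

**Tracking** builds a bipartite graph between consecutive frames over the
Top-K detections. Initial edge features embed
`(IoU_ij, cosine similarity, contour similarity)`; message-passing rounds
update edges as `e_ij^t = f_e(e_ij^0, e_ij^{t-1}, v_i^{t-1}, v_j^t,
MhD_ij, shape_ij)` with the Mahalanobis distance
`MhD = ((v_i - v_j)' M (v_i - v_j))^{1/2}` and a three-term shape
similarity. An Edge-CLAS readout scores each pair with `S_sim` in [0, 1];
pairs above the threshold `S_tau` enter an optimal one-to-one assignment.
Unmatched tracks survive occlusion for up to `max_gap` frames.

**Quantification** computes per-cell perimeter (um), area (um^2),
circularity `4*pi*A/P^2` and min-area-rectangle aspect ratio, plus
origin-normalized trajectories, arc-length path lengths, and descriptive
cohort comparisons. Detection is scored with COCO-style AP/AR and tracking
with CLEAR-MOT (MOTA, IDS, FP, FN) and IDF1.

## Worked example

Train the desk-scale segmenter on simulated scenes, segment a fresh frame,
and quantify it:

```r
library(dpetrack)

train <- segmenter_training_data(60, seed = 0)
model <- train_segmenter(train,
                         training_schedule(L0 = 1, gamma = 0.5,
                                           decay_every = 10, epochs = 20),
                         seed = 0)
tail(model$log$loss, 1)
#> [1] 0.4381

scene <- scene_config(n_cells = 3, width = 96, height = 96, duration = 0,
                      radius_mean = 10, radius_sd = 1.5,
                      n_protrusions = c(1, 3), protrusion_len = 5, seed = 42)
sim <- simulate_sequence(scene)
inst <- segment_frame(sim$frames[[1]], model, score_thr = 0.3)
inst[[1]]
#> <cell_instance frame=0 id=? score=0.649 vertices=128>

morphology_table(inst, pixel_size = 0.8)
#>   frame id perimeter area circularity aspect_ratio
#> 1     0 NA      63.3  251       0.788        0.567
#> 2     0 NA      57.0  189       0.732        0.737
#> 3     0 NA      51.1  180       0.866        0.694
```

All three simulated cells are recovered; the perimeters (51-63 um at
0.8 um/px), sub-unity circularities and aspect ratios around 0.6-0.7
describe moderately elongated cells with protrusions. Scoring against the
generator's ground truth:

```r
gtp <- lapply(sim$gt$instances[[1]], function(z)
  list(frame = 0L, polygon = z$polygon))
ev <- average_precision(inst, gtp)
sprintf("AP50 = %.2f, AP = %.2f", ev$ap50, ev$ap)
#> [1] "AP50 = 1.00, AP = 0.96"
```

Tracking and migration analysis run the same way from per-frame instances
(`link_tracks()`, `tracks_to_trajectories()`, `path_length()`,
`cohort_compare()`), or from the shell:

```sh
Rscript inst/cli/dpetrack.R simulate --out-dir sim/ --seed 4
Rscript inst/cli/dpetrack.R segment  --images sim/stack.tif --out instances.json
Rscript inst/cli/dpetrack.R track    --instances instances.json --out tracks.csv
Rscript inst/cli/dpetrack.R evaluate --pred tracks.csv --gt sim/gt_tracks.csv --out report.json
Rscript inst/cli/dpetrack.R analyze  --tracks tracks.csv --instances instances.json --out analysis/
```

## Layout

| Path | Contents |
| --- | --- |
| `R/geometry.R` | contours, chain codes, morphometry, IoU, similarities |
| `R/backbone.R` | FT-KAN activations/convolutions, pyramid extractor |
| `R/segmenter.R` | detection, BFE/MLP offsets, landmarks, DPE, training |
| `R/tracker.R` | frame graphs, message passing, Edge CLAS, lifecycle |
| `R/metrics.R` | COCO-style AP/AR, CLEAR-MOT + IDF1 |
| `R/simulate.R` | synthetic scenes, motion, occlusion, ground truth |
| `R/quantify.R` | morphology tables, trajectories, cohorts |
| `R/io.R`, `R/cli.R` | JSON/CSV/TIFF/YAML interchange, CLI |
| `vignettes/dpetrack-methods.Rmd` | the methods notes: models, defaults, limitations |
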