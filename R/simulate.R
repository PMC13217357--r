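#' Synthetic time-lapse scene configuration
#'
#' Defaults emulate spindle-shaped hippocampal-neuron-like cells imaged at
#' 10-minute intervals over 20 h (121 frames): moderately elongated bodies of
#' ~80-120 px perimeter with a few thin protrusions, persistent-random-walk
#' motion slow enough that trajectories accumulate tens of micrometers over
#' the acquisition, low-contrast rendering with soft edges and additive
#' Gaussian noise. The "stress" motility multiplier scales step lengths to
#' mimic reduced motility under oxidative stress.
#'
#' @param width,height scene size in px.
#' @param n_cells number of cells.
#' @param radius_mean,radius_sd base ellipse mean radius (px).
#' @param axis_ratio minor/major axis ratio of the body ellipse.
#' @param n_protrusions integer range (min, max) of protrusion spikes.
#' @param protrusion_len mean protrusion length (px).
#' @param protrusion_width angular half-width of a protrusion (radians).
#' @param step_mean mean per-frame step length (px).
#' @param turn_sd s.d. of the per-frame heading change (radians); lower =
#'   more persistent walks.
#' @param stress_multiplier motility multiplier (< 1 slows cells down).
#' @param drop_prob per-frame probability that a visible cell is dropped
#'   from the detection stream (occlusion model).
#' @param max_consecutive_drops cap on consecutive dropped frames per cell.
#' @param overlap_event_rate fraction of cell pairs steered to pass within
#'   one diameter of each other (true partial occlusion).
#' @param noise_sd additive Gaussian noise s.d. (8-bit counts).
#' @param background,foreground background / cell intensity (8-bit counts).
#' @param frame_interval acquisition interval (minutes).
#' @param duration total acquisition (minutes).
#' @param pixel_size micrometres per pixel (used downstream by quantify).
#' @param seed RNG seed; fixes the whole sequence bit-exactly.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(width = 256L, height = 256L, n_cells = 12L,
                         radius_mean = 16, radius_sd = 2, axis_ratio = 0.55,
                         n_protrusions = c(2L, 5L), protrusion_len = 8,
                         protrusion_width = 0.25,
                         step_mean = 0.65, turn_sd = 0.6,
                         stress_multiplier = 1,
                         drop_prob = 0, max_consecutive_drops = 2L,
                         overlap_event_rate = 0,
                         noise_sd = 8, background = 40, foreground = 150,
                         frame_interval = 10, duration = 1200,
                         pixel_size = 0.8, seed = 0L) {
  cfg <- as.list(environment())
  stopifnot(width > 0, height > 0, n_cells >= 1, radius_mean > 0,
            axis_ratio > 0, axis_ratio <= 1,
            drop_prob >= 0, drop_prob <= 1,
            overlap_event_rate >= 0, overlap_event_rate <= 1,
            frame_interval > 0, duration >= 0, pixel_size > 0)
  class(cfg) <- "scene_config"
  cfg
}

#' Number of frames for an acquisition
#'
#' A sequence imaged for `duration` minutes at `interval`-minute spacing
#' contains duration/interval + 1 frames (both endpoints captured); 20 h at
#' 10-minute intervals gives 121 frames.
#'
#' @param duration total time (minutes). @param interval frame spacing (minutes).
#' @export
frame_count <- function(duration, interval) {
  if (interval <= 0) stop("frame_count: interval must be positive")
  k <- duration / interval
  if (abs(k - round(k)) > 1e-9)
    stop("frame_count: interval does not divide duration")
  as.integer(round(k)) + 1L
}

#' Generate one protrusion-bearing cell shape
#'
#' Radial model about the cell center: an ellipse base plus k smooth angular
#' bumps (protrusions). The polygon is star-shaped, hence always simple.
#' Protrusion tips are returned exactly (angle and radius of each bump peak).
#' Circularity decreases as the number or length of protrusions grows.
#'
#' @param params a [scene_config()] (shape fields are used).
#' @param rng optional integer seed applied locally; when NULL the current
#'   RNG state is consumed.
#' @param n_vertices polygon resolution.
#' @return list(contour, tips) with coordinates centered on (0, 0).
#' @export
generate_cell_shape <- function(params = scene_config(), rng = NULL,
                                n_vertices = 96L) {
  if (!is.null(rng)) set.seed(rng)
  a <- max(stats::rnorm(1, params$radius_mean, params$radius_sd), 4)
  b <- a * params$axis_ratio
  kr <- params$n_protrusions
  k <- if (kr[1] >= kr[2]) kr[1] else sample(kr[1]:kr[2], 1L)
  phi <- stats::runif(1, 0, 2 * pi)  # body orientation
  if (k > 0) {
    # jittered regular spacing keeps spikes >= 3 widths apart, so spikes
    # never merge and each tip is a genuine radial local maximum
    jit <- max(pi / k - 1.5 * params$protrusion_width, 0)
    ang <- (2 * pi * (seq_len(k) - 1L) / k + stats::runif(1, 0, 2 * pi) +
              stats::runif(k, -jit, jit)) %% (2 * pi)
    ang <- sort(ang)
    amp <- pmax(stats::rnorm(k, params$protrusion_len, params$protrusion_len / 4), 2.5)
  } else {
    ang <- numeric(0); amp <- numeric(0)
  }
  radial <- function(theta) {
    # theta measured in the body frame
    r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    if (k > 0) {
      for (i in seq_len(k)) {
        d <- (theta - ang[i] + pi) %% (2 * pi) - pi
        r <- r + amp[i] * exp(-d^2 / (2 * params$protrusion_width^2))
      }
    }
    r
  }
  # tips are the exact local maxima of the radial model near each spike
  # (the ellipse slope shifts the bump peak slightly); spikes whose maximum
  # degenerates to the window edge are not genuine protrusions and carry no
  # tip
  tip_ang <- numeric(0)
  if (k > 0) {
    pw <- params$protrusion_width
    for (i in seq_len(k)) {
      opt <- stats::optimize(radial, c(ang[i] - 1.5 * pw, ang[i] + 1.5 * pw),
                             maximum = TRUE, tol = 1e-9)
      interior <- min(opt$maximum - (ang[i] - 1.5 * pw),
                      (ang[i] + 1.5 * pw) - opt$maximum) > 1e-3
      if (interior) tip_ang <- c(tip_ang, opt$maximum)
    }
  }
  theta <- sort(unique(c(seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)],
                         tip_ang %% (2 * pi))))
  r <- radial(theta)
  xy <- cbind(r * cos(theta + phi), r * sin(theta + phi))
  tips <- if (length(tip_ang)) {
    rt <- radial(tip_ang)
    cbind(rt * cos(tip_ang + phi), rt * sin(tip_ang + phi))
  } else matrix(numeric(0), ncol = 2L)
  list(contour = contour(xy), tips = tips)
}

# separable Gaussian blur of an image matrix (rows = y)
gaussian_blur <- function(img, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad <- function(m, r) {
    m <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
    cbind(m[, rep(1L, r), drop = FALSE], m, m[, rep(ncol(m), r), drop = FALSE])
  }
  p <- pad(img, r)
  H <- nrow(img); W <- ncol(img)
  tmp <- matrix(0, H, W + 2L * r)
  for (i in seq_along(k)) tmp <- tmp + k[i] * p[(i - 1L) + seq_len(H), ]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * tmp[, (i - 1L) + seq_len(W)]
  out
}

# rasterize a polygon into an existing canvas (center-of-pixel ownership)
rasterize_into <- function(canvas, poly, value) {
  H <- nrow(canvas); W <- ncol(canvas)
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  xs <- max(1L, floor(xr[1])):min(W, ceiling(xr[2]))
  ys <- max(1L, floor(yr[1])):min(H, ceiling(yr[2]))
  if (!length(xs) || !length(ys)) return(canvas)
  # pixel (col=x, row=y) center at (x - 0.5, y - 0.5)
  gx <- rep(xs - 0.5, each = length(ys))
  gy <- rep(ys - 0.5, times = length(xs))
  inside <- points_in_polygon(gx, gy, poly)
  if (any(inside)) {
    rows <- rep(ys, times = length(xs))[inside]
    cols <- rep(xs, each = length(ys))[inside]
    canvas[cbind(rows, cols)] <- value
  }
  canvas
}

#' Simulate a time-lapse sequence with full ground truth
#'
#' Cells follow a persistent random walk (gamma-distributed step lengths,
#' wrapped-normal heading changes) with slow body rotation; frames are
#' rendered as filled polygons with a 1-px Gaussian soft edge plus additive
#' Gaussian noise, quantized to 8 bits. Ground truth carries every instance
#' polygon (persistent ids), protrusion-tip lists, and visibility flags.
#'
#' @param cfg a [scene_config()].
#' @param render render image frames (TRUE); FALSE produces ground truth
#'   only (frames = NULL), e.g. for large motion-statistics cohorts.
#' @return list(frames, gt): `frames` is a list of H x W matrices in [0, 1];
#'   `gt` is a list with `instances` (per-frame list of id/polygon/tips/
#'   visible), `tracks` (data.frame frame, id, x, y) and `cfg`.
#' @export
simulate_sequence <- function(cfg = scene_config(), render = TRUE) {
  set.seed(cfg$seed)
  n_frames <- frame_count(cfg$duration, cfg$frame_interval)
  margin <- cfg$radius_mean + cfg$protrusion_len + 4
  shapes <- lapply(seq_len(cfg$n_cells), function(i)
    generate_cell_shape(cfg))
  # seed positions with a minimum separation (suspended cells settle apart;
  # overlap/occlusion events arise later through motion)
  min_sep <- 2.2 * cfg$radius_mean
  pos <- matrix(0, cfg$n_cells, 2L)
  for (i in seq_len(cfg$n_cells)) {
    for (try in seq_len(200L)) {
      p <- c(stats::runif(1, margin, cfg$width - margin),
             stats::runif(1, margin, cfg$height - margin))
      if (i == 1L || min(sqrt(rowSums(sweep(pos[seq_len(i - 1L), , drop = FALSE],
                                            2L, p)^2))) >= min_sep) break
    }
    pos[i, ] <- p
  }
  heading <- stats::runif(cfg$n_cells, 0, 2 * pi)
  rotrate <- stats::rnorm(cfg$n_cells, 0, 0.03)
  rot <- numeric(cfg$n_cells)
  # overlap events: steer selected pairs toward each other mid-sequence
  n_pairs <- floor(cfg$overlap_event_rate * cfg$n_cells / 2)
  pairs <- if (n_pairs > 0)
    matrix(sample(cfg$n_cells, 2L * n_pairs), ncol = 2L) else NULL

  frames <- vector("list", n_frames)
  inst <- vector("list", n_frames)
  tr <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    clean <- if (render) matrix(cfg$background, cfg$height, cfg$width)
    per_frame <- vector("list", cfg$n_cells)
    for (i in seq_len(cfg$n_cells)) {
      th <- rot[i]
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      poly <- unclass(shapes[[i]]$contour) %*% t(R)
      poly <- sweep(poly, 2L, pos[i, ], "+")
      tips <- if (nrow(shapes[[i]]$tips)) {
        sweep(shapes[[i]]$tips %*% t(R), 2L, pos[i, ], "+")
      } else shapes[[i]]$tips
      if (render) clean <- rasterize_into(clean, poly, cfg$foreground)
      per_frame[[i]] <- list(id = i, polygon = contour(poly), tips = tips,
                             visible = TRUE)
    }
    inst[[f]] <- per_frame
    tr[[f]] <- data.frame(frame = f - 1L, id = seq_len(cfg$n_cells),
                          x = pos[, 1L], y = pos[, 2L])
    if (render) {
      img <- gaussian_blur(clean, 1)
      img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
      frames[[f]] <- matrix(pmin(pmax(round(img), 0), 255), nrow(img)) / 255
    }

    if (f < n_frames) {
      step <- stats::rgamma(cfg$n_cells, shape = 2,
                            scale = cfg$step_mean / 2) * cfg$stress_multiplier
      heading <- heading + stats::rnorm(cfg$n_cells, 0, cfg$turn_sd)
      if (!is.null(pairs) && f > n_frames / 4 && f < n_frames / 2) {
        for (p in seq_len(nrow(pairs))) {
          a <- pairs[p, 1L]; b <- pairs[p, 2L]
          heading[a] <- atan2(pos[b, 2L] - pos[a, 2L], pos[b, 1L] - pos[a, 1L])
          heading[b] <- atan2(pos[a, 2L] - pos[b, 2L], pos[a, 1L] - pos[b, 1L])
        }
      }
      pos <- pos + step * cbind(cos(heading), sin(heading))
      pos[, 1L] <- pmin(pmax(pos[, 1L], margin), cfg$width - margin)
      pos[, 2L] <- pmin(pmax(pos[, 2L], margin), cfg$height - margin)
      rot <- rot + rotrate
    }
  }
  list(frames = if (render) frames,
       gt = list(instances = inst,
                 tracks = do.call(rbind, tr),
                 cfg = cfg))
}

#' Inject detection drops (occlusion model) into a ground-truth stream
#'
#' Flags frames in which a cell goes missing from the detection stream
#' (ground truth itself is untouched). Runs of consecutive drops never
#' exceed `cfg$max_consecutive_drops`.
#'
#' @param gt ground truth from [simulate_sequence()].
#' @param cfg the scene config (drop fields are used).
#' @param rng optional integer seed applied locally.
#' @return gt with per-instance `visible` flags updated.
#' @export
inject_occlusion <- function(gt, cfg, rng = NULL) {
  if (!is.null(rng)) set.seed(rng)
  n_frames <- length(gt$instances)
  ids <- unique(unlist(lapply(gt$instances, function(fr)
    vapply(fr, function(z) z$id, integer(1)))))
  for (id in ids) {
    run <- 0L
    for (f in seq_len(n_frames)) {
      k <- which(vapply(gt$instances[[f]], function(z) z$id, integer(1)) == id)
      if (!length(k)) next
      drop <- run < cfg$max_consecutive_drops &&
        stats::runif(1) < cfg$drop_prob
      if (drop) {
        gt$instances[[f]][[k]]$visible <- FALSE
        run <- run + 1L
      } else run <- 0L
    }
  }
  gt
}

# detections (cell_instance list per frame) from GT visibility flags;
# appearance features from the shape (and image when given)
detections_from_gt <- function(gt, frames = NULL) {
  lapply(seq_along(gt$instances), function(f) {
    vis <- Filter(function(z) isTRUE(z$visible), gt$instances[[f]])
    lapply(vis, function(z) {
      app <- appearance_descriptor(z$polygon,
                                   if (!is.null(frames)) frames[[f]] else NULL)
      cell_instance(frame = f - 1L, contour = z$polygon, score = 1,
                    appearance = app, id = z$id)
    })
  })
}
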