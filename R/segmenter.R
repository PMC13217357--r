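# Instance-segmentation head: center-heatmap detection on the stride-4
# pyramid level, ellipse initial contours, chain-code Boundary Feature
# Enhancement (BFE) offsets, circular-convolution MLP vertex offsets, and
# the Dynamic Profile Evolution (DPE) landmark-driven refinement loop.

#' Initialize segmenter head weights
#'
#' Heads are linear maps on backbone features: a 1-channel center heatmap, a
#' 2-channel log box-size regressor, the BFE per-vertex offset head
#' (features + one-hot chain-code direction), and `mlp_passes` refinement
#' passes of a circular 1-D convolution + MLP offset head. All offset heads
#' are zero-initialized, so an untrained segmenter reduces to the initial
#' ellipse contour (ablation identity).
#'
#' @param n_features channels of the stride-4 pyramid level.
#' @param hidden hidden width of the MLP offset head.
#' @param mlp_passes number of MLP refinement passes.
#' @param r_max offset bound in px (offsets pass through tanh * r_max).
#' @export
seg_weights_init <- function(n_features = 16L, hidden = 32L, mlp_passes = 1L,
                             r_max = 4) {
  passes <- lapply(seq_len(mlp_passes), function(i)
    list(W1 = matrix(0, 3L * n_features, hidden), b1 = numeric(hidden),
         W2 = matrix(0, hidden, 2L), b2 = numeric(2L)))
  structure(list(n_features = n_features, r_max = r_max,
                 det_w = matrix(0, n_features, 1L), det_b = -2,
                 size_w = matrix(0, n_features, 2L),
                 size_b = c(log(30), log(30)),
                 bfe_W = matrix(0, n_features + 8L, 2L), bfe_b = numeric(2L),
                 dpe_W = matrix(0, n_features, 2L), dpe_b = numeric(2L),
                 mlp = passes),
            class = "seg_weights")
}

# axis-aligned bbox IoU; boxes are (x, y, w, h)
bbox_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  u <- a[3] * a[4] + b[3] * b[4] - inter
  if (u <= 0) 0 else inter / u
}

#' Decode detections from a center heatmap
#'
#' Peak-local-max decoding: cells that are 3x3 local maxima with score above
#' `score_thr` become candidates; greedy non-maximum suppression on box IoU
#' keeps the higher-scored of overlapping candidates.
#'
#' @param heatmap H x W score matrix in [0, 1].
#' @param size_map H x W x 2 array of box (w, h) in px (constant fallback
#'   allowed via a 2-vector).
#' @param stride feature-to-image stride.
#' @param score_thr detection threshold. @param nms_iou suppression IoU.
#' @return list of detections: list(bbox, center, score).
#' @export
detect_peaks <- function(heatmap, size_map = c(30, 30), stride = 4L,
                         score_thr = 0.4, nms_iou = 0.5) {
  H <- nrow(heatmap); W <- ncol(heatmap)
  if (length(size_map) == 2L)
    size_map <- array(rep(size_map, each = H * W), c(H, W, 2L))
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- heatmap
  ismax <- heatmap >= score_thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ismax <- ismax & (heatmap >= pad[2:(H + 1L) + dy, 2:(W + 1L) + dx])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  ord <- order(heatmap[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  dets <- list()
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1L]; c <- idx[i, 2L]
    cx <- (c - 0.5) * stride; cy <- (r - 0.5) * stride
    w <- max(size_map[r, c, 1L], 2); h <- max(size_map[r, c, 2L], 2)
    box <- c(cx - w / 2, cy - h / 2, w, h)
    keep <- TRUE
    for (d in dets) if (bbox_iou(box, d$bbox) > nms_iou) { keep <- FALSE; break }
    if (keep) dets[[length(dets) + 1L]] <-
        list(bbox = box, center = c(cx, cy), score = heatmap[r, c])
  }
  dets
}

#' Run the detection head on a feature pyramid
#'
#' @param pyramid a [backbone_forward()] pyramid.
#' @param weights a [seg_weights_init()] object.
#' @inheritParams detect_peaks
#' @export
detect <- function(pyramid, weights, score_thr = 0.4, nms_iou = 0.5) {
  lev <- pyramid$levels[[1L]]
  f <- lev$fmap
  H <- dim(f)[1L]; W <- dim(f)[2L]
  Fm <- matrix(f, H * W, dim(f)[3L])
  hm <- matrix(stats::plogis(Fm %*% weights$det_w + weights$det_b), H, W)
  sz <- array(exp(sweep(Fm %*% weights$size_w, 2L, c(weights$size_b), "+")),
              c(H, W, 2L))
  detect_peaks(hm, sz, lev$stride, score_thr, nms_iou)
}

#' Ellipse initial contour inscribed in a bounding box
#'
#' @param bbox (x, y, w, h). @param n_vertices vertex count (>= 8),
#'   equally spaced in angle, positively oriented.
#' @export
init_contour <- function(bbox, n_vertices = 128L) {
  if (n_vertices < 8L) stop("init_contour: n_vertices must be >= 8")
  if (bbox[3] <= 0 || bbox[4] <= 0) stop("init_contour: degenerate box")
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  contour(cbind(bbox[1] + bbox[3] / 2 + bbox[3] / 2 * cos(th),
                bbox[2] + bbox[4] / 2 + bbox[4] / 2 * sin(th)))
}

# per-vertex BFE input: sampled stride-4 features + one-hot local
# chain-code direction of the discretized contour
bfe_inputs <- function(c, pyramid) {
  lev <- pyramid$levels[[1L]]
  feat <- sample_fmap(lev$fmap, unclass(c), lev$stride)
  dirs <- contour_chain_dirs(c)
  onehot <- matrix(0, nrow(c), 8L)
  onehot[cbind(seq_len(nrow(c)), dirs + 1L)] <- 1
  cbind(feat, onehot)
}

#' Boundary Feature Enhancement offsets
#'
#' Predicts a bounded 2-D offset per vertex from the concatenation of the
#' bilinearly sampled backbone feature vector at the vertex and the one-hot
#' local chain-code direction; output contour = input + offsets. A
#' zero-weight head is the identity. |offset| <= r_max via tanh.
#'
#' @param c contour (fixed vertex count). @param pyramid feature pyramid.
#' @param weights seg weights. @export
bfe_offsets <- function(c, pyramid, weights) {
  c <- as_contour(c)
  X <- bfe_inputs(c, pyramid)
  off <- tanh(sweep(X %*% weights$bfe_W, 2L, weights$bfe_b, "+")) * weights$r_max
  contour(unclass(c) + off)
}

#' MLP vertex-offset refinement
#'
#' Each pass samples backbone features at the current vertices, mixes them
#' with a circular kernel-3 1-D convolution along the contour, and maps the
#' result through a tanh MLP to bounded per-vertex offsets. Zero-weight
#' passes are the identity, so k passes with zeroed trailing passes equal
#' fewer passes.
#'
#' @inheritParams bfe_offsets
#' @param passes how many configured passes to apply (default: all).
#' @export
mlp_offsets <- function(c, pyramid, weights, passes = length(weights$mlp)) {
  c <- as_contour(c)
  lev <- pyramid$levels[[1L]]
  for (p in seq_len(passes)) {
    pw <- weights$mlp[[p]]
    X <- sample_fmap(lev$fmap, unclass(c), lev$stride)
    n <- nrow(X)
    prv <- X[c(n, seq_len(n - 1L)), , drop = FALSE]
    nxt <- X[c(2:n, 1L), , drop = FALSE]
    Xc <- cbind(prv, X, nxt)
    h <- tanh(sweep(Xc %*% pw$W1, 2L, pw$b1, "+"))
    off <- tanh(sweep(h %*% pw$W2, 2L, pw$b2, "+")) * weights$r_max
    c <- contour(unclass(c) + off)
  }
  c
}

# Sobel gradient (components + magnitude) of an image matrix
gradient_sobel <- function(img) {
  H <- nrow(img); W <- ncol(img)
  p <- rbind(img[1L, ], img, img[H, ])
  p <- cbind(p[, 1L], p, p[, W])
  gx <- (p[2:(H + 1), 3:(W + 2)] - p[2:(H + 1), 1:W]) * 2 +
    (p[1:H, 3:(W + 2)] - p[1:H, 1:W]) +
    (p[3:(H + 2), 3:(W + 2)] - p[3:(H + 2), 1:W])
  gy <- (p[3:(H + 2), 2:(W + 1)] - p[1:H, 2:(W + 1)]) * 2 +
    (p[3:(H + 2), 1:W] - p[1:H, 1:W]) +
    (p[3:(H + 2), 3:(W + 2)] - p[1:H, 3:(W + 2)])
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

gradient_magnitude <- function(img) gradient_sobel(img)$mag

# n-fold 4-neighborhood erosion (TRUE = deep interior)
erode_mask <- function(mask, n = 1L) {
  for (i in seq_len(n)) {
    er <- mask
    er[-1, ] <- er[-1, ] & mask[-nrow(mask), ]
    er[-nrow(er), ] <- er[-nrow(er), ] & mask[-1, ]
    er[, -1] <- er[, -1] & mask[, -ncol(mask)]
    er[, -ncol(er)] <- er[, -ncol(er)] & mask[, -1]
    mask <- er
  }
  mask
}

# connected component (8-neighborhood) of a logical mask containing the
# given (row, col); nearest TRUE pixel is used when the start is FALSE
flood_component <- function(mask, start_rc) {
  H <- nrow(mask); W <- ncol(mask)
  r0 <- min(max(start_rc[1L], 1L), H); c0 <- min(max(start_rc[2L], 1L), W)
  if (!mask[r0, c0]) {
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) return(mask & FALSE)
    k <- which.min((idx[, 1L] - r0)^2 + (idx[, 2L] - c0)^2)
    r0 <- idx[k, 1L]; c0 <- idx[k, 2L]
  }
  comp <- matrix(FALSE, H, W)
  queue <- integer(H * W)
  queue[1L] <- (c0 - 1L) * H + r0
  head <- 1L; tail <- 1L
  comp[queue[1L]] <- TRUE
  while (head <= tail) {
    p <- queue[head]; head <- head + 1L
    r <- ((p - 1L) %% H) + 1L; cc <- ((p - 1L) %/% H) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1L || rr > H || c2 < 1L || c2 > W) next
      q <- (c2 - 1L) * H + rr
      if (mask[q] && !comp[q]) {
        comp[q] <- TRUE
        tail <- tail + 1L
        queue[tail] <- q
      }
    }
  }
  comp
}

# gradient-magnitude ridge: non-maximum suppression along the gradient
# direction (Canny-style), yielding a ~1 px wide boundary ring
gradient_ridge <- function(img, rel_thr = 0.3) {
  gs <- gradient_sobel(img)
  g <- gs$mag
  H <- nrow(g); W <- ncol(g)
  gmax <- max(g)
  if (gmax <= 0) return(matrix(FALSE, H, W))
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- g
  ang <- atan2(gs$gy, gs$gx)
  # quantize direction to 4 axes (0, 45, 90, 135 degrees)
  q <- (round(ang / (pi / 4)) %% 4L)
  sh <- function(dy, dx) pad[2:(H + 1L) + dy, 2:(W + 1L) + dx]
  ridge <- matrix(FALSE, H, W)
  dirs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L),
               `3` = c(1L, -1L))
  for (k in 0:3) {
    d <- dirs[[k + 1L]]
    sel <- q == k
    ridge[sel] <- g[sel] >= sh(d[1L], d[2L])[sel] &
      g[sel] >= sh(-d[1L], -d[2L])[sel]
  }
  out <- ridge & (g >= rel_thr * gmax)
  attr(out, "g") <- g
  attr(out, "q") <- q
  out
}

# sub-pixel ridge positions: parabola fit of the gradient magnitude along
# the quantized gradient direction at each ridge pixel. idx: (row, col).
# Returns per-point (dx, dy) offsets in px, clamped to +-0.5.
ridge_subpixel <- function(ridge, idx) {
  g <- attr(ridge, "g"); q <- attr(ridge, "q")
  H <- nrow(g); W <- ncol(g)
  dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  off <- matrix(0, nrow(idx), 2L)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1L]; cc <- idx[i, 2L]
    d <- dirs[[q[r, cc] + 1L]]
    rm <- r - d[1L]; cm <- cc - d[2L]; rp <- r + d[1L]; cp <- cc + d[2L]
    if (min(rm, rp) < 1L || max(rm, rp) > H ||
        min(cm, cp) < 1L || max(cm, cp) > W) next
    g0 <- g[r, cc]; gm <- g[rm, cm]; gp <- g[rp, cp]
    den <- gm - 2 * g0 + gp
    if (abs(den) < 1e-12) next
    delta <- max(min(0.5 * (gm - gp) / den, 0.5), -0.5)
    off[i, ] <- delta * c(d[2L], d[1L])   # (dx, dy)
  }
  off
}

#' Extract cellular landmarks around an instance
#'
#' Classical landmark extractor: boundary saliency points are 3x3 local
#' maxima of the Sobel gradient magnitude inside a margin around the
#' instance; protrusion-tip candidates are angular local maxima of the
#' radial distance of the thresholded object boundary from the instance
#' centroid (up-weighted, since tips carry the thin-protrusion signal).
#' Falls back to the contour vertices on flat patches.
#'
#' @param image full frame matrix in [0, 1].
#' @param c current instance contour (image coordinates).
#' @param margin px around the contour bbox searched for landmarks.
#' @param max_points cap on returned landmarks (highest weights kept).
#' @return list(points = n x 2 (x, y), weights = saliency >= 0).
#' @export
extract_landmarks <- function(image, c, margin = 12, max_points = 600L) {
  c <- as_contour(c)
  H <- nrow(image); W <- ncol(image)
  x0 <- max(1L, floor(min(c[, 1L]) - margin))
  x1 <- min(W, ceiling(max(c[, 1L]) + margin))
  y0 <- max(1L, floor(min(c[, 2L]) - margin))
  y1 <- min(H, ceiling(max(c[, 2L]) + margin))
  patch <- image[y0:y1, x0:x1, drop = FALSE]
  fallback <- list(points = unclass(c), weights = rep(1, nrow(c)))
  if (nrow(patch) < 3L || ncol(patch) < 3L) return(fallback)
  patch <- gaussian_blur(patch, 1)   # denoise before saliency
  g <- gradient_magnitude(patch)
  gmax <- max(g)
  if (gmax < 1e-3 || diff(range(patch)) < 1e-3) return(fallback)
  ctr <- polygon_centroid(c)

  # object support: connected thresholded component around the centroid,
  # dilated slightly; keeps this instance's boundary and excludes ridges
  # belonging to neighboring cells inside the search window
  thr <- (max(patch) + min(patch)) / 2
  mask <- patch > thr
  if (mean(mask) > 0.5) mask <- !mask   # object darker than background
  comp <- flood_component(mask, c(round(ctr[2] - y0 + 1.5),
                                  round(ctr[1] - x0 + 1.5)))
  dil <- comp
  for (rep_i in 1:3) {
    d2m <- dil
    d2m[-1, ] <- d2m[-1, ] | dil[-nrow(dil), ]
    d2m[-nrow(d2m), ] <- d2m[-nrow(d2m), ] | dil[-1, ]
    d2m[, -1] <- d2m[, -1] | dil[, -ncol(dil)]
    d2m[, -ncol(d2m)] <- d2m[, -ncol(d2m)] | dil[, -1]
    dil <- d2m
  }
  ridge <- gradient_ridge(patch)
  keep <- ridge & dil & !erode_mask(comp, 2L)
  idx <- which(keep, arr.ind = TRUE)
  pts <- if (nrow(idx)) {
    # pixel centers in full-image coordinates, sub-pixel refined along the
    # gradient direction
    sp <- ridge_subpixel(ridge, idx)
    cbind(x0 + idx[, 2L] - 1.5 + sp[, 1L], y0 + idx[, 1L] - 1.5 + sp[, 2L])
  } else matrix(numeric(0), ncol = 2L)
  wts <- if (nrow(idx)) g[idx] / gmax else numeric(0)

  # protrusion tips: angular radial maxima of the component boundary
  if (any(comp)) {
    bidx <- which(comp & !erode_mask(comp, 1L), arr.ind = TRUE)
    if (nrow(bidx) > 4L) {
      bx <- x0 + bidx[, 2L] - 1.5; by <- y0 + bidx[, 1L] - 1.5
      rr <- sqrt((bx - ctr[1])^2 + (by - ctr[2])^2)
      aa <- atan2(by - ctr[2], bx - ctr[1])
      nb <- 72L
      bin <- pmin(floor((aa + pi) / (2 * pi) * nb) + 1L, nb)
      rmax <- tapply(rr, factor(bin, levels = seq_len(nb)), max)
      rmax[is.na(rmax)] <- 0
      prv <- c(rmax[nb], rmax[-nb]); nxt <- c(rmax[-1L], rmax[1L])
      tipbin <- which(rmax > 0 & rmax >= prv & rmax >= nxt & rmax > stats::median(rr))
      for (b in tipbin) {
        in_b <- which(bin == b)
        j <- in_b[which.max(rr[in_b])]
        pts <- rbind(pts, c(bx[j], by[j]))
        wts <- c(wts, 2)
      }
    }
  }
  if (!nrow(pts)) return(fallback)
  if (nrow(pts) > max_points) {
    keep <- order(wts, decreasing = TRUE)[seq_len(max_points)]
    pts <- pts[keep, , drop = FALSE]; wts <- wts[keep]
  }
  list(points = pts, weights = wts)
}

#' Dynamic Profile Evolution
#'
#' Iteratively stretches or contracts each vertex toward its nearest
#' landmark: the step is alpha * w * min(|pull|, capture_radius) along the
#' pull direction, where pull is the vector to the nearest landmark and w
#' its normalized saliency; top-saliency anchor landmarks (protrusion tips)
#' additionally attract one dedicated vertex each, and an optional learned
#' residual offset head (beta; zero by default) can adjust the front. The
#' step field is smoothed along the contour, geometrically damped, and
#' trust-region capped so the mean displacement never increases. Vertices
#' are redistributed by arc length between iterations; iteration stops when
#' the mean vertex displacement falls below `tol` or `max_iter` is reached.
#' Self-intersecting results are repaired by angular reprojection about the
#' centroid.
#'
#' @param c starting contour. @param landmarks from [extract_landmarks()].
#' @param pyramid optional feature pyramid (only used by the beta head).
#' @param weights optional seg weights carrying a beta head.
#' @param max_iter,tol convergence controls (px).
#' @param alpha attraction step size. @param beta residual gain.
#' @param capture_radius px cap on the per-step pull.
#' @param damping geometric per-iteration step decay in (0, 1]; guarantees a
#'   shrinking displacement tail on noisy saliency fields.
#' @return list(contour, iterations, displacement) where displacement is the
#'   per-iteration mean |step| log.
#' @export
dpe_evolve <- function(c, landmarks, pyramid = NULL, weights = NULL,
                       max_iter = 80L, tol = 0.05, alpha = 0.7, beta = 0,
                       capture_radius = 12, damping = 0.97) {
  if (max_iter < 1L) stop("dpe_evolve: max_iter must be >= 1")
  if (tol <= 0) stop("dpe_evolve: tol must be positive")
  c <- as_contour(c)
  P <- landmarks$points
  if (is.null(dim(P)) || nrow(P) == 0L)
    return(list(contour = c, iterations = 0L, displacement = numeric(0)))
  wn <- landmarks$weights / max(landmarks$weights)
  n <- nrow(c)
  disp_log <- numeric(0)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    v <- unclass(c)
    d2 <- outer(v[, 1L], P[, 1L], "-")^2 + outer(v[, 2L], P[, 2L], "-")^2
    jmin <- max.col(-d2, ties.method = "first")
    lm <- P[jmin, , drop = FALSE]
    # full pull toward the nearest landmark (vertices are stretched or
    # contracted toward landmarks), capped at the capture radius; the sign
    # of its normal component distinguishes expansion from contraction
    pvx <- lm[, 1L] - v[, 1L]; pvy <- lm[, 2L] - v[, 2L]
    pd <- sqrt(pvx^2 + pvy^2)
    gain <- ifelse(pd > 1e-9,
                   alpha * damping^(it - 1L) * wn[jmin] *
                     pmin(pd, capture_radius) / pd, 0)
    sx <- gain * pvx; sy <- gain * pvy
    # reverse term: every landmark also attracts its nearest vertex, so
    # distant boundary segments (elongated ends) are always covered
    kmin <- max.col(-t(d2), ties.method = "first")
    rx <- P[, 1L] - v[kmin, 1L]; ry <- P[, 2L] - v[kmin, 2L]
    sw <- rowsum(wn, kmin)
    sxk <- rowsum(wn * rx, kmin) / sw
    syk <- rowsum(wn * ry, kmin) / sw
    ks <- as.integer(rownames(sw))
    rd <- sqrt(sxk^2 + syk^2)
    rgain <- ifelse(rd > 1e-9,
                    alpha * damping^(it - 1L) * pmin(rd, capture_radius) / rd, 0)
    sx[ks] <- sx[ks] + rgain * sxk
    sy[ks] <- sy[ks] + rgain * syk
    # circular moving average of the step field: regularizes the front
    # without disturbing fixed points (zero steps stay zero)
    sx <- (sx + sx[c(n, seq_len(n - 1L))] + sx[c(2:n, 1L)]) / 3
    sy <- (sy + sy[c(n, seq_len(n - 1L))] + sy[c(2:n, 1L)]) / 3
    v2 <- v + cbind(sx, sy)
    # anchor landmarks (top-saliency, e.g. protrusion tips) stretch their
    # nearest vertex directly toward them so thin protrusions are entered
    anchors <- which(wn >= 0.99)
    taken <- integer(0)
    for (ai in anchors) {
      dax <- P[ai, 1L] - v2[, 1L]; day <- P[ai, 2L] - v2[, 2L]
      da <- sqrt(dax^2 + day^2)
      if (length(taken)) da[taken] <- Inf   # one vertex per anchor
      k <- which.min(da)
      taken <- c(taken, k)
      if (is.finite(da[k]) && da[k] > 1e-9) {
        gain <- alpha * damping^(it - 1L) * min(da[k], capture_radius) / da[k]
        v2[k, ] <- v2[k, ] + gain * c(dax[k], day[k])
      }
    }
    if (beta != 0 && !is.null(pyramid) && !is.null(weights)) {
      lev <- pyramid$levels[[1L]]
      X <- sample_fmap(lev$fmap, v2, lev$stride)
      res <- tanh(sweep(X %*% weights$dpe_W, 2L, weights$dpe_b, "+")) * weights$r_max
      v2 <- v2 + beta * res
    }
    dv <- v2 - v
    md <- mean(sqrt(rowSums(dv^2)))
    # monotone trust region: never let the mean displacement grow from one
    # iteration to the next (scale the whole step field down instead)
    if (length(disp_log) && md > disp_log[length(disp_log)] && md > 0) {
      sc <- disp_log[length(disp_log)] / md
      v2 <- v + dv * sc
      md <- md * sc
    }
    disp_log <- c(disp_log, md)
    iterations <- it
    c <- contour(v2)
    if (md < tol) break
    c <- resample_contour(c, n)
  }
  if (!contour_is_simple(c)) {
    v <- unclass(c)
    ctr <- polygon_centroid(c)
    ang <- atan2(v[, 2L] - ctr[2], v[, 1L] - ctr[1])
    c <- resample_contour(contour(v[order(ang), , drop = FALSE]), n)
  }
  list(contour = c, iterations = iterations, displacement = disp_log)
}

#' Postprocess segmented instances
#'
#' Smooths each contour (circular moving average), drops instances below
#' `min_area`, and deduplicates near-identical instances (mutual polygon IoU
#' above `dedup_iou`, higher score kept).
#'
#' @param instances list of [cell_instance()].
#' @param min_area px^2 noise threshold. @param smooth_window odd window.
#' @param dedup_iou IoU above which two instances are duplicates.
#' @export
postprocess <- function(instances, min_area = 30, smooth_window = 5L,
                        dedup_iou = 0.8) {
  instances <- lapply(instances, function(ins) {
    ins$contour <- smooth_contour(ins$contour, smooth_window)
    ins
  })
  instances <- remove_noise(instances, min_area)
  if (length(instances) < 2L || dedup_iou >= 1) return(instances)
  ord <- order(vapply(instances, function(z) z$score, numeric(1)),
               decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    dup <- FALSE
    for (k in kept) if (polygon_iou(instances[[i]]$contour, k$contour) > dedup_iou) {
      dup <- TRUE; break
    }
    if (!dup) kept[[length(kept) + 1L]] <- instances[[i]]
  }
  kept
}

#' Training schedule with stepped learning-rate decay
#'
#' @param L0 initial learning rate. @param gamma decay factor in (0, 1].
#' @param decay_every epochs between decays. @param epochs total epochs.
#' @param batch_size batch size. @param dropout_p feature dropout probability.
#' @export
training_schedule <- function(L0 = 1e-5, gamma = 0.1, decay_every = 50L,
                              epochs = 200L, batch_size = 4L, dropout_p = 0.1) {
  stopifnot(L0 > 0, gamma > 0, gamma <= 1, decay_every >= 1, epochs >= 1,
            dropout_p >= 0, dropout_p < 1)
  structure(list(L0 = L0, gamma = gamma, decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 dropout_p = dropout_p),
            class = "training_schedule")
}

#' Learning rate at a given epoch
#'
#' Stepped decay L_{i+1} = L_i * gamma applied every `decay_every` epochs:
#' closed form L0 * gamma^floor(epoch / decay_every).
#'
#' @param schedule a [training_schedule()]. @param epoch 0-based epoch.
#' @export
lr_at_epoch <- function(schedule, epoch) {
  if (any(epoch < 0)) stop("lr_at_epoch: epoch must be >= 0")
  schedule$L0 * schedule$gamma^floor(epoch / schedule$decay_every)
}

# smooth-L1 (Huber, delta = 1) value and derivative
smooth_l1 <- function(r) {
  a <- abs(r)
  list(val = ifelse(a < 1, 0.5 * r^2, a - 0.5),
       grad = ifelse(a < 1, r, sign(r)))
}

# align a GT contour to an init contour: resample to n and choose the cyclic
# rotation (and orientation already normalized) minimizing total distance
align_gt_contour <- function(gt, init_c) {
  n <- nrow(init_c)
  g <- unclass(resample_contour(gt, n))
  v <- unclass(init_c)
  best <- NULL; bestcost <- Inf
  for (s in seq_len(n)) {
    idx <- ((seq_len(n) + s - 2L) %% n) + 1L
    cost <- sum((g[idx, ] - v)^2)
    if (cost < bestcost) { bestcost <- cost; best <- g[idx, , drop = FALSE] }
  }
  best
}

#' Train the segmenter heads on a synthetic dataset
#'
#' Desk-scale trainer: the FT-KAN backbone stays at its seeded random
#' initialization (random-feature regime) and the linear heads are trained
#' with analytic gradients -- penalty-reduced focal loss on the center
#' heatmap, L2 on log box sizes at GT centers, and smooth-L1 on the
#' tanh-bounded BFE vertex offsets against arc-length-aligned GT polygons.
#' Feature dropout (schedule$dropout_p) regularizes the heads. Deterministic
#' given `seed`.
#'
#' @param dataset list of samples: list(image = matrix, polygons = list of
#'   contours).
#' @param schedule a [training_schedule()].
#' @param seed integer seed.
#' @param n_vertices contour vertex count used for the offset head targets.
#' @param verbose print per-epoch loss.
#' @return list(backbone, seg = trained [seg_weights_init()] weights,
#'   log = data.frame(epoch, loss, lr), schedule).
#' @export
train_segmenter <- function(dataset, schedule = training_schedule(),
                            seed = 0L, n_vertices = 128L, verbose = FALSE) {
  if (!length(dataset)) stop("train_segmenter: empty dataset")
  set.seed(seed)
  backbone <- backbone_init(seed)
  C <- backbone$widths[1L]
  w <- seg_weights_init(n_features = C)

  # precompute stride-4 features, heatmap targets, size/offset targets
  feats <- list(); hms <- list(); sizes <- list(); bfeX <- list(); bfeT <- list()
  for (si in seq_along(dataset)) {
    smp <- dataset[[si]]
    pyr <- backbone_forward(smp$image, backbone)
    lev <- pyr$levels[[1L]]
    H4 <- dim(lev$fmap)[1L]; W4 <- dim(lev$fmap)[2L]
    feats[[si]] <- matrix(lev$fmap, H4 * W4, C)
    hm <- matrix(0, H4, W4)
    ctr_cells <- matrix(0L, 0L, 2L); tgt_sz <- matrix(0, 0L, 2L)
    for (poly in smp$polygons) {
      poly <- as_contour(poly)
      ct <- polygon_centroid(poly)
      cc <- pmin(pmax(round(ct[1] / 4 + 0.5), 1L), W4)
      rr <- pmin(pmax(round(ct[2] / 4 + 0.5), 1L), H4)
      for (dy in -3:3) for (dx in -3:3) {
        r2 <- rr + dy; c2 <- cc + dx
        if (r2 >= 1L && r2 <= H4 && c2 >= 1L && c2 <= W4)
          hm[r2, c2] <- max(hm[r2, c2], exp(-(dy^2 + dx^2) / (2 * 1.5^2)))
      }
      ctr_cells <- rbind(ctr_cells, c(rr, cc))
      bw <- diff(range(poly[, 1L])); bh <- diff(range(poly[, 2L]))
      tgt_sz <- rbind(tgt_sz, c(log(max(bw, 2)), log(max(bh, 2))))
      # BFE offset targets from the GT-box ellipse init
      icont <- init_contour(c(min(poly[, 1L]), min(poly[, 2L]), bw, bh),
                            n_vertices)
      gal <- align_gt_contour(poly, icont)
      X <- bfe_inputs(icont, pyr)
      t <- pmin(pmax((gal - unclass(icont)) / w$r_max, -0.97), 0.97)
      bfeX[[length(bfeX) + 1L]] <- X
      bfeT[[length(bfeT) + 1L]] <- t
    }
    hms[[si]] <- hm
    sizes[[si]] <- list(cells = ctr_cells, tgt = tgt_sz, W4 = W4)
  }
  Fall <- do.call(rbind, feats)
  Yall <- unlist(lapply(hms, as.numeric))
  Ypos <- as.numeric(Yall >= 0.999)
  negw <- (1 - Yall)^4
  szX <- do.call(rbind, lapply(seq_along(dataset), function(si) {
    cells <- sizes[[si]]$cells
    if (!nrow(cells)) return(NULL)
    H4 <- nrow(hms[[si]])
    feats[[si]][(cells[, 2L] - 1L) * H4 + cells[, 1L], , drop = FALSE]
  }))
  szT <- do.call(rbind, lapply(sizes, function(z) z$tgt))
  bX <- do.call(rbind, bfeX)
  bT <- do.call(rbind, bfeT)

  npx <- length(Yall); nb <- nrow(bX)
  log_df <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  for (ep in seq_len(schedule$epochs)) {
    lr <- lr_at_epoch(schedule, ep - 1L)
    drop_mask <- if (schedule$dropout_p > 0)
      (stats::runif(C) >= schedule$dropout_p) / (1 - schedule$dropout_p)
    else rep(1, C)
    Fd <- sweep(Fall, 2L, drop_mask, "*")
    # --- detection: penalty-reduced focal-style BCE on the heatmap
    z <- as.numeric(Fd %*% w$det_w) + w$det_b
    p <- stats::plogis(z)
    eps <- 1e-12
    wts <- ifelse(Ypos == 1, 40, negw)
    det_loss <- -sum(wts * (Ypos * log(p + eps) + (1 - Ypos) * log(1 - p + eps))) / npx
    gz <- wts * (p - Ypos) / npx
    w$det_w <- w$det_w - lr * crossprod(Fd, gz)
    w$det_b <- w$det_b - lr * sum(gz)
    # --- box size regression at GT centers (step clipped by the Gram
    # trace so the quadratic objective cannot diverge at large lr)
    size_loss <- 0
    if (!is.null(szX) && nrow(szX)) {
      szXd <- sweep(szX, 2L, drop_mask, "*")
      lr_sz <- min(lr, 0.45 / max(2 * (sum(szXd^2) / nrow(szXd) + 1), 1e-8))
      pred <- sweep(szXd %*% w$size_w, 2L, c(w$size_b), "+")
      r <- pred - szT
      size_loss <- mean(r^2)
      g <- 2 * r / nrow(r)
      w$size_w <- w$size_w - lr_sz * crossprod(szXd, g)
      w$size_b <- w$size_b - lr_sz * colSums(g)
    }
    # --- BFE offsets (smooth-L1 through tanh)
    bXd <- bX
    bXd[, seq_len(C)] <- sweep(bX[, seq_len(C), drop = FALSE], 2L, drop_mask, "*")
    zb <- sweep(bXd %*% w$bfe_W, 2L, w$bfe_b, "+")
    u <- tanh(zb)
    sl <- smooth_l1(u - bT)
    bfe_loss <- mean(sl$val)
    gzb <- sl$grad * (1 - u^2) / nb
    w$bfe_W <- w$bfe_W - lr * crossprod(bXd, gzb)
    w$bfe_b <- w$bfe_b - lr * colSums(gzb)

    total <- det_loss + size_loss + bfe_loss
    log_df <- rbind(log_df, data.frame(epoch = ep, loss = total, lr = lr,
                                       det = det_loss, size = size_loss,
                                       bfe = bfe_loss))
    if (verbose) message(sprintf("epoch %3d  lr %.2e  loss %.5f", ep, lr, total))
  }
  list(backbone = backbone, seg = w, log = log_df, schedule = schedule)
}

#' Segment one frame end to end
#'
#' Detection -> ellipse init -> BFE offsets -> MLP offsets -> landmark
#' extraction -> DPE evolution -> postprocessing.
#'
#' @param image H x W matrix in [0, 1].
#' @param model list(backbone, seg) as returned by [train_segmenter()].
#' @param score_thr,nms_iou detection parameters.
#' @param n_vertices contour vertices.
#' @param min_area,smooth_window,dedup_iou postprocessing parameters.
#' @param frame frame index stored on the instances.
#' @param dpe_args list of overrides for [dpe_evolve()].
#' @export
segment_frame <- function(image, model, frame = 0L, score_thr = 0.4,
                          nms_iou = 0.5, n_vertices = 128L, min_area = 30,
                          smooth_window = 5L, dedup_iou = 0.8,
                          dpe_args = list()) {
  pyr <- backbone_forward(image, model$backbone)
  dets <- detect(pyr, model$seg, score_thr, nms_iou)
  instances <- list()
  for (d in dets) {
    c0 <- init_contour(d$bbox, n_vertices)
    c1 <- bfe_offsets(c0, pyr, model$seg)
    c2 <- mlp_offsets(c1, pyr, model$seg)
    lm <- extract_landmarks(image, c2)
    ev <- do.call(dpe_evolve, c(list(c = c2, landmarks = lm, pyramid = pyr,
                                     weights = model$seg), dpe_args))
    app <- appearance_descriptor(ev$contour, image)
    instances[[length(instances) + 1L]] <-
      cell_instance(frame = frame, contour = ev$contour, score = d$score,
                    appearance = app)
  }
  postprocess(instances, min_area, smooth_window, dedup_iou)
}

#' Appearance descriptor for a cell instance
#'
#' Deterministic node-feature vector for the tracker: 8-bin normalized
#' radial profile of the contour, log area, circularity, aspect ratio, and
#' (when an image is given) mean and s.d. of the interior intensity.
#'
#' @param c contour. @param image optional frame matrix.
#' @return numeric vector of length 13.
#' @export
appearance_descriptor <- function(c, image = NULL) {
  c <- as_contour(c)
  ctr <- polygon_centroid(c)
  v <- unclass(resample_contour(c, 64L))
  r <- sqrt((v[, 1L] - ctr[1])^2 + (v[, 2L] - ctr[2])^2)
  a <- atan2(v[, 2L] - ctr[2], v[, 1L] - ctr[1])
  bin <- pmin(floor((a + pi) / (2 * pi) * 8) + 1L, 8L)
  prof <- tapply(r, factor(bin, levels = 1:8), mean)
  prof[is.na(prof)] <- mean(r)
  prof <- as.numeric(prof) / mean(r)
  mi <- 0; sdi <- 0
  if (!is.null(image)) {
    xs <- max(1L, floor(min(v[, 1L]))):min(ncol(image), ceiling(max(v[, 1L])))
    ys <- max(1L, floor(min(v[, 2L]))):min(nrow(image), ceiling(max(v[, 2L])))
    if (length(xs) > 1L && length(ys) > 1L) {
      gx <- rep(xs - 0.5, each = length(ys))
      gy <- rep(ys - 0.5, times = length(xs))
      inside <- points_in_polygon(gx, gy, c)
      if (sum(inside) > 1L) {
        px <- image[cbind(rep(ys, times = length(xs))[inside],
                          rep(xs, each = length(ys))[inside])]
        mi <- mean(px); sdi <- stats::sd(px)
      }
    }
  }
  c(prof, log1p(polygon_area(c)), circularity(c), aspect_ratio(c), mi, sdi)
}
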