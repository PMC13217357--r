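# Shared fixtures and independent oracles, all generated in code.

unit_square <- function() contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))

rect_contour <- function(w, h, angle = 0, center = c(0, 0)) {
  v <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  contour(sweep(v %*% t(R), 2L, center, "+"))
}

regular_ngon <- function(n, R = 1, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  contour(cbind(center[1] + R * cos(th), center[2] + R * sin(th)))
}

# random convex polygon: convex hull of seeded points
rand_convex_polygon <- function(seed, n_pts = 12L, scale = 10) {
  set.seed(seed)
  p <- matrix(stats::runif(2L * n_pts, 0, scale), ncol = 2L)
  p <- p + matrix(stats::runif(2L, 0, 5), nrow(p), 2L, byrow = TRUE)
  contour(p[grDevices::chull(p[, 1L], p[, 2L]), , drop = FALSE])
}

# --- independent rasterized IoU oracle -------------------------------------
# supersampled point-membership count with its own crossing-number test
# (written separately from the package's clipping code path)
oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  cnt <- rep(0L, length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
    x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
    hit <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    cnt <- cnt + as.integer(hit)
  }
  cnt %% 2L == 1L
}

raster_iou_oracle <- function(a, b, supersample = 8L) {
  a <- unclass(a); b <- unclass(b)
  xr <- range(c(a[, 1L], b[, 1L])); yr <- range(c(a[, 2L], b[, 2L]))
  step <- 1 / supersample
  gx <- seq(xr[1] - step, xr[2] + step, by = step)
  gy <- seq(yr[1] - step, yr[2] + step, by = step)
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  ina <- oracle_point_in_poly(px, py, a)
  inb <- oracle_point_in_poly(px, py, b)
  u <- sum(ina | inb)
  if (u == 0L) return(0)
  sum(ina & inb) / u
}

# clean single-cell star scene; returns image, GT polygon and exact tips
star_fixture <- function(seed, noise_sd = 0) {
  cfg <- scene_config(n_cells = 1L, width = 96L, height = 96L,
                      noise_sd = noise_sd, duration = 0,
                      n_protrusions = c(5L, 5L), protrusion_len = 8,
                      seed = seed)
  sim <- simulate_sequence(cfg)
  z <- sim$gt$instances[[1L]][[1L]]
  list(image = sim$frames[[1L]], polygon = z$polygon, tips = z$tips)
}

# closed 8-connected staircase path along a w x h pixel rectangle perimeter
rect_pixel_path <- function(w, h, x0 = 0L, y0 = 0L) {
  top <- cbind(x0 + 0:(w - 1L), y0)
  right <- cbind(x0 + w - 1L, y0 + 1:(h - 1L))
  bottom <- if (w >= 2L) cbind(x0 + (w - 2L):0, y0 + h - 1L)
  left <- if (h > 2L) cbind(x0, y0 + (h - 2L):1)
  p <- rbind(top, right, bottom, left)
  storage.mode(p) <- "integer"
  dimnames(p) <- NULL
  p
}

# brute-force maximum-score one-to-one matching by permutation enumeration
brute_force_matching_value <- function(S, threshold) {
  n <- nrow(S); m <- ncol(S)
  nn <- max(n, m)
  Sp <- matrix(0, nn, nn)
  Sadm <- S
  Sadm[S <= threshold] <- 0
  Sp[seq_len(n), seq_len(m)] <- Sadm
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- 0
  for (p in perms(seq_len(nn)))
    best <- max(best, sum(Sp[cbind(seq_len(nn), p)]))
  best
}

# labeled detection sequences for tracker training/evaluation
make_labeled_sequences <- function(n_sequences, n_cells = 8L, n_frames = 10L,
                                   seed0 = 0L) {
  lapply(seq_len(n_sequences), function(i) {
    cfg <- scene_config(n_cells = n_cells, width = 192L, height = 192L,
                        duration = (n_frames - 1L) * 10, seed = seed0 + i)
    sim <- simulate_sequence(cfg)
    dpetrack:::detections_from_gt(sim$gt, sim$frames)
  })
}
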