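#' Contour objects
#'
#' A contour is an ordered closed polygon delineating one cell instance,
#' stored as an n x 2 numeric matrix of sub-pixel (x, y) coordinates.
#' Image convention: origin top-left, x rightward, y downward. The closing
#' edge (last vertex back to the first) is implicit. Orientation is
#' normalized so the signed shoelace area is positive ("counter-clockwise"
#' under this module's sign convention).
#'
#' @param xy numeric matrix (or 2-column data.frame) of vertices.
#' @return object of class `dpe_contour` (an n x 2 matrix).
#' @export
contour <- function(xy) {
  xy <- as.matrix(xy)
  if (!is.numeric(xy) || ncol(xy) != 2L)
    stop("contour: vertices must be an n x 2 numeric matrix")
  if (nrow(xy) < 3L)
    stop("invalid contour: fewer than 3 vertices")
  if (!all(is.finite(xy)))
    stop("invalid contour: non-finite coordinates")
  dimnames(xy) <- NULL
  if (shoelace_signed(xy) < 0) xy <- xy[nrow(xy):1L, , drop = FALSE]
  class(xy) <- c("dpe_contour", "matrix", "array")
  xy
}

#' @export
is_contour <- function(x) inherits(x, "dpe_contour")

as_contour <- function(x) if (is_contour(x)) x else contour(x)

# signed shoelace area; positive for the normalized orientation
shoelace_signed <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

#' Polygon area by the shoelace formula
#'
#' @param c a contour (or n x 2 matrix, coerced).
#' @return area in px^2 (positive for simple polygons).
#' @export
polygon_area <- function(c) {
  c <- as_contour(c)
  abs(shoelace_signed(c))
}

#' Polygon perimeter
#'
#' Sum of consecutive-vertex Euclidean distances including the closing edge.
#' @inheritParams polygon_area
#' @return length in px.
#' @export
polygon_perimeter <- function(c) {
  c <- as_contour(c)
  d <- rbind(c[-1L, , drop = FALSE], c[1L, , drop = FALSE]) - c
  sum(sqrt(rowSums(d^2)))
}

#' Area centroid of a polygon
#' @inheritParams polygon_area
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(c) {
  c <- as_contour(c)
  x <- c[, 1L]; y <- c[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Circularity (isoperimetric ratio)
#'
#' 4*pi*Area / Perimeter^2; equals 1 for a disk and decreases as the shape
#' departs from circular. Values can exceed 1 by a small discretization
#' epsilon only for near-degenerate inputs.
#'
#' @inheritParams polygon_area
#' @export
circularity <- function(c) {
  c <- as_contour(c)
  p <- polygon_perimeter(c)
  if (p <= 0) stop("circularity: zero perimeter")
  4 * pi * polygon_area(c) / p^2
}

# minimum-area rotated bounding rectangle via rotating calipers on the hull.
# Returns list(width, height, angle) with width >= height.
min_area_rect <- function(c) {
  c <- as_contour(c)
  h <- grDevices::chull(c[, 1L], c[, 2L])
  hv <- c[h, , drop = FALSE]
  n <- nrow(hv)
  if (n < 2L) stop("min_area_rect: degenerate polygon")
  edges <- rbind(hv[-1L, , drop = FALSE], hv[1L, , drop = FALSE]) - hv
  lens <- sqrt(rowSums(edges^2))
  keep <- lens > 1e-12
  if (!any(keep)) stop("min_area_rect: degenerate polygon")
  angs <- unique(atan2(edges[keep, 2L], edges[keep, 1L]) %% (pi / 2))
  best <- NULL
  for (a in angs) {
    ca <- cos(-a); sa <- sin(-a)
    rx <- hv[, 1L] * ca - hv[, 2L] * sa
    ry <- hv[, 1L] * sa + hv[, 2L] * ca
    w <- diff(range(rx)); hgt <- diff(range(ry))
    if (is.null(best) || w * hgt < best$area)
      best <- list(area = w * hgt, width = max(w, hgt), height = min(w, hgt),
                   angle = a)
  }
  best
}

#' Aspect ratio of the minimum-area rotated bounding rectangle
#'
#' Minor side / major side, in (0, 1]; 1 for a square, small for slivers.
#' Invariant to rigid rotation.
#'
#' @inheritParams polygon_area
#' @export
aspect_ratio <- function(c) {
  r <- min_area_rect(as_contour(c))
  if (r$width <= 1e-12) stop("aspect_ratio: degenerate (zero-size) polygon")
  if (r$height <= 1e-12) stop("aspect_ratio: degenerate (zero-width) polygon")
  r$height / r$width
}

# ---- exact polygon intersection ------------------------------------------
# Sutherland-Hodgman: clip subject polygon (any simple polygon) against one
# convex CCW polygon. Subject and clip are plain n x 2 matrices. Returns the
# clipped polygon (possibly 0 rows).
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    # signed distance: positive = inside (left of edge for CCW clip, i.e.
    # positive-signed-area orientation in this module's convention)
    s <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])
    np <- nrow(out)
    nxt <- c(2:np, 1L)[seq_len(np)]
    if (np == 1L) nxt <- 1L
    s2 <- s[nxt]
    res_x <- numeric(0); res_y <- numeric(0)
    # vectorized construction: for each edge (j -> nxt[j]) emit points
    cur_in <- s >= 0
    nxt_in <- s2 >= 0
    cross <- cur_in != nxt_in
    t <- ifelse(cross, s / (s - s2), 0)
    ix <- out[, 1L] + t * (out[nxt, 1L] - out[, 1L])
    iy <- out[, 2L] + t * (out[nxt, 2L] - out[, 2L])
    # ordering: current point (if inside), then intersection (if crossing)
    keep_cur <- cur_in
    m <- sum(keep_cur) + sum(cross)
    if (m == 0L) return(out[0L, , drop = FALSE])
    ox <- numeric(m); oy <- numeric(m)
    k <- 0L
    for (j in seq_len(np)) {
      if (keep_cur[j]) { k <- k + 1L; ox[k] <- out[j, 1L]; oy[k] <- out[j, 2L] }
      if (cross[j])   { k <- k + 1L; ox[k] <- ix[j];       oy[k] <- iy[j] }
    }
    out <- cbind(ox, oy)
  }
  out
}

#' Intersection-over-union of two polygons
#'
#' Exact polygon clipping (no rasterization): the first polygon is fanned
#' into signed triangles about its centroid; the second is clipped against
#' each triangle (Sutherland-Hodgman) and the signed clipped areas summed,
#' which yields the exact intersection area for simple polygons.
#'
#' @param a,b contours.
#' @return IoU in [0, 1]; 0 for disjoint or degenerate inputs.
#' @export
polygon_iou <- function(a, b) {
  a <- as_contour(a); b <- as_contour(b)
  aa <- polygon_area(a); ab <- polygon_area(b)
  if (aa < 1e-12 || ab < 1e-12) return(0)
  # cheap reject on axis-aligned bounding boxes
  if (max(a[, 1L]) < min(b[, 1L]) || max(b[, 1L]) < min(a[, 1L]) ||
      max(a[, 2L]) < min(b[, 2L]) || max(b[, 2L]) < min(a[, 2L])) return(0)
  inter <- polygon_intersection_area(a, b)
  u <- aa + ab - inter
  if (u <= 0) return(0)
  min(max(inter / u, 0), 1)
}

# exact area of A v B for simple polygons (signed triangle fan about A's
# centroid; each fan triangle is convex so S-H clipping of B is exact)
polygon_intersection_area <- function(a, b) {
  o <- polygon_centroid(a)
  n <- nrow(a)
  bm <- unclass(b)
  total <- 0
  for (i in seq_len(n)) {
    p <- a[i, ]; q <- a[if (i == n) 1L else i + 1L, ]
    s2 <- (p[1L] - o[1L]) * (q[2L] - o[2L]) - (q[1L] - o[1L]) * (p[2L] - o[2L])
    if (abs(s2) < 1e-14) next
    tri <- if (s2 > 0) rbind(o, p, q) else rbind(o, q, p)
    cl <- clip_convex(bm, tri)
    if (nrow(cl) >= 3L) total <- total + sign(s2) * abs(shoelace_signed(cl))
  }
  max(total, 0)
}

#' Bounded contour-shape similarity
#'
#' 1 - dH / (dH + D) where dH is the symmetric Hausdorff distance between
#' the two boundaries after centroid alignment (translation-invariant) and D
#' is the mean of the two semi-major axis lengths (half the major side of
#' the minimum-area rotated rectangle). Equals 1 for congruent translated
#' contours and decays toward 0 with increasing shape discrepancy.
#'
#' @param a,b contours.
#' @param n_samples boundary samples used for the Hausdorff estimate.
#' @export
contour_similarity <- function(a, b, n_samples = 128L) {
  a <- as_contour(a); b <- as_contour(b)
  pa <- resample_contour(a, n_samples); pb <- resample_contour(b, n_samples)
  pa <- sweep(unclass(pa), 2L, polygon_centroid(a))
  pb <- sweep(unclass(pb), 2L, polygon_centroid(b))
  dx <- outer(pa[, 1L], pb[, 1L], "-"); dy <- outer(pa[, 2L], pb[, 2L], "-")
  d2 <- dx * dx + dy * dy
  dh <- sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
  D <- (min_area_rect(a)$width + min_area_rect(b)$width) / 4
  if (dh + D <= 0) return(1)
  1 - dh / (dh + D)
}

#' Multi-term shape similarity between two cell instances
#'
#' Sum of three bounded, translation-invariant terms: area ratio
#' min(A1,A2)/max(A1,A2), aspect-ratio agreement 1 - |r1 - r2|, and
#' [contour_similarity()]. Range [0, 3]; equals 3 for identical shapes.
#'
#' @param a,b `cell_instance` objects or contours.
#' @export
shape_similarity <- function(a, b) {
  ca <- if (is_contour(a)) a else a$contour
  cb <- if (is_contour(b)) b else b$contour
  a1 <- polygon_area(ca); a2 <- polygon_area(cb)
  t_area <- if (max(a1, a2) <= 0) 0 else min(a1, a2) / max(a1, a2)
  t_ar <- 1 - abs(aspect_ratio(ca) - aspect_ratio(cb))
  t_area + t_ar + contour_similarity(ca, cb)
}

# ---- Freeman chain codes --------------------------------------------------
# direction table: code k moves by CHAIN_DIRS[k+1, ] in (x, y), y downward
CHAIN_DIRS <- matrix(c(1L, 0L,   1L, 1L,   0L, 1L,  -1L, 1L,
                       -1L, 0L, -1L, -1L,  0L, -1L,  1L, -1L),
                     ncol = 2L, byrow = TRUE)

#' Encode a closed 8-connected pixel path as a Freeman chain code
#'
#' @param path integer n x 2 matrix of pixel (x, y); consecutive pixels must
#'   be 8-adjacent and the path closes back to its first pixel (a final
#'   repeat of the start pixel is tolerated and stripped).
#' @return list with `start` (first pixel) and `codes` (integers 0-7).
#' @export
chain_encode <- function(path) {
  path <- as.matrix(path)
  storage.mode(path) <- "integer"
  n <- nrow(path)
  if (n >= 2L && all(path[n, ] == path[1L, ])) { path <- path[-n, , drop = FALSE]; n <- n - 1L }
  if (n == 1L) return(structure(list(start = path[1L, ], codes = integer(0)),
                                class = "dpe_chaincode"))
  nxt <- rbind(path[-1L, , drop = FALSE], path[1L, , drop = FALSE])
  d <- nxt - path
  codes <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(CHAIN_DIRS[, 1L] == d[i, 1L] & CHAIN_DIRS[, 2L] == d[i, 2L])
    if (length(hit) != 1L)
      stop("chain_encode: pixels ", i, " and ", i %% n + 1L, " are not 8-adjacent")
    codes[i] <- hit - 1L
  }
  structure(list(start = path[1L, ], codes = codes), class = "dpe_chaincode")
}

#' Decode a Freeman chain code back to its pixel path
#' @param cc object from [chain_encode()].
#' @return integer n x 2 pixel path (closed: applying all codes returns to start).
#' @export
chain_decode <- function(cc) {
  if (!all(cc$codes %in% 0:7)) stop("chain_decode: codes must be in 0..7")
  n <- length(cc$codes)
  if (n == 0L) return(matrix(cc$start, ncol = 2L))
  steps <- CHAIN_DIRS[cc$codes + 1L, , drop = FALSE]
  xy <- rbind(cc$start,
              sweep(apply(steps, 2L, cumsum)[-n, , drop = FALSE], 2L, cc$start, "+"))
  storage.mode(xy) <- "integer"
  dimnames(xy) <- NULL
  xy
}

# local chain-code direction (0..7) at each vertex of a (sub-pixel) contour,
# from the discretized direction to the next vertex
contour_chain_dirs <- function(c) {
  c <- as_contour(c)
  d <- rbind(c[-1L, , drop = FALSE], c[1L, , drop = FALSE]) - c
  ang <- atan2(d[, 2L], d[, 1L])
  (round(ang / (pi / 4)) %% 8L)
}

#' Resample a contour to n equally spaced vertices by arc length
#'
#' Vertex 1 of the output coincides with vertex 1 of the input; the rest are
#' placed at uniform arc-length spacing along the closed boundary.
#'
#' @param c contour. @param n target vertex count (>= 3).
#' @export
resample_contour <- function(c, n) {
  c <- as_contour(c)
  n <- as.integer(n)
  if (n < 3L) stop("resample_contour: n must be >= 3")
  pass <- function(v) {
    pts <- rbind(v, v[1L, , drop = FALSE])
    seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    cs <- c(0, cumsum(seg))
    P <- cs[length(cs)]
    if (P <= 0) stop("resample_contour: zero-length contour")
    target <- (0:(n - 1L)) / n * P
    idx <- findInterval(target, cs, rightmost.closed = TRUE)
    idx[idx >= nrow(pts)] <- nrow(pts) - 1L
    t <- (target - cs[idx]) / pmax(seg[idx], 1e-300)
    pts[idx, , drop = FALSE] + t * (pts[idx + 1L, , drop = FALSE] -
                                      pts[idx, , drop = FALSE])
  }
  # iterate the equal-arc-length pass to its fixed point (equal chord
  # spacing), which makes resampling idempotent
  out <- pass(unclass(c))
  for (i in 1:60) {
    nxt <- pass(out)
    delta <- max(abs(nxt - out))
    out <- nxt
    if (delta < 1e-9) break
  }
  contour(out)
}

#' Circular moving-average smoothing of contour vertices
#' @param c contour. @param window odd window length >= 1 (1 = identity).
#' @export
smooth_contour <- function(c, window = 3L) {
  c <- as_contour(c)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("smooth_contour: window must be odd >= 1")
  if (window == 1L) return(c)
  n <- nrow(c)
  h <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, o) ((i - 1L + o) %% n) + 1L)
  sm <- cbind(rowMeans(matrix(c[idx, 1L], n)), rowMeans(matrix(c[idx, 2L], n)))
  contour(sm)
}

#' Drop instances below a minimum area
#' @param instances list of `cell_instance`. @param min_area px^2 threshold.
#' @export
remove_noise <- function(instances, min_area) {
  Filter(function(ins) polygon_area(ins$contour) >= min_area, instances)
}

# vectorized even-odd point-in-polygon test (used by the rasterizer and tests)
points_in_polygon <- function(px, py, poly) {
  poly <- unclass(as_contour(poly))
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# does the closed polygon self-intersect? brute-force segment pair test
contour_is_simple <- function(c) {
  c <- unclass(as_contour(c))
  n <- nrow(c)
  p1 <- c; p2 <- rbind(c[-1L, , drop = FALSE], c[1L, , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_intersect(p1[i, ], p2[i, ], p1[js, , drop = FALSE],
                               p2[js, , drop = FALSE]))) return(FALSE)
  }
  TRUE
}

# do segment (a, b) and segments (c[k,], d[k,]) properly intersect?
segments_intersect <- function(a, b, c, d) {
  d1 <- (b[1L] - a[1L]) * (c[, 2L] - a[2L]) - (b[2L] - a[2L]) * (c[, 1L] - a[1L])
  d2 <- (b[1L] - a[1L]) * (d[, 2L] - a[2L]) - (b[2L] - a[2L]) * (d[, 1L] - a[1L])
  d3 <- (d[, 1L] - c[, 1L]) * (a[2L] - c[, 2L]) - (d[, 2L] - c[, 2L]) * (a[1L] - c[, 1L])
  d4 <- (d[, 1L] - c[, 1L]) * (b[2L] - c[, 2L]) - (d[, 2L] - c[, 2L]) * (b[1L] - c[, 1L])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}
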