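# Convolutional feature extractor with Fourier-series Kolmogorov-Arnold
# (FT-KAN) layers. Every learnable scalar weight of a KAN-style convolution
# is replaced by a univariate function; here that function is a truncated
# Fourier series, so a whole FT-KAN convolution reduces to cos/sin feature
# expansion followed by an ordinary linear convolution. All layers are plain
# matrix computations (im2col + matmul), deterministic given the seed.

#' FT-KAN activation specification
#'
#' phi(x) = sum_{k=1..G} a_k cos(k s x) + b_k sin(k s x), with s the input
#' scale mapping (bounded) features into an angular domain.
#'
#' @param a,b numeric coefficient vectors of equal length G >= 1.
#' @param input_scale positive scalar s.
#' @export
ftkan_spec <- function(a, b, input_scale = pi / 3) {
  if (length(a) != length(b) || length(a) < 1L)
    stop("ftkan_spec: a and b must have equal length G >= 1")
  if (!all(is.finite(a)) || !all(is.finite(b)) || !is.finite(input_scale))
    stop("ftkan_spec: coefficients must be finite")
  structure(list(G = length(a), a = as.numeric(a), b = as.numeric(b),
                 input_scale = input_scale), class = "ftkan_spec")
}

#' Evaluate an FT-KAN activation
#'
#' @param x numeric (vectorized).
#' @param spec an [ftkan_spec()].
#' @export
ftkan_activation <- function(x, spec) {
  s <- spec$input_scale
  out <- numeric(length(x))
  for (k in seq_len(spec$G))
    out <- out + spec$a[k] * cos(k * s * x) + spec$b[k] * sin(k * s * x)
  out
}

# analytic gradients of phi wrt coefficients and x
ftkan_activation_grad <- function(x, spec) {
  s <- spec$input_scale
  ks <- seq_len(spec$G)
  da <- vapply(ks, function(k) cos(k * s * x), numeric(length(x)))
  db <- vapply(ks, function(k) sin(k * s * x), numeric(length(x)))
  dx <- numeric(length(x))
  for (k in ks)
    dx <- dx + k * s * (-spec$a[k] * sin(k * s * x) + spec$b[k] * cos(k * s * x))
  list(da = da, db = db, dx = dx)
}

# im2col: x is H x W x C array; returns [Ho*Wo, k*k*C] patch matrix with
# zero padding; column order = (channel-major, then row-major window taps)
im2col <- function(x, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- if (length(d) == 3L) d[3L] else 1L
  if (length(d) == 2L) dim(x) <- c(H, W, 1L)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(0, c(Hp, Wp, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  rows0 <- (seq_len(Ho) - 1L) * stride
  cols0 <- (seq_len(Wo) - 1L) * stride
  out <- matrix(0, Ho * Wo, k * k * C)
  col <- 0L
  for (ci in seq_len(C)) {
    for (dy in seq_len(k)) {
      for (dx in seq_len(k)) {
        col <- col + 1L
        out[, col] <- xp[rows0 + dy, cols0 + dx, ci]
      }
    }
  }
  attr(out, "out_shape") <- c(Ho, Wo)
  out
}

# plain 2D convolution: w is [k*k*Cin, Cout] in im2col column order
conv2d <- function(x, w, bias = NULL, k = 3L, stride = 1L,
                   pad = (k - 1L) %/% 2L) {
  P <- im2col(x, k, stride, pad)
  y <- P %*% w
  if (!is.null(bias)) y <- sweep(y, 2L, bias, "+")
  sh <- attr(P, "out_shape")
  array(y, c(sh[1L], sh[2L], ncol(w)))
}

#' FT-KAN convolution layer specification
#'
#' Coefficient arrays `a` and `b` have dim (G, k*k*in_channels, out_channels):
#' one truncated Fourier series per (window tap, input channel, output
#' channel) triple.
#'
#' @param in_channels,out_channels channel counts.
#' @param k window size. @param G harmonics. @param input_scale angular scale.
#' @param init_sd s.d. of the random coefficient initialization (0 = zeros).
#' @param seed optional local seed for the initialization.
#' @export
ftkan_conv_spec <- function(in_channels, out_channels, k = 3L, G = 3L,
                            input_scale = pi / 3, init_sd = NULL, seed = NULL) {
  if (G < 1L) stop("ftkan_conv_spec: G must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_in <- k * k * in_channels
  if (is.null(init_sd)) init_sd <- 1 / sqrt(n_in * G)
  mk <- function() array(if (init_sd > 0) stats::rnorm(G * n_in * out_channels, 0, init_sd)
                         else 0, c(G, n_in, out_channels))
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 k = as.integer(k), G = as.integer(G),
                 input_scale = input_scale, a = mk(), b = mk(),
                 bias = numeric(out_channels)),
            class = "ftkan_conv_spec")
}

#' Apply an FT-KAN convolution to a feature map
#'
#' Each output channel is the sum, over input channels and the k x k window,
#' of a per-pair FT-KAN activation applied to the input values.
#'
#' @param fmap H x W (x Cin) array. @param spec an [ftkan_conv_spec()].
#' @param stride,pad convolution geometry.
#' @export
ftkan_conv <- function(fmap, spec, stride = 1L, pad = (spec$k - 1L) %/% 2L) {
  d <- dim(fmap)
  cin <- if (length(d) == 3L) d[3L] else 1L
  if (cin != spec$in_channels) stop("ftkan_conv: channel mismatch")
  P <- im2col(fmap, spec$k, stride, pad)
  s <- spec$input_scale
  y <- matrix(0, nrow(P), spec$out_channels)
  for (k in seq_len(spec$G)) {
    y <- y + cos(k * s * P) %*% spec$a[k, , ] + sin(k * s * P) %*% spec$b[k, , ]
  }
  y <- sweep(y, 2L, spec$bias, "+")
  sh <- attr(P, "out_shape")
  array(y, c(sh[1L], sh[2L], spec$out_channels))
}

#' Initialize backbone weights
#'
#' Architecture: a plain two-block stem (3x3 stride-2 convolutions with tanh
#' nonlinearities, keeping features bounded for the Fourier layers) followed
#' by two FT-KAN convolutions, yielding a 3-level pyramid at strides 4/8/16
#' with 16/32/64 channels by default.
#'
#' @param seed integer seed (weights are deterministic given it).
#' @param widths channel counts of the three pyramid levels.
#' @param G Fourier harmonics per FT-KAN weight.
#' @param input_scale angular input scale of FT-KAN layers; tanh features lie
#'   in (-1, 1) so pi/3 keeps arguments well inside (-pi, pi) at G = 3.
#' @export
backbone_init <- function(seed = 0L, widths = c(16L, 32L, 64L), G = 3L,
                          input_scale = pi / 3) {
  set.seed(seed)
  he <- function(n_in, n_out) matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)),
                                     n_in, n_out)
  c0 <- widths[1L] %/% 2L
  w <- list(
    widths = widths, G = G,
    stem1_w = he(9L * 1L, c0), stem1_b = numeric(c0),
    stem2_w = he(9L * c0, widths[1L]), stem2_b = numeric(widths[1L]),
    kan1 = ftkan_conv_spec(widths[1L], widths[2L], k = 3L, G = G,
                           input_scale = input_scale),
    kan2 = ftkan_conv_spec(widths[2L], widths[3L], k = 3L, G = G,
                           input_scale = input_scale)
  )
  class(w) <- "dpe_backbone"
  w
}

#' Backbone forward pass
#'
#' @param image H x W matrix with finite values in [0, 1]; H and W must be
#'   at least the largest stride (16).
#' @param weights a [backbone_init()] object.
#' @return `feature_pyramid`: list of levels, each list(stride, fmap) with
#'   fmap an H/stride x W/stride x C array; strides 4, 8, 16.
#' @export
backbone_forward <- function(image, weights = backbone_init()) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("backbone_forward: image must be a finite numeric matrix")
  if (nrow(image) < 16L || ncol(image) < 16L)
    stop("backbone_forward: image smaller than the maximum stride (16)")
  x <- array(image, c(dim(image), 1L))
  h1 <- tanh(conv2d(x, weights$stem1_w, weights$stem1_b, k = 3L, stride = 2L))
  l1 <- tanh(conv2d(h1, weights$stem2_w, weights$stem2_b, k = 3L, stride = 2L))
  l2 <- tanh(ftkan_conv(l1, weights$kan1, stride = 2L))
  l3 <- tanh(ftkan_conv(l2, weights$kan2, stride = 2L))
  structure(list(levels = list(list(stride = 4L, fmap = l1),
                               list(stride = 8L, fmap = l2),
                               list(stride = 16L, fmap = l3))),
            class = "feature_pyramid")
}

# bilinear sampling of an fmap at image-coordinate points (border clamped).
# pts: n x 2 (x, y) in image px; stride maps image -> feature grid, where
# feature cell (row r, col c) sits at image point ((c - 0.5) * stride,
# (r - 0.5) * stride).
sample_fmap <- function(fmap, pts, stride) {
  H <- dim(fmap)[1L]; W <- dim(fmap)[2L]; C <- dim(fmap)[3L]
  fx <- pts[, 1L] / stride + 0.5
  fy <- pts[, 2L] / stride + 0.5
  fx <- pmin(pmax(fx, 1), W); fy <- pmin(pmax(fy, 1), H)
  x0 <- pmin(floor(fx), W - 1L); y0 <- pmin(floor(fy), H - 1L)
  tx <- fx - x0; ty <- fy - y0
  m <- matrix(fmap, H * W, C)
  idx <- function(r, c) (c - 1L) * H + r
  m[idx(y0, x0), , drop = FALSE] * ((1 - tx) * (1 - ty)) +
    m[idx(y0, x0 + 1L), , drop = FALSE] * (tx * (1 - ty)) +
    m[idx(y0 + 1L, x0), , drop = FALSE] * ((1 - tx) * ty) +
    m[idx(y0 + 1L, x0 + 1L), , drop = FALSE] * (tx * ty)
}
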