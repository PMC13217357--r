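test_that("peak decoding finds isolated maxima and suppresses overlaps", {
  expect_length(detect_peaks(matrix(0, 16, 16)), 0L)
  hm <- matrix(0, 16, 16)
  for (r in 1:16) for (cc in 1:16)
    hm[r, cc] <- exp(-((r - 9)^2 + (cc - 6)^2) / 8)
  dets <- detect_peaks(hm, c(10, 10), stride = 4L, score_thr = 0.4)
  expect_length(dets, 1L)
  # argmax at (row 9, col 6) -> image center ((6-.5)*4, (9-.5)*4)
  expect_lt(max(abs(dets[[1L]]$center - c(22, 34))), 1)
  # two overlapping boxes: higher peak survives
  hm2 <- matrix(0, 16, 16)
  hm2[8, 8] <- 0.9
  hm2[8, 10] <- 0.7
  d2 <- detect_peaks(hm2, c(20, 20), stride = 4L, score_thr = 0.4,
                     nms_iou = 0.3)
  expect_length(d2, 1L)
  expect_equal(d2[[1L]]$score, 0.9)
})

test_that("initial contours are inscribed ellipses with uniform angles", {
  c1 <- init_contour(c(0, 0, 10, 10), 64L)
  ctr <- polygon_centroid(c1)
  expect_equal(ctr, c(5, 5), tolerance = 1e-9)
  r <- sqrt(rowSums(sweep(unclass(c1), 2L, ctr)^2))
  expect_equal(max(r) - min(r), 0, tolerance = 1e-9)   # circle
  c2 <- init_contour(c(0, 0, 20, 10), 256L)
  rect <- dpetrack:::min_area_rect(c2)
  expect_equal(rect$width / rect$height, 2, tolerance = 1e-6)
  expect_gt(dpetrack:::shoelace_signed(c2), 0)
  expect_error(init_contour(c(0, 0, 0, 5)), "degenerate")
  expect_error(init_contour(c(0, 0, 5, 5), 4L), ">= 8")
})

test_that("zero-weight offset heads are the identity and offsets are bounded", {
  bb <- backbone_init(0)
  img <- matrix(runif(64 * 64), 64, 64)
  pyr <- backbone_forward(img, bb)
  w <- seg_weights_init(16L, mlp_passes = 2L)
  c0 <- init_contour(c(10, 10, 30, 20), 64L)
  expect_equal(unclass(bfe_offsets(c0, pyr, w)), unclass(c0))
  expect_equal(unclass(mlp_offsets(c0, pyr, w)), unclass(c0))
  # random head: |offset| <= r_max
  set.seed(1)
  w$bfe_W[] <- rnorm(length(w$bfe_W), 0, 5)
  off <- unclass(bfe_offsets(c0, pyr, w)) - unclass(c0)
  expect_lte(max(abs(off)), w$r_max + 1e-12)
  # two MLP passes with zeroed second pass == one pass
  set.seed(2)
  w$mlp[[1L]]$W1[] <- rnorm(length(w$mlp[[1L]]$W1), 0, 0.3)
  w$mlp[[1L]]$W2[] <- rnorm(length(w$mlp[[1L]]$W2), 0, 0.3)
  expect_equal(unclass(mlp_offsets(c0, pyr, w, passes = 2L)),
               unclass(mlp_offsets(c0, pyr, w, passes = 1L)))
})

test_that("BFE offsets are equivariant to stride-multiple translations", {
  bb <- backbone_init(5)
  img <- matrix(0.1, 96, 96)
  img[30:44, 30:44] <- 0.8
  sh <- 16
  img2 <- matrix(0.1, 96, 96)
  img2[(30:44) + sh, (30:44) + sh] <- 0.8
  w <- seg_weights_init(16L)
  set.seed(3)
  w$bfe_W[] <- rnorm(length(w$bfe_W), 0, 0.5)
  c0 <- init_contour(c(28, 28, 18, 18), 48L)
  c1 <- contour(sweep(unclass(c0), 2L, c(sh, sh), "+"))
  o0 <- unclass(bfe_offsets(c0, backbone_forward(img, bb), w)) - unclass(c0)
  o1 <- unclass(bfe_offsets(c1, backbone_forward(img2, bb), w)) - unclass(c1)
  expect_equal(o1, o0, tolerance = 1e-4)
})

test_that("gradients flow through the MLP head to every vertex", {
  bb <- backbone_init(7)
  img <- matrix(runif(64 * 64), 64, 64)
  pyr <- backbone_forward(img, bb)
  w <- seg_weights_init(16L)
  set.seed(8)
  w$mlp[[1L]]$W1[] <- rnorm(length(w$mlp[[1L]]$W1), 0, 0.4)
  w$mlp[[1L]]$W2[] <- rnorm(length(w$mlp[[1L]]$W2), 0, 0.4)
  c0 <- init_contour(c(12, 12, 36, 30), 16L)
  loss <- function(cc) sum(unclass(mlp_offsets(cc, pyr, w))^2)
  base <- loss(c0)
  eps <- 1e-4
  grads <- vapply(seq_len(nrow(c0)), function(i) {
    cp <- unclass(c0); cp[i, 1L] <- cp[i, 1L] + eps
    abs(loss(contour(cp)) - base) / eps
  }, numeric(1))
  expect_true(all(grads > 0))
})

test_that("landmarks cover star tips, disk rims, and survive blank patches", {
  fx <- star_fixture(4)
  lm <- extract_landmarks(fx$image, fx$polygon)
  expect_gte(nrow(lm$points), 1L)
  expect_true(all(lm$weights >= 0))
  for (i in seq_len(nrow(fx$tips))) {
    d <- sqrt((lm$points[, 1L] - fx$tips[i, 1L])^2 +
                (lm$points[, 2L] - fx$tips[i, 2L])^2)
    expect_lt(min(d), 2)
  }
  # uniform disk: landmarks on the rim
  img <- matrix(0.1, 64, 64)
  disk <- regular_ngon(90, R = 14, center = c(32, 32))
  img <- dpetrack:::rasterize_into(img, unclass(disk), 0.9)
  lm2 <- extract_landmarks(img, disk)
  rd <- abs(sqrt((lm2$points[, 1L] - 32)^2 + (lm2$points[, 2L] - 32)^2) - 14)
  expect_lt(stats::quantile(rd, 0.9), 2)
  # blank patch: fallback to contour vertices, no crash
  blank <- matrix(0.5, 64, 64)
  cc <- regular_ngon(12, R = 8, center = c(30, 30))
  lm3 <- extract_landmarks(blank, cc)
  expect_equal(lm3$points, unclass(cc))
})

test_that("DPE fixes points on vertex-coincident landmarks", {
  cc <- regular_ngon(24, R = 10, center = c(32, 32))
  lm <- list(points = unclass(cc), weights = rep(1, 24))
  ev <- dpe_evolve(cc, lm, max_iter = 10L, tol = 0.05)
  expect_equal(ev$iterations, 1L)
  expect_equal(ev$displacement, 0)
  expect_equal(unclass(ev$contour), unclass(cc))
})

test_that("DPE recovers star shapes from circle initializations", {
  for (sd in c(1, 4, 13)) {
    fx <- star_fixture(sd)
    lm <- extract_landmarks(fx$image, fx$polygon)
    ctr <- polygon_centroid(fx$polygon)
    circ <- init_contour(c(ctr[1] - 10, ctr[2] - 10, 20, 20), 128L)
    ev <- dpe_evolve(circ, lm)
    expect_gte(polygon_iou(ev$contour, fx$polygon), 0.9)
    expect_true(dpetrack:::contour_is_simple(ev$contour))
    tail5 <- utils::tail(ev$displacement, 5L)
    expect_true(all(diff(tail5) <= 1e-9))
  }
})

test_that("DPE output stays simple across many seeded fixtures", {
  ok <- TRUE
  for (sd in 1:40) {
    fx <- star_fixture(sd, noise_sd = 8)
    lm <- extract_landmarks(fx$image, fx$polygon)
    ctr <- polygon_centroid(fx$polygon)
    circ <- init_contour(c(ctr[1] - 11, ctr[2] - 11, 22, 22), 96L)
    ev <- dpe_evolve(circ, lm, max_iter = 40L)
    ok <- ok && dpetrack:::contour_is_simple(ev$contour)
  }
  expect_true(ok)
})

test_that("postprocess smooths, deduplicates and respects no-op settings", {
  ins <- list(cell_instance(0, regular_ngon(32, 10, c(20, 20)), score = 0.9),
              cell_instance(0, regular_ngon(32, 10.2, c(20.1, 20)), score = 0.5),
              cell_instance(0, regular_ngon(16, 1.5, c(50, 50)), score = 0.8))
  noop <- postprocess(ins, min_area = 0, smooth_window = 1L, dedup_iou = 1)
  expect_length(noop, 3L)
  expect_equal(unclass(noop[[1L]]$contour), unclass(ins[[1L]]$contour))
  pp <- postprocess(ins, min_area = 30, smooth_window = 3L, dedup_iou = 0.8)
  expect_length(pp, 1L)
  expect_equal(pp[[1L]]$score, 0.9)
  # smoothing a spiky contour raises circularity
  set.seed(6)
  th <- 2 * pi * (0:63) / 64
  r <- 10 + rnorm(64, 0, 0.8)
  spiky <- cell_instance(0, contour(cbind(30 + r * cos(th), 30 + r * sin(th))))
  sm <- postprocess(list(spiky), min_area = 0, smooth_window = 5L,
                    dedup_iou = 1)
  expect_gt(circularity(sm[[1L]]$contour), circularity(spiky$contour))
})

test_that("the learning-rate schedule follows stepped geometric decay", {
  sch <- training_schedule(L0 = 1e-5, gamma = 0.1, decay_every = 50L)
  expect_equal(lr_at_epoch(sch, 0), 1e-5)
  expect_equal(lr_at_epoch(sch, 120), 1e-7)
  expect_error(lr_at_epoch(sch, -1), ">= 0")
  flat <- training_schedule(L0 = 3e-4, gamma = 1, decay_every = 10L)
  expect_equal(lr_at_epoch(flat, 0:199), rep(3e-4, 200))
  # closed form equals iterative application for 200 epochs
  L <- 1e-5
  for (ep in 0:199) {
    expect_identical(lr_at_epoch(sch, ep), L)
    if ((ep + 1) %% 50 == 0) L <- L * 0.1
  }
})

test_that("training is seeded-deterministic and a zero-rate run is inert", {
  data <- segmenter_training_data(6L, seed = 0)
  tiny <- training_schedule(L0 = 1e-300, gamma = 1, decay_every = 10L,
                            epochs = 1L, dropout_p = 0)
  m0 <- train_segmenter(data, tiny, seed = 0)
  fresh <- seg_weights_init(16L)
  expect_equal(m0$seg$det_w, fresh$det_w, tolerance = 1e-12)
  expect_equal(m0$seg$bfe_W, fresh$bfe_W, tolerance = 1e-12)
  sch <- training_schedule(L0 = 1, gamma = 0.5, decay_every = 10L,
                           epochs = 5L)
  m1 <- train_segmenter(data, sch, seed = 3)
  m2 <- train_segmenter(data, sch, seed = 3)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$seg$det_w, m2$seg$det_w)
  expect_error(train_segmenter(list(), sch), "empty")
})

test_that("an untrained segmenter reduces to initial contours (ablation identity)", {
  bb <- backbone_init(0)
  img <- matrix(runif(64 * 64, 0.4, 0.6), 64, 64)
  pyr <- backbone_forward(img, bb)
  w <- seg_weights_init(16L)
  c0 <- init_contour(c(10, 14, 28, 22), 64L)
  c1 <- mlp_offsets(bfe_offsets(c0, pyr, w), pyr, w)
  expect_equal(unclass(c1), unclass(c0))
  pp <- postprocess(list(cell_instance(0, c1)), min_area = 0,
                    smooth_window = 1L, dedup_iou = 1)
  expect_equal(unclass(pp[[1L]]$contour), unclass(c0))
})
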