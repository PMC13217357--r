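test_that("polygon area and perimeter match closed forms", {
  sq <- unit_square()
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)
  tri <- contour(rbind(c(0, 0), c(2, 0), c(0, 2)))
  expect_equal(polygon_area(tri), 2)
  tri345 <- contour(rbind(c(0, 0), c(3, 0), c(0, 4)))
  expect_equal(polygon_perimeter(tri345), 12)
  for (n in c(5L, 17L, 64L)) {
    R <- 2.5
    expect_equal(polygon_perimeter(regular_ngon(n, R)),
                 n * 2 * R * sin(pi / n), tolerance = 1e-9)
  }
  expect_error(contour(rbind(c(0, 0), c(1, 1))), "fewer than 3")
})

test_that("circularity matches isoperimetric closed forms", {
  expect_equal(circularity(regular_ngon(6)), pi * sqrt(3) / 6,
               tolerance = 1e-6)
  expect_equal(circularity(unit_square()), pi / 4, tolerance = 1e-12)
  expect_equal(circularity(regular_ngon(360)), 1, tolerance = 1e-3)
  # strictly increasing along regular N-gons
  vals <- vapply(c(3L, 4L, 6L, 12L, 60L, 360L),
                 function(n) circularity(regular_ngon(n)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= 1 + 1e-6))
})

test_that("aspect ratio uses the min-area rotated rectangle", {
  expect_equal(aspect_ratio(unit_square()), 1, tolerance = 1e-9)
  expect_equal(aspect_ratio(rect_contour(2, 1)), 0.5, tolerance = 1e-9)
  expect_equal(aspect_ratio(rect_contour(4, 1, angle = pi / 4)), 0.25,
               tolerance = 1e-9)
  # rigid-rotation invariance
  set.seed(42)
  p <- rand_convex_polygon(42)
  a0 <- aspect_ratio(p)
  for (th in c(0.3, 1.1, 2.7)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    expect_equal(aspect_ratio(contour(unclass(p) %*% t(R))), a0,
                 tolerance = 1e-6)
  }
})

test_that("polygon IoU is exact on analytic cases", {
  sq <- unit_square()
  expect_equal(polygon_iou(sq, sq), 1)
  far <- rect_contour(1, 1, center = c(10, 10))
  expect_equal(polygon_iou(sq, far), 0)
  off <- contour(rbind(c(0.5, 0), c(1.5, 0), c(1.5, 1), c(0.5, 1)))
  expect_equal(polygon_iou(sq, off), 1 / 3, tolerance = 1e-12)
  # non-convex against enclosing box: IoU = area ratio
  star <- star_fixture(2)$polygon
  box <- contour(rbind(c(0, 0), c(96, 0), c(96, 96), c(0, 96)))
  expect_equal(polygon_iou(star, box), polygon_area(star) / polygon_area(box),
               tolerance = 1e-9)
})

test_that("polygon IoU agrees with the supersampled raster oracle", {
  set.seed(7)
  for (k in 1:30) {
    a <- rand_convex_polygon(1000 + k)
    b <- rand_convex_polygon(2000 + k)
    expect_lt(abs(polygon_iou(a, b) - raster_iou_oracle(a, b)), 0.02)
    expect_equal(polygon_iou(a, b), polygon_iou(b, a), tolerance = 1e-9)
  }
})

test_that("contour similarity is translation-invariant and shape-sensitive", {
  sq <- unit_square()
  expect_equal(contour_similarity(sq, rect_contour(1, 1, center = c(17, -4))),
               1, tolerance = 1e-9)
  s3 <- contour(3 * unclass(unit_square()))
  s11 <- contour(1.1 * unclass(unit_square()))
  v3 <- contour_similarity(sq, s3)
  v11 <- contour_similarity(sq, s11)
  expect_true(v3 > 0 && v3 < 1)
  expect_lt(v3, v11)
  sliver <- rect_contour(20, 1)
  expect_lt(contour_similarity(sq, sliver), 0.5)
})

test_that("shape similarity sums its three bounded terms", {
  a <- cell_instance(0, unit_square(), appearance = c(1, 0))
  expect_equal(shape_similarity(a, a), 3, tolerance = 1e-9)
  b <- cell_instance(1, rect_contour(1, 1, center = c(5, 5)),
                     appearance = c(1, 0))
  expect_equal(shape_similarity(a, b), 3, tolerance = 1e-9)
  # half the area, same aspect ratio and contour class: area term = 0.5
  half <- contour(unclass(unit_square()) * sqrt(0.5))
  s <- shape_similarity(unit_square(), half)
  a_term <- min(1, 0.5) / max(1, 0.5)
  expect_equal(a_term, 0.5)
  expect_equal(s - (1 - abs(aspect_ratio(unit_square()) - aspect_ratio(half))) -
                 contour_similarity(unit_square(), half), 0.5,
               tolerance = 1e-9)
})

test_that("chain codes round-trip closed pixel paths", {
  p <- rect_pixel_path(3L, 3L)
  cc <- chain_encode(p)
  expect_length(cc$codes, 8L)
  expect_true(all(cc$codes %in% 0:7))
  expect_equal(chain_decode(cc), p)
  # single pixel: empty code, round-trips
  single <- matrix(c(5L, 7L), ncol = 2L)
  cc1 <- chain_encode(single)
  expect_length(cc1$codes, 0L)
  expect_equal(chain_decode(cc1), single)
  # seeded random rectangles (staircase boundaries) round-trip
  set.seed(11)
  for (k in 1:20) {
    w <- sample(2:12, 1L); h <- sample(2:12, 1L)
    p <- rect_pixel_path(w, h, sample(0:50, 1L), sample(0:50, 1L))
    expect_equal(chain_decode(chain_encode(p)), p)
  }
  bad <- rbind(c(0L, 0L), c(5L, 5L), c(0L, 1L))
  expect_error(chain_encode(bad), "8-adjacent")
})

test_that("resampling preserves arc length and is idempotent", {
  sq <- unit_square()
  r4 <- resample_contour(sq, 4L)
  expect_equal(unclass(r4), unclass(sq), tolerance = 1e-12)
  r400 <- resample_contour(sq, 400L)
  expect_lt(abs(polygon_perimeter(r400) - 4) / 4, 0.005)
  set.seed(3)
  p <- rand_convex_polygon(99)
  once <- resample_contour(p, 64L)
  twice <- resample_contour(once, 64L)
  expect_equal(unclass(twice), unclass(once), tolerance = 1e-6)
  expect_error(resample_contour(sq, 2L), ">= 3")
})

test_that("smoothing and noise removal behave as contracts state", {
  sq <- unit_square()
  expect_equal(unclass(smooth_contour(sq, 1L)), unclass(sq))
  # one spiked vertex gets attenuated
  spiky <- contour(rbind(c(0, 0), c(0.5, -0.1), c(1, 0), c(1, 1), c(0, 1)))
  sm <- smooth_contour(spiky, 3L)
  expect_lt(abs(min(sm[, 2L])), 0.1)
  inst <- list(cell_instance(0, contour(rbind(c(0, 0), c(5, 0), c(5, 1), c(0, 1)))),
               cell_instance(0, contour(rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5)))))
  kept <- remove_noise(inst, 10)
  expect_length(kept, 1L)
  expect_equal(polygon_area(kept[[1L]]$contour), 50)
})

test_that("morphometry is invariant to vertex rotation and translation", {
  set.seed(5)
  p <- rand_convex_polygon(123)
  n <- nrow(p)
  rot_order <- contour(unclass(p)[c(4:n, 1:3), ])
  shifted <- contour(sweep(unclass(p), 2L, c(31, -7), "+"))
  for (f in list(polygon_area, polygon_perimeter, circularity, aspect_ratio)) {
    expect_equal(f(rot_order), f(p), tolerance = 1e-9)
    expect_equal(f(shifted), f(p), tolerance = 1e-9)
  }
  expect_equal(polygon_iou(p, rot_order), 1, tolerance = 1e-9)
  expect_equal(contour_similarity(p, shifted), 1, tolerance = 1e-6)
})
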