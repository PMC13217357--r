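mk_inst <- function(frame, center, r = 6, app = c(1, 0, 0), score = 1,
                    id = NA_integer_, n = 24L) {
  cell_instance(frame, regular_ngon(n, r, center), score = score,
                appearance = app, id = id)
}

test_that("Top-K keeps the highest scores with deterministic tie-breaks", {
  ins <- list(mk_inst(0, c(10, 10), score = 0.9),
              mk_inst(0, c(30, 10), score = 0.5),
              mk_inst(0, c(50, 10), score = 0.7))
  kept <- select_topk(ins, 2L)
  expect_equal(vapply(kept, function(z) z$score, numeric(1)), c(0.9, 0.7))
  expect_identical(select_topk(ins, 10L), ins)
  expect_error(select_topk(ins, 0L), ">= 1")
  # ties: larger area first, then earlier position; verified against a
  # brute-force ordering oracle
  tied <- list(mk_inst(0, c(10, 10), r = 3, score = 0.5),
               mk_inst(0, c(30, 10), r = 8, score = 0.5),
               mk_inst(0, c(50, 10), r = 5, score = 0.5))
  sc <- vapply(tied, function(z) z$score, numeric(1))
  ar <- vapply(tied, function(z) polygon_area(z$contour), numeric(1))
  oracle <- order(-sc, -ar, seq_along(tied))[1:2]
  kept2 <- select_topk(tied, 2L)
  expect_setequal(vapply(kept2, function(z) polygon_area(z$contour), numeric(1)),
                  ar[oracle])
})

test_that("cosine similarity matches hand values and guards zero vectors", {
  expect_equal(cosine_sim(c(2, 1, 0), c(2, 1, 0)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 0), c(1, 1)), 1 / sqrt(2), tolerance = 1e-9)
  expect_warning(z <- cosine_sim(c(0, 0), c(1, 1)), "zero vector")
  expect_equal(z, 0)
})

test_that("Mahalanobis distance reduces to closed forms", {
  expect_equal(mahalanobis_dist(c(3, 4), c(0, 0), diag(2)), 5, tolerance = 1e-12)
  expect_equal(mahalanobis_dist(c(1, 2, 3), c(1, 2, 3), diag(3)), 0)
  expect_equal(mahalanobis_dist(c(1, 0), c(0, 0), diag(c(4, 1))), 2,
               tolerance = 1e-12)
  # M = I equals Euclidean exactly on random vectors
  set.seed(1)
  for (k in 1:10) {
    a <- rnorm(5); b <- rnorm(5)
    expect_identical(mahalanobis_dist(a, b, diag(5)), sqrt(sum((a - b)^2)))
  }
  expect_error(mahalanobis_dist(c(1, 0), c(0, 0), matrix(c(1, 2, 2, -9), 2)),
               "positive semi-definite")
  expect_error(mahalanobis_dist(c(1, 0), c(0, 0), matrix(c(1, 5, 0, 1), 2)),
               "symmetric")
})

test_that("initial edge features apply f to (IoU, Sim, Contour)", {
  w <- tracker_weights(d_node = 3L, d_e = 4L, seed = 0)
  a <- mk_inst(0, c(20, 20))
  b <- mk_inst(1, c(20, 20))
  e <- init_edge(a, b, w, direction = +1)
  expect_equal(e[1:3], c(1, 1, 1), tolerance = 1e-9)
  expect_equal(e[4L], 1)   # direction flag encoded
  e2 <- init_edge(a, b, w, direction = -1)
  expect_equal(e2[4L], -1)
  # disjoint instances with orthogonal appearance: (0, 0, contour-term)
  c_ <- mk_inst(1, c(200, 200), app = c(0, 1, 0))
  e3 <- init_edge(a, c_, w, direction = +1)
  expect_equal(e3[1L], 0)
  expect_equal(e3[2L], 0)
  expect_equal(e3[3L], contour_similarity(a$contour, c_$contour),
               tolerance = 1e-6)
  wz <- w; wz$W_init[] <- 0
  expect_equal(init_edge(a, b, wz), rep(0, 4))
})

test_that("message passing is deterministic, T=0 is identity, and the two-round
           unroll matches a hand computation", {
  w <- tracker_weights(d_node = 13L, d_e = 8L, seed = 3)
  left <- list(mk_inst(0, c(30, 30), app = appearance_descriptor(
    regular_ngon(24, 6, c(30, 30)))))
  right <- list(mk_inst(1, c(32, 30), app = appearance_descriptor(
    regular_ngon(24, 6, c(32, 30)))))
  g0 <- build_frame_graph(left, right, w)
  expect_length(g0$edges, 1L)
  gid <- update_graph(g0, w, T_rounds = 0L)
  expect_identical(gid$edges[[1L]]$e_ij, g0$edges[[1L]]$e_ij)
  g2 <- update_graph(g0, w, T_rounds = 2L)
  # manual unroll of the same two rounds
  e <- g0$edges[[1L]]
  vl <- g0$v_left[1L, ]; vr <- g0$v_right[1L, ]
  eij <- e$e_ij; eji <- e$e_ji
  for (t in 1:2) {
    eij_new <- dpetrack:::edge_update_one(e$e0_ij, eij, vl, vr, e$mhd,
                                          e$shape, w, +1)
    eji_new <- dpetrack:::edge_update_one(e$e0_ji, eji, vl, vr, e$mhd,
                                          e$shape, w, -1)
    eij <- eij_new; eji <- eji_new
    ml <- as.numeric(eij %*% w$W_msg)
    mr <- as.numeric(eji %*% w$W_msg)
    vl <- vl + tanh(as.numeric(ml %*% w$W_node) + w$b_node)
    vr <- vr + tanh(as.numeric(mr %*% w$W_node) + w$b_node)
  }
  expect_equal(g2$edges[[1L]]$e_ij, eij, tolerance = 1e-6)
  expect_equal(g2$edges[[1L]]$e_ji, eji, tolerance = 1e-6)
  expect_equal(as.numeric(g2$v_left[1L, ]), vl, tolerance = 1e-6)
})

test_that("edge update ignoring everything but e0 reduces to f_e(e0)", {
  w <- tracker_weights(d_node = 2L, d_e = 4L, seed = 1)
  # zero all W_e rows except those consuming e0
  w$W_e[-(1:4), ] <- 0
  e0 <- c(0.3, 0.5, 0.7, 1)
  out1 <- dpetrack:::edge_update_one(e0, runif(4), rnorm(2), rnorm(2),
                                     runif(1), runif(1), w, +1)
  out2 <- dpetrack:::edge_update_one(e0, runif(4), rnorm(2), rnorm(2),
                                     runif(1), runif(1), w, +1)
  expect_equal(out1, out2, tolerance = 1e-12)
  expect_equal(out1, e0 + tanh(as.numeric(e0 %*% w$W_e[1:4, ]) + w$b_e))
})

test_that("edge confidence is 0.5 at zero weights and direction-symmetric", {
  w <- tracker_weights(d_node = 3L, d_e = 4L, seed = 0)
  a <- mk_inst(0, c(20, 20)); b <- mk_inst(1, c(22, 20))
  g <- update_graph(build_frame_graph(list(a), list(b), w), w)
  e <- g$edges[[1L]]
  expect_equal(edge_confidence(e, w), 0.5)
  set.seed(5)
  w$clas_w <- rnorm(length(w$clas_w))
  s1 <- edge_confidence(e, w)
  esw <- e
  esw$e_ij <- e$e_ji; esw$e_ji <- e$e_ij
  esw$e0_ij <- e$e0_ji; esw$e0_ji <- e$e0_ij
  expect_equal(edge_confidence(esw, w), s1, tolerance = 1e-12)
  expect_true(s1 >= 0 && s1 <= 1)
})

test_that("matching equals the brute-force optimal assignment", {
  # the worked 2x2 example
  w <- tracker_weights(d_node = 2L, d_e = 4L, seed = 0)
  S <- matrix(c(0.9, 0.3, 0.2, 0.8), 2, 2)
  mm <- dpetrack:::max_score_matching(S, 0.5)
  expect_equal(mm[order(mm[, 1L]), , drop = FALSE],
               cbind(row = 1:2, col = 1:2))
  # all below threshold: nothing matched
  expect_equal(nrow(dpetrack:::max_score_matching(matrix(0.2, 3, 3), 0.5)), 0L)
  # 200 seeded random score matrices up to 6x6 against permutation oracle
  set.seed(2024)
  for (k in 1:200) {
    n <- sample(1:6, 1L); m <- sample(1:6, 1L)
    S <- matrix(runif(n * m), n, m)
    thr <- runif(1, 0.1, 0.7)
    got <- dpetrack:::max_score_matching(S, thr)
    val <- if (nrow(got)) sum(S[got]) else 0
    expect_equal(val, brute_force_matching_value(S, thr), tolerance = 1e-9)
    if (nrow(got)) {
      expect_true(all(S[got] > thr))
      expect_false(any(duplicated(got[, 1L])))
      expect_false(any(duplicated(got[, 2L])))
    }
  }
})

test_that("track linking bridges gaps and keeps identities", {
  w <- tracker_weights(d_node = 13L, seed = 0)
  w$clas_w[] <- 0
  w$clas_w[w$d_e + 1L] <- 4   # readout on the IoU slot of e0
  # single static cell over 10 frames
  frames1 <- lapply(0:9, function(f) list(
    mk_inst(f, c(40, 40), app = appearance_descriptor(regular_ngon(24, 6, c(40, 40))))))
  tr1 <- link_tracks(frames1, w, S_tau = 0.5)
  expect_length(tr1, 1L)
  expect_length(tr1[[1L]]$observations, 10L)
  # gap of 2 frames (<= max_gap 3): same id before and after
  frames2 <- frames1
  frames2[[6]] <- list(); frames2[[7]] <- list()
  tr2 <- link_tracks(frames2, w, S_tau = 0.5, max_gap = 3L)
  expect_length(tr2, 1L)
  expect_equal(vapply(tr2[[1L]]$observations, function(o) o$frame, integer(1)),
               c(0:4, 7:9))
  # gap beyond max_gap: identity terminates, new track born
  tr3 <- link_tracks(frames2, w, S_tau = 0.5, max_gap = 1L)
  expect_length(tr3, 2L)
  # two well-separated crossing cells: no identity switch
  mk_app <- function(ctr, r) appearance_descriptor(regular_ngon(24, r, ctr))
  frames4 <- lapply(0:9, function(f) {
    c1 <- c(20 + 6 * f, 40); c2 <- c(80 - 6 * f, 120)
    list(mk_inst(f, c1, r = 6, app = mk_app(c1, 6), id = NA),
         mk_inst(f, c2, r = 8, app = mk_app(c2, 8), id = NA))
  })
  tr4 <- link_tracks(frames4, w, S_tau = 0.5)
  expect_length(tr4, 2L)
  for (t in tr4) expect_length(t$observations, 10L)
  # deterministic under re-run
  tr4b <- link_tracks(frames4, w, S_tau = 0.5)
  expect_identical(tracks_to_frames(tr4), tracks_to_frames(tr4b))
})

test_that("tracker training separates true from false edges", {
  seqs <- make_labeled_sequences(3L, n_cells = 6L, n_frames = 6L, seed0 = 100L)
  tm <- train_tracker(seqs, training_schedule(L0 = 2, gamma = 0.5,
                                              decay_every = 10L, epochs = 25L,
                                              dropout_p = 0),
                      seed = 0)
  expect_lt(utils::tail(tm$log$loss, 1L), tm$log$loss[1L])
  hold <- make_labeled_sequences(1L, n_cells = 6L, n_frames = 6L, seed0 = 900L)
  pr <- edge_predictions(hold, tm$weights)
  acc <- mean((pr$s_sim > 0.5) == (pr$label == 1))
  expect_gte(acc, 0.95)
  # label permutation control: accuracy collapses to chance
  set.seed(1)
  perm <- pr
  perm$label <- sample(perm$label)
  acc0 <- mean((perm$s_sim > 0.5) == (perm$label == 1))
  expect_lt(abs(acc0 - 0.5), 0.25)
  # zero learning rate leaves the readout untouched
  tm0 <- train_tracker(seqs, training_schedule(L0 = 1e-300, gamma = 1,
                                               decay_every = 10L, epochs = 2L,
                                               dropout_p = 0), seed = 0)
  expect_equal(tm0$weights$clas_w,
               tracker_weights(d_node = 13L, seed = 0)$clas_w,
               tolerance = 1e-12)
})
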