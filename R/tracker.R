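# Multi-Feature Spatial Similarity-Boosted graph tracker: consecutive-frame
# bipartite graphs whose edges start from (IoU, appearance cosine, contour
# similarity), are updated by message passing conditioned on Mahalanobis
# distance and shape similarity, and are read out by an edge-confidence
# (Edge CLAS) head; matches are the optimal one-to-one assignment over
# edges whose confidence exceeds S_tau.

#' Keep the K highest-score instances of a frame
#'
#' Ties are broken deterministically by larger polygon area, then lower
#' list position.
#'
#' @param instances list of [cell_instance()]. @param K how many to keep.
#' @export
select_topk <- function(instances, K) {
  if (K < 1L) stop("select_topk: K must be >= 1")
  if (length(instances) <= K) return(instances)
  sc <- vapply(instances, function(z) z$score, numeric(1))
  ar <- vapply(instances, function(z) polygon_area(z$contour), numeric(1))
  ord <- order(-sc, -ar, seq_along(instances))
  instances[sort(ord[seq_len(K)])]
}

#' Cosine similarity of two feature vectors
#'
#' @param v_a,v_b numeric vectors of equal length.
#' @return dot(a, b) / (|a| |b|) in [-1, 1]; 0 (with a warning) when either
#'   vector is zero.
#' @export
cosine_sim <- function(v_a, v_b) {
  na <- sqrt(sum(v_a^2)); nb <- sqrt(sum(v_b^2))
  if (na == 0 || nb == 0) {
    warning("cosine_sim: zero vector; returning 0")
    return(0)
  }
  sum(v_a * v_b) / (na * nb)
}

#' Mahalanobis distance between two feature vectors
#'
#' ((v_a - v_b)' M (v_a - v_b))^(1/2). With M the inverse covariance this is
#' the standard Mahalanobis distance; M = I reduces to Euclidean distance.
#'
#' @param v_a,v_b numeric vectors. @param M symmetric positive-semidefinite
#'   weighting matrix (default identity).
#' @export
mahalanobis_dist <- function(v_a, v_b, M = diag(length(v_a))) {
  d <- v_a - v_b
  M <- as.matrix(M)
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)))
    stop("mahalanobis_dist: M must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("mahalanobis_dist: M must be positive semi-definite")
  if (all(M == diag(nrow(M)))) return(sqrt(sum(d^2)))  # exact Euclidean case
  q <- as.numeric(t(d) %*% M %*% d)
  sqrt(max(q, 0))
}

#' Initialize tracker weights
#'
#' `f_init` maps the 3-vector (IoU, cosine, contour similarity) plus a
#' direction flag to a d_e edge feature; by default it is the identity
#' embedding (first three dims copy the similarities). Message-passing maps
#' `W_e` (residual edge update) and node aggregation maps are seeded random;
#' the Edge-CLAS readout is zero (confidence 0.5 everywhere) until trained.
#'
#' @param d_node node-feature (appearance) dimension.
#' @param d_e edge-feature dimension (>= 3).
#' @param T_rounds message-passing rounds.
#' @param seed integer seed for the random message maps.
#' @export
tracker_weights <- function(d_node = 13L, d_e = 8L, T_rounds = 3L, seed = 0L) {
  stopifnot(d_e >= 3L, T_rounds >= 0L)
  set.seed(seed)
  rm_ <- function(ni, no, sd = 1 / sqrt(ni)) matrix(stats::rnorm(ni * no, 0, sd), ni, no)
  W_init <- matrix(0, 4L, d_e)
  W_init[1L, 1L] <- 1; W_init[2L, 2L] <- 1; W_init[3L, 3L] <- 1
  if (d_e >= 4L) W_init[4L, 4L] <- 1   # direction encoding
  n_in <- 2L * d_e + 2L * d_node + 2L
  structure(list(d_node = d_node, d_e = d_e, T_rounds = as.integer(T_rounds),
                 W_init = W_init, b_init = numeric(d_e),
                 W_e = rm_(n_in, d_e, 0.3 / sqrt(n_in)), b_e = numeric(d_e),
                 W_msg = rm_(d_e, d_node, 0.3 / sqrt(d_e)),
                 W_node = rm_(d_node, d_node, 0.3 / sqrt(d_node)),
                 b_node = numeric(d_node),
                 clas_w = numeric(2L * d_e + 2L), clas_b = 0),
            class = "tracker_weights")
}

#' Initial edge feature for a directed pair
#'
#' e0_ij = f(IoU_ij, Sim_ij, Contour_ij): a fully connected layer applied to
#' the IoU, appearance cosine similarity and contour similarity of the two
#' instances, with a +-1 direction flag so e0_ij and e0_ji are distinct.
#'
#' @param i,j `cell_instance`s (i from frame t-1, j from frame t).
#' @param weights [tracker_weights()]. @param direction +1 for i->j, -1 for
#'   j->i.
#' @param sims optional precomputed c(iou, cos, contour) to avoid repeating
#'   the geometry.
#' @export
init_edge <- function(i, j, weights, direction = 1, sims = NULL) {
  if (is.null(sims)) {
    sims <- c(polygon_iou(i$contour, j$contour),
              if (length(i$appearance) && length(j$appearance))
                cosine_sim(i$appearance, j$appearance) else 0,
              contour_similarity(i$contour, j$contour))
  }
  as.numeric(c(sims, direction) %*% weights$W_init) + weights$b_init
}

#' Build the bipartite graph between two consecutive frames
#'
#' Nodes are the instances of frames t-1 (left) and t (right); a directed
#' edge pair (e_ij, e_ji) is created for every pair whose centroid distance
#' is below the gate radius. Carries the Mahalanobis weighting matrix
#' (default: inverse of the diagonal empirical node-feature covariance;
#' `mhd_matrix = "literal_sigma"` uses the covariance itself as printed,
#' `"identity"` the identity) and the per-pair shape similarity.
#'
#' @param left,right lists of [cell_instance()].
#' @param weights [tracker_weights()].
#' @param gate_radius px; NULL = 3 x mean equivalent cell diameter.
#' @param mhd_matrix "inverse_cov", "literal_sigma" or "identity".
#' @return `frame_graph` object.
#' @export
build_frame_graph <- function(left, right, weights, gate_radius = NULL,
                              mhd_matrix = c("inverse_cov", "literal_sigma",
                                             "identity")) {
  mhd_matrix <- match.arg(mhd_matrix)
  n <- length(left); m <- length(right)
  # per-instance geometry cache: similarity terms for every gated pair are
  # computed from 64-vertex simplifications, areas, min-area rectangles and
  # centroid-centered boundary samples prepared once per instance
  gcache <- function(ins) {
    cc <- ins$contour
    c64 <- unclass(resample_contour(cc, 64L))
    ctr <- polygon_centroid(cc)
    r <- min_area_rect(cc)
    list(c64 = c64, area = polygon_area(cc), ar = r$height / max(r$width, 1e-12),
         major = r$width, ctr = ctr, pts0 = sweep(c64, 2L, ctr))
  }
  gl <- lapply(left, gcache); gr <- lapply(right, gcache)
  cl <- if (n) t(vapply(gl, function(z) z$ctr, numeric(2))) else matrix(0, 0, 2)
  cr <- if (m) t(vapply(gr, function(z) z$ctr, numeric(2))) else matrix(0, 0, 2)
  if (is.null(gate_radius)) {
    areas <- vapply(c(left, right), function(z) polygon_area(z$contour), numeric(1))
    gate_radius <- if (length(areas)) 3 * mean(2 * sqrt(areas / pi)) else Inf
  }
  d <- weights$d_node
  getv <- function(z) {
    a <- z$appearance
    if (length(a) >= d) a[seq_len(d)] else c(a, numeric(d - length(a)))
  }
  vl <- if (n) t(vapply(left, getv, numeric(d))) else matrix(0, 0, d)
  vr <- if (m) t(vapply(right, getv, numeric(d))) else matrix(0, 0, d)
  M <- diag(d)
  if (n + m >= 3L && mhd_matrix != "identity") {
    va <- rbind(vl, vr)
    vv <- apply(va, 2L, stats::var)
    vv[!is.finite(vv) | vv < 1e-6] <- 1e-6
    M <- if (mhd_matrix == "inverse_cov") diag(1 / vv) else diag(vv)
  }
  edges <- NULL
  if (n && m) {
    dx <- outer(cl[, 1L], cr[, 1L], "-"); dy <- outer(cl[, 2L], cr[, 2L], "-")
    dist <- sqrt(dx^2 + dy^2)
    idx <- which(dist < gate_radius, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- lapply(seq_len(nrow(idx)), function(k) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        a <- gl[[i]]; b <- gr[[j]]
        iou <- polygon_iou(a$c64, b$c64)
        cs <- if (length(left[[i]]$appearance) && length(right[[j]]$appearance))
          cosine_sim(left[[i]]$appearance, right[[j]]$appearance) else 0
        dxp <- outer(a$pts0[, 1L], b$pts0[, 1L], "-")
        dyp <- outer(a$pts0[, 2L], b$pts0[, 2L], "-")
        d2p <- dxp * dxp + dyp * dyp
        dh <- sqrt(max(max(apply(d2p, 1L, min)), max(apply(d2p, 2L, min))))
        D <- (a$major + b$major) / 4
        csim <- if (dh + D <= 0) 1 else 1 - dh / (dh + D)
        sims <- c(iou, cs, csim)
        shp <- min(a$area, b$area) / max(a$area, b$area) +
          (1 - abs(a$ar - b$ar)) + csim
        e0_ij <- init_edge(left[[i]], right[[j]], weights, +1, sims)
        e0_ji <- init_edge(left[[i]], right[[j]], weights, -1, sims)
        list(i = i, j = j, sims = sims,
             mhd = mahalanobis_dist(vl[i, ], vr[j, ], M),
             shape = shp,
             e0_ij = e0_ij, e0_ji = e0_ji,
             e_ij = e0_ij, e_ji = e0_ji)
      })
    }
  }
  structure(list(left = left, right = right, v_left = vl, v_right = vr,
                 edges = if (is.null(edges)) list() else edges,
                 M = M, gate_radius = gate_radius, rounds_done = 0L),
            class = "frame_graph")
}

# one directed edge update: residual tanh layer on the printed argument list
# (e0, e_prev, v_i, v_j, MhD, shape); the +-1 direction flag reuses the last
# input slot pairing with MhD/shape block
edge_update_one <- function(e0, e_prev, vi, vj, mhd, shape, weights, direction) {
  x <- c(e0, e_prev, vi, vj, mhd * direction, shape)
  e0 + tanh(as.numeric(x %*% weights$W_e) + weights$b_e)
}

#' Message-passing update of a frame graph
#'
#' Per round every directed edge feature is updated as
#' e_ij^t = e_ij^0 + tanh(W_e [e_ij^0; e_ij^{t-1}; v_i^{t-1}; v_j^t; MhD_ij;
#' shape_ij]) (residual form), and every node aggregates its incident edge
#' features through a learned map followed by a sum and a residual tanh
#' update. Deterministic given the weights; T = 0 is the identity.
#'
#' @param g [build_frame_graph()] output. @param weights tracker weights.
#' @param T_rounds rounds (default: weights$T_rounds).
#' @export
update_graph <- function(g, weights, T_rounds = weights$T_rounds) {
  if (T_rounds < 0L) stop("update_graph: T_rounds must be >= 0")
  if (!length(g$edges) || T_rounds == 0L) return(g)
  for (t in seq_len(T_rounds)) {
    new_edges <- lapply(g$edges, function(e) {
      vi <- g$v_left[e$i, ]; vj <- g$v_right[e$j, ]
      e$e_ij <- edge_update_one(e$e0_ij, e$e_ij, vi, vj, e$mhd, e$shape,
                                weights, +1)
      e$e_ji <- edge_update_one(e$e0_ji, e$e_ji, vi, vj, e$mhd, e$shape,
                                weights, -1)
      e
    })
    g$edges <- new_edges
    # node update: learned map of incident edge features, summed, residual
    msg_l <- matrix(0, nrow(g$v_left), ncol(g$v_left))
    msg_r <- matrix(0, nrow(g$v_right), ncol(g$v_right))
    for (e in g$edges) {
      msg_l[e$i, ] <- msg_l[e$i, ] + as.numeric(e$e_ij %*% weights$W_msg)
      msg_r[e$j, ] <- msg_r[e$j, ] + as.numeric(e$e_ji %*% weights$W_msg)
    }
    upd <- function(v, m) v + tanh(sweep(m %*% weights$W_node, 2L,
                                         weights$b_node, "+"))
    g$v_left <- upd(g$v_left, msg_l)
    g$v_right <- upd(g$v_right, msg_r)
  }
  g$rounds_done <- g$rounds_done + as.integer(T_rounds)
  g
}

# CLAS input for one direction of an edge
clas_input <- function(e, dir = c("ij", "ji")) {
  dir <- match.arg(dir)
  if (dir == "ij") c(e$e_ij, e$e0_ij, e$mhd, e$shape)
  else c(e$e_ji, e$e0_ji, e$mhd, e$shape)
}

#' Edge confidence (Edge CLAS)
#'
#' Matching probability S_sim in [0, 1] for an updated edge: a learned
#' linear readout of [e^T; e^0; MhD; shape], squashed by a sigmoid, averaged
#' symmetrically over the two edge directions. A zero-weight readout gives
#' 0.5 for every edge.
#'
#' @param e one edge of an updated [frame_graph].
#' @param weights tracker weights.
#' @export
edge_confidence <- function(e, weights) {
  s1 <- stats::plogis(sum(clas_input(e, "ij") * weights$clas_w) + weights$clas_b)
  s2 <- stats::plogis(sum(clas_input(e, "ji") * weights$clas_w) + weights$clas_b)
  (s1 + s2) / 2
}

#' Threshold-respecting optimal matching of a frame graph
#'
#' Computes S_sim for every edge and returns the one-to-one assignment
#' maximizing total S_sim over edges with S_sim > S_tau (optimal assignment
#' on the thresholded score matrix). Unmatched right nodes are births;
#' unmatched left nodes are deaths/occlusions.
#'
#' @param g updated [frame_graph]. @param S_tau matching threshold.
#' @param weights tracker weights.
#' @return `match_result`: list(pairs = data.frame(i, j, s_sim), births,
#'   deaths).
#' @export
match_graph <- function(g, weights, S_tau = 0.5) {
  n <- length(g$left); m <- length(g$right)
  S <- matrix(-Inf, n, m)
  for (e in g$edges) S[e$i, e$j] <- edge_confidence(e, weights)
  pairs <- max_score_matching(S, S_tau)
  df <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                   s_sim = if (nrow(pairs)) S[pairs] else numeric(0))
  structure(list(pairs = df,
                 births = setdiff(seq_len(m), df$j),
                 deaths = setdiff(seq_len(n), df$i)),
            class = "match_result")
}

#' Link per-frame detections into tracks
#'
#' Frame-by-frame graph matching with an occlusion lifecycle: tracks
#' unmatched in a frame enter an occluded state and re-enter the next
#' graph's left side with their last-seen contour and features for up to
#' `max_gap` frames, after which they terminate. Track ids are assigned in
#' creation order and never reused.
#'
#' @param det_frames list (one element per frame) of lists of
#'   [cell_instance()].
#' @param weights trained [tracker_weights()].
#' @param S_tau matching threshold. @param top_k per-frame detection cap.
#' @param max_gap occlusion tolerance (frames).
#' @param gate_radius,mhd_matrix see [build_frame_graph()].
#' @return list of `dpe_track` objects.
#' @export
link_tracks <- function(det_frames, weights, S_tau = 0.5, top_k = 200L,
                        max_gap = 3L, gate_radius = NULL,
                        mhd_matrix = "inverse_cov") {
  if (!length(det_frames)) stop("link_tracks: need at least one frame")
  tracks <- list()
  next_id <- 1L
  active <- integer(0)   # indices into tracks of active/occluded tracks
  first <- select_topk(det_frames[[1L]], top_k)
  for (ins in first) {
    ins$id <- next_id
    tracks[[next_id]] <- new_track(next_id, list(ins))
    active <- c(active, next_id)
    next_id <- next_id + 1L
  }
  for (f in seq_along(det_frames)[-1L]) {
    right <- select_topk(det_frames[[f]], top_k)
    left <- lapply(active, function(ti) {
      obs <- tracks[[ti]]$observations
      obs[[length(obs)]]
    })
    if (length(left) && length(right)) {
      g <- build_frame_graph(left, right, weights, gate_radius, mhd_matrix)
      g <- update_graph(g, weights)
      mr <- match_graph(g, weights, S_tau)
    } else {
      mr <- list(pairs = data.frame(i = integer(0), j = integer(0)),
                 births = seq_along(right), deaths = seq_along(left))
    }
    survivors <- integer(0)
    for (k in seq_len(nrow(mr$pairs))) {
      ti <- active[mr$pairs$i[k]]
      ins <- right[[mr$pairs$j[k]]]
      ins$id <- ti
      tracks[[ti]]$observations <- c(tracks[[ti]]$observations, list(ins))
      tracks[[ti]]$state <- "active"
      tracks[[ti]]$gap <- 0L
      survivors <- c(survivors, ti)
    }
    for (di in mr$deaths) {
      ti <- active[di]
      tracks[[ti]]$gap <- tracks[[ti]]$gap + 1L
      if (tracks[[ti]]$gap > max_gap) {
        tracks[[ti]]$state <- "terminated"
      } else {
        tracks[[ti]]$state <- "occluded"
        survivors <- c(survivors, ti)
      }
    }
    for (bi in mr$births) {
      ins <- right[[bi]]
      ins$id <- next_id
      tracks[[next_id]] <- new_track(next_id, list(ins))
      survivors <- c(survivors, next_id)
      next_id <- next_id + 1L
    }
    active <- sort(survivors)
  }
  tracks
}

#' Train the tracker's Edge-CLAS readout on labeled sequences
#'
#' Builds consecutive-frame graphs from ground-truth-labeled detections,
#' runs the (seeded, fixed) message-passing rounds, and fits the logistic
#' Edge-CLAS readout by full-batch gradient descent with binary
#' cross-entropy on edge labels (same GT identity = positive). Deterministic
#' given the seed.
#'
#' @param sequences list of sequences; each is a list (frames) of lists of
#'   [cell_instance()] whose `id` fields carry GT identities.
#' @param schedule [training_schedule()]; desk-scale default.
#' @param seed integer seed (also seeds the fixed message-passing weights).
#' @param weights optional pre-built [tracker_weights()].
#' @return list(weights, log = data.frame(epoch, loss, lr), n_edges).
#' @export
train_tracker <- function(sequences,
                          schedule = training_schedule(L0 = 0.5, gamma = 0.5,
                                                       decay_every = 10L,
                                                       epochs = 30L,
                                                       dropout_p = 0),
                          seed = 0L, weights = NULL) {
  if (!length(sequences)) stop("train_tracker: empty data")
  set.seed(seed)
  d_node <- length(sequences[[1L]][[1L]][[1L]]$appearance)
  if (is.null(weights)) weights <- tracker_weights(d_node = d_node, seed = seed)
  X <- list(); y <- numeric(0)
  for (sq in sequences) {
    for (f in seq_along(sq)[-1L]) {
      left <- sq[[f - 1L]]; right <- sq[[f]]
      if (!length(left) || !length(right)) next
      g <- build_frame_graph(left, right, weights)
      g <- update_graph(g, weights)
      for (e in g$edges) {
        lab <- as.numeric(!is.na(left[[e$i]]$id) && !is.na(right[[e$j]]$id) &&
                            left[[e$i]]$id == right[[e$j]]$id)
        X[[length(X) + 1L]] <- clas_input(e, "ij")
        y <- c(y, lab)
        X[[length(X) + 1L]] <- clas_input(e, "ji")
        y <- c(y, lab)
      }
    }
  }
  if (!length(y)) stop("train_tracker: no edges generated")
  Xm <- do.call(rbind, X)
  n <- nrow(Xm)
  w <- weights$clas_w; b <- weights$clas_b
  log_df <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  for (ep in seq_len(schedule$epochs)) {
    lr <- lr_at_epoch(schedule, ep - 1L)
    z <- as.numeric(Xm %*% w) + b
    p <- stats::plogis(z)
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    gz <- (p - y) / n
    w <- w - lr * as.numeric(crossprod(Xm, gz))
    b <- b - lr * sum(gz)
    log_df <- rbind(log_df, data.frame(epoch = ep, loss = loss, lr = lr))
  }
  weights$clas_w <- w; weights$clas_b <- b
  list(weights = weights, log = log_df, n_edges = n)
}

#' Classify held-out edges with a trained tracker
#'
#' Convenience evaluation used by the toy-training checks: rebuilds graphs
#' from labeled sequences and returns predicted S_sim with GT labels.
#'
#' @inheritParams train_tracker
#' @param weights trained tracker weights.
#' @return data.frame(s_sim, label).
#' @export
edge_predictions <- function(sequences, weights) {
  out <- list()
  for (sq in sequences) {
    for (f in seq_along(sq)[-1L]) {
      left <- sq[[f - 1L]]; right <- sq[[f]]
      if (!length(left) || !length(right)) next
      g <- update_graph(build_frame_graph(left, right, weights), weights)
      for (e in g$edges) {
        lab <- as.numeric(!is.na(left[[e$i]]$id) && !is.na(right[[e$j]]$id) &&
                            left[[e$i]]$id == right[[e$j]]$id)
        out[[length(out) + 1L]] <- c(edge_confidence(e, weights), lab)
      }
    }
  }
  m <- do.call(rbind, out)
  data.frame(s_sim = m[, 1L], label = m[, 2L])
}
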