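# Evaluation: COCO-style average precision / recall for polygon instance
# detection, and CLEAR-MOT + IDF1 for multi-object tracking.

# greedy score-ordered matching of detections to GTs at one IoU threshold
# within one frame set. iou_mat: dets x gts. Returns logical TP flags per
# detection and matched-gt index (NA = FP).
greedy_match <- function(iou_mat, thr) {
  nd <- nrow(iou_mat); ng <- ncol(iou_mat)
  gt_used <- rep(FALSE, ng)
  m <- rep(NA_integer_, nd)
  for (d in seq_len(nd)) {
    best <- 0; bj <- NA_integer_
    for (j in seq_len(ng)) {
      if (gt_used[j]) next
      if (iou_mat[d, j] >= thr && iou_mat[d, j] > best) {
        best <- iou_mat[d, j]; bj <- j
      }
    }
    if (!is.na(bj)) { gt_used[bj] <- TRUE; m[d] <- bj }
  }
  m
}

#' COCO-style detection evaluation for polygon instances
#'
#' Detections (score-ranked) are greedily matched to ground truth at each
#' IoU threshold; AP uses 101-point interpolated precision, AR is the mean
#' over thresholds of the best recall. Area classes follow the COCO cutoffs
#' (small < 32^2 px^2, mid 32^2-96^2, large > 96^2).
#'
#' @param dets list of [cell_instance()] (any number of frames; matching is
#'   within-frame).
#' @param gts list of list(frame, polygon) ground-truth instances.
#' @param iou_thresholds IoU grid (default 0.50:0.05:0.95).
#' @return `detection_eval` list: ap, ap50, ar, ar_small, ar_mid, ar_large,
#'   and the per-threshold precision/recall curves.
#' @export
average_precision <- function(dets, gts,
                              iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  area_class <- function(a) if (a < 32^2) "small" else if (a <= 96^2) "mid" else "large"
  gt_frames <- vapply(gts, function(g) as.integer(g$frame), integer(1))
  gt_area <- vapply(gts, function(g) polygon_area(g$polygon), numeric(1))
  gt_class <- vapply(gt_area, area_class, character(1))
  det_frames <- vapply(dets, function(d) as.integer(d$frame), integer(1))
  scores <- vapply(dets, function(d) d$score, numeric(1))
  ord <- order(scores, decreasing = TRUE)

  # IoU of each detection against GTs of its frame (computed once)
  iou_cache <- vector("list", length(dets))
  for (d in seq_along(dets)) {
    js <- which(gt_frames == det_frames[d])
    iou_cache[[d]] <- if (length(js))
      vapply(js, function(j) polygon_iou(dets[[d]]$contour, gts[[j]]$polygon),
             numeric(1)) else numeric(0)
    names(iou_cache[[d]]) <- js
  }

  recall_grid <- seq(0, 1, by = 0.01)
  eval_one <- function(thr, keep_gt) {
    ng <- sum(keep_gt)
    if (ng == 0L) return(list(ap = NA_real_, rec = NA_real_,
                              precision = numeric(0), recall = numeric(0)))
    gt_used <- rep(FALSE, length(gts))
    tp <- logical(0); fp <- logical(0)
    for (d in ord) {
      js <- as.integer(names(iou_cache[[d]]))
      ious <- iou_cache[[d]]
      cand <- which(!gt_used[js] & keep_gt[js] & ious >= thr)
      if (length(cand)) {
        j <- js[cand[which.max(ious[cand])]]
        gt_used[j] <- TRUE
        tp <- c(tp, TRUE); fp <- c(fp, FALSE)
      } else {
        # detections matching an out-of-class GT are ignored, not FPs
        ign <- which(keep_gt[js] == FALSE & ious >= thr & !gt_used[js])
        if (length(ign)) next
        tp <- c(tp, FALSE); fp <- c(fp, TRUE)
      }
    }
    ctp <- cumsum(tp); cfp <- cumsum(fp)
    rec <- ctp / ng
    prec <- ctp / pmax(ctp + cfp, 1)
    # 101-point interpolation with monotone precision envelope
    if (length(prec)) for (i in rev(seq_along(prec))[-1L])
      prec[i] <- max(prec[i], prec[i + 1L])
    pint <- vapply(recall_grid, function(r) {
      ok <- which(rec >= r)
      if (length(ok)) prec[ok[1L]] else 0
    }, numeric(1))
    list(ap = mean(pint), rec = if (length(rec)) max(rec) else 0,
         precision = prec, recall = rec)
  }

  all_gt <- rep(TRUE, length(gts))
  res <- lapply(iou_thresholds, eval_one, keep_gt = all_gt)
  aps <- vapply(res, function(z) z$ap, numeric(1))
  recs <- vapply(res, function(z) z$rec, numeric(1))
  by_class <- function(cls) {
    keep <- gt_class == cls
    if (!any(keep)) return(NA_real_)
    mean(vapply(iou_thresholds, function(t) eval_one(t, keep)$rec, numeric(1)))
  }
  structure(list(ap = mean(aps), ap50 = res[[1L]]$ap,
                 ar = mean(recs),
                 ar_small = by_class("small"), ar_mid = by_class("mid"),
                 ar_large = by_class("large"),
                 iou_thresholds = iou_thresholds,
                 curves = res),
            class = "detection_eval")
}

# normalize tracking input to per-frame lists of list(id, polygon=..|xy=..)
as_frame_objects <- function(x) {
  if (is.data.frame(x)) {
    frames <- sort(unique(x$frame))
    idcol <- if ("track_id" %in% names(x)) "track_id" else "id"
    return(lapply(frames, function(f) {
      rows <- which(x$frame == f)
      lapply(rows, function(r)
        list(id = x[[idcol]][r], xy = c(x$x[r], x$y[r])))
    }))
  }
  x
}

#' CLEAR-MOT and IDF1 tracking evaluation
#'
#' Per-frame correspondence: previous-frame GT-prediction pairs are kept
#' while still valid (identity persistence), remaining objects are matched
#' by optimal assignment on IoU (polygons) or gated distance (point input).
#' MOTA = 1 - (FN + FP + IDS) / total GT observations; IDS counts GT tracks
#' whose matched prediction id changes between matched frames. IDF1 comes
#' from a global optimal identity matching between GT and predicted tracks.
#'
#' @param pred,gt per-frame lists of list(id, polygon) (as produced by
#'   [tracks_to_frames()]), or data.frames with columns frame, track_id/id,
#'   x, y (centroid fallback).
#' @param iou_match_thr IoU threshold for a valid correspondence.
#' @param dist_gate px gate when only centroids are available.
#' @return `tracking_eval` list: mota, idf1, ids, fp, fn, n_gt, idtp.
#' @export
clear_mot <- function(pred, gt, iou_match_thr = 0.5, dist_gate = 20) {
  pred <- as_frame_objects(pred); gt <- as_frame_objects(gt)
  n_frames <- max(length(pred), length(gt))
  # per-frame pair similarity matrix (IoU, or gated centroid distance for
  # point-only input) computed once and reused for persistence + assignment
  frame_sim <- function(gf, pf) {
    S <- matrix(0, length(gf), length(pf))
    for (a in seq_along(gf)) for (b in seq_along(pf)) {
      ga <- gf[[a]]; pb <- pf[[b]]
      S[a, b] <- if (!is.null(ga$polygon) && !is.null(pb$polygon)) {
        polygon_iou(ga$polygon, pb$polygon)
      } else {
        pa <- if (!is.null(ga$xy)) ga$xy else polygon_centroid(ga$polygon)
        pc <- if (!is.null(pb$xy)) pb$xy else polygon_centroid(pb$polygon)
        d <- sqrt(sum((pa - pc)^2))
        if (d > dist_gate) 0 else 1 - d / dist_gate
      }
    }
    S
  }
  has_poly <- function(gf, pf) length(gf) && length(pf) &&
    !is.null(gf[[1L]]$polygon) && !is.null(pf[[1L]]$polygon)
  fp <- 0L; fn <- 0L; ids <- 0L; n_gt <- 0L
  last_match <- list()   # gt id -> pred id of its most recent match
  prev_pairs <- list()   # gt id -> pred id matched in previous frame
  co_occur <- list()     # identity-overlap counts for IDF1
  n_gt_obs <- 0L; n_pred_obs <- 0L
  for (f in seq_len(n_frames)) {
    gf <- if (f <= length(gt)) gt[[f]] else list()
    pf <- if (f <= length(pred)) pred[[f]] else list()
    n_gt <- n_gt + length(gf)
    n_gt_obs <- n_gt_obs + length(gf)
    n_pred_obs <- n_pred_obs + length(pf)
    gids <- vapply(gf, function(z) as.character(z$id), character(1))
    pids <- vapply(pf, function(z) as.character(z$id), character(1))
    matched_g <- rep(FALSE, length(gf)); matched_p <- rep(FALSE, length(pf))
    pairs <- list()
    Sf <- frame_sim(gf, pf)
    ok <- if (has_poly(gf, pf)) Sf >= iou_match_thr else Sf > 0
    # identity persistence: keep still-valid previous pairs first
    for (gi in seq_along(gf)) {
      prev <- prev_pairs[[gids[gi]]]
      if (is.null(prev)) next
      pi <- which(pids == prev & !matched_p)
      if (length(pi) == 1L && ok[gi, pi]) {
        matched_g[gi] <- TRUE; matched_p[pi] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(gi, pi)
      }
    }
    # optimal assignment on the rest
    rg <- which(!matched_g); rp <- which(!matched_p)
    if (length(rg) && length(rp)) {
      S <- Sf[rg, rp, drop = FALSE]
      S[!ok[rg, rp, drop = FALSE]] <- 0
      mm <- max_score_matching(S, 0)
      for (k in seq_len(nrow(mm))) {
        gi <- rg[mm[k, 1L]]; pi <- rp[mm[k, 2L]]
        matched_g[gi] <- TRUE; matched_p[pi] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(gi, pi)
      }
    }
    fn <- fn + sum(!matched_g)
    fp <- fp + sum(!matched_p)
    new_prev <- list()
    for (pr in pairs) {
      gid <- gids[pr[1L]]; pid <- pids[pr[2L]]
      lm <- last_match[[gid]]
      if (!is.null(lm) && lm != pid) ids <- ids + 1L
      last_match[[gid]] <- pid
      new_prev[[gid]] <- pid
      key <- paste(gid, pid, sep = "\r")
      co_occur[[key]] <- (if (is.null(co_occur[[key]])) 0L else co_occur[[key]]) + 1L
    }
    prev_pairs <- new_prev
  }
  # IDF1: global min-cost identity matching on co-occurrence counts
  idtp <- 0L
  if (length(co_occur)) {
    keys <- strsplit(names(co_occur), "\r", fixed = TRUE)
    gu <- unique(vapply(keys, `[`, character(1), 1L))
    pu <- unique(vapply(keys, `[`, character(1), 2L))
    Cm <- matrix(0, length(gu), length(pu), dimnames = list(gu, pu))
    for (k in seq_along(keys))
      Cm[keys[[k]][1L], keys[[k]][2L]] <- co_occur[[k]]
    mm <- max_score_matching(Cm, 0)
    idtp <- sum(Cm[mm])
  }
  idf1 <- if (n_gt_obs + n_pred_obs > 0) 2 * idtp / (n_gt_obs + n_pred_obs) else NA_real_
  mota <- if (n_gt > 0) 1 - (fn + fp + ids) / n_gt else NA_real_
  structure(list(mota = mota, idf1 = idf1, ids = ids, fp = fp, fn = fn,
                 n_gt = n_gt, idtp = idtp),
            class = "tracking_eval")
}

#' Convert tracker output to per-frame id/polygon lists
#'
#' @param tracks list of `dpe_track` from [link_tracks()].
#' @param n_frames total frame count (default: inferred).
#' @export
tracks_to_frames <- function(tracks, n_frames = NULL) {
  frames <- unlist(lapply(tracks, function(t)
    vapply(t$observations, function(o) o$frame, integer(1))))
  if (is.null(n_frames)) n_frames <- if (length(frames)) max(frames) + 1L else 0L
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) out[[f]] <- list()
  for (t in tracks) {
    for (o in t$observations) {
      f <- o$frame + 1L
      out[[f]][[length(out[[f]]) + 1L]] <- list(id = t$track_id,
                                                polygon = o$contour)
    }
  }
  out
}

#' Ground truth to per-frame id/polygon lists
#' @param gt the `gt` element of [simulate_sequence()] output.
#' @param visible_only drop occluded instances.
#' @export
gt_to_frames <- function(gt, visible_only = FALSE) {
  lapply(gt$instances, function(fr) {
    fr <- if (visible_only) Filter(function(z) isTRUE(z$visible), fr) else fr
    lapply(fr, function(z) list(id = z$id, polygon = z$polygon))
  })
}
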