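#' Per-frame cell detection
#'
#' Bundles one detected cell in one frame: its contour, detection score,
#' appearance feature vector (the tracker's node feature), and axis-aligned
#' bounding box.
#'
#' @param frame 0-based frame index.
#' @param contour a [contour()].
#' @param score detection confidence in [0, 1].
#' @param appearance numeric feature vector (finite).
#' @param id optional identity label (assigned by the tracker).
#' @param bbox optional (x, y, w, h); derived from the contour when missing.
#' @export
cell_instance <- function(frame, contour, score = 1, appearance = numeric(0),
                          id = NA_integer_, bbox = NULL) {
  contour <- as_contour(contour)
  if (!is.finite(score) || score < 0 || score > 1)
    stop("cell_instance: score must be in [0, 1]")
  if (length(appearance) && !all(is.finite(appearance)))
    stop("cell_instance: appearance features must be finite")
  if (is.null(bbox)) {
    bbox <- c(min(contour[, 1L]), min(contour[, 2L]),
              diff(range(contour[, 1L])), diff(range(contour[, 2L])))
  }
  structure(list(frame = as.integer(frame), id = id, contour = contour,
                 score = as.numeric(score), appearance = as.numeric(appearance),
                 bbox = as.numeric(bbox)),
            class = "dpe_instance")
}

#' @export
print.dpe_instance <- function(x, ...) {
  cat(sprintf("<cell_instance frame=%d id=%s score=%.3f vertices=%d>\n",
              x$frame, ifelse(is.na(x$id), "?", as.character(x$id)),
              x$score, nrow(x$contour)))
  invisible(x)
}

instance_centroid <- function(ins) polygon_centroid(ins$contour)

#' Identity-labeled sequence of cell observations
#'
#' @param track_id integer id (unique per run, never reused).
#' @param observations list of `cell_instance` with strictly increasing frames.
#' @param state one of "active", "occluded", "terminated".
#' @export
new_track <- function(track_id, observations = list(), state = "active") {
  fr <- vapply(observations, function(o) o$frame, integer(1))
  if (length(fr) > 1L && any(diff(fr) <= 0L))
    stop("new_track: observation frames must be strictly increasing")
  structure(list(track_id = as.integer(track_id), observations = observations,
                 state = state, gap = 0L),
            class = "dpe_track")
}
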