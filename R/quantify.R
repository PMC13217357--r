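# Downstream quantification: morphology tables, distribution summaries,
# trajectories with origin normalization, path lengths, cohort comparison.

#' Per-instance morphology table
#'
#' One record per instance with physical units: perimeter (um), area (um^2),
#' circularity and aspect ratio (dimensionless). Geometry is computed in
#' pixels and converted with the pixel size (perimeter x s, area x s^2).
#'
#' @param instances list of [cell_instance()] (or bare contours).
#' @param pixel_size um per px (> 0).
#' @return data.frame(frame, id, perimeter, area, circularity, aspect_ratio).
#' @export
morphology_table <- function(instances, pixel_size = 1) {
  if (pixel_size <= 0) stop("morphology_table: pixel_size must be positive")
  if (!length(instances))
    return(data.frame(frame = integer(0), id = integer(0),
                      perimeter = numeric(0), area = numeric(0),
                      circularity = numeric(0), aspect_ratio = numeric(0)))
  rows <- lapply(instances, function(ins) {
    cc <- if (is_contour(ins)) ins else ins$contour
    data.frame(frame = if (is_contour(ins)) NA_integer_ else ins$frame,
               id = if (is_contour(ins)) NA_integer_ else
                 as.integer(ifelse(is.na(ins$id), NA, ins$id)),
               perimeter = polygon_perimeter(cc) * pixel_size,
               area = polygon_area(cc) * pixel_size^2,
               circularity = circularity(cc),
               aspect_ratio = aspect_ratio(cc))
  })
  do.call(rbind, rows)
}

#' Distribution summary with Gaussian overlay parameters
#'
#' Histogram plus moment-matched normal-fit parameters; flags when the
#' histogram mode disagrees with the fitted mean by more than half a
#' standard deviation (an indication the sample is not unimodal Gaussian).
#'
#' @param values numeric vector (>= 1 value).
#' @param bins histogram bin count.
#' @return list(mean, sd, mode_bin, histogram, fit = c(mean, sd),
#'   mode_mismatch flag).
#' @export
distribution_summary <- function(values, bins = 30L) {
  if (!length(values)) stop("distribution_summary: empty input")
  m <- mean(values); s <- if (length(values) > 1L) stats::sd(values) else 0
  if (diff(range(values)) == 0) {
    h <- list(mids = m, counts = length(values))
    return(list(mean = m, sd = 0, mode_bin = m, histogram = h,
                fit = c(mean = m, sd = 0), mode_mismatch = FALSE))
  }
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  mode_bin <- h$mids[which.max(h$counts)]
  list(mean = m, sd = s, mode_bin = mode_bin, histogram = h,
       fit = c(mean = m, sd = s),
       mode_mismatch = s > 0 && abs(mode_bin - m) > s / 2)
}

#' Trajectory object
#'
#' @param track_id id. @param x,y coordinates (um). @param t time (minutes),
#'   strictly increasing.
#' @export
trajectory <- function(track_id, x, y, t) {
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("trajectory: time must be strictly increasing")
  structure(list(track_id = track_id,
                 points = data.frame(x = x, y = y, t = t)),
            class = "dpe_trajectory")
}

#' Extract centroid trajectories from tracks
#'
#' Trajectory point = polygon area centroid of each observation, scaled to
#' um; time from the frame index and acquisition interval.
#'
#' @param tracks list of `dpe_track`. @param pixel_size um/px.
#' @param frame_interval minutes between frames.
#' @export
tracks_to_trajectories <- function(tracks, pixel_size = 1, frame_interval = 10) {
  lapply(tracks, function(tr) {
    ctr <- t(vapply(tr$observations, function(o) polygon_centroid(o$contour),
                    numeric(2)))
    fr <- vapply(tr$observations, function(o) o$frame, integer(1))
    trajectory(tr$track_id, ctr[, 1L] * pixel_size, ctr[, 2L] * pixel_size,
               fr * frame_interval)
  })
}

#' Translate a trajectory so it starts at the origin
#'
#' All points are shifted so the first point is (0, 0); time untouched.
#' @param traj a [trajectory()].
#' @export
origin_normalize <- function(traj) {
  p <- traj$points
  p$x <- p$x - p$x[1L]
  p$y <- p$y - p$y[1L]
  traj$points <- p
  traj
}

#' Cumulative arc length of a trajectory
#'
#' Sum of consecutive 2-D Euclidean distances along the centroid path (um);
#' always at least the net displacement.
#' @param traj a [trajectory()] with >= 2 points.
#' @export
path_length <- function(traj) {
  p <- traj$points
  if (nrow(p) < 2L) stop("path_length: need at least 2 points")
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
}

#' Compare path-length distributions of two cohorts
#'
#' Descriptive only (no hypothesis test): per-group summaries of trajectory
#' path lengths and the B/A mean ratio.
#'
#' @param traj_a,traj_b non-empty lists of [trajectory()].
#' @return list(summary_a, summary_b, mean_ratio, lengths_a, lengths_b).
#' @export
cohort_compare <- function(traj_a, traj_b) {
  if (!length(traj_a) || !length(traj_b))
    stop("cohort_compare: both groups must be non-empty")
  la <- vapply(traj_a, path_length, numeric(1))
  lb <- vapply(traj_b, path_length, numeric(1))
  summ <- function(v) list(n = length(v), mean = mean(v),
                           sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                           sd_undefined = length(v) < 2L)
  list(summary_a = summ(la), summary_b = summ(lb),
       mean_ratio = mean(lb) / mean(la),
       lengths_a = la, lengths_b = lb)
}
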