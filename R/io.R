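# Interchange formats: image stacks (multipage TIFF / PNG directory),
# instance polygons (JSON), track tables (CSV), YAML run configuration.
# Every writer stamps a metadata block with the tool version and a config
# hash so runs are attributable.

pkg_version <- function() {
  as.character(utils::packageVersion("dpetrack"))
}

# stable polynomial rolling hash of an R object's deparsed form (no
# external digest dependency; stays within 31 bits)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a grayscale image stack
#'
#' Accepts a multipage TIFF file or a directory of PNG frames (sorted by
#' name). Frames are grayscale-converted (channel mean) and normalized to
#' [0, 1]. Mixed frame dimensions are an error.
#'
#' @param path TIFF file or PNG directory.
#' @return list of H x W matrices in [0, 1].
#' @export
read_image_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("read_image_stack: no PNG frames in ", path)
    frames <- lapply(files, png::readPNG)
  } else {
    if (!file.exists(path)) stop("read_image_stack: no such file: ", path)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
  }
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- apply(f[, , seq_len(min(3L, dim(f)[3L])),
                                           drop = FALSE], c(1L, 2L), mean)
    f <- as.matrix(f)
    if (max(f) > 1) f <- f / 255
    f
  })
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), character(1))
  if (length(unique(dims)) > 1L)
    stop("read_image_stack: mixed frame dimensions: ",
         paste(unique(dims), collapse = ", "))
  frames
}

#' Write a stack of [0, 1] matrices as a multipage TIFF
#' @param frames list of matrices. @param path output file.
#' @export
write_image_stack <- function(frames, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write instances to JSON
#'
#' Schema: top-level `_meta` (tool, version, config hash) and `instances`,
#' each {frame, id, score, vertices: [[x, y], ...]}.
#'
#' @param instances flat list of [cell_instance()] (or per-frame nested list).
#' @param path output file. @param config optional config stamped via hash.
#' @export
write_instances_json <- function(instances, path, config = NULL) {
  if (length(instances) && is.list(instances[[1L]]) &&
      !inherits(instances[[1L]], "dpe_instance"))
    instances <- do.call(c, instances)
  recs <- lapply(instances, function(ins) {
    list(frame = ins$frame,
         id = if (is.na(ins$id)) NULL else ins$id,
         score = ins$score,
         vertices = unclass(ins$contour),
         appearance = if (length(ins$appearance)) ins$appearance else NULL)
  })
  obj <- list(`_meta` = list(tool = "dpetrack", version = pkg_version(),
                             config_hash = config_hash(config),
                             n_instances = length(recs)),
              instances = recs)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read instances from JSON
#' @param path file written by [write_instances_json()].
#' @return flat list of [cell_instance()].
#' @export
read_instances_json <- function(path) {
  if (!file.exists(path)) stop("read_instances_json: no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj$instances, function(r) {
    v <- do.call(rbind, lapply(r$vertices, function(p) c(p[[1]], p[[2]])))
    cell_instance(frame = r$frame,
                  contour = contour(v),
                  score = r$score,
                  appearance = if (!is.null(r$appearance))
                    unlist(r$appearance) else numeric(0),
                  id = if (!is.null(r$id)) as.integer(r$id) else NA_integer_)
  })
}

#' Write tracks to CSV
#'
#' Columns: frame, track_id, x_centroid, y_centroid, score, instance_index
#' (0-based position of the instance within its frame's detection list, -1
#' if unknown). A `#`-prefixed metadata header records the tool version and
#' config hash.
#'
#' @param tracks list of `dpe_track` or a data.frame with those columns.
#' @param path output file. @param config optional config stamped via hash.
#' @export
write_tracks_csv <- function(tracks, path, config = NULL) {
  df <- if (is.data.frame(tracks)) tracks else {
    rows <- lapply(tracks, function(tr) {
      do.call(rbind, lapply(tr$observations, function(o) {
        ctr <- polygon_centroid(o$contour)
        data.frame(frame = o$frame, track_id = tr$track_id,
                   x_centroid = ctr[1L], y_centroid = ctr[2L],
                   score = o$score, instance_index = -1L)
      }))
    })
    df <- do.call(rbind, rows)
    df[order(df$frame, df$track_id), , drop = FALSE]
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dpetrack %s", pkg_version()),
               sprintf("# config_hash=%s", config_hash(config))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a tracks CSV, validating the schema
#'
#' Errors (naming the offending track id) if any track's frames are not
#' strictly increasing.
#'
#' @param path file written by [write_tracks_csv()].
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) stop("read_tracks_csv: no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "track_id", "x_centroid", "y_centroid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_tracks_csv: missing columns: ", paste(miss, collapse = ", "))
  for (id in unique(df$track_id)) {
    fr <- df$frame[df$track_id == id]
    if (any(diff(fr) <= 0))
      stop("read_tracks_csv: non-monotone frames for track id ", id)
  }
  df
}

#' Export tracks in Cell-Tracking-Challenge res_track.txt form
#'
#' One line per track: `id start_frame end_frame parent` (parent always 0;
#' no lineage model).
#' @param tracks list of `dpe_track`. @param path output file.
#' @export
write_res_track <- function(tracks, path) {
  lines <- vapply(tracks, function(tr) {
    fr <- vapply(tr$observations, function(o) o$frame, integer(1))
    sprintf("%d %d %d 0", tr$track_id, min(fr), max(fr))
  }, character(1))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  invisible(path)
}

# ---- run configuration ----------------------------------------------------

default_config <- function() {
  list(
    seed = 0L,
    log_level = "info",
    pixel_size = 0.8,
    backbone = list(channels = c(16L, 32L, 64L), harmonics = 3L,
                    input_scale = pi / 3),
    segmenter = list(n_vertices = 128L, score_thr = 0.4, nms_iou = 0.5,
                     min_area = 30, smooth_window = 5L, dedup_iou = 0.8,
                     dpe_alpha = 0.5, dpe_tol = 0.05, dpe_max_iter = 50L,
                     dpe_capture_radius = 12),
    tracker = list(s_tau = 0.5, top_k = 200L, max_gap = 3L,
                   rounds = 3L, d_e = 8L, mhd_matrix = "inverse_cov",
                   gate_radius = NULL),
    simulate = unclass(scene_config()),
    quantify = list(bins = 30L, frame_interval = 10)
  )
}

#' Load and validate a run configuration
#'
#' YAML sections mirror the module parameters; unknown keys (at top level
#' or within a section) are rejected. A missing path yields the defaults.
#'
#' @param path YAML file or NULL.
#' @return validated config list.
#' @export
run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("run_config: no such file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("run_config: unknown config keys: ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(badk))
        stop("run_config: unknown keys in section '", k, "': ",
             paste(badk, collapse = ", "))
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

log_msg <- function(level, stage, msg) {
  message(sprintf("%s %s %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, stage, msg))
}
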