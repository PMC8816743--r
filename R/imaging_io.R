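# Image stacks, path/ROI annotations and tidy measurement tables.

#' Multi-channel (optionally multi-frame) image stack
#'
#' The container behind all quantification: a 4-D pixel array in TCYX order
#' with named channels and a physical pixel size. Single-frame stacks carry a
#' degenerate T axis of length 1 with `frame_interval_s = NULL`.
#'
#' @param pixels numeric array; accepted shapes are `[Y, X]` (one channel,
#'   one frame), `[C, Y, X]` (one frame) or `[T, C, Y, X]`.
#' @param channel_names character vector naming the channel axis.
#' @param pixel_size_um isotropic pixel size, micrometres per pixel (> 0).
#' @param frame_interval_s time between frames in seconds; required when the
#'   stack has more than one frame.
#' @return an object of class `image_stack` with elements `pixels`
#'   (`[T, C, Y, X]`), `channel_names`, `pixel_size_um`, `frame_interval_s`.
#' @export
image_stack <- function(pixels, channel_names, pixel_size_um,
                        frame_interval_s = NULL) {
  nd <- length(dim(pixels))
  if (is.null(dim(pixels)) || nd < 2 || nd > 4) {
    stop("pixels must be a 2-, 3- or 4-dimensional array")
  }
  if (nd == 2) dim(pixels) <- c(1L, 1L, dim(pixels))
  if (nd == 3) dim(pixels) <- c(1L, dim(pixels))
  if (length(channel_names) != dim(pixels)[2]) {
    stop("channel_names length (", length(channel_names),
         ") does not match channel axis (", dim(pixels)[2], ")")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("configuration error: pixel_size_um must be a single positive number")
  }
  if (dim(pixels)[1] > 1 && is.null(frame_interval_s)) {
    stop("configuration error: frame_interval_s is required for time series")
  }
  if (!is.null(frame_interval_s) &&
      (!is.finite(frame_interval_s) || frame_interval_s <= 0)) {
    stop("frame_interval_s must be positive")
  }
  if (any(pixels < 0)) stop("pixel intensities must be non-negative")
  structure(
    list(pixels = pixels, channel_names = as.character(channel_names),
         pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "image_stack: %d frame(s) x %d channel(s) [%s] x %d x %d px, %.4g um/px\n",
    d[1], d[2], paste(x$channel_names, collapse = ","), d[3], d[4],
    x$pixel_size_um))
  invisible(x)
}

#' Number of frames of a stack
#' @param stack an `image_stack`.
#' @export
n_frames <- function(stack) dim(stack$pixels)[1]

#' Extract one channel plane as a `[Y, X]` matrix
#'
#' @param stack an `image_stack`.
#' @param channel channel name or index.
#' @param frame frame index (1-based), default 1.
#' @export
get_channel <- function(stack, channel, frame = 1L) {
  ci <- if (is.character(channel)) match(channel, stack$channel_names) else channel
  if (is.na(ci) || ci < 1 || ci > dim(stack$pixels)[2]) {
    stop("unknown channel: ", channel)
  }
  if (frame < 1 || frame > dim(stack$pixels)[1]) stop("frame out of range")
  stack$pixels[frame, ci, , ]
}

#' Write an image stack to multi-page TIFF
#'
#' Pages are stored frame-major (frame 1 channels, frame 2 channels, ...) as
#' 32-bit float, scaled to `[0, 1]`. Axes, channel names, pixel size, frame
#' interval and the intensity scale are recorded in a JSON sidecar file
#' (`<path>.json`) so that [read_image_stack()] round-trips the stack.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  scale <- max(stack$pixels, 1)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      pages[[k]] <- stack$pixels[t, c, , ] / scale
      k <- k + 1L
    }
  }
  meta <- list(axes = "TCYX", n_frames = d[1],
               channels = stack$channel_names,
               pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               intensity_scale = scale)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("I/O error writing TIFF: ", path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Metadata written by [write_image_stack()] (JSON sidecar `<path>.json`) is
#' used when present; otherwise the axis layout, channel names and pixel size
#' must be supplied. Pages are assumed frame-major in TCYX order.
#'
#' @param path TIFF file path.
#' @param channel_names,pixel_size_um,n_frames,frame_interval_s overrides for
#'   files without embedded metadata.
#' @return an `image_stack`.
#' @export
read_image_stack <- function(path, channel_names = NULL, pixel_size_um = NULL,
                             n_frames = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  pages <- try(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE),
               silent = TRUE)
  if (inherits(pages, "try-error")) stop("I/O error: unreadable TIFF: ", path)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- try(jsonlite::fromJSON(sidecar), silent = TRUE)
    if (inherits(meta, "try-error") || !is.list(meta)) meta <- NULL
  }
  scale <- 1
  if (!is.null(meta)) {
    if (is.null(channel_names)) channel_names <- meta$channels
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (is.null(n_frames)) n_frames <- meta$n_frames
    if (is.null(frame_interval_s)) frame_interval_s <- meta$frame_interval_s
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(pixel_size_um)) {
    stop("configuration error: pixel_size_um not in TIFF metadata and not supplied")
  }
  np <- length(pages)
  if (is.null(n_frames)) n_frames <- 1L
  if (np %% n_frames != 0) stop("page count ", np, " not divisible by n_frames")
  nc <- np %/% n_frames
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("configuration error: ", nc, " channels in file but ",
         length(channel_names), " channel names")
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  px <- array(0, dim = c(n_frames, nc, ny, nx))
  k <- 1L
  for (t in seq_len(n_frames)) {
    for (c in seq_len(nc)) {
      px[t, c, , ] <- pages[[k]] * scale
      k <- k + 1L
    }
  }
  image_stack(px, channel_names, pixel_size_um,
              frame_interval_s = if (n_frames > 1) frame_interval_s else NULL)
}

#' Neurite path annotation
#'
#' An ordered polyline traced from the soma outward along one neurite, the
#' line-ROI along which profiles and kymographs are extracted.
#'
#' @param cell_id cell identifier.
#' @param role `"axon"` or `"dendrite"`.
#' @param points_px two-column matrix of 0-based (x, y) pixel coordinates,
#'   first point at the somatic end.
#' @export
path_annotation <- function(cell_id, role = c("axon", "dendrite"), points_px) {
  role <- match.arg(role)
  points_px <- as.matrix(points_px)
  if (nrow(points_px) < 2) {
    stop("validation error: path for cell ", cell_id, " has fewer than 2 points")
  }
  step <- sqrt(diff(points_px[, 1])^2 + diff(points_px[, 2])^2)
  if (any(step == 0)) {
    stop("validation error: path for cell ", cell_id,
         " has identical consecutive points")
  }
  structure(list(cell_id = as.character(cell_id), role = role,
                 points_px = points_px),
            class = "path_annotation")
}

#' Polygon region-of-interest annotation
#'
#' @param cell_id cell identifier.
#' @param label `"soma"`, `"background"` or `"custom"`.
#' @param polygon_px two-column matrix of 0-based (x, y) vertices; the polygon
#'   is implicitly closed and must be simple with positive area.
#' @export
roi_annotation <- function(cell_id, label = c("soma", "background", "custom"),
                           polygon_px) {
  label <- match.arg(label)
  polygon_px <- as.matrix(polygon_px)
  # drop an explicit closing vertex
  n <- nrow(polygon_px)
  if (n >= 2 && all(polygon_px[1, ] == polygon_px[n, ])) {
    polygon_px <- polygon_px[-n, , drop = FALSE]
  }
  if (!polygon_is_simple(polygon_px)) {
    stop("validation error: ROI polygon for cell ", cell_id,
         " is self-intersecting")
  }
  if (abs(polygon_area(polygon_px)) <= 0) {
    stop("validation error: ROI for cell ", cell_id, " has zero area")
  }
  structure(list(cell_id = as.character(cell_id), label = label,
                 polygon_px = polygon_px),
            class = "roi_annotation")
}

#' Write path and ROI annotations to JSON
#'
#' @param paths list of `path_annotation`.
#' @param rois list of `roi_annotation`.
#' @param path output JSON file.
#' @export
write_annotations <- function(paths, rois, path) {
  ids <- unique(c(vapply(paths, `[[`, "", "cell_id"),
                  vapply(rois, `[[`, "", "cell_id")))
  cells <- lapply(ids, function(id) {
    list(
      cell_id = id,
      paths = lapply(Filter(function(p) p$cell_id == id, paths), function(p) {
        list(role = p$role, points_px = unname(apply(p$points_px, 1, c,
                                                     simplify = FALSE)))
      }),
      rois = lapply(Filter(function(r) r$cell_id == id, rois), function(r) {
        list(label = r$label, polygon_px = unname(apply(r$polygon_px, 1, c,
                                                        simplify = FALSE)))
      })
    )
  })
  jsonlite::write_json(list(cells = cells), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read path and ROI annotations from JSON
#'
#' Validates every record against the type invariants; duplicate
#' (cell, role) path pairs and degenerate geometry raise validation errors.
#'
#' @param path JSON file written by [write_annotations()] (schema: a `cells`
#'   array, each with `cell_id`, `paths` of `{role, points_px}` and `rois` of
#'   `{label, polygon_px}`).
#' @return list with elements `paths` and `rois`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$cells)) stop("validation error: no 'cells' array in ", path)
  paths <- list(); rois <- list()
  seen <- character(0)
  for (cell in doc$cells) {
    id <- cell$cell_id
    for (p in cell$paths) {
      key <- paste(id, p$role)
      if (key %in% seen) {
        stop("validation error: duplicate path for cell ", id,
             " role ", p$role)
      }
      seen <- c(seen, key)
      pts <- do.call(rbind, lapply(p$points_px, unlist))
      paths[[length(paths) + 1]] <- path_annotation(id, p$role, pts)
    }
    for (r in cell$rois) {
      poly <- do.call(rbind, lapply(r$polygon_px, unlist))
      rois[[length(rois) + 1]] <- roi_annotation(id, r$label, poly)
    }
  }
  list(paths = paths, rois = rois)
}

measurement_columns <- c("cell_id", "replicate_id", "condition",
                         "metric_name", "value", "units")

#' Assemble a tidy measurement table
#'
#' @param cell_id,replicate_id,condition,metric_name,value,units column
#'   vectors (recycled to a common length).
#' @return data.frame with the fixed column order used by
#'   [write_measurements()].
#' @export
measurement_table <- function(cell_id = character(), replicate_id = "r1",
                              condition = "none", metric_name = character(),
                              value = numeric(), units = "au") {
  n <- max(length(cell_id), length(value), length(metric_name))
  df <- data.frame(cell_id = rep_len(as.character(cell_id), n),
                   replicate_id = rep_len(as.character(replicate_id), n),
                   condition = rep_len(as.character(condition), n),
                   metric_name = rep_len(as.character(metric_name), n),
                   value = rep_len(as.numeric(value), n),
                   units = rep_len(as.character(units), n),
                   stringsAsFactors = FALSE)
  validate_measurements(df)
  df
}

#' Validate a measurement table
#'
#' Checks the fixed column set and that no (cell_id, metric_name, condition)
#' triple is duplicated.
#' @param table a data.frame.
#' @return the table, invisibly.
#' @export
validate_measurements <- function(table) {
  if (!all(measurement_columns %in% names(table))) {
    stop("validation error: missing columns: ",
         paste(setdiff(measurement_columns, names(table)), collapse = ", "))
  }
  key <- paste(table$cell_id, table$metric_name, table$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (cell_id, metric_name, condition) rows")
  }
  invisible(table)
}

#' Write a measurement table to CSV
#'
#' UTF-8, '.' decimal separator, fixed column order.
#' @param table a valid measurement table.
#' @param path output CSV path.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  ok <- try(utils::write.csv(table[, measurement_columns, drop = FALSE], path,
                             row.names = FALSE, fileEncoding = "UTF-8"),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("I/O error writing ", path)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#' @param path CSV path.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "numeric"))
  validate_measurements(df)
  df
}
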