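# Mitochondrial segmentation, somatodendritic ROI delineation and
# background-corrected, control-normalised intensity quantification.

#' Segmentation configuration
#'
#' @param method `"global_otsu"` (per-cell normalised Otsu threshold, the
#'   default — robust to the overall fluorescence-intensity differences
#'   between cells), `"adaptive_local"` (pixel above the mean of its local
#'   window plus an offset) or `"fixed"`.
#' @param fixed_threshold required iff `method = "fixed"`.
#' @param local_window_um window for the adaptive method (default 5 um).
#' @param min_object_area_um2 objects smaller than this are removed.
#' @export
segmentation_config <- function(method = c("global_otsu", "adaptive_local",
                                           "fixed"),
                                fixed_threshold = NULL, local_window_um = 5,
                                min_object_area_um2 = 0.2) {
  method <- match.arg(method)
  if (method == "fixed" && is.null(fixed_threshold)) {
    stop("configuration error: fixed_threshold required for method='fixed'")
  }
  if (method != "fixed" && !is.null(fixed_threshold)) {
    stop("configuration error: fixed_threshold only valid for method='fixed'")
  }
  if (local_window_um <= 0) stop("local_window_um must be positive")
  structure(list(method = method, fixed_threshold = fixed_threshold,
                 local_window_um = local_window_um,
                 min_object_area_um2 = min_object_area_um2),
            class = "segmentation_config")
}

# Remove connected components below a pixel-area cutoff.
remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask > 0)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_px)
  if (length(small)) mask[lab %in% small] <- 0
  mask
}

#' Segment punctate mitochondria into a binary mask
#'
#' The default method rescales the channel to its own [min, max] before Otsu
#' thresholding, which makes the mask invariant to both global gain and
#' global additive offsets and accounts for intensity differences between
#' cells. Objects below `min_object_area_um2` are removed. A blank image
#' yields an empty mask, not an error.
#'
#' @param stack an [image_stack()].
#' @param channel channel name (default `"MITO"`).
#' @param config a [segmentation_config()].
#' @param frame frame index.
#' @return binary matrix `[Y, X]` with values 0/1.
#' @export
segment_mitochondria <- function(stack, channel = "MITO",
                                 config = segmentation_config(),
                                 frame = 1L) {
  img <- get_channel(stack, channel, frame)
  mask <- segment_matrix(img, stack$pixel_size_um, config)
  mask
}

# Matrix-level worker (also used on kymographs).
segment_matrix <- function(img, pixel_size_um, config) {
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(0, nrow(img), ncol(img)))
  mask <- switch(
    config$method,
    global_otsu = {
      norm <- (img - rng[1]) / diff(rng)
      th <- EBImage::otsu(norm, range = c(0, 1))
      (norm > th) * 1
    },
    adaptive_local = {
      w <- max(3, round(config$local_window_um / pixel_size_um))
      if (w %% 2 == 0) w <- w + 1
      local_mean <- as.matrix(EBImage::filter2(
        EBImage::Image(img), matrix(1 / w^2, w, w)))
      offset <- 0.1 * diff(rng)
      (img > local_mean + offset) * 1
    },
    fixed = (img > config$fixed_threshold) * 1
  )
  min_px <- config$min_object_area_um2 / pixel_size_um^2
  remove_small_objects(mask, min_px)
}

#' Delineate somatodendritic ROIs from the MAP2 channel
#'
#' Thresholds MAP2 at a background-relative level (Otsu splits the dim
#' dendrites from the bright soma rather than signal from background when
#' most pixels are background, so the MAP2-positive mask uses
#' `background + threshold_frac * (upper percentile - background)` instead),
#' labels connected components and accepts as somata the components passing
#' the area and eccentricity gates; everything else MAP2-positive is the
#' dendritic mask. The soma is the large, roughly isotropic blob; dendrites
#' are thin and elongated.
#'
#' @param stack an [image_stack()].
#' @param channel MAP2 channel name.
#' @param min_area_um2 soma area gate (default 80 um^2).
#' @param max_eccentricity soma eccentricity gate (default 0.9).
#' @param threshold_frac MAP2-positive cut as a fraction of the
#'   background-to-99.5th-percentile range (default 0.3).
#' @return list with `somata` (list of per-soma lists: `cell_id`, `mask`,
#'   `centroid_px`, `area_um2`) and `dendrite_mask` (binary matrix).
#'   Errors with "no soma" when no component passes the gates.
#' @export
somatodendritic_rois <- function(stack, channel = "MAP2", min_area_um2 = 80,
                                 max_eccentricity = 0.9,
                                 threshold_frac = 0.3) {
  img <- get_channel(stack, channel)
  rng <- range(img)
  if (diff(rng) == 0) stop("no soma: blank MAP2 channel")
  bg <- estimate_background(img)
  hi <- stats::quantile(img, 0.995)
  th <- bg + threshold_frac * (hi - bg)
  mask <- (img > th) * 1
  if (!any(mask > 0)) stop("no soma: no MAP2-positive pixel")
  px_area <- stack$pixel_size_um^2
  # strip the (thin) neurites by erosion so each soma survives as a compact
  # core, then gate the cores on size and shape
  r <- max(2, round(1.2 / stack$pixel_size_um))
  er <- EBImage::erode(mask, EBImage::makeBrush(2 * r + 1, "disc"))
  lab <- EBImage::bwlabel(er)
  somata <- list()
  if (max(lab) > 0) {
    feats <- EBImage::computeFeatures.moment(lab)
    if (is.null(dim(feats))) feats <- matrix(feats, nrow = 1,
                                             dimnames = list(NULL,
                                                             names(feats)))
    areas <- tabulate(lab[lab > 0], nbins = max(lab)) * px_area
    pass <- which(areas >= min_area_um2 * 0.5 &
                    feats[, "m.eccentricity"] <= max_eccentricity)
    for (j in seq_along(pass)) {
      k <- pass[j]
      somata[[j]] <- list(cell_id = sprintf("cell%03d", j),
                          mask = (lab == k) * 1,
                          centroid_px = c(x = unname(feats[k, "m.cy"]) - 1,
                                          y = unname(feats[k, "m.cx"]) - 1),
                          area_um2 = areas[k])
    }
  }
  if (!length(somata)) stop("no soma: no component passes the soma gates")
  soma_all <- Reduce(`+`, lapply(somata, `[[`, "mask"))
  # exclude a margin around each soma so its rim (lost to erosion-based
  # detection) is not mistaken for dendrite
  rim <- max(3, round(2 / stack$pixel_size_um))
  soma_grown <- EBImage::dilate(
    (soma_all > 0) * 1, EBImage::makeBrush(2 * rim + 1, "disc"))
  dendrite_mask <- mask * (soma_grown == 0)
  list(somata = somata, dendrite_mask = dendrite_mask)
}

# Background estimate: mean over an annotated background ROI when given,
# else the mean of the lowest decile of pixels outside all cell masks.
estimate_background <- function(img, background_roi = NULL,
                                cell_mask = NULL) {
  if (!is.null(background_roi)) {
    m <- polygon_mask(background_roi$polygon_px, dim(img))
    return(mean(img[m]))
  }
  pool <- if (is.null(cell_mask)) img else img[cell_mask == 0]
  q <- stats::quantile(pool, 0.1)
  mean(pool[pool <= q])
}

#' Somatic intensity fold-change vs control cells
#'
#' Per cell: soma-mean intensity minus the image background (annotated
#' background ROI when available, else the lowest-decile rule), then
#' normalised to the mean corrected intensity of the control cells — so the
#' control group mean is 1 by construction, and global additive offsets and
#' multiplicative gain cancel.
#'
#' @param cells list of per-cell lists: `stack` (an [image_stack()]),
#'   `condition`, `cell_id`, `replicate_id`, optional `soma_roi`
#'   ([roi_annotation()]) and `background_roi`. When `soma_roi` is absent,
#'   the soma is segmented from `map2_channel` via [somatodendritic_rois()].
#' @param channel intensity channel (default `"TAU"`).
#' @param control condition label of the control group.
#' @param map2_channel channel used for soma detection fallback.
#' @return data.frame of somatic measurements: cell_id, replicate_id,
#'   condition, raw_mean, background, corrected, normalized.
#' @export
somatic_intensity_foldchange <- function(cells, channel = "TAU",
                                         control = "Ctrl",
                                         map2_channel = "MAP2") {
  rows <- lapply(cells, function(cell) {
    img <- get_channel(cell$stack, channel)
    if (!is.null(cell$soma_roi)) {
      soma_mask <- polygon_mask(cell$soma_roi$polygon_px, dim(img))
    } else {
      soma_mask <- somatodendritic_rois(cell$stack,
                                        channel = map2_channel)$somata[[1]]$mask > 0
    }
    bg <- estimate_background(img, cell$background_roi,
                              cell_mask = soma_mask * 1)
    raw <- mean(img[soma_mask])
    data.frame(cell_id = cell$cell_id,
               replicate_id = if (is.null(cell$replicate_id)) "r1" else
                 cell$replicate_id,
               condition = cell$condition, raw_mean = raw, background = bg,
               corrected = raw - bg, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ctrl <- df$corrected[df$condition == control]
  if (!length(ctrl)) stop("no control cells with condition '", control, "'")
  ctrl_mean <- mean(ctrl)
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("cannot normalize: control corrected mean is not positive")
  }
  df$normalized <- df$corrected / ctrl_mean
  df
}

#' Somatic / dendritic polarity index of a channel
#'
#' `(soma mean - background) / (dendritic mean - background)`; the MAP2
#' polarity readout.
#'
#' @param stack an [image_stack()].
#' @param soma_mask,dendrite_mask binary matrices (e.g. from
#'   [somatodendritic_rois()]).
#' @param channel channel name (default `"MAP2"`).
#' @param background_roi optional [roi_annotation()].
#' @return a single number.
#' @export
map2_polarity_index <- function(stack, soma_mask, dendrite_mask,
                                channel = "MAP2", background_roi = NULL) {
  if (!any(dendrite_mask > 0)) stop("dendritic mask is empty")
  img <- get_channel(stack, channel)
  bg <- estimate_background(img, background_roi,
                            cell_mask = (soma_mask + dendrite_mask > 0) * 1)
  dend <- mean(img[dendrite_mask > 0]) - bg
  if (dend <= 0) stop("dendritic corrected mean is not positive")
  (mean(img[soma_mask > 0]) - bg) / dend
}

#' Per-ROI intensity time series, normalised to the first frame
#'
#' For every frame, the mean intensity inside each ROI minus the per-frame
#' background, divided by the frame-1 value — the membrane-potential (TMRM)
#' readout for photoactivation experiments.
#'
#' @param timelapse an [image_stack()] with a time axis.
#' @param rois list of [roi_annotation()].
#' @param channel channel name or index.
#' @param background_roi optional [roi_annotation()] for background.
#' @return data.frame with columns roi, time_s, frame, intensity, relative.
#' @export
roi_timeseries <- function(timelapse, rois, channel,
                           background_roi = NULL) {
  nt <- n_frames(timelapse)
  if (nt < 2) stop("time axis required: single-frame stack")
  img1 <- get_channel(timelapse, channel, 1)
  masks <- lapply(rois, function(r) {
    m <- polygon_mask(r$polygon_px, dim(img1))
    if (!any(m)) stop("ROI '", r$label, "' lies outside the image")
    m
  })
  bg_mask <- if (!is.null(background_roi)) {
    polygon_mask(background_roi$polygon_px, dim(img1))
  } else NULL
  rows <- list()
  for (t in seq_len(nt)) {
    img <- get_channel(timelapse, channel, t)
    bg <- if (!is.null(bg_mask)) mean(img[bg_mask]) else
      estimate_background(img, NULL, Reduce(`+`, masks) * 1)
    for (i in seq_along(rois)) {
      rows[[length(rows) + 1]] <- data.frame(
        roi = rois[[i]]$label, frame = t,
        time_s = (t - 1) * timelapse$frame_interval_s,
        intensity = mean(img[masks[[i]]]) - bg, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$relative <- NA_real_
  for (r in unique(df$roi)) {
    sel <- df$roi == r
    first <- df$intensity[sel][1]
    if (first == 0) stop("frame-1 intensity is zero for ROI ", r)
    df$relative[sel] <- df$intensity[sel] / first
  }
  df
}
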