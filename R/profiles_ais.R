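# Arclength intensity profiles, AIS-start detection and aligned,
# replicate-weighted mitochondrial presence profiles.

#' Arclength-indexed line profile
#'
#' @param cell_id cell identifier.
#' @param channel channel name the profile was taken from.
#' @param step_um sampling step along the path (um).
#' @param values intensity samples; `values[i]` sits at arclength
#'   `(i - 1) * step_um` with arclength 0 at the somatic end.
#' @export
line_profile <- function(cell_id, channel, step_um, values) {
  if (!is.finite(step_um) || step_um <= 0) stop("step_um must be positive")
  if (length(values) < 2) stop("profile needs at least 2 samples")
  if (!all(is.finite(values))) stop("profile values must be finite")
  structure(list(cell_id = as.character(cell_id), channel = channel,
                 step_um = step_um, values = as.numeric(values)),
            class = "line_profile")
}

#' Arclength axis of a line profile (um)
#' @param profile a `line_profile`.
#' @export
profile_positions <- function(profile) {
  (seq_along(profile$values) - 1) * profile$step_um
}

# Sample offsets spanning width_um perpendicular to the path tangent.
perpendicular_offsets <- function(width_um, pixel_size_um) {
  half_px <- (width_um / 2) / pixel_size_um
  n_side <- max(1L, ceiling(half_px))
  seq(-half_px, half_px, length.out = 2 * n_side + 1)
}

#' Extract an intensity profile along a neurite path
#'
#' Samples every `step_um` along the polyline by bilinear interpolation,
#' averaged (or max-projected) across `width_um` perpendicular to the local
#' tangent — the in-silico version of an ImageJ line-ROI plot profile.
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @param path a [path_annotation()].
#' @param width_um line width; default 3 pixels.
#' @param step_um sampling step; default one pixel.
#' @param frame frame index for time series.
#' @param aggregate `"mean"` (plot profile) or `"max"` (kymograph rows).
#' @return a [line_profile()].
#' @export
extract_profile <- function(stack, channel, path,
                            width_um = 3 * stack$pixel_size_um,
                            step_um = stack$pixel_size_um, frame = 1L,
                            aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  img <- get_channel(stack, channel, frame)
  extract_profile_img(img, stack$pixel_size_um, path, width_um, step_um,
                      aggregate)
}

# Matrix-level worker so kymograph building can reuse interpolation geometry.
extract_profile_img <- function(img, pixel_size_um, path, width_um, step_um,
                                aggregate = "mean", sampler = bilinear) {
  pts <- path$points_px
  ny <- nrow(img); nx <- ncol(img)
  if (any(pts[, 1] < 0 | pts[, 1] > nx - 1 | pts[, 2] < 0 |
            pts[, 2] > ny - 1)) {
    bad <- which(pts[, 1] < 0 | pts[, 1] > nx - 1 | pts[, 2] < 0 |
                   pts[, 2] > ny - 1)[1]
    stop("path exits image bounds at vertex ", bad, " (",
         pts[bad, 1], ", ", pts[bad, 2], ")")
  }
  total_um <- max(polyline_arclength(pts, pixel_size_um))
  s_um <- seq(0, total_um, by = step_um)
  samp <- polyline_sample(pts, s_um / pixel_size_um)
  offs <- perpendicular_offsets(width_um, pixel_size_um)
  vals <- matrix(NA_real_, length(s_um), length(offs))
  for (j in seq_along(offs)) {
    xj <- samp$xy[, 1] + offs[j] * samp$normal[, 1]
    yj <- samp$xy[, 2] + offs[j] * samp$normal[, 2]
    vals[, j] <- sampler(img, xj, yj)
  }
  agg <- if (aggregate == "mean") {
    rowMeans(vals, na.rm = TRUE)
  } else {
    apply(vals, 1, max, na.rm = TRUE)
  }
  agg[!is.finite(agg)] <- 0
  line_profile(path$cell_id, "profile", step_um, agg)
}

#' Centered sliding (boxcar) mean of a profile
#'
#' The window covers `window_um` of arclength (2*floor(window/2/step) + 1
#' samples); at the edges the window shrinks to the available support, so a
#' constant profile is unchanged everywhere and an affine profile is
#' unchanged in the interior.
#'
#' @param profile a [line_profile()].
#' @param window_um window size in um (default 1).
#' @return a smoothed [line_profile()].
#' @export
sliding_mean <- function(profile, window_um = 1.0) {
  if (window_um < profile$step_um) {
    stop("validation error: window_um (", window_um,
         ") is smaller than the sample step (", profile$step_um, ")")
  }
  half <- floor(window_um / 2 / profile$step_um + 1e-9)
  k <- 2L * half + 1L
  sm <- zoo::rollapply(profile$values, width = k, FUN = mean,
                       align = "center", partial = TRUE)
  line_profile(profile$cell_id, profile$channel, profile$step_um, sm)
}

#' Detect the AIS start from an AIS-marker profile
#'
#' Applies a centered sliding mean (default 1 um) and returns the smallest
#' arclength whose smoothed value is at least `threshold_fraction` of the
#' smoothed maximum — the 30%-of-max rule. The rule is invariant to
#' multiplicative intensity gain but not to additive offsets (a property of
#' a fraction-of-maximum criterion).
#'
#' @param profile a [line_profile()] of the AIS-marker channel.
#' @param threshold_fraction fraction of the smoothed maximum (default 0.30).
#' @param window_um sliding-mean window (default 1).
#' @return list of class `ais_start` with `cell_id`, `start_um`,
#'   `smoothing_window_um`, `threshold_fraction` and `at_origin` (TRUE with a
#'   warning when the crossing is at arclength 0, e.g. for a monotonically
#'   decreasing profile).
#' @export
detect_ais_start <- function(profile, threshold_fraction = 0.30,
                             window_um = 1.0) {
  sm <- sliding_mean(profile, window_um)
  m <- max(sm$values)
  if (m <= 0) stop("no AIS detected: profile is all zero")
  idx <- which(sm$values >= threshold_fraction * m)[1]
  start_um <- (idx - 1) * profile$step_um
  at_origin <- idx == 1L
  if (at_origin) {
    warning("AIS start at arclength 0 (profile maximum at the somatic end)")
  }
  structure(list(cell_id = profile$cell_id, start_um = start_um,
                 smoothing_window_um = window_um,
                 threshold_fraction = threshold_fraction,
                 at_origin = at_origin),
            class = "ais_start")
}

#' Binary presence profile along a path
#'
#' Samples a segmentation mask along the path: a sample is 1 iff any mask
#' pixel within `width_um` of the path at that arclength is foreground
#' (nearest-neighbour lookup, no interpolation of the binary values).
#'
#' @param mask binary matrix (`[Y, X]`, values 0/1) or an [image_stack()]
#'   channel name together with `stack`.
#' @param path a [path_annotation()].
#' @param pixel_size_um pixel size of the mask.
#' @param width_um,step_um sampling geometry as in [extract_profile()].
#' @return a [line_profile()] with values in {0, 1}.
#' @export
binary_presence_profile <- function(mask, path, pixel_size_um,
                                    width_um = 3 * pixel_size_um,
                                    step_um = pixel_size_um) {
  if (!all(mask %in% c(0, 1))) {
    stop("validation error: mask is not binary")
  }
  p <- extract_profile_img(mask, pixel_size_um, path, width_um, step_um,
                           aggregate = "max", sampler = nearest_px)
  line_profile(path$cell_id, "presence", step_um,
               as.numeric(p$values > 0.5))
}

#' Align presence profiles to the AIS start and average across cells
#'
#' Profiles are shifted so arclength 0 is the detected AIS start (negative =
#' somatic side). At every aligned position the per-replicate cell mean is
#' computed first and the reported mean is the unweighted mean of replicate
#' means (the biological-replicate-weighted mean); SD is across replicate
#' means. Positions covered by fewer than `min_cells` cells in total are
#' dropped.
#'
#' @param profiles list of [line_profile()] (equal `step_um`).
#' @param starts list of [detect_ais_start()] results, one per profile.
#' @param replicates character vector of replicate labels, one per profile.
#' @param min_cells minimum total cells per retained position (default 3).
#' @return list of class `aligned_profile_set`: `axis_um`, `cells` (matrix
#'   cells x positions with NA outside coverage), `cell_ids`, `replicates`,
#'   `mean`, `sd`, `n`, `step_um`.
#' @export
align_and_average <- function(profiles, starts, replicates = NULL,
                              min_cells = 3) {
  n <- length(profiles)
  stopifnot(n >= 1, length(starts) == n)
  if (is.null(replicates)) replicates <- rep("rep1", n)
  stopifnot(length(replicates) == n)
  step <- profiles[[1]]$step_um
  if (any(abs(vapply(profiles, `[[`, 0, "step_um") - step) > 1e-9)) {
    stop("profiles must share one step_um")
  }
  off <- vapply(starts, function(s) round(s$start_um / step), 0)
  lens <- vapply(profiles, function(p) length(p$values), 0)
  lo <- min(-off); hi <- max(lens - 1 - off)
  axis_idx <- lo:hi
  cells <- matrix(NA_real_, n, length(axis_idx))
  for (i in seq_len(n)) {
    cols <- (0:(lens[i] - 1)) - off[i] - lo + 1
    cells[i, cols] <- profiles[[i]]$values
  }
  n_pos <- colSums(!is.na(cells))
  reps <- unique(replicates)
  # drop replicates contributing zero cells
  empty <- setdiff(reps, replicates)
  if (length(empty)) warning("replicates without cells excluded: ",
                             paste(empty, collapse = ", "))
  rep_means <- t(vapply(reps, function(r) {
    colMeans(cells[replicates == r, , drop = FALSE], na.rm = TRUE)
  }, numeric(length(axis_idx))))
  rep_means[!is.finite(rep_means)] <- NA
  mean_w <- colMeans(rep_means, na.rm = TRUE)
  sd_w <- apply(rep_means, 2, stats::sd, na.rm = TRUE)
  keep <- n_pos >= min_cells
  structure(list(axis_um = axis_idx[keep] * step,
                 cells = cells[, keep, drop = FALSE],
                 cell_ids = vapply(profiles, `[[`, "", "cell_id"),
                 replicates = replicates,
                 mean = mean_w[keep], sd = sd_w[keep], n = n_pos[keep],
                 step_um = step, min_cells = min_cells),
            class = "aligned_profile_set")
}

#' Default analysis windows relative to the AIS start
#'
#' 10 um spans: proximal `[-5, +5]`, then central and distal shifted by a
#' fixed offset (default 15 um) so the spacing between windows is the same
#' across experiments.
#'
#' @param offset_um shift between consecutive windows (default 15).
#' @export
default_windows <- function(offset_um = 15) {
  list(proximal = c(-5, 5),
       central = c(-5, 5) + offset_um,
       distal = c(-5, 5) + 2 * offset_um)
}

#' Per-replicate means of an aligned profile set over named windows
#'
#' For each window and replicate, the mean over that replicate's cells of the
#' per-cell mean within the span — the unit entering the replicate-level
#' statistics.
#'
#' @param aligned an [align_and_average()] result.
#' @param windows named list of c(lo, hi) spans in um relative to the AIS
#'   start; default [default_windows()].
#' @return data.frame with columns window, replicate_id, mean, n_cells, plus
#'   attribute `"overall"`: named vector of means of replicate means.
#' @export
region_means <- function(aligned, windows = default_windows()) {
  out <- list()
  overall <- numeric(0)
  for (w in names(windows)) {
    span <- windows[[w]]
    sel <- aligned$axis_um >= span[1] & aligned$axis_um <= span[2]
    if (!any(sel)) {
      stop("window ", w, " [", span[1], ", ", span[2],
           "] is outside the aligned axis")
    }
    cell_means <- rowMeans(aligned$cells[, sel, drop = FALSE], na.rm = TRUE)
    reps <- unique(aligned$replicates)
    rep_rows <- lapply(reps, function(r) {
      cm <- cell_means[aligned$replicates == r]
      cm <- cm[is.finite(cm)]
      data.frame(window = w, replicate_id = r,
                 mean = mean(cm), n_cells = length(cm),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rep_rows)
    out[[w]] <- rows
    overall[w] <- mean(rows$mean[is.finite(rows$mean)])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "overall") <- overall
  res
}
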