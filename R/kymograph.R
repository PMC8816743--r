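# Kymograph construction along the axon path, trafficking-event detection
# and per-cell event fractions.

#' Build per-channel kymographs from a time-lapse stack
#'
#' Each kymograph row is one arclength position (distance from the somatic
#' end) and each column one frame; the value is the maximum intensity across
#' `width_um` perpendicular to the path, so puncta slightly off the traced
#' line are not lost. Moving particles appear as sloped ridges, stationary
#' ones as vertical bands.
#'
#' @param timelapse an [image_stack()] with a time axis.
#' @param path a [path_annotation()] along the axon.
#' @param width_um perpendicular max-projection width (default 1.5 um).
#' @param step_um distance-axis step (default one pixel).
#' @param channels channels to build (default all).
#' @return named list of `kymograph` objects: `matrix` ([distance x time]),
#'   `distance_step_um`, `time_step_s`, `channel`.
#' @export
build_kymograph <- function(timelapse, path, width_um = 1.5,
                            step_um = timelapse$pixel_size_um,
                            channels = timelapse$channel_names) {
  if (n_frames(timelapse) < 2) {
    stop("single-frame input: a kymograph needs a time axis")
  }
  out <- list()
  for (ch in channels) {
    cols <- lapply(seq_len(n_frames(timelapse)), function(t) {
      extract_profile(timelapse, ch, path, width_um = width_um,
                      step_um = step_um, frame = t,
                      aggregate = "max")$values
    })
    out[[ch]] <- structure(
      list(matrix = do.call(cbind, cols), distance_step_um = step_um,
           time_step_s = timelapse$frame_interval_s, channel = ch),
      class = "kymograph")
  }
  out
}

# Remove stationary structure from a kymograph: subtract the per-row
# (per-distance) temporal median, which cancels the stationary cluster band
# and constant background while leaving transient moving ridges.
remove_stationary <- function(mat) {
  med <- apply(mat, 1, stats::median)
  pmax(mat - med, 0)
}

#' Detect and classify trafficking events in per-channel kymographs
#'
#' Stationary structure (the anchored cluster band, background) is removed by
#' per-row temporal median subtraction; the remainder is Otsu-thresholded and
#' connected ridge components become candidate tracks. A track is kept as an
#' event when its net displacement is at least `min_displacement_um`, its
#' fitted speed is at least `min_speed_um_s`, and its distance range overlaps
#' `cluster_span` (events are counted only if they go past the cluster).
#' Direction follows the sign of the net displacement (anterograde = away
#' from the soma); origin is `"cluster"` iff the track's channel is red and
#' it originates inside `cluster_span`, else `"other"`. The stationary band
#' itself is never an event.
#'
#' @param kymos named list from [build_kymograph()] (channels `green`/`red`;
#'   a missing red channel downgrades all origins to `"other"` with a
#'   warning).
#' @param cluster_span c(lo, hi) distance interval of the AIS cluster (um).
#' @param min_displacement_um minimum net displacement (default 2).
#' @param min_speed_um_s minimum |fitted speed| (default 0.1).
#' @param max_speed_um_s fastest linkable particle (default 0.8): a particle
#'   moving at speed v displaces v * frame interval between columns, so ridge
#'   pixels of fast movers are not 8-connected; a vertical dilation sized to
#'   half that displacement re-links them before labelling (kept as small as
#'   possible so that distinct concurrent tracks are not merged).
#' @param min_frames minimum track length in frames (default 3).
#' @return data.frame of events: channel, t_start_s, t_end_s, x_start_um,
#'   x_end_um, displacement_um, speed_um_s, direction, origin.
#' @export
detect_and_classify_events <- function(kymos, cluster_span,
                                       min_displacement_um = 2,
                                       min_speed_um_s = 0.1,
                                       max_speed_um_s = 0.8,
                                       min_frames = 3L) {
  steps_d <- vapply(kymos, `[[`, 0, "distance_step_um")
  steps_t <- vapply(kymos, `[[`, 0, "time_step_s")
  if (length(unique(round(steps_d, 9))) > 1 ||
      length(unique(round(steps_t, 9))) > 1) {
    stop("kymograph channels must share identical axes")
  }
  has_red <- "red" %in% names(kymos)
  if (!has_red) {
    warning("no red channel: origins reported as 'other' ",
            "(non-photoconverted experiment)")
  }
  rows <- list()
  for (ch in names(kymos)) {
    k <- kymos[[ch]]
    mat <- remove_stationary(k$matrix)
    rng <- range(mat)
    if (diff(rng) == 0) next
    norm <- (mat - rng[1]) / diff(rng)
    th <- EBImage::otsu(norm, range = c(0, 1))
    bin <- (norm > th) * 1
    # re-link ridge pixels of fast movers across columns: pixels Delta rows
    # apart in adjacent columns become 8-connected once each is extended by
    # Delta/2 rows
    # the 3-column width additionally bridges the 1-column holes left where
    # a mover crosses a stationary punctum (whose row median removes both)
    e <- ceiling(max_speed_um_s * k$time_step_s / k$distance_step_um / 2)
    linked <- if (e > 0) {
      EBImage::dilate(bin, matrix(1, 2 * e + 1, 3))
    } else bin
    lab <- EBImage::bwlabel(linked)
    lab[bin == 0] <- 0   # centroids come from real ridge pixels only
    nobj <- max(lab)
    if (nobj == 0) next
    for (obj in seq_len(nobj)) {
      px <- which(lab == obj, arr.ind = TRUE)
      if (nrow(px) < min_frames) next
      w <- mat[px]
      cols_t <- sort(unique(px[, 2]))
      if (length(cols_t) < min_frames) next
      cen <- vapply(cols_t, function(tc) {
        sel <- px[, 2] == tc
        sum(px[sel, 1] * w[sel]) / sum(w[sel])
      }, 0)
      t_s <- (cols_t - 1) * k$time_step_s
      d_um <- (cen - 1) * k$distance_step_um
      fit <- stats::lm.fit(cbind(1, t_s), d_um)
      speed <- fit$coefficients[2]
      displacement <- d_um[length(d_um)] - d_um[1]
      if (abs(displacement) < min_displacement_um) next
      if (abs(speed) < min_speed_um_s) next
      d_range <- range(d_um)
      # pad the span tests by one frame of travel: the first sampled frame of
      # a particle born near the span edge sits up to v*dt beyond it
      pad <- max_speed_um_s * k$time_step_s + k$distance_step_um
      if (d_range[2] < cluster_span[1] - pad ||
          d_range[1] > cluster_span[2] + pad) next
      x_start <- d_um[1]
      origin <- if (has_red && ch == "red" &&
                    x_start >= cluster_span[1] - pad &&
                    x_start <= cluster_span[2] + pad) "cluster" else "other"
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, t_start_s = t_s[1], t_end_s = t_s[length(t_s)],
        x_start_um = x_start, x_end_um = d_um[length(d_um)],
        displacement_um = displacement, speed_um_s = unname(speed),
        direction = if (displacement > 0) "anterograde" else "retrograde",
        origin = origin, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(channel = character(), t_start_s = numeric(),
                      t_end_s = numeric(), x_start_um = numeric(),
                      x_end_um = numeric(), displacement_um = numeric(),
                      speed_um_s = numeric(), direction = character(),
                      origin = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-cell trafficking-event fractions and cohort means
#'
#' Each trafficking event is expressed as a fraction of its cell's total
#' events, split along two dichotomies: cluster- vs other-origin, and
#' antero- vs retrograde. Cells with zero events (no mitochondrial movement)
#' are excluded rather than counted as zero. The cohort mean is the
#' unweighted mean of per-cell fractions.
#'
#' @param events_per_cell named list of event data.frames (one per cell, as
#'   from [detect_and_classify_events()]).
#' @return list with `per_cell` (data.frame: cell_id, n_events,
#'   cluster_fraction, other_fraction, anterograde_fraction,
#'   retrograde_fraction), `cohort` (named vector of means), `n_excluded`.
#' @export
event_fractions <- function(events_per_cell) {
  if (is.null(names(events_per_cell))) {
    names(events_per_cell) <- sprintf("cell%03d",
                                      seq_along(events_per_cell))
  }
  rows <- list()
  n_excluded <- 0L
  for (id in names(events_per_cell)) {
    ev <- events_per_cell[[id]]
    n <- nrow(ev)
    if (n == 0) { n_excluded <- n_excluded + 1L; next }
    rows[[id]] <- data.frame(
      cell_id = id, n_events = n,
      cluster_fraction = mean(ev$origin == "cluster"),
      other_fraction = mean(ev$origin == "other"),
      anterograde_fraction = mean(ev$direction == "anterograde"),
      retrograde_fraction = mean(ev$direction == "retrograde"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("all cells excluded: no trafficking events")
  per_cell <- do.call(rbind, rows)
  rownames(per_cell) <- NULL
  cohort <- colMeans(per_cell[, c("cluster_fraction", "other_fraction",
                                  "anterograde_fraction",
                                  "retrograde_fraction")])
  list(per_cell = per_cell, cohort = cohort, n_excluded = n_excluded)
}
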