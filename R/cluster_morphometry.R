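# Per-cell classification of the AIS-mitochondria cluster, the cohort ratio,
# and mitochondrial mass vs axon volume/diameter comparisons.

#' Criteria for calling an AIS-mitochondria cluster
#'
#' Three criteria, evaluated on AIS-aligned profiles:
#' 1. mitochondria present in the proximal AIS (within
#'    `proximal_window_um` of the AIS start): mean binary presence at least
#'    `presence_min_fraction`;
#' 2. relative absence in the central AIS: central presence mean at most
#'    `central_absence_max_ratio` times the proximal mean;
#' 3. visible accumulation / higher brightness: proximal peak intensity at
#'    least `brightness_min_gain` times the brightness of comparable
#'    mitochondria outside the proximal window.
#'
#' The qualitative criteria are visual in origin; the numeric thresholds are
#' configurable with defaults that separate strongly clustered from
#' cluster-free cells.
#'
#' @param proximal_window_um half-width of the proximal window around the AIS
#'   start (default 7.5).
#' @param presence_min_fraction criterion-1 threshold (default 0.3).
#' @param central_absence_max_ratio criterion-2 ratio alpha in (0, 1]
#'   (default 0.5).
#' @param brightness_min_gain criterion-3 gain beta >= 1 (default 1.5).
#' @param central_window_um central-AIS span relative to the AIS start
#'   (default c(10, 20), the shared "central" region definition).
#' @export
cluster_criteria <- function(proximal_window_um = 7.5,
                             presence_min_fraction = 0.3,
                             central_absence_max_ratio = 0.5,
                             brightness_min_gain = 1.5,
                             central_window_um = c(10, 20)) {
  stopifnot(proximal_window_um > 0,
            central_absence_max_ratio > 0, central_absence_max_ratio <= 1,
            brightness_min_gain >= 1)
  structure(list(proximal_window_um = proximal_window_um,
                 presence_min_fraction = presence_min_fraction,
                 central_absence_max_ratio = central_absence_max_ratio,
                 brightness_min_gain = brightness_min_gain,
                 central_window_um = central_window_um),
            class = "cluster_criteria")
}

#' Classify one cell's AIS-mitochondria cluster
#'
#' Evaluates the three criteria on the cell's binary presence profile and raw
#' intensity profile (both along the same axon path) and assigns the
#' category: `"+"` when all 3 criteria are met, `"~"` when 2 are met, `"-"`
#' for at most 1. All criteria are ratios or fractions, so the call is
#' invariant to multiplicative intensity gain.
#'
#' @param presence a [line_profile()] with values in {0, 1}.
#' @param intensity a [line_profile()] of raw mitochondrial intensity along
#'   the same path (same step).
#' @param ais_start an [detect_ais_start()] result (or a number, um).
#' @param criteria a [cluster_criteria()].
#' @return list of class `cluster_call`: `cell_id`, `c1`, `c2`, `c3`,
#'   `n_met`, `category`, `valid`, and the supporting `proximal_presence`,
#'   `central_presence`, `proximal_peak`, `axonal_reference`. Cells whose
#'   profile does not reach the end of the central window are marked
#'   `valid = FALSE` (category NA) and should be excluded.
#' @export
classify_cluster <- function(presence, intensity, ais_start,
                             criteria = cluster_criteria()) {
  start_um <- if (inherits(ais_start, "ais_start")) ais_start$start_um else
    as.numeric(ais_start)
  pos_p <- profile_positions(presence)
  pos_i <- profile_positions(intensity)
  central <- start_um + criteria$central_window_um
  if (max(pos_p) < central[2] || max(pos_i) < central[2]) {
    return(structure(list(cell_id = presence$cell_id, c1 = NA, c2 = NA,
                          c3 = NA, n_met = NA_integer_,
                          category = NA_character_, valid = FALSE),
                     class = "cluster_call"))
  }
  prox <- abs(pos_p - start_um) <= criteria$proximal_window_um
  cen <- pos_p >= central[1] & pos_p <= central[2]
  prox_mean <- mean(presence$values[prox])
  cen_mean <- mean(presence$values[cen])
  prox_i <- abs(pos_i - start_um) <= criteria$proximal_window_um
  prox_peak <- max(intensity$values[prox_i])
  # brightness reference: upper (90th-percentile) intensity where
  # mitochondria sit outside the proximal window, i.e. the brightness of
  # comparable mitochondria further along the axon -- the criterion compares
  # mitochondria against mitochondria, not against empty-axon background
  n_common <- min(length(pos_p), length(pos_i))
  outside_mito <- presence$values[seq_len(n_common)] > 0 &
    !prox_i[seq_len(n_common)]
  ax_median <- if (any(outside_mito)) {
    unname(stats::quantile(intensity$values[seq_len(n_common)][outside_mito],
                           0.9))
  } else {
    stats::median(intensity$values)
  }
  c1 <- prox_mean >= criteria$presence_min_fraction
  c2 <- cen_mean <= criteria$central_absence_max_ratio * prox_mean
  c3 <- prox_peak >= criteria$brightness_min_gain * ax_median
  n_met <- sum(c1, c2, c3)
  category <- if (n_met == 3) "+" else if (n_met == 2) "~" else "-"
  structure(list(cell_id = presence$cell_id, c1 = c1, c2 = c2, c3 = c3,
                 n_met = n_met, category = category, valid = TRUE,
                 proximal_presence = prox_mean, central_presence = cen_mean,
                 proximal_peak = prox_peak, axonal_reference = ax_median),
            class = "cluster_call")
}

#' Cohort cluster ratio and positive fraction
#'
#' The printed cohort statistic is
#' `Ratio = n_total / (n_plus + 0.5 * n_tilde)` (values >= 1); its
#' reciprocal, `positive_fraction = (n_plus + 0.5 * n_tilde) / n_total`, is
#' on the 0-1 scale of a "fraction of cells showing the cluster morphology"
#' and is reported alongside. When `n_plus + 0.5 * n_tilde = 0` the printed
#' ratio is undefined (returned as NA) and the fraction is 0. Whenever both
#' are defined, `printed_ratio * positive_fraction == 1`.
#'
#' @param n_plus,n_tilde,n_minus category counts.
#' @return list with `printed_ratio`, `positive_fraction`, `n_total` and the
#'   counts.
#' @export
cluster_ratio <- function(n_plus, n_tilde, n_minus) {
  n_total <- n_plus + n_tilde + n_minus
  if (n_total <= 0) stop("n_total must be positive")
  denom <- n_plus + 0.5 * n_tilde
  list(printed_ratio = if (denom > 0) n_total / denom else NA_real_,
       positive_fraction = denom / n_total,
       n_total = n_total, n_plus = n_plus, n_tilde = n_tilde,
       n_minus = n_minus)
}

#' Summarise a list of cluster calls
#'
#' Drops invalid cells, tabulates categories and computes [cluster_ratio()].
#' @param calls list of [classify_cluster()] results.
#' @return list with `counts` (named vector `+`, `~`, `-`), `n_excluded` and
#'   the `cluster_ratio()` fields.
#' @export
summarize_cluster_calls <- function(calls) {
  valid <- Filter(function(x) isTRUE(x$valid), calls)
  cats <- vapply(valid, `[[`, "", "category")
  counts <- c(`+` = sum(cats == "+"), `~` = sum(cats == "~"),
              `-` = sum(cats == "-"))
  c(list(counts = counts, n_excluded = length(calls) - length(valid)),
    cluster_ratio(counts[["+"]], counts[["~"]], counts[["-"]]))
}

#' Axon diameter and extrapolated cross-sectional area along a path
#'
#' At every `step_um` of arclength the diameter is the full width at half
#' maximum (FWHM) of the intensity cut perpendicular to the local tangent of
#' the volume-marker channel; the cross-sectional area is extrapolated from
#' the diameter as `area = (diameter / 2)^2 * 0.6 * pi` (the axon is modelled
#' as 60% of the circular cross-section).
#'
#' @param stack an [image_stack()].
#' @param path a [path_annotation()].
#' @param channel volume-marker channel (default `"VOL"`).
#' @param step_um sampling step (default 1 um).
#' @param max_radius_um half-length of the perpendicular cut (default 3 um).
#' @return data.frame with columns arclength_um, diameter_um, area_um2,
#'   skipped (TRUE where the cut left the image or no half-max crossing
#'   exists).
#' @export
diameter_and_area_profile <- function(stack, path, channel = "VOL",
                                      step_um = 1.0, max_radius_um = 3) {
  img <- get_channel(stack, channel)
  ps <- stack$pixel_size_um
  total_um <- max(polyline_arclength(path$points_px, ps))
  s_um <- seq(0, total_um, by = step_um)
  samp <- polyline_sample(path$points_px, s_um / ps)
  offs_um <- seq(-max_radius_um, max_radius_um, by = ps / 2)
  rows <- lapply(seq_along(s_um), function(i) {
    xs <- samp$xy[i, 1] + (offs_um / ps) * samp$normal[i, 1]
    ys <- samp$xy[i, 2] + (offs_um / ps) * samp$normal[i, 2]
    cut <- bilinear(img, xs, ys)
    if (anyNA(cut)) {
      return(data.frame(arclength_um = s_um[i], diameter_um = NA,
                        area_um2 = NA, skipped = TRUE))
    }
    d <- fwhm_of_cut(offs_um, cut)
    data.frame(arclength_um = s_um[i], diameter_um = d,
               area_um2 = cross_section_area(d), skipped = is.na(d))
  })
  do.call(rbind, rows)
}

# Full width at half maximum of a 1-D cut; linear interpolation at the
# crossings nearest the peak. NA when the cut does not fall to half max on
# both sides.
fwhm_of_cut <- function(x, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  if (y[pk] <= 0) return(NA_real_)
  left <- NA_real_
  for (i in seq(pk, 2)) {
    if (y[i - 1] < half && y[i] >= half) {
      left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) *
        (x[i] - x[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(pk, length(y) - 1)) {
    if (y[i + 1] < half && y[i] >= half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Cross-sectional area extrapolated from a diameter
#'
#' `area = (diameter / 2)^2 * 0.6 * pi` (um^2 for um input).
#' @param diameter_um axon diameter.
#' @export
cross_section_area <- function(diameter_um) {
  (diameter_um / 2)^2 * 0.6 * pi
}

#' Mitochondrial mass vs axon volume on the AIS-aligned axis
#'
#' Both raw profiles are aligned to the AIS start and each is divided by its
#' own first retained value, so both curves start at 1; a mass/volume ratio
#' rising above 1 in the proximal window is the brightness signature of the
#' cluster that binary presence cannot show.
#'
#' @param mito,volume [line_profile()]s along the same path (same step).
#' @param ais_start an [detect_ais_start()] result or a number (um).
#' @return data.frame with columns position_um (relative to AIS start),
#'   mito_rel, volume_rel, ratio.
#' @export
mass_vs_volume_profile <- function(mito, volume, ais_start) {
  start_um <- if (inherits(ais_start, "ais_start")) ais_start$start_um else
    as.numeric(ais_start)
  if (abs(mito$step_um - volume$step_um) > 1e-9) {
    stop("profiles must share one step_um")
  }
  n <- min(length(mito$values), length(volume$values))
  pos <- (seq_len(n) - 1) * mito$step_um - start_um
  keep <- pos >= 0
  m <- mito$values[seq_len(n)][keep]
  v <- volume$values[seq_len(n)][keep]
  if (m[1] <= 0 || v[1] <= 0) {
    stop("first retained profile value must be positive for normalization")
  }
  data.frame(position_um = pos[keep], mito_rel = m / m[1],
             volume_rel = v / v[1], ratio = (m / m[1]) / (v / v[1]))
}
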