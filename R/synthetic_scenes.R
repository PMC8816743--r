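# Synthetic fluorescence neuron scenes and time-lapse movies with ground truth.
#
# The generator emulates the statistical structure of the real data behind the
# quantifications: a soma with dendrites and one axon, an AIS-marker channel
# ramping up at a defined start point, punctate mitochondria optionally
# clustered within +/- 7.5 um of the AIS start and depleted in the central
# AIS, somatodendritic MAP2/TAU with a configurable somatic-TAU fold, and
# scripted moving particles for trafficking movies. Every scene returns the
# ground truth needed to score the downstream estimators.

#' Configuration of a synthetic neuron scene
#'
#' Defaults are the study conditions used throughout the package's tests:
#' 0.25 um pixels on a 384 px canvas (96 um field), an 8 um soma, a 60 um
#' axon whose AIS-marker signal starts 5 um from the soma edge, and punctate
#' mitochondria at 0.15 per um baseline density. A "cluster-positive" cell
#' adds `cluster_mito_count` puncta within `cluster_window_um` of the AIS
#' start, amplified by `cluster_amplitude_gain`, and thins central-AIS puncta
#' by `central_depletion_factor`.
#'
#' @param pixel_size_um isotropic pixel size (um/px).
#' @param image_size_px canvas size, either one integer (square) or c(ny, nx).
#' @param soma_radius_um soma disc radius.
#' @param n_dendrites number of dendrites.
#' @param axon_length_um axon arclength from the soma edge.
#' @param ais_start_um arclength of AIS onset, measured from the soma edge
#'   along the axon path (the path annotation also starts at the soma edge).
#' @param ais_length_um AIS plateau length beyond the 1 um onset ramp.
#' @param cluster_present render an AIS-mitochondria cluster.
#' @param cluster_window_um half-width of the proximal cluster region around
#'   the AIS start (default 7.5).
#' @param cluster_mito_count puncta in the cluster.
#' @param cluster_amplitude_gain amplitude gain of cluster puncta vs baseline.
#' @param central_depletion_factor in [0, 1]; probability of keeping a
#'   baseline punctum in the central AIS when the cluster is present.
#' @param baseline_mito_density baseline puncta per um of neurite.
#' @param mito_sigma_um Gaussian sigma of one punctum.
#' @param tau_somatic_fold somatic TAU mean as a multiple of the fixed axonal
#'   TAU reference (the "treatment effect"; 1 = control).
#' @param map2_somatic_ratio somatic / dendritic MAP2 intensity ratio.
#' @param background_level constant background added to every channel.
#' @param poisson_scale photons per intensity unit for shot noise (0 = off).
#' @param gaussian_sd read-noise standard deviation (0 = off).
#' @param fill_proximal,fill_central render a dense punctum train across the
#'   proximal ([-5, +5] um) / central ([+10, +20] um) window relative to the
#'   AIS start; used for Bernoulli presence-probability cohorts.
#' @param mito_amplitude,ais_amplitude,map2_amplitude,tau_axon_level,
#'   vol_amplitude channel amplitudes (arbitrary units).
#' @param axon_width_um,dendrite_width_um rendered neurite widths (FWHM) at
#'   the soma; the axon tapers to 60% of this width at its tip.
#' @param seed RNG seed for this scene.
#' @return a `scene_config` list.
#' @export
scene_config <- function(pixel_size_um = 0.25, image_size_px = 384,
                         soma_radius_um = 8, n_dendrites = 3,
                         axon_length_um = 60, ais_start_um = 5,
                         ais_length_um = 25, cluster_present = FALSE,
                         cluster_window_um = 7.5, cluster_mito_count = 6,
                         cluster_amplitude_gain = 3,
                         central_depletion_factor = 0.3,
                         baseline_mito_density = 0.15, mito_sigma_um = 0.4,
                         tau_somatic_fold = 1, map2_somatic_ratio = 2.3,
                         background_level = 10, poisson_scale = 1,
                         gaussian_sd = 2, fill_proximal = NA,
                         fill_central = NA, mito_amplitude = 120,
                         ais_amplitude = 100, map2_amplitude = 100,
                         tau_axon_level = 40, vol_amplitude = 100,
                         axon_width_um = 1.2, dendrite_width_um = 1.6,
                         seed = 1L) {
  if (length(image_size_px) == 1) image_size_px <- c(image_size_px, image_size_px)
  cfg <- list(pixel_size_um = pixel_size_um, image_size_px = image_size_px,
              soma_radius_um = soma_radius_um, n_dendrites = n_dendrites,
              axon_length_um = axon_length_um, ais_start_um = ais_start_um,
              ais_length_um = ais_length_um, cluster_present = cluster_present,
              cluster_window_um = cluster_window_um,
              cluster_mito_count = cluster_mito_count,
              cluster_amplitude_gain = cluster_amplitude_gain,
              central_depletion_factor = central_depletion_factor,
              baseline_mito_density = baseline_mito_density,
              mito_sigma_um = mito_sigma_um,
              tau_somatic_fold = tau_somatic_fold,
              map2_somatic_ratio = map2_somatic_ratio,
              background_level = background_level,
              poisson_scale = poisson_scale, gaussian_sd = gaussian_sd,
              fill_proximal = fill_proximal, fill_central = fill_central,
              mito_amplitude = mito_amplitude, ais_amplitude = ais_amplitude,
              map2_amplitude = map2_amplitude, tau_axon_level = tau_axon_level,
              vol_amplitude = vol_amplitude, axon_width_um = axon_width_um,
              dendrite_width_um = dendrite_width_um, seed = seed)
  lens <- c("pixel_size_um", "soma_radius_um", "axon_length_um",
            "ais_length_um", "cluster_window_um", "mito_sigma_um",
            "axon_width_um", "dendrite_width_um")
  for (f in lens) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("configuration error: ", f, " must be positive")
    }
  }
  if (cfg$ais_start_um < 0) stop("configuration error: ais_start_um < 0")
  if (cfg$central_depletion_factor < 0 || cfg$central_depletion_factor > 1) {
    stop("configuration error: central_depletion_factor must be in [0, 1]")
  }
  if (cfg$tau_somatic_fold < 0) {
    stop("configuration error: tau_somatic_fold must be >= 0")
  }
  structure(cfg, class = "scene_config")
}

#' Turn all noise sources of a scene config off
#' @param config a `scene_config`.
#' @export
no_noise <- function(config) {
  config$poisson_scale <- 0
  config$gaussian_sd <- 0
  config$background_level <- 0
  config
}

# ---- low-level renderers ---------------------------------------------------

# Add Gaussian puncta to a canvas; each stamp is confined to a +/- 4 sigma
# window so rendering cost scales with puncta, not canvas size.
stamp_puncta <- function(canvas, x_px, y_px, amplitude, sigma_px) {
  ny <- nrow(canvas); nx <- ncol(canvas)
  sigma_px <- rep_len(sigma_px, length(x_px))
  amplitude <- rep_len(amplitude, length(x_px))
  for (i in seq_along(x_px)) {
    r <- ceiling(4 * sigma_px[i])
    xr <- max(0, floor(x_px[i] - r)):min(nx - 1, ceiling(x_px[i] + r))
    yr <- max(0, floor(y_px[i] - r)):min(ny - 1, ceiling(y_px[i] + r))
    if (!length(xr) || !length(yr)) next
    gx <- exp(-(xr - x_px[i])^2 / (2 * sigma_px[i]^2))
    gy <- exp(-(yr - y_px[i])^2 / (2 * sigma_px[i]^2))
    canvas[yr + 1, xr + 1] <- canvas[yr + 1, xr + 1] +
      amplitude[i] * outer(gy, gx)
  }
  canvas
}

# Distance/arclength field of a polyline: for every pixel within `pad_px` of
# the polyline, the perpendicular distance to the nearest point and the
# arclength of that point. Used to render tubes with axial intensity and
# width profiles.
polyline_field <- function(dim_yx, points_px, pad_px) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  best_d2 <- matrix(Inf, ny, nx)
  best_arc <- matrix(NA_real_, ny, nx)
  seg <- diff(points_px)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  for (k in seq_len(nrow(seg))) {
    p0 <- points_px[k, ]; sv <- seg[k, ]; L2 <- sum(sv^2)
    x0 <- max(0, floor(min(points_px[k:(k + 1), 1]) - pad_px))
    x1 <- min(nx - 1, ceiling(max(points_px[k:(k + 1), 1]) + pad_px))
    y0 <- max(0, floor(min(points_px[k:(k + 1), 2]) - pad_px))
    y1 <- min(ny - 1, ceiling(max(points_px[k:(k + 1), 2]) + pad_px))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    px <- matrix(rep(xs, each = length(ys)), length(ys))
    py <- matrix(rep(ys, times = length(xs)), length(ys))
    tt <- ((px - p0[1]) * sv[1] + (py - p0[2]) * sv[2]) / L2
    tt <- pmin(pmax(tt, 0), 1)
    dx <- px - (p0[1] + tt * sv[1]); dy <- py - (p0[2] + tt * sv[2])
    d2 <- dx * dx + dy * dy
    sub <- best_d2[ys + 1, xs + 1]
    upd <- d2 < sub
    sub[upd] <- d2[upd]
    best_d2[ys + 1, xs + 1] <- sub
    arc_sub <- best_arc[ys + 1, xs + 1]
    arc_new <- cum[k] + tt * seg_len[k]
    arc_sub[upd] <- arc_new[upd]
    best_arc[ys + 1, xs + 1] <- arc_sub
  }
  list(d2 = best_d2, arc = best_arc)
}

# Render a tube along a polyline as a flat-top profile with a soft edge:
# intensity = axial(arc_um) * plogis((width/2 - d) / edge). The full width at
# half maximum of the cross-section equals width_fun_um(arc) exactly, so
# FWHM-based diameter measurements recover the rendered width.
render_tube <- function(dim_yx, points_px, pixel_size_um, axial_fun,
                        width_fun_um, edge_px = 0.8) {
  arc_all <- polyline_arclength(points_px, pixel_size_um)
  max_w <- max(width_fun_um(seq(0, max(arc_all), length.out = 50)))
  pad_px <- ceiling((max_w / 2) / pixel_size_um + 4 * edge_px) + 1
  f <- polyline_field(dim_yx, points_px, pad_px)
  out <- matrix(0, dim_yx[1], dim_yx[2])
  hit <- is.finite(f$d2) & !is.na(f$arc)
  arc_um <- f$arc[hit] * pixel_size_um
  half_px <- (width_fun_um(arc_um) / 2) / pixel_size_um
  out[hit] <- axial_fun(arc_um) *
    stats::plogis((half_px - sqrt(f$d2[hit])) / edge_px)
  out
}

# Soft-edged disc centred at (cx, cy) px with radius r_px.
render_disc <- function(dim_yx, cx, cy, r_px, amplitude, edge_px = 1) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  xs <- 0:(nx - 1); ys <- 0:(ny - 1)
  r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  amplitude * stats::plogis((r_px - r) / edge_px)
}

# Smooth random polyline from `start` with initial heading, steered back
# towards the canvas centre near the margin so paths stay in bounds and never
# self-cross (curvature is bounded by `wiggle_sd`).
random_polyline <- function(start, heading, length_um, pixel_size_um, dim_yx,
                            step_um = 2, wiggle_sd = 0.12, margin_px = 10) {
  n_seg <- max(2L, ceiling(length_um / step_um))
  step_px <- (length_um / n_seg) / pixel_size_um
  pts <- matrix(NA_real_, n_seg + 1, 2)
  pts[1, ] <- start
  cx <- (dim_yx[2] - 1) / 2; cy <- (dim_yx[1] - 1) / 2
  h <- heading
  for (k in seq_len(n_seg)) {
    h <- h + stats::rnorm(1, 0, wiggle_sd)
    nxt <- pts[k, ] + step_px * c(cos(h), sin(h))
    if (nxt[1] < margin_px || nxt[1] > dim_yx[2] - 1 - margin_px ||
        nxt[2] < margin_px || nxt[2] > dim_yx[1] - 1 - margin_px) {
      # steer towards the centre instead
      h_c <- atan2(cy - pts[k, 2], cx - pts[k, 1])
      h <- h + 0.5 * (h_c - h)
      nxt <- pts[k, ] + step_px * c(cos(h), sin(h))
    }
    pts[k + 1, ] <- nxt
  }
  if (any(pts[, 1] < 2) || any(pts[, 1] > dim_yx[2] - 3) ||
      any(pts[, 2] < 2) || any(pts[, 2] > dim_yx[1] - 3)) {
    stop("configuration error: neuron geometry does not fit image_size_px")
  }
  pts
}

# Apply background + shot + read noise to a clean channel.
apply_noise <- function(clean, background_level, poisson_scale, gaussian_sd) {
  img <- clean + background_level
  if (poisson_scale > 0) {
    img[] <- stats::rpois(length(img), pmax(img, 0) * poisson_scale) /
      poisson_scale
  }
  if (gaussian_sd > 0) {
    img[] <- img + stats::rnorm(length(img), 0, gaussian_sd)
  }
  pmax(img, 0)
}

# ---- scene layout (geometry + puncta), shared by stills and movies ---------

scene_layout <- function(config) {
  dim_yx <- config$image_size_px
  ps <- config$pixel_size_um
  soma_r_px <- config$soma_radius_um / ps
  margin <- 10
  soma_c <- c(margin + soma_r_px + 4,
              (dim_yx[1] - 1) / 2 + stats::rnorm(1, 0, 2))
  axon_start <- soma_c + c(soma_r_px, 0)
  axon <- random_polyline(axon_start, heading = stats::rnorm(1, 0, 0.1),
                          length_um = config$axon_length_um,
                          pixel_size_um = ps, dim_yx = dim_yx)
  dendrites <- list()
  if (config$n_dendrites > 0) {
    angles <- pi + seq(-1, 1, length.out = config$n_dendrites + 2)[
      2:(config$n_dendrites + 1)] * 1.2 + stats::rnorm(config$n_dendrites, 0, 0.1)
    dendrites <- lapply(angles, function(a) {
      start <- soma_c + soma_r_px * c(cos(a), sin(a))
      random_polyline(start, a, length_um = 25, pixel_size_um = ps,
                      dim_yx = dim_yx, wiggle_sd = 0.15)
    })
  }
  axon_len <- max(polyline_arclength(axon, ps))

  s0 <- config$ais_start_um
  central_win <- s0 + c(10, 20)   # matches region_means default central window
  prox_fill_win <- s0 + c(-5, 5)
  puncta <- data.frame(arclength_um = numeric(), amplitude = numeric(),
                       origin = character())
  # baseline puncta along the axon (Poisson process)
  n_base <- stats::rpois(1, config$baseline_mito_density * axon_len)
  if (n_base > 0) {
    s_base <- sort(stats::runif(n_base, 0, axon_len))
    amp <- config$mito_amplitude * stats::runif(n_base, 0.7, 1.3)
    keep <- rep(TRUE, n_base)
    if (config$cluster_present && config$central_depletion_factor < 1) {
      central <- s_base >= central_win[1] & s_base <= central_win[2]
      keep[central] <- stats::runif(sum(central)) < config$central_depletion_factor
    }
    if (isTRUE(config$fill_proximal) || isTRUE(config$fill_central) ||
        isFALSE(config$fill_proximal) || isFALSE(config$fill_central)) {
      # Bernoulli presence mode: windows are controlled explicitly, so drop
      # chance baseline puncta from both windows
      in_win <- (s_base >= prox_fill_win[1] & s_base <= prox_fill_win[2]) |
        (s_base >= central_win[1] & s_base <= central_win[2])
      keep[in_win] <- FALSE
    }
    if (any(keep)) {
      puncta <- rbind(puncta, data.frame(arclength_um = s_base[keep],
                                         amplitude = amp[keep],
                                         origin = "baseline"))
    }
  }
  if (config$cluster_present && config$cluster_mito_count > 0) {
    s_cl <- stats::runif(config$cluster_mito_count,
                         max(0, s0 - config$cluster_window_um),
                         s0 + config$cluster_window_um)
    puncta <- rbind(puncta, data.frame(
      arclength_um = s_cl,
      amplitude = config$mito_amplitude * config$cluster_amplitude_gain *
        stats::runif(config$cluster_mito_count, 0.85, 1.15),
      origin = "cluster"))
  }
  for (win_flag in c("fill_proximal", "fill_central")) {
    if (isTRUE(config[[win_flag]])) {
      win <- if (win_flag == "fill_proximal") prox_fill_win else central_win
      win[1] <- max(0, win[1])
      s_fill <- seq(win[1] + 0.3, win[2] - 0.3, by = 0.8)
      puncta <- rbind(puncta, data.frame(
        arclength_um = s_fill,
        amplitude = config$mito_amplitude *
          stats::runif(length(s_fill), 0.9, 1.1),
        origin = sub("fill_", "", win_flag)))
    }
  }
  # dendritic baseline puncta (rendered only; not part of axonal truth)
  dend_puncta <- lapply(dendrites, function(d) {
    len <- max(polyline_arclength(d, ps))
    n <- stats::rpois(1, config$baseline_mito_density * len)
    sort(stats::runif(n, 0, len))
  })
  list(dim_yx = dim_yx, soma_c = soma_c, soma_r_px = soma_r_px, axon = axon,
       dendrites = dendrites, axon_len = axon_len, puncta = puncta,
       dend_puncta = dend_puncta, central_win = central_win)
}

# xy pixel position of arclength s_um along a polyline
arc_to_xy <- function(points_px, s_um, pixel_size_um) {
  polyline_sample(points_px, s_um / pixel_size_um)$xy
}

# ---- public generators -----------------------------------------------------

#' Generate one synthetic neuron scene
#'
#' Renders channels `MAP2`, `AIS`, `MITO`, `TAU`, `VOL` on one frame. The AIS
#' channel is zero before `ais_start_um`, rises linearly over 1 um to a
#' plateau of length `ais_length_um` and then decays exponentially. MAP2 is
#' high in soma and dendrites and decays along the proximal axon; TAU's
#' somatic mean is `tau_somatic_fold` times the fixed axonal reference; VOL
#' fills the neuron with a tapering width profile; MITO is a sum of Gaussian
#' puncta. Identical config + seed gives identical pixels.
#'
#' @param config a [scene_config()].
#' @param cell_id identifier used in annotations and ground truth.
#' @param replicate_id replicate label carried into annotations/ground truth.
#' @return list with `stack` (an [image_stack()]), `truth` (ground-truth
#'   list: `ais_start_um`, `ais_length_um`, `axon_length_um`, `soma_center_px`,
#'   puncta table with arclengths/positions/amplitudes/origins, true
#'   `category` ("+" when `cluster_present` else "-"), `tau_somatic_fold`,
#'   `map2_somatic_ratio`), and `annotations` (axon + first-dendrite paths,
#'   soma and background ROIs).
#' @export
generate_scene <- function(config, cell_id = "cell1", replicate_id = "r1") {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    lay <- scene_layout(config)
    ps <- config$pixel_size_um
    dim_yx <- lay$dim_yx
    s0 <- config$ais_start_um

    ais_axial <- function(s) {
      config$ais_amplitude * ifelse(
        s < s0, 0,
        ifelse(s < s0 + 1, s - s0,
               ifelse(s < s0 + config$ais_length_um, 1,
                      exp(-(s - s0 - config$ais_length_um) / 3))))
    }
    axon_width <- function(s) {
      config$axon_width_um * (1 - 0.4 * pmin(s / lay$axon_len, 1))
    }
    dend_width <- function(s) config$dendrite_width_um * (1 - 0.5 * pmin(s / 25, 1))

    vol <- render_disc(dim_yx, lay$soma_c[1], lay$soma_c[2], lay$soma_r_px,
                       config$vol_amplitude) +
      render_tube(dim_yx, lay$axon, ps,
                  function(s) config$vol_amplitude, axon_width)
    map2 <- render_disc(dim_yx, lay$soma_c[1], lay$soma_c[2], lay$soma_r_px,
                        config$map2_amplitude * config$map2_somatic_ratio) +
      render_tube(dim_yx, lay$axon, ps,
                  function(s) config$map2_amplitude * exp(-s / 3), axon_width)
    tau <- render_disc(dim_yx, lay$soma_c[1], lay$soma_c[2], lay$soma_r_px,
                       config$tau_axon_level * config$tau_somatic_fold) +
      render_tube(dim_yx, lay$axon, ps,
                  function(s) config$tau_axon_level, axon_width)
    for (d in lay$dendrites) {
      vol <- vol + render_tube(dim_yx, d, ps,
                               function(s) config$vol_amplitude, dend_width)
      map2 <- map2 + render_tube(dim_yx, d, ps,
                                 function(s) config$map2_amplitude, dend_width)
      tau <- tau + render_tube(dim_yx, d, ps,
                               function(s) 0.2 * config$tau_axon_level,
                               dend_width)
    }
    ais <- render_tube(dim_yx, lay$axon, ps, ais_axial, axon_width)

    mito <- render_disc(dim_yx, lay$soma_c[1], lay$soma_c[2], lay$soma_r_px,
                        0.2 * config$mito_amplitude)
    sig_px <- config$mito_sigma_um / ps
    puncta <- lay$puncta
    if (nrow(puncta) > 0) {
      xy <- arc_to_xy(lay$axon, puncta$arclength_um, ps)
      puncta$x_px <- xy[, 1]; puncta$y_px <- xy[, 2]
      mito <- stamp_puncta(mito, puncta$x_px, puncta$y_px, puncta$amplitude,
                           sig_px)
    } else {
      puncta$x_px <- numeric(0); puncta$y_px <- numeric(0)
    }
    for (i in seq_along(lay$dendrites)) {
      sd_ <- lay$dend_puncta[[i]]
      if (length(sd_)) {
        xy <- arc_to_xy(lay$dendrites[[i]], sd_, ps)
        mito <- stamp_puncta(mito, xy[, 1], xy[, 2],
                             config$mito_amplitude, sig_px)
      }
    }

    chans <- list(MAP2 = map2, AIS = ais, MITO = mito, TAU = tau, VOL = vol)
    px <- array(0, dim = c(1, length(chans), dim_yx[1], dim_yx[2]))
    for (i in seq_along(chans)) {
      px[1, i, , ] <- apply_noise(chans[[i]], config$background_level,
                                  config$poisson_scale, config$gaussian_sd)
    }
    stack <- image_stack(px, names(chans), ps)

    theta <- seq(0, 2 * pi, length.out = 25)[-25]
    soma_poly <- cbind(lay$soma_c[1] + lay$soma_r_px * cos(theta),
                       lay$soma_c[2] + lay$soma_r_px * sin(theta))
    bg_poly <- cbind(c(dim_yx[2] - 24, dim_yx[2] - 4, dim_yx[2] - 4,
                       dim_yx[2] - 24),
                     c(3, 3, 23, 23))
    annotations <- list(
      paths = c(list(path_annotation(cell_id, "axon", lay$axon)),
                if (length(lay$dendrites)) {
                  list(path_annotation(cell_id, "dendrite", lay$dendrites[[1]]))
                }),
      rois = list(roi_annotation(cell_id, "soma", soma_poly),
                  roi_annotation(cell_id, "background", bg_poly)))

    truth <- list(cell_id = cell_id, replicate_id = replicate_id,
                  ais_start_um = s0, ais_length_um = config$ais_length_um,
                  axon_length_um = lay$axon_len,
                  soma_center_px = lay$soma_c,
                  soma_radius_um = config$soma_radius_um,
                  puncta = puncta, mito_sigma_um = config$mito_sigma_um,
                  category = if (isTRUE(config$cluster_present)) "+" else "-",
                  fill_proximal = config$fill_proximal,
                  fill_central = config$fill_central,
                  tau_somatic_fold = config$tau_somatic_fold,
                  map2_somatic_ratio = config$map2_somatic_ratio)
    list(stack = stack, truth = truth, annotations = annotations)
  })
}

#' Script of trafficking events for a time-lapse movie
#'
#' @param t_start_s,x_start_um,velocity_um_per_s,duration_s,origin,channel
#'   parallel vectors, one entry per event. `origin` is `"cluster"` or
#'   `"other"`; `channel` is `"red"` or `"green"`. Cluster-origin events must
#'   start within `cluster_window_um` of the AIS start and be red (the
#'   photoconverted cluster population).
#' @param config the `scene_config` the script will be rendered against
#'   (used to validate cluster-origin start positions).
#' @return data.frame of class `event_script`.
#' @export
event_script <- function(t_start_s = numeric(), x_start_um = numeric(),
                         velocity_um_per_s = numeric(),
                         duration_s = numeric(), origin = character(),
                         channel = character(), config = NULL) {
  df <- data.frame(t_start_s = t_start_s, x_start_um = x_start_um,
                   velocity_um_per_s = velocity_um_per_s,
                   duration_s = duration_s, origin = as.character(origin),
                   channel = as.character(channel), stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$origin %in% c("cluster", "other")),
              all(df$channel %in% c("red", "green")),
              all(df$duration_s > 0), all(df$t_start_s >= 0))
    if (any(df$velocity_um_per_s == 0)) {
      stop("validation error: moving events must have non-zero velocity")
    }
    if (!is.null(config)) {
      cl <- df$origin == "cluster"
      bad <- cl & (abs(df$x_start_um - config$ais_start_um) >
                     config$cluster_window_um | df$channel != "red")
      if (any(bad)) {
        stop("validation error: cluster-origin events must start inside the ",
             "cluster window and be red")
      }
    }
  }
  class(df) <- c("event_script", "data.frame")
  df
}

#' Generate a two-channel time-lapse movie from an event script
#'
#' Renders `green`/`red` frames every `interval_s` for `duration_s` seconds.
#' When `cluster_present`, the photoconverted cluster appears as a stationary
#' red band at the cluster location in every frame; a few stationary green
#' puncta sit further along the axon. Each scripted event renders as a
#' Gaussian punctum moving at its velocity in its channel; events that exit
#' the axon extent mid-run are clipped and flagged in the ground truth.
#'
#' @param config a [scene_config()] (use a rectangular `image_size_px` for
#'   long axons).
#' @param script an [event_script()].
#' @param duration_s,interval_s movie length and frame interval (seconds).
#' @param cell_id cell identifier.
#' @return list with `stack` (time series [image_stack()]), `truth`
#'   (events table with a `clipped` flag, cluster span, axon path) and
#'   `annotations` (the axon path).
#' @export
generate_timelapse <- function(config, script, duration_s, interval_s,
                               cell_id = "cell1") {
  stopifnot(inherits(config, "scene_config"))
  if (interval_s <= 0 || duration_s < interval_s) {
    stop("configuration error: interval_s must be positive and <= duration_s")
  }
  with_seed(config$seed, {
    lay <- scene_layout(config)
    ps <- config$pixel_size_um
    dim_yx <- lay$dim_yx
    sig_px <- config$mito_sigma_um / ps
    times <- seq(0, duration_s, by = interval_s)

    static <- list(green = matrix(0, dim_yx[1], dim_yx[2]),
                   red = matrix(0, dim_yx[1], dim_yx[2]))
    static$green <- render_disc(dim_yx, lay$soma_c[1], lay$soma_c[2],
                                lay$soma_r_px, 0.15 * config$mito_amplitude)
    if (isTRUE(config$cluster_present)) {
      cl <- lay$puncta[lay$puncta$origin == "cluster", , drop = FALSE]
      if (nrow(cl)) {
        xy <- arc_to_xy(lay$axon, cl$arclength_um, ps)
        static$red <- stamp_puncta(static$red, xy[, 1], xy[, 2],
                                   cl$amplitude, sig_px)
      }
    }
    stat_other <- lay$puncta[lay$puncta$origin == "baseline", , drop = FALSE]
    if (nrow(stat_other)) {
      xy <- arc_to_xy(lay$axon, stat_other$arclength_um, ps)
      static$green <- stamp_puncta(static$green, xy[, 1], xy[, 2],
                                   stat_other$amplitude, sig_px)
    }

    ev <- as.data.frame(script)
    ev$clipped <- logical(nrow(ev))
    px <- array(0, dim = c(length(times), 2, dim_yx[1], dim_yx[2]))
    for (ti in seq_along(times)) {
      t <- times[ti]
      frame <- static
      if (nrow(ev)) {
        active <- which(t >= ev$t_start_s & t <= ev$t_start_s + ev$duration_s)
        for (i in active) {
          s <- ev$x_start_um[i] + ev$velocity_um_per_s[i] * (t - ev$t_start_s[i])
          if (s < 0 || s > lay$axon_len) {
            ev$clipped[i] <- TRUE
            next
          }
          xy <- arc_to_xy(lay$axon, s, ps)
          frame[[ev$channel[i]]] <- stamp_puncta(
            frame[[ev$channel[i]]], xy[1], xy[2],
            1.2 * config$mito_amplitude, sig_px)
        }
      }
      px[ti, 1, , ] <- apply_noise(frame$green, config$background_level,
                                   config$poisson_scale, config$gaussian_sd)
      px[ti, 2, , ] <- apply_noise(frame$red, config$background_level,
                                   config$poisson_scale, config$gaussian_sd)
    }
    stack <- image_stack(px, c("green", "red"), ps,
                         frame_interval_s = interval_s)
    cluster_span <- c(max(0, config$ais_start_um - config$cluster_window_um),
                      config$ais_start_um + config$cluster_window_um)
    truth <- list(cell_id = cell_id, events = ev, cluster_span = cluster_span,
                  ais_start_um = config$ais_start_um,
                  axon_length_um = lay$axon_len)
    annotations <- list(paths = list(path_annotation(cell_id, "axon",
                                                     lay$axon)),
                        rois = list())
    list(stack = stack, truth = truth, annotations = annotations)
  })
}

#' Generate a random, detector-compatible event script
#'
#' Events are drawn so that every track crosses or overlaps the cluster span
#' (the detector only counts events that go past the cluster) and so that no
#' two same-channel tracks come within `min_gap_um` of each other in
#' kymograph spacetime (time scaled to distance at 0.8 um/s), which keeps the
#' rendered ridges well separated even for tracks that nearly touch just
#' before/after one another.
#'
#' @param config a [scene_config()].
#' @param n_events number of events.
#' @param duration_s movie duration the script must fit in.
#' @param p_cluster probability that an event originates from the cluster
#'   (red, starting inside the cluster span).
#' @param speed_range_um_s absolute speed range.
#' @param min_gap_um minimum spacetime separation between same-channel
#'   tracks (um; default 8).
#' @param seed RNG seed.
#' @return an [event_script()].
#' @export
random_event_script <- function(config, n_events, duration_s,
                                p_cluster = 0.15,
                                speed_range_um_s = c(0.3, 0.8),
                                min_gap_um = 8, seed = 1L) {
  with_seed(seed, {
    s0 <- config$ais_start_um
    span <- c(max(0, s0 - config$cluster_window_um),
              s0 + config$cluster_window_um)
    axon_len <- config$axon_length_um
    # fix each event's origin up front so the origin marginal stays exactly
    # Bernoulli(p_cluster); rejection-resampling only the kinematics would
    # otherwise enrich the rarer channel (fewer same-channel collisions)
    origins <- ifelse(stats::runif(n_events) < p_cluster, "cluster", "other")
    acc <- list()
    tries <- 0
    while (length(acc) < n_events && tries < 8000) {
      tries <- tries + 1
      origin <- origins[length(acc) + 1]
      speed <- stats::runif(1, speed_range_um_s[1], speed_range_um_s[2])
      dur <- stats::runif(1, 12, 25)
      if (origin == "cluster") {
        channel <- "red"
        x0 <- stats::runif(1, span[1] + 1, span[2] - 1)
        v <- sample(c(-1, 1), 1) * speed
        if (x0 + v * dur < 1 || x0 + v * dur > axon_len - 1) v <- -v
      } else {
        channel <- "green"
        antero <- stats::runif(1) < 0.6
        if (antero) {
          v <- speed
          x0 <- stats::runif(1, max(1, span[1] - 10), span[2] - 1)
        } else {
          v <- -speed
          x0 <- stats::runif(1, max(span[1] + 4, 6),
                             min(axon_len - 1, span[2] + 10))
        }
      }
      # every event must reach the cluster span ("went past the cluster")
      if (v > 0 && x0 < span[1]) dur <- max(dur, (span[1] + 1 - x0) / speed)
      if (v < 0 && x0 > span[2]) dur <- max(dur, (x0 - span[2] + 1) / speed)
      # and the whole run stays inside the axon so nothing is clipped
      if (v > 0) dur <- min(dur, (axon_len - 1 - x0) / speed)
      if (v < 0) dur <- min(dur, (x0 - 1) / speed)
      if (dur < 8 || (v < 0 && x0 - speed * dur > span[2]) ||
          (v > 0 && x0 + speed * dur < span[1])) next
      t0 <- stats::runif(1, 0, max(0.1, duration_s - dur))
      cand <- list(t0 = t0, x0 = x0, v = v, dur = dur, origin = origin,
                   channel = channel)
      # spacetime samples (x in um, t scaled to um at 0.8 um/s)
      track_pts <- function(e) {
        tt <- seq(e$t0, e$t0 + e$dur, length.out = 40)
        cbind(e$x0 + e$v * (tt - e$t0), tt * 0.8)
      }
      pc <- track_pts(cand)
      ok <- TRUE
      for (e in acc) {
        if (e$channel != channel) next
        pe <- track_pts(e)
        d2 <- outer(pc[, 1], pe[, 1], `-`)^2 + outer(pc[, 2], pe[, 2], `-`)^2
        if (min(d2) < min_gap_um^2) { ok <- FALSE; break }
      }
      if (ok) acc[[length(acc) + 1]] <- cand
    }
    if (length(acc) < n_events) {
      stop("could not place ", n_events, " non-overlapping events; ",
           "increase duration_s or reduce n_events")
    }
    event_script(
      t_start_s = vapply(acc, `[[`, 0, "t0"),
      x_start_um = vapply(acc, `[[`, 0, "x0"),
      velocity_um_per_s = vapply(acc, `[[`, 0, "v"),
      duration_s = vapply(acc, `[[`, 0, "dur"),
      origin = vapply(acc, `[[`, "", "origin"),
      channel = vapply(acc, `[[`, "", "channel"),
      config = config)
  })
}

#' Generate a cohort of scenes with jittered geometry
#'
#' Produces `n_cells` scenes from a template config; exactly
#' `round(n_cells * cluster_fraction)` cells are cluster-positive, assigned
#' deterministically under `seed`. Per-cell geometry (AIS start, soma radius,
#' axon length) is jittered. With `p_proximal` / `p_central` given, each
#' cell's proximal/central presence window is instead filled (dense punctum
#' train) with the stated Bernoulli probability — the generative model behind
#' the presence-probability recovery experiments.
#'
#' @param config template [scene_config()].
#' @param n_cells number of cells (> 0).
#' @param cluster_fraction fraction of cluster-positive cells in [0, 1].
#' @param seed cohort seed (drives assignment, jitter and per-cell seeds).
#' @param n_replicates number of biological replicate labels to cycle over.
#' @param p_proximal,p_central optional Bernoulli presence probabilities;
#'   when given they override cluster rendering in those windows.
#' @param dir optional directory; when given, images (TIFF), annotations
#'   (JSON) and a `manifest.json` are written there and file paths returned.
#' @return list with `scenes` (each as from [generate_scene()]) and
#'   `manifest` (data.frame: cell_id, replicate_id, cluster_present, seed,
#'   ais_start_um, plus file paths when `dir` is used).
#' @export
generate_cohort <- function(config, n_cells, cluster_fraction = 0,
                            seed = 1L, n_replicates = 3,
                            p_proximal = NULL, p_central = NULL, dir = NULL) {
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("validation error: n_cells must be >= 1")
  }
  if (cluster_fraction < 0 || cluster_fraction > 1) {
    stop("validation error: cluster_fraction must be in [0, 1]")
  }
  n_cells <- as.integer(n_cells)
  with_seed(seed, {
    k <- round(n_cells * cluster_fraction)
    positive <- rep(FALSE, n_cells)
    if (k > 0) positive[sample.int(n_cells, k)] <- TRUE
    cell_seeds <- sample.int(.Machine$integer.max - 1, n_cells)
    jit_start <- stats::runif(n_cells, -1.5, 1.5)
    jit_soma <- stats::runif(n_cells, 0.9, 1.1)
    jit_axon <- stats::runif(n_cells, -4, 4)
    fill_p <- if (!is.null(p_proximal)) {
      stats::runif(n_cells) < p_proximal
    } else rep(NA, n_cells)
    fill_c <- if (!is.null(p_central)) {
      stats::runif(n_cells) < p_central
    } else rep(NA, n_cells)

    scenes <- vector("list", n_cells)
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      cfg <- config
      cfg$seed <- cell_seeds[i]
      cfg$cluster_present <- positive[i]
      cfg$ais_start_um <- max(1, config$ais_start_um + jit_start[i])
      cfg$soma_radius_um <- config$soma_radius_um * jit_soma[i]
      cfg$axon_length_um <- max(45, config$axon_length_um + jit_axon[i])
      if (!is.null(p_proximal)) cfg$fill_proximal <- fill_p[i]
      if (!is.null(p_central)) cfg$fill_central <- fill_c[i]
      cell_id <- sprintf("cell%03d", i)
      rep_id <- sprintf("rep%d", (i - 1) %% n_replicates + 1)
      scenes[[i]] <- generate_scene(cfg, cell_id = cell_id,
                                    replicate_id = rep_id)
      rows[[i]] <- data.frame(cell_id = cell_id, replicate_id = rep_id,
                              cluster_present = positive[i],
                              seed = cell_seeds[i],
                              ais_start_um = cfg$ais_start_um,
                              fill_proximal = fill_p[i],
                              fill_central = fill_c[i],
                              stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      manifest$image <- file.path(dir, paste0(manifest$cell_id, ".tif"))
      manifest$annotations <- file.path(dir,
                                        paste0(manifest$cell_id, ".json"))
      for (i in seq_len(n_cells)) {
        write_image_stack(scenes[[i]]$stack, manifest$image[i])
        write_annotations(scenes[[i]]$annotations$paths,
                          scenes[[i]]$annotations$rois,
                          manifest$annotations[i])
      }
      jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(scenes = scenes, manifest = manifest)
  })
}
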