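# Geometry helpers shared by profile extraction and the scene renderer.
#
# Convention used package-wide: pixel coordinates are 0-based and a pixel's
# center sits at its integer coordinate; (x, y) maps to array element
# [y + 1, x + 1]. Arclength 0 is the first path point (somatic end).

#' Cumulative arclength of a polyline
#'
#' @param points numeric matrix with two columns (x, y), in pixel units.
#' @param pixel_size_um physical size of one pixel in micrometres; the
#'   returned arclengths are in micrometres.
#' @return numeric vector, one entry per vertex, starting at 0.
#' @keywords internal
polyline_arclength <- function(points, pixel_size_um = 1) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 1)
  d <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
  c(0, cumsum(d)) * pixel_size_um
}

#' Sample positions and unit tangents along a polyline at given arclengths
#'
#' Linear interpolation between vertices; the tangent at a sample is the
#' direction of the segment it falls on (averaged at vertices).
#'
#' @param points two-column matrix of vertices (pixel units).
#' @param s_px arclengths at which to sample, in pixel units, within
#'   `[0, total length]` (values are clamped).
#' @return list with `xy` (n x 2 positions), `tangent` (n x 2 unit vectors)
#'   and `normal` (n x 2 unit vectors, tangent rotated +90 degrees).
#' @keywords internal
polyline_sample <- function(points, s_px) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 2)
  seg <- diff(points)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop("polyline has zero-length segments")
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- pmin(pmax(s_px, 0), total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(seg))
  frac <- (s - cum[idx]) / seg_len[idx]
  xy <- points[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tang <- seg[idx, , drop = FALSE] / seg_len[idx]
  list(xy = xy, tangent = tang,
       normal = cbind(-tang[, 2], tang[, 1]))
}

#' Bilinear interpolation of a matrix at continuous pixel coordinates
#'
#' @param img numeric matrix indexed `[y + 1, x + 1]`.
#' @param x,y 0-based continuous pixel coordinates (vectors of equal length).
#' @param outside value returned for samples outside the image (default NA).
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear <- function(img, x, y, outside = NA_real_) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 0 & y >= 0 & x <= nx - 1 & y <= ny - 1
  # clamp the upper neighbour so samples exactly on the last row/col work
  x0c <- pmin(pmax(x0, 0), nx - 1); y0c <- pmin(pmax(y0, 0), ny - 1)
  x1c <- pmin(x0c + 1, nx - 1);     y1c <- pmin(y0c + 1, ny - 1)
  i00 <- cbind(y0c + 1, x0c + 1); i01 <- cbind(y0c + 1, x1c + 1)
  i10 <- cbind(y1c + 1, x0c + 1); i11 <- cbind(y1c + 1, x1c + 1)
  v <- img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
  v[!ok] <- outside
  v
}

#' Nearest-neighbour lookup of a matrix at continuous pixel coordinates
#' @inheritParams bilinear
#' @keywords internal
nearest_px <- function(img, x, y, outside = NA_real_) {
  ny <- nrow(img); nx <- ncol(img)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 0 & yi >= 0 & xi <= nx - 1 & yi <= ny - 1
  v <- rep(outside, length(x))
  v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
  v
}

#' Signed area of a polygon (shoelace formula), in squared input units
#' @keywords internal
polygon_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- nrow(polygon)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Proper intersection test between segments p1-p2 and p3-p4 (shared endpoints
# do not count). Used to validate polygon annotations.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Is a polygon simple (non-self-intersecting)?
#' @keywords internal
polygon_is_simple <- function(polygon) {
  n <- nrow(polygon)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (they share a vertex)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (segments_cross(polygon[idx[i, 1], ], polygon[idx[i, 2], ],
                         polygon[idx[j, 1], ], polygon[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Even-odd point-in-polygon test for a grid of pixels
#'
#' @param polygon two-column matrix of vertices (0-based pixel coords).
#' @param dim_yx image dimensions c(ny, nx).
#' @return logical matrix [ny, nx], TRUE where the pixel center is inside.
#' @keywords internal
polygon_mask <- function(polygon, dim_yx) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  xs <- polygon[, 1]; ys <- polygon[, 2]
  n <- length(xs)
  mask <- matrix(FALSE, ny, nx)
  px <- rep(0:(nx - 1), each = ny)
  py <- rep(0:(ny - 1), times = nx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(py + 1, px + 1)] <- inside
  mask
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
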