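# Internal geometry and numeric helpers.

.TWO_PI <- 2 * pi

#' @noRd
.stop_scarq <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "scarq_error")))
}

#' Wrap angles into [0, 2*pi)
#' @noRd
.wrap_angle <- function(theta) theta %% .TWO_PI

#' Signed polygon area (shoelace); positive when counterclockwise
#' @noRd
.polygon_signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' @noRd
.polygon_area <- function(p) abs(.polygon_signed_area(p))

#' Polygon centroid by the standard signed-area formula
#' @noRd
.polygon_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Point-in-polygon for pixel-center grids
#'
#' @param px,py numeric vectors of query coordinates (mm).
#' @param poly n x 2 vertex matrix (open ring).
#' @param boundary logical; whether points on the boundary count as inside.
#' @noRd
.in_polygon <- function(px, py, poly, boundary = TRUE) {
  pracma::inpolygon(px, py, poly[, 1L], poly[, 2L], boundary = boundary)
}

#' Pixel-center coordinates of a slice grid
#'
#' Pixels are 0-based row-major externally; internally R matrices are
#' 1-based with rows along y. Pixel (i, j) covers
#' x in [j*dx, (j+1)*dx), y in [i*dy, (i+1)*dy); its center is
#' ((j+0.5)*dx, (i+0.5)*dy).
#' @noRd
.pixel_centers <- function(grid_shape, pixel_spacing) {
  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  dx <- pixel_spacing[1L]; dy <- pixel_spacing[2L]
  list(
    x = (seq_len(nc) - 0.5) * dx,
    y = (seq_len(nr) - 0.5) * dy
  )
}

#' Full coordinate matrices (nr x nc) of pixel centers
#' @noRd
.center_grids <- function(grid_shape, pixel_spacing) {
  ctr <- .pixel_centers(grid_shape, pixel_spacing)
  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  list(
    X = matrix(rep(ctr$x, each = nr), nr, nc),
    Y = matrix(rep(ctr$y, times = nc), nr, nc)
  )
}

#' Bilinear interpolation of a numeric matrix sampled at pixel centers
#'
#' Values outside the outermost pixel centers are clamped to the edge.
#' @noRd
.bilinear <- function(m, x, y, pixel_spacing) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- x / pixel_spacing[1L] - 0.5
  gy <- y / pixel_spacing[2L] - 0.5
  j0 <- pmin(pmax(floor(gx), 0), nc - 2L)
  i0 <- pmin(pmax(floor(gy), 0), nr - 2L)
  fx <- pmin(pmax(gx - j0, 0), 1)
  fy <- pmin(pmax(gy - i0, 0), 1)
  i0 <- i0 + 1L; j0 <- j0 + 1L
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i0, j0 + 1L)] * fx * (1 - fy) +
    m[cbind(i0 + 1L, j0)] * (1 - fx) * fy +
    m[cbind(i0 + 1L, j0 + 1L)] * fx * fy
}

#' Nearest-pixel (containing-pixel) lookup of a matrix
#' @noRd
.nearest_pixel <- function(m, x, y, pixel_spacing) {
  nr <- nrow(m); nc <- ncol(m)
  j <- pmin(pmax(floor(x / pixel_spacing[1L]), 0), nc - 1L) + 1L
  i <- pmin(pmax(floor(y / pixel_spacing[2L]), 0), nr - 1L) + 1L
  m[cbind(i, j)]
}

#' Maximum positive crossing parameter of rays with a polygon
#'
#' Rays start at `origin` with direction angles `angles`. Returns, per
#' angle, the largest positive t at which the ray crosses an edge of
#' `poly` (NA when the ray misses the polygon entirely).
#' @noRd
.ray_polygon_t <- function(origin, angles, poly) {
  p1 <- poly
  p2 <- poly[c(seq_len(nrow(poly))[-1L], 1L), , drop = FALSE]
  ex <- p2[, 1L] - p1[, 1L]
  ey <- p2[, 2L] - p1[, 2L]
  wx <- p1[, 1L] - origin[1L]
  wy <- p1[, 2L] - origin[2L]
  cw <- wx * ey - wy * ex                      # cross(w, e), per edge
  cs <- cos(angles); sn <- sin(angles)
  # denom[a, v] = cross(u_a, e_v)
  denom <- outer(cs, ey) - outer(sn, ex)
  tmat <- sweep(1 / denom, 2L, cw, `*`)        # t = cross(w, e) / denom
  qmat <- (outer(sn, wx) - outer(cs, wy)) / denom
  ok <- is.finite(tmat) & tmat > 0 & qmat >= 0 & qmat < 1
  tmat[!ok] <- -Inf
  tt <- apply(tmat, 1L, max)
  tt[!is.finite(tt)] <- NA_real_
  tt
}

#' Round half away from zero (printed clinical percentages)
#' @noRd
.round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Union arrangement of angular intervals with per-interval maximal depth
#'
#' `ints` is a data.frame with columns start, end (radians, already split
#' so start < end within [0, 2*pi]) and depth. Returns elementary
#' intervals (start, end, depth = max over covering inputs); gaps are
#' omitted.
#' @noRd
.depth_arrangement <- function(ints) {
  if (nrow(ints) == 0L) {
    return(data.frame(start = numeric(), end = numeric(), depth = numeric()))
  }
  bp <- sort(unique(c(ints$start, ints$end)))
  out <- data.frame(start = bp[-length(bp)], end = bp[-1L])
  mid <- (out$start + out$end) / 2
  out$depth <- vapply(mid, function(m) {
    covering <- ints$depth[ints$start <= m & m < ints$end]
    if (length(covering)) max(covering) else NA_real_
  }, numeric(1))
  out[!is.na(out$depth) & out$depth > 0, , drop = FALSE]
}

#' Split an angular interval [a, a+span) into pieces within [0, 2*pi)
#' @noRd
.split_interval <- function(start, span) {
  start <- .wrap_angle(start)
  if (span >= .TWO_PI) return(data.frame(start = 0, end = .TWO_PI))
  end <- start + span
  if (end <= .TWO_PI) {
    data.frame(start = start, end = end)
  } else {
    data.frame(start = c(start, 0), end = c(.TWO_PI, end - .TWO_PI))
  }
}

#' Overlap length of [a1, b1) with [a2, b2) (both within [0, 2*pi])
#' @noRd
.interval_overlap <- function(a1, b1, a2, b2) {
  max(0, min(b1, b2) - max(a1, a2))
}
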