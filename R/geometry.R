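# LV geometry: slice contours, stacks, myocardial rasterization, mass.

#' Construct a single short-axis slice geometry
#'
#' A slice is described by its endocardial and epicardial contours in
#' millimetres in the image coordinate frame (x rightwards along columns,
#' y downwards along rows), the pixel spacing of the co-registered raster
#' grid, and the axial span the slice represents (thickness plus gap).
#'
#' @param endo,epi closed simple polygons as n x 2 matrices of vertices in
#'   mm; the last vertex must not repeat the first. The endocardial
#'   contour must lie strictly inside the epicardial contour.
#' @param pixel_spacing numeric length-2, (dx, dy) in mm/pixel; or a single
#'   number for square pixels.
#' @param slice_span slice thickness plus inter-slice gap, mm.
#' @param z_index integer slice order, 0 = most basal.
#' @param grid_shape integer length-2, (rows, cols) of the raster grid.
#' @return An object of class `slice_geometry`.
#' @seealso [contour_stack()], [rasterize_myocardium()]
#' @export
slice_geometry <- function(endo, epi, pixel_spacing, slice_span, z_index = 0L,
                           grid_shape) {
  endo <- .as_polygon(endo, "endo")
  epi <- .as_polygon(epi, "epi")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) {
    .stop_scarq("pixel_spacing must be positive", "scarq_geometry_error")
  }
  if (slice_span <= 0) {
    .stop_scarq("slice_span must be positive", "scarq_geometry_error")
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 2L)) {
    .stop_scarq("grid_shape must be two integers >= 2", "scarq_geometry_error")
  }
  if (!all(.in_polygon(endo[, 1L], endo[, 2L], epi, boundary = FALSE))) {
    .stop_scarq(
      sprintf("slice z=%d: endocardial contour is not strictly inside the epicardial contour",
              as.integer(z_index)),
      "scarq_geometry_error"
    )
  }
  structure(
    list(
      z_index = as.integer(z_index),
      endo = endo, epi = epi,
      pixel_spacing = as.numeric(pixel_spacing),
      slice_span = as.numeric(slice_span),
      grid_shape = grid_shape
    ),
    class = "slice_geometry"
  )
}

#' @noRd
.as_polygon <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L || !all(is.finite(p))) {
    .stop_scarq(sprintf("%s polygon must be a finite n x 2 matrix with n >= 3", what),
                "scarq_geometry_error")
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(p)
  if (all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (.polygon_area(p) <= 0) {
    .stop_scarq(sprintf("%s polygon is degenerate (zero area)", what),
                "scarq_geometry_error")
  }
  unname(p)
}

#' Assemble an ordered stack of short-axis slices
#'
#' @param slices list of [slice_geometry()] objects ordered basal to
#'   apical with strictly increasing `z_index`.
#' @param rv_insertion_angle angular position (radians, image frame) of the
#'   anterior right-ventricular insertion point; the origin from which AHA
#'   sectors are counted counterclockwise. One value for the whole stack,
#'   or one per slice.
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(slices, rv_insertion_angle = 0) {
  if (!length(slices)) .stop_scarq("empty stack", "scarq_geometry_error")
  if (!all(vapply(slices, inherits, logical(1), "slice_geometry"))) {
    .stop_scarq("slices must all be slice_geometry objects", "scarq_geometry_error")
  }
  z <- vapply(slices, `[[`, integer(1), "z_index")
  if (any(diff(z) <= 0)) {
    .stop_scarq("z_index must be strictly increasing basal to apical",
                "scarq_geometry_error")
  }
  n <- length(slices)
  if (!length(rv_insertion_angle) %in% c(1L, n)) {
    .stop_scarq("rv_insertion_angle must have length 1 or one value per slice",
                "scarq_geometry_error")
  }
  structure(
    list(slices = slices, rv_insertion_angle = as.numeric(rv_insertion_angle)),
    class = "contour_stack"
  )
}

#' @export
print.contour_stack <- function(x, ...) {
  n <- length(x$slices)
  cat(sprintf("<contour_stack> %d slice%s, rv insertion %.3f rad\n",
              n, if (n == 1L) "" else "s", x$rv_insertion_angle[1L]))
  invisible(x)
}

#' @noRd
.rv_angle_of_slice <- function(stack, i) {
  a <- stack$rv_insertion_angle
  if (length(a) == 1L) a else a[i]
}

#' Rasterize the myocardium of a stack
#'
#' A pixel belongs to the myocardium when its center lies inside the
#' epicardial contour (boundary inclusive) and outside or on the
#' endocardial contour. Identical consecutive slice geometries are
#' rasterized once and reused.
#'
#' @param stack a [contour_stack()], or a single [slice_geometry()].
#' @return An object of class `myocardium_mask`: a list with one logical
#'   matrix per slice (`masks`), per-slice `pixel_area` (mm^2) and
#'   `voxel_volume` (mm^3).
#' @export
rasterize_myocardium <- function(stack) {
  if (inherits(stack, "slice_geometry")) {
    stack <- contour_stack(list(stack))
  }
  masks <- vector("list", length(stack$slices))
  pixel_area <- numeric(length(masks))
  voxel_volume <- numeric(length(masks))
  prev <- NULL
  for (i in seq_along(stack$slices)) {
    sl <- stack$slices[[i]]
    key <- list(sl$endo, sl$epi, sl$pixel_spacing, sl$grid_shape)
    if (!is.null(prev) && identical(prev$key, key)) {
      m <- prev$m
    } else {
      g <- .center_grids(sl$grid_shape, sl$pixel_spacing)
      in_epi <- .in_polygon(as.vector(g$X), as.vector(g$Y), sl$epi, boundary = TRUE)
      in_endo <- .in_polygon(as.vector(g$X), as.vector(g$Y), sl$endo, boundary = FALSE)
      m <- matrix(in_epi & !in_endo, sl$grid_shape[1L], sl$grid_shape[2L])
      prev <- list(key = key, m = m)
    }
    if (!any(m)) {
      .stop_scarq(sprintf("slice z=%d rasterizes to an empty myocardium", sl$z_index),
                  "scarq_geometry_error")
    }
    masks[[i]] <- m
    pixel_area[i] <- prod(sl$pixel_spacing)
    voxel_volume[i] <- pixel_area[i] * sl$slice_span
  }
  structure(
    list(masks = masks, pixel_area = pixel_area, voxel_volume = voxel_volume),
    class = "myocardium_mask"
  )
}

#' Left-ventricular mass of a stack
#'
#' Myocardial voxel volumes are summed over all slices and converted to
#' grams at a myocardial density of 1.05 g/cm^3.
#'
#' @inheritParams rasterize_myocardium
#' @param myo optional precomputed [rasterize_myocardium()] result.
#' @param density_g_per_cm3 myocardial tissue density (default 1.05).
#' @return LV mass in grams.
#' @export
lv_mass <- function(stack, myo = NULL, density_g_per_cm3 = 1.05) {
  if (is.null(myo)) myo <- rasterize_myocardium(stack)
  counts <- vapply(myo$masks, sum, numeric(1))
  sum(counts * myo$voxel_volume) / 1000 * density_g_per_cm3
}

#' Endocardial centroid of a slice (chord origin)
#' @noRd
.endo_centroid <- function(sl) .polygon_centroid(sl$endo)
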