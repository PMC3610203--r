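# AHA 17-segment model: slice levels and angular sectors.

.LEVELS <- c("basal", "mid", "apical")

#' Assign short-axis slices to AHA levels
#'
#' Slices are partitioned into contiguous basal, mid and apical thirds by
#' count; when the count is not divisible by three the remainder goes
#' basal-first, then mid.
#'
#' @inheritParams rasterize_myocardium
#' @return Character vector, one of `"basal"`, `"mid"`, `"apical"` per
#'   slice, in stack order.
#' @examples
#' stack <- make_annulus_stack(n_slices = 11)
#' table(assign_levels(stack))  # 4 basal, 4 mid, 3 apical
#' @export
assign_levels <- function(stack) {
  n <- length(stack$slices)
  if (n < 3L) {
    .stop_scarq("AHA level assignment needs at least 3 slices",
                "scarq_mapping_error")
  }
  base <- n %/% 3L
  rem <- n %% 3L
  counts <- c(basal = base + (rem >= 1L), mid = base + (rem >= 2L), apical = base)
  rep(.LEVELS, times = counts)
}

#' Map an angle to an AHA segment ID
#'
#' Angles are measured counterclockwise from the anterior RV insertion.
#' Basal and mid levels have six 60-degree sectors (segments 1-6 and
#' 7-12); the apical level has four 90-degree sectors (segments 13-16).
#' Sector boundaries are half-open `[start, end)` so every angle maps to
#' exactly one segment; angles are wrapped modulo 2*pi.
#'
#' @param level `"basal"`, `"mid"` or `"apical"`.
#' @param angle angle(s) in radians in the image frame.
#' @param rv_insertion_angle angular origin in radians.
#' @return Integer segment ID(s) in 1-16.
#' @export
segment_id <- function(level, angle, rv_insertion_angle = 0) {
  level <- match.arg(level, .LEVELS)
  rel <- .wrap_angle(angle - rv_insertion_angle)
  if (level == "apical") {
    13L + pmin(as.integer(rel %/% (pi / 2)), 3L)
  } else {
    offset <- if (level == "basal") 1L else 7L
    offset + pmin(as.integer(rel %/% (pi / 3)), 5L)
  }
}

#' Segment IDs belonging to an AHA level
#' @noRd
.level_segments <- function(level) {
  switch(level, basal = 1:6, mid = 7:12, apical = 13:16)
}

#' Sector boundaries (relative to the RV insertion) for a level
#' @noRd
.level_sectors <- function(level) {
  n <- if (level == "apical") 4L else 6L
  width <- .TWO_PI / n
  data.frame(
    segment_id = .level_segments(level),
    start = (seq_len(n) - 1L) * width,
    end = seq_len(n) * width
  )
}

#' Per-pixel segment labels of one slice
#'
#' @return Integer matrix; NA outside the myocardium.
#' @noRd
.slice_segment_labels <- function(sl, myo_mask, level, rv_angle) {
  ctr <- .endo_centroid(sl)
  g <- .center_grids(sl$grid_shape, sl$pixel_spacing)
  ang <- atan2(g$Y - ctr[2L], g$X - ctr[1L])
  lab <- matrix(segment_id(level, as.vector(ang), rv_angle),
                sl$grid_shape[1L], sl$grid_shape[2L])
  lab[!myo_mask] <- NA_integer_
  lab
}
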