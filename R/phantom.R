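# Synthetic LV phantoms: annular stacks, wedge scars with analytic truth,
# and a toy cohort simulator.

#' Circular annulus contour stack
#'
#' Builds a stack of identical short-axis slices whose endocardial and
#' epicardial contours are concentric circles sampled as polygons. The LV
#' center sits at the grid center; the grid side is
#' `2*ceil((r_epi + margin)/dx)` pixels, so the center falls on a pixel
#' corner and the rasterization keeps its 4-fold symmetry.
#'
#' @param n_slices number of slices.
#' @param r_endo,r_epi endocardial/epicardial radii in mm (0 < r_endo < r_epi).
#' @param pixel_spacing pixel size in mm (scalar or (dx, dy)).
#' @param slice_span slice thickness plus gap, mm.
#' @param rv_insertion_angle angular origin for AHA sectors, radians.
#' @param n_vertices polygon vertices per contour (>= 256).
#' @param margin clearance between the epicardium and the grid edge, mm.
#' @return A [contour_stack()] carrying the phantom parameters as the
#'   `"annulus"` attribute (used for closed-form truth).
#' @export
make_annulus_stack <- function(n_slices = 10L, r_endo = 20, r_epi = 30,
                               pixel_spacing = 1, slice_span = 10,
                               rv_insertion_angle = 0, n_vertices = 512L,
                               margin = 5) {
  if (!(r_endo > 0 && r_epi > r_endo)) {
    .stop_scarq("need 0 < r_endo < r_epi", "scarq_geometry_error")
  }
  if (n_vertices < 256L) {
    .stop_scarq("n_vertices must be at least 256", "scarq_geometry_error")
  }
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  half <- ceiling((r_epi + margin) / pixel_spacing)
  grid_shape <- as.integer(2 * rev(half))        # (rows, cols)
  center <- c(half[1L] * pixel_spacing[1L], half[2L] * pixel_spacing[2L])
  th <- seq(0, .TWO_PI, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  circ <- function(r) cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
  slices <- lapply(seq_len(n_slices) - 1L, function(z) {
    slice_geometry(circ(r_endo), circ(r_epi), pixel_spacing, slice_span,
                   z_index = z, grid_shape = grid_shape)
  })
  stack <- contour_stack(slices, rv_insertion_angle)
  attr(stack, "annulus") <- list(r_endo = r_endo, r_epi = r_epi,
                                 center = center, n_slices = n_slices)
  stack
}

#' Specify a wedge-shaped scar
#'
#' A wedge extends from the endocardium to a fractional radial depth over
#' an angular span, on a range of slices. The binary mask is purely
#' geometric; noise and partial-volume ramps affect only the optional
#' intensity channel.
#'
#' @param theta_start wedge start angle, radians (image frame).
#' @param theta_span angular span, radians, in (0, 2*pi].
#' @param depth radial depth fraction of the wall, in (0, 1].
#' @param slices inclusive 1-based slice index range (length 2), or NULL
#'   for all slices.
#' @param intensity `"binary"` or `"ramp"` (linear core-to-remote ramp of
#'   width `edge_width_mm` across the wedge boundary, plus Gaussian noise).
#' @param core,remote intensity calibration for the ramp model.
#' @param edge_width_mm transition width of the partial-volume ramp, mm.
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @return An object of class `wedge_spec`.
#' @export
wedge_spec <- function(theta_start, theta_span, depth, slices = NULL,
                       intensity = c("binary", "ramp"), core = 1000,
                       remote = 200, edge_width_mm = 2, noise_sd = 0) {
  intensity <- match.arg(intensity)
  if (!(theta_span > 0 && theta_span <= .TWO_PI)) {
    .stop_scarq("theta_span must lie in (0, 2*pi]", "scarq_range_error")
  }
  if (!(depth > 0 && depth <= 1)) {
    .stop_scarq("depth must lie in (0, 1]", "scarq_range_error")
  }
  structure(
    list(theta_start = theta_start, theta_span = theta_span, depth = depth,
         slices = slices, intensity = intensity, core = core, remote = remote,
         edge_width_mm = edge_width_mm, noise_sd = noise_sd),
    class = "wedge_spec"
  )
}

#' Apply wedge scars to an annulus phantom
#'
#' Rasterizes the union of the wedges into a [scar_raster()] (pixel-center
#' classification, intersected with the myocardium) and derives the
#' closed-form expectations of every metric from the wedge geometry alone
#' - never from the rasters.
#'
#' @param stack an annulus stack from [make_annulus_stack()].
#' @param wedges a [wedge_spec()] or list of them; overlapping wedges
#'   compose by union (the deepest wedge wins where they overlap).
#' @param seed optional seed for intensity noise.
#' @return list with `scar` (a [scar_raster()]) and `truth` (see
#'   [phantom_truth()]).
#' @export
apply_wedges <- function(stack, wedges, seed = NULL) {
  ann <- attr(stack, "annulus")
  if (is.null(ann)) {
    .stop_scarq("apply_wedges needs a stack built by make_annulus_stack",
                "scarq_geometry_error")
  }
  if (inherits(wedges, "wedge_spec")) wedges <- list(wedges)
  n <- length(stack$slices)
  for (w in wedges) {
    if (!is.null(w$slices) &&
        (w$slices[1L] < 1L || w$slices[2L] > n || w$slices[1L] > w$slices[2L])) {
      .stop_scarq("wedge slice range outside the stack", "scarq_range_error")
    }
  }
  if (!is.null(seed)) set.seed(seed)

  sl1 <- stack$slices[[1L]]
  g <- .center_grids(sl1$grid_shape, sl1$pixel_spacing)
  R <- sqrt((g$X - ann$center[1L])^2 + (g$Y - ann$center[2L])^2)
  TH <- .wrap_angle(atan2(g$Y - ann$center[2L], g$X - ann$center[1L]))
  myo <- rasterize_myocardium(stack)
  dr <- ann$r_epi - ann$r_endo

  any_ramp <- any(vapply(wedges, function(w) w$intensity == "ramp", logical(1)))
  masks <- vector("list", n)
  intens <- if (any_ramp) vector("list", n) else NULL
  core <- if (any_ramp) max(vapply(wedges, `[[`, numeric(1), "core")) else NULL
  remote <- if (any_ramp) min(vapply(wedges, `[[`, numeric(1), "remote")) else NULL

  for (i in seq_len(n)) {
    m <- matrix(FALSE, sl1$grid_shape[1L], sl1$grid_shape[2L])
    ramp_val <- if (any_ramp) matrix(0, nrow(m), ncol(m)) else NULL
    for (w in wedges) {
      rng <- if (is.null(w$slices)) c(1L, n) else w$slices
      if (i < rng[1L] || i > rng[2L]) next
      r_out <- ann$r_endo + w$depth * dr
      dth <- .wrap_angle(TH - w$theta_start)
      inside <- myo$masks[[i]] & dth < w$theta_span & R < r_out
      m <- m | inside
      if (any_ramp) {
        # signed distance to the wedge boundary (positive inside), from
        # the analytic geometry: radial and arc distances to the edges
        d_rad <- pmin(R - ann$r_endo, r_out - R)
        ang_in <- pmin(dth, w$theta_span - dth)
        ang_out <- pmin(.wrap_angle(w$theta_start - TH),
                        .wrap_angle(TH - w$theta_start - w$theta_span))
        d_ang <- ifelse(dth < w$theta_span, ang_in, -ang_out) * R
        sd <- pmin(d_rad, d_ang)
        f <- pmin(pmax(sd / w$edge_width_mm + 0.5, 0), 1)
        ramp_val <- pmax(ramp_val, f)
      }
    }
    masks[[i]] <- m
    if (any_ramp) {
      v <- remote + (core - remote) * ramp_val
      sdn <- max(vapply(wedges, `[[`, numeric(1), "noise_sd"))
      if (sdn > 0) v <- v + matrix(rnorm(length(v), sd = sdn), nrow(v), ncol(v))
      intens[[i]] <- v
    }
  }
  scar <- scar_raster(masks, intensity = intens,
                      remote_intensity = remote, core_intensity = core)
  list(scar = scar, truth = phantom_truth(stack, wedges))
}

#' Closed-form expectations for a wedge phantom
#'
#' Derives, from the wedge specifications and annulus geometry only, the
#' exact per-segment STAB/STLB/WIT (binary) /SMST expectations and the
#' global percent scar, LV mass and scar mass. For an endocardium-attached
#' wedge of depth d covering a fraction f of a sector of an annulus with
#' radii r1 < r2: STLB = 100*d*f, SMST = 100*d where intersected,
#' STAB = WIT = 100*f*((r1+d*(r2-r1))^2 - r1^2)/(r2^2 - r1^2); overlapping
#' wedges resolve to the maximal depth per angular interval.
#'
#' @inheritParams apply_wedges
#' @return list with `segments` (data.frame segment_id, stab, stlb, wit,
#'   smst), `percent_scar`, `lv_mass_g`, `scar_mass_g`.
#' @export
phantom_truth <- function(stack, wedges) {
  ann <- attr(stack, "annulus")
  if (is.null(ann)) {
    .stop_scarq("phantom_truth needs a stack built by make_annulus_stack",
                "scarq_geometry_error")
  }
  if (inherits(wedges, "wedge_spec")) wedges <- list(wedges)
  n <- length(stack$slices)
  levels <- assign_levels(stack)
  rv <- stack$rv_insertion_angle[1L]
  r1 <- ann$r_endo; r2 <- ann$r_epi
  area_den <- r2^2 - r1^2
  area_frac <- function(d) ((r1 + d * (r2 - r1))^2 - r1^2) / area_den

  # per-slice angular depth arrangements, angles relative to the RV insertion
  arrangements <- lapply(seq_len(n), function(i) {
    ints <- do.call(rbind, lapply(wedges, function(w) {
      rng <- if (is.null(w$slices)) c(1L, n) else w$slices
      if (i < rng[1L] || i > rng[2L]) return(NULL)
      pieces <- .split_interval(w$theta_start - rv, w$theta_span)
      pieces$depth <- w$depth
      pieces
    }))
    if (is.null(ints)) ints <- data.frame(start = numeric(), end = numeric(),
                                          depth = numeric())
    .depth_arrangement(ints)
  })

  seg <- data.frame(segment_id = 1:16, stab = 0, stlb = 0, wit = 0, smst = 0)
  scar_area_total <- 0
  for (lv in .LEVELS) {
    slice_idx <- which(levels == lv)
    sectors <- .level_sectors(lv)
    for (k in seq_len(nrow(sectors))) {
      sid <- sectors$segment_id[k]
      width <- sectors$end[k] - sectors$start[k]
      stlb_num <- stab_num <- 0
      den <- width * length(slice_idx)
      mx <- 0
      for (i in slice_idx) {
        arr <- arrangements[[i]]
        for (j in seq_len(nrow(arr))) {
          ov <- .interval_overlap(sectors$start[k], sectors$end[k],
                                  arr$start[j], arr$end[j])
          if (ov <= 1e-12) next
          stlb_num <- stlb_num + ov * arr$depth[j]
          stab_num <- stab_num + ov * area_frac(arr$depth[j])
          mx <- max(mx, arr$depth[j])
        }
      }
      seg$stlb[sid] <- 100 * stlb_num / den
      seg$stab[sid] <- 100 * stab_num / den
      seg$wit[sid] <- seg$stab[sid]
      seg$smst[sid] <- 100 * mx
    }
  }
  for (cl in c("stab", "stlb", "wit", "smst")) {
    seg[[cl]] <- pmin(pmax(seg[[cl]], 0), 100)
  }
  # global burden: sum over slices of the union scar area
  scar_area <- vapply(arrangements, function(arr) {
    if (!nrow(arr)) return(0)
    sum((arr$end - arr$start) / 2 * ((r1 + arr$depth * (r2 - r1))^2 - r1^2))
  }, numeric(1))
  myo_area <- pi * area_den
  pct <- min(max(100 * sum(scar_area) / (myo_area * n), 0), 100)
  span <- stack$slices[[1L]]$slice_span
  mass <- 1.05 * myo_area * span * n / 1000
  list(segments = seg, percent_scar = pct, lv_mass_g = mass,
       scar_mass_g = pct / 100 * mass)
}

#' Simulate a toy ICD cohort
#'
#' Draws a log-normal scar-mass distribution and a binary endpoint
#' (appropriate device therapy) from a logistic model
#' `P(event) = plogis(alpha + beta * scar_mass)`. Defaults emulate the
#' study conditions of a 66-patient coronary-artery-disease ICD cohort
#' with median scar mass near 20 g and roughly one event in five patients.
#'
#' @param n_patients number of patients (>= 2).
#' @param meanlog,sdlog log-normal parameters of the scar-mass draw
#'   (`sdlog` must be positive).
#' @param alpha,beta logistic intercept and per-gram slope of the event
#'   model.
#' @param seed integer seed; the table is reproducible under the same seed.
#' @return data.frame with `patient_id`, `scar_mass_g`, `event` (0/1).
#' @export
make_cohort <- function(n_patients = 66L, meanlog = log(20), sdlog = 0.5,
                        alpha = -3.0, beta = 0.08, seed = 1L) {
  if (n_patients < 2L) .stop_scarq("need at least 2 patients", "scarq_range_error")
  if (sdlog <= 0) .stop_scarq("sdlog must be positive", "scarq_range_error")
  set.seed(seed)
  mass <- rlnorm(n_patients, meanlog, sdlog)
  p <- stats::plogis(alpha + beta * mass)
  data.frame(
    patient_id = seq_len(n_patients),
    scar_mass_g = mass,
    event = rbinom(n_patients, 1L, p)
  )
}
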