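# Scar burden and the four per-segment transmurality estimators.

#' Construct a scar raster
#'
#' A per-slice binary scar classification co-registered with the contour
#' stack's raster grid, optionally carrying a signal-intensity channel
#' with remote (normal myocardium) and core (dense scar) calibration
#' intensities for partial-volume weighting.
#'
#' @param masks list of logical matrices, one per slice; TRUE = scar.
#' @param intensity optional list of numeric matrices of the same shapes.
#' @param remote_intensity,core_intensity calibration scalars; required
#'   together with `intensity`, and `core_intensity` must exceed
#'   `remote_intensity`.
#' @return An object of class `scar_raster`.
#' @export
scar_raster <- function(masks, intensity = NULL, remote_intensity = NULL,
                        core_intensity = NULL) {
  masks <- lapply(masks, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "logical"
    m
  })
  if (!is.null(intensity)) {
    if (length(intensity) != length(masks)) {
      .stop_scarq("intensity must have one matrix per slice", "scarq_shape_error")
    }
    same <- mapply(function(a, b) identical(dim(a), dim(b)), masks, intensity)
    if (!all(same)) {
      .stop_scarq("intensity grids must match mask shapes", "scarq_shape_error")
    }
    if (is.null(remote_intensity) || is.null(core_intensity)) {
      .stop_scarq("remote_intensity and core_intensity are required with an intensity channel",
                  "scarq_calibration_error")
    }
    if (core_intensity <= remote_intensity) {
      .stop_scarq("core_intensity must exceed remote_intensity",
                  "scarq_calibration_error")
    }
  }
  structure(
    list(masks = masks, intensity = intensity,
         remote_intensity = remote_intensity, core_intensity = core_intensity),
    class = "scar_raster"
  )
}

#' Clip scar to the myocardium, warning when pixels are removed
#' @noRd
.clip_scar <- function(scar, myo) {
  outside <- 0L
  for (i in seq_along(scar$masks)) {
    bad <- scar$masks[[i]] & !myo$masks[[i]]
    if (any(bad)) {
      outside <- outside + sum(bad)
      scar$masks[[i]] <- scar$masks[[i]] & myo$masks[[i]]
    }
  }
  if (outside > 0L) {
    warning(sprintf("clipped %d scar pixel(s) outside the myocardium", outside),
            call. = FALSE)
  }
  scar
}

#' Global percent scar
#'
#' Hyperenhanced (scar) tissue volume as a percentage of total LV
#' myocardial volume, volume-weighted across slices with differing spans.
#'
#' @param scar a [scar_raster()].
#' @param myo a [rasterize_myocardium()] result.
#' @return Percent scar in `[0, 100]`.
#' @export
percent_scar <- function(scar, myo) {
  if (length(scar$masks) != length(myo$masks)) {
    .stop_scarq("scar and myocardium have different slice counts", "scarq_shape_error")
  }
  scar <- .clip_scar(scar, myo)
  myo_vol <- sum(vapply(myo$masks, sum, numeric(1)) * myo$voxel_volume)
  if (myo_vol <= 0) .stop_scarq("empty myocardium", "scarq_geometry_error")
  scar_vol <- sum(vapply(scar$masks, sum, numeric(1)) * myo$voxel_volume)
  100 * scar_vol / myo_vol
}

#' Scar mass
#'
#' @param percent_scar percent of LV volume occupied by scar.
#' @param lv_mass LV mass in grams.
#' @return Scar mass in grams.
#' @export
scar_mass <- function(percent_scar, lv_mass) {
  stopifnot(percent_scar >= 0, lv_mass >= 0)
  percent_scar / 100 * lv_mass
}

#' Area-based transmurality (STAB)
#'
#' Scar area as a fraction of myocardial area within a segment, areas
#' summed over the segment's slices.
#'
#' @param scar_area_mm2,myo_area_mm2 per-segment areas in mm^2.
#' @return Transmurality percent; NA where the segment has no myocardium.
#' @export
stab <- function(scar_area_mm2, myo_area_mm2) {
  ifelse(myo_area_mm2 > 0, 100 * scar_area_mm2 / myo_area_mm2, NA_real_)
}

#' Cast transmurality chords across an angular sector of one slice
#'
#' Rays are cast from the endocardial centroid at uniform angles within
#' `theta_range` (sub-sector midpoints). Each chord runs from its
#' endocardial to its epicardial crossing; the scar extent along it is
#' measured from `n_samples` equidistant sample points against the scar
#' raster. With `interp = "bilinear"` (default) the scar and myocardium
#' rasters are bilinearly interpolated at the sample points and the chord
#' scar length is `wall * sum(scar)/sum(myo)`, which cancels the shared
#' pixel quantization of the two fields at the wall boundaries; with
#' `interp = "nearest"` each sample contributes its containing pixel's
#' binary scar status.
#'
#' @param stack a [contour_stack()].
#' @param scar a [scar_raster()].
#' @param slice slice index (1-based position in the stack).
#' @param theta_range length-2 angular interval (radians, image frame);
#'   chords are cast at `n_chords` midpoint angles inside it.
#' @param n_chords number of chords (>= 1; sectors use >= 8).
#' @param n_samples sample points per chord.
#' @param interp `"bilinear"` or `"nearest"`.
#' @param myo optional precomputed myocardium mask.
#' @return data.frame with columns `angle`, `wall_mm`, `scar_mm`; chords
#'   that fail to cross both contours are dropped with a warning.
#' @export
cast_chords <- function(stack, scar, slice, theta_range, n_chords = 60L,
                        n_samples = 200L, interp = c("bilinear", "nearest"),
                        myo = NULL) {
  interp <- match.arg(interp)
  if (is.null(myo)) myo <- rasterize_myocardium(stack)
  sl <- stack$slices[[slice]]
  angles <- theta_range[1L] +
    (seq_len(n_chords) - 0.5) / n_chords * (theta_range[2L] - theta_range[1L])
  res <- .cast_chords_slice(sl, scar$masks[[slice]], myo$masks[[slice]],
                            angles, n_samples, interp)
  dropped <- sum(!res$valid)
  if (dropped == n_chords) {
    .stop_scarq("all chords failed to intersect both contours", "scarq_chord_error")
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d chord(s) that missed a contour", dropped),
            call. = FALSE)
  }
  data.frame(angle = angles, wall_mm = res$wall, scar_mm = res$scar)[res$valid, ]
}

#' Vectorized chord casting on one slice
#' @noRd
.cast_chords_slice <- function(sl, scar_mask, myo_mask, angles, n_samples, interp) {
  ctr <- .endo_centroid(sl)
  t_endo <- .ray_polygon_t(ctr, angles, sl$endo)
  t_epi <- .ray_polygon_t(ctr, angles, sl$epi)
  valid <- is.finite(t_endo) & is.finite(t_epi) & t_epi > t_endo
  wall <- t_epi - t_endo
  nA <- length(angles)
  scar_len <- rep(NA_real_, nA)
  if (any(valid)) {
    idx <- which(valid)
    frac <- (seq_len(n_samples) - 0.5) / n_samples
    tt <- outer(t_endo[idx], rep(1, n_samples)) +
      outer(wall[idx], frac)                       # nIdx x K radii
    xx <- ctr[1L] + tt * cos(angles[idx])
    yy <- ctr[2L] + tt * sin(angles[idx])
    if (interp == "bilinear") {
      sv <- .bilinear(scar_mask * 1, as.vector(xx), as.vector(yy), sl$pixel_spacing)
      mv <- .bilinear(myo_mask * 1, as.vector(xx), as.vector(yy), sl$pixel_spacing)
      sv <- matrix(sv, length(idx)); mv <- matrix(mv, length(idx))
      num <- rowSums(sv)
      den <- rowSums(mv)
      frac_scar <- ifelse(den > 1e-9, pmin(num / den, 1), 0)
      scar_len[idx] <- frac_scar * wall[idx]
    } else {
      sv <- .nearest_pixel(scar_mask, as.vector(xx), as.vector(yy), sl$pixel_spacing)
      sv <- matrix(sv, length(idx))
      scar_len[idx] <- rowSums(sv) / n_samples * wall[idx]
    }
  }
  list(wall = wall, scar = scar_len, valid = valid)
}

#' Line-based transmurality (STLB) from chords
#'
#' Thickness-weighted mean radial scar extent:
#' `100 * sum(scar_mm) / sum(wall_mm)` over the segment's chords. With
#' `weighted = FALSE` the unweighted mean of per-chord ratios is used.
#'
#' @param chords data.frame as returned by [cast_chords()] (rows from
#'   several slices may be concatenated).
#' @param weighted logical; thickness-weighted (default) or plain mean.
#' @return Transmurality percent; NA when no valid chords are supplied.
#' @export
stlb <- function(chords, weighted = TRUE) {
  ok <- is.finite(chords$wall_mm) & chords$wall_mm > 0 & is.finite(chords$scar_mm)
  if (!any(ok)) return(NA_real_)
  if (weighted) {
    100 * sum(chords$scar_mm[ok]) / sum(chords$wall_mm[ok])
  } else {
    100 * mean(chords$scar_mm[ok] / chords$wall_mm[ok])
  }
}

#' Spatial maximal scar transmurality (SMST) from chords
#'
#' The maximum per-chord transmurality in the segment. SMST retains the
#' spatial notion of transmurality: a narrow transmural lesion scores
#' 100 even when its circumferential extent is small.
#'
#' @inheritParams stlb
#' @return Transmurality percent; NA when no valid chords are supplied.
#' @export
smst <- function(chords) {
  ok <- is.finite(chords$wall_mm) & chords$wall_mm > 0 & is.finite(chords$scar_mm)
  if (!any(ok)) return(NA_real_)
  100 * max(chords$scar_mm[ok] / chords$wall_mm[ok])
}

#' Intensity-weighted infarct transmurality (WIT)
#'
#' Scar mass fraction of the segment with each scar pixel weighted by its
#' normalized intensity, `w = clamp((I - remote)/(core - remote), 0, 1)`,
#' to account for partial-volume effects. Without an intensity channel
#' every scar pixel has weight 1 and WIT reduces to the segment's binary
#' scar mass fraction (equal to STAB under uniform voxel size).
#'
#' @param scar_weighted_mass,total_mass per-segment masses (arbitrary
#'   consistent units).
#' @return Transmurality percent; NA where the segment has no mass.
#' @export
wit <- function(scar_weighted_mass, total_mass) {
  ifelse(total_mass > 0, 100 * scar_weighted_mass / total_mass, NA_real_)
}

#' Partial-volume weights of scar pixels
#' @noRd
.wit_weights <- function(intensity_values, remote, core) {
  pmin(pmax((intensity_values - remote) / (core - remote), 0), 1)
}

#' Per-segment transmurality by the four estimators
#'
#' Computes STAB, STLB, WIT and SMST for AHA segments 1-16 of a stack.
#' Segment 17 (the apex cap) has no short-axis chords; its scar presence,
#' taken from the most apical slice, is attached as the
#' `apex_has_scar` attribute.
#'
#' @inheritParams cast_chords
#' @param stlb_weighted thickness-weighted STLB averaging (see [stlb()]).
#' @param min_scar_area_mm2 segments whose scar area falls below this
#'   threshold are treated as scar-free (default 0 = no filter).
#' @return data.frame with one row per segment 1-16 and columns
#'   `segment_id`, `stab`, `stlb`, `wit`, `smst` (percent; NA for
#'   segments with no myocardial pixels) and `has_scar`.
#' @export
segment_transmurality <- function(stack, scar, n_chords = 60L, n_samples = 200L,
                                  interp = c("bilinear", "nearest"),
                                  stlb_weighted = TRUE, min_scar_area_mm2 = 0,
                                  myo = NULL) {
  interp <- match.arg(interp)
  if (n_chords < 8L) {
    .stop_scarq("n_chords must be at least 8 per sector", "scarq_chord_error")
  }
  if (is.null(myo)) myo <- rasterize_myocardium(stack)
  scar <- .clip_scar(scar, myo)
  levels <- assign_levels(stack)

  has_int <- !is.null(scar$intensity)
  myo_area <- scar_area <- tot_mass <- scar_wmass <- numeric(16L)
  chord_scar <- chord_wall <- vector("list", 16L)
  chord_max <- rep(-Inf, 16L)

  for (i in seq_along(stack$slices)) {
    sl <- stack$slices[[i]]
    level <- levels[i]
    rv <- .rv_angle_of_slice(stack, i)
    m <- myo$masks[[i]]
    s <- scar$masks[[i]]
    lab <- .slice_segment_labels(sl, m, level, rv)
    px_area <- myo$pixel_area[i]
    vx_mass <- myo$voxel_volume[i]          # per-pixel mass up to the density
    segs <- .level_segments(level)

    cnt_m <- tabulate(lab[m], nbins = 16L)
    cnt_s <- tabulate(lab[s], nbins = 16L)
    myo_area <- myo_area + cnt_m * px_area
    scar_area <- scar_area + cnt_s * px_area
    tot_mass <- tot_mass + cnt_m * vx_mass
    if (has_int) {
      w <- .wit_weights(scar$intensity[[i]][s], scar$remote_intensity,
                        scar$core_intensity)
      wsum <- vapply(split(w, factor(lab[s], levels = 1:16)), sum, numeric(1))
      scar_wmass <- scar_wmass + wsum * vx_mass
    } else {
      scar_wmass <- scar_wmass + cnt_s * vx_mass
    }

    sectors <- .level_sectors(level)
    angles <- rv + as.vector(t(
      outer(sectors$start, rep(1, n_chords)) +
        outer(sectors$end - sectors$start, (seq_len(n_chords) - 0.5) / n_chords)
    ))
    res <- .cast_chords_slice(sl, s, m, angles, n_samples, interp)
    for (k in seq_len(nrow(sectors))) {
      sid <- sectors$segment_id[k]
      idx <- ((k - 1L) * n_chords + 1L):(k * n_chords)
      ok <- res$valid[idx]
      if (any(ok)) {
        chord_scar[[sid]] <- c(chord_scar[[sid]], res$scar[idx][ok])
        chord_wall[[sid]] <- c(chord_wall[[sid]], res$wall[idx][ok])
      }
    }
  }

  # minimum-area filter: blank segments below the scar-area threshold
  blank <- min_scar_area_mm2 > 0 & scar_area < min_scar_area_mm2 & scar_area > 0
  out <- data.frame(
    segment_id = 1:16,
    stab = stab(scar_area, myo_area),
    stlb = NA_real_, wit = wit(scar_wmass, tot_mass), smst = NA_real_,
    has_scar = scar_area > 0
  )
  for (sid in 1:16) {
    if (length(chord_wall[[sid]])) {
      ch <- data.frame(wall_mm = chord_wall[[sid]], scar_mm = chord_scar[[sid]])
      out$stlb[sid] <- stlb(ch, weighted = stlb_weighted)
      out$smst[sid] <- smst(ch)
    }
  }
  # a segment without a single scar pixel has no scar to measure: zero the
  # chord metrics there, so interpolation support reaching across a sector
  # boundary cannot score a scar-free segment
  none <- !out$has_scar & myo_area > 0
  out$stlb[none] <- 0
  out$smst[none] <- 0
  if (any(blank)) {
    out$stab[blank] <- 0; out$stlb[blank] <- 0
    out$wit[blank] <- 0; out$smst[blank] <- 0
    out$has_scar[blank] <- FALSE
  }
  # guard against float overshoot of the [0, 100] contract
  for (cl in c("stab", "stlb", "wit", "smst")) {
    out[[cl]] <- pmin(pmax(out[[cl]], 0), 100)
  }
  apical_scar <- scar$masks[[length(scar$masks)]]
  attr(out, "apex_has_scar") <- any(apical_scar)
  out
}

#' Quartile profile of per-segment transmurality values
#'
#' Transmural extent is split into the bins 1-24%, 25-49%, 50-74% and
#' 75-100% (half-open lower edges; 75 is inclusive upward since scar
#' >= 75% is defined as transmural). Values in (0, 1) round into the
#' first bin; zeros and NAs are excluded, so the bin counts sum to the
#' number of segments with any scar by this estimator.
#'
#' @param values per-segment transmurality percentages in `[0, 100]`.
#' @return list with `counts` (named integer vector over the four bins)
#'   and `total` (segments with value > 0).
#' @export
quartile_profile <- function(values) {
  v <- values[!is.na(values)]
  if (any(v < 0 | v > 100)) {
    .stop_scarq("transmurality values must lie in [0, 100]", "scarq_range_error")
  }
  v <- v[v > 0]
  counts <- c(
    `1-24` = sum(v < 25),
    `25-49` = sum(v >= 25 & v < 50),
    `50-74` = sum(v >= 50 & v < 75),
    `75-100` = sum(v >= 75)
  )
  list(counts = counts, total = length(v))
}

#' Patient-level scar summary
#'
#' Assembles the global scar burden (percent scar, scar mass, LV mass)
#' and, per transmurality estimator, the quartile profile of the 16
#' segmental values and the count of transmural (>= 75%) segments.
#'
#' @inheritParams segment_transmurality
#' @param density_g_per_cm3 myocardial density used for masses.
#' @return An object of class `patient_scar_summary`.
#' @export
summarize_patient <- function(stack, scar, n_chords = 60L, n_samples = 200L,
                              interp = c("bilinear", "nearest"),
                              stlb_weighted = TRUE, min_scar_area_mm2 = 0,
                              density_g_per_cm3 = 1.05) {
  interp <- match.arg(interp)
  myo <- rasterize_myocardium(stack)
  scar <- .clip_scar(scar, myo)
  segs <- segment_transmurality(stack, scar, n_chords = n_chords,
                                n_samples = n_samples, interp = interp,
                                stlb_weighted = stlb_weighted,
                                min_scar_area_mm2 = min_scar_area_mm2,
                                myo = myo)
  pct <- percent_scar(scar, myo)
  mass <- lv_mass(stack, myo, density_g_per_cm3)
  methods <- c("stab", "stlb", "wit", "smst")
  profiles <- lapply(methods, function(m) quartile_profile(segs[[m]]))
  names(profiles) <- methods
  n_transmural <- vapply(profiles, function(p) unname(p$counts[["75-100"]]), integer(1))
  structure(
    list(
      percent_scar = pct,
      lv_mass_g = mass,
      scar_mass_g = scar_mass(pct, mass),
      segments = segs,
      profiles = profiles,
      n_transmural = n_transmural,
      apex_has_scar = attr(segs, "apex_has_scar")
    ),
    class = "patient_scar_summary"
  )
}

#' @export
print.patient_scar_summary <- function(x, ...) {
  cat(sprintf("<patient_scar_summary>\n  LV mass %.1f g | scar mass %.1f g | percent scar %.1f%%\n",
              x$lv_mass_g, x$scar_mass_g, x$percent_scar))
  for (m in names(x$profiles)) {
    p <- x$profiles[[m]]
    cat(sprintf("  %-4s quartiles [1-24 / 25-49 / 50-74 / >=75]: %s (total %d)\n",
                toupper(m), paste(p$counts, collapse = " / "), p$total))
  }
  invisible(x)
}
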