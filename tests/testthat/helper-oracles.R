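# Independent oracles and fixture builders used across the suite.
# Each oracle is deliberately implemented apart from the package's own
# code paths (different point-in-polygon routine, brute-force sampling,
# direct hypergeometric enumeration).

# --- rasterization oracle: mgcv::in.out point-in-polygon ------------------

oracle_myocardium <- function(sl) {
  nr <- sl$grid_shape[1L]; nc <- sl$grid_shape[2L]
  dx <- sl$pixel_spacing[1L]; dy <- sl$pixel_spacing[2L]
  xs <- rep((seq_len(nc) - 0.5) * dx, each = nr)
  ys <- rep((seq_len(nr) - 0.5) * dy, times = nc)
  close_ring <- function(p) rbind(p, p[1L, ])
  in_epi <- mgcv::in.out(close_ring(sl$epi), cbind(xs, ys))
  in_endo <- mgcv::in.out(close_ring(sl$endo), cbind(xs, ys))
  matrix(in_epi & !in_endo, nr, nc)
}

# --- dense chord-casting oracle ------------------------------------------

# Measures scar length along a ray of an annulus phantom by brute force:
# K dense samples between the exact circle radii, classified against the
# raster by straightforward containing-pixel (or bilinear) arithmetic.
oracle_chord <- function(stack, scar_mask, myo_mask, angle, K = 1e4,
                         interp = "nearest") {
  ann <- attr(stack, "annulus")
  sl <- stack$slices[[1L]]
  dx <- sl$pixel_spacing[1L]; dy <- sl$pixel_spacing[2L]
  tt <- ann$r_endo + (seq_len(K) - 0.5) / K * (ann$r_epi - ann$r_endo)
  x <- ann$center[1L] + tt * cos(angle)
  y <- ann$center[2L] + tt * sin(angle)
  wall <- ann$r_epi - ann$r_endo
  if (interp == "nearest") {
    j <- floor(x / dx) + 1L
    i <- floor(y / dy) + 1L
    hit <- scar_mask[cbind(i, j)]
    sum(hit) / K * wall
  } else {
    bl <- function(m, px, py) {
      gx <- px / dx - 0.5; gy <- py / dy - 0.5
      j0 <- pmin(pmax(floor(gx), 0), ncol(m) - 2L)
      i0 <- pmin(pmax(floor(gy), 0), nrow(m) - 2L)
      fx <- gx - j0; fy <- gy - i0
      m[cbind(i0 + 1L, j0 + 1L)] * (1 - fx) * (1 - fy) +
        m[cbind(i0 + 1L, j0 + 2L)] * fx * (1 - fy) +
        m[cbind(i0 + 2L, j0 + 1L)] * (1 - fx) * fy +
        m[cbind(i0 + 2L, j0 + 2L)] * fx * fy
    }
    num <- sum(bl(scar_mask * 1, x, y))
    den <- sum(bl(myo_mask * 1, x, y))
    min(num / den, 1) * wall
  }
}

# --- Fisher's exact test oracle: direct hypergeometric enumeration -------

oracle_fisher <- function(tp, fp, fn, tn) {
  r1 <- tp + fp          # test-positive margin
  c1 <- tp + fn          # event margin
  n <- tp + fp + fn + tn
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  xs <- lo:hi
  d <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(tp, c1, n - c1, r1)
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

# --- diagnostic-stats oracle: frequency counting on expanded labels ------

oracle_diagnostics <- function(tp, fp, fn, tn) {
  test <- rep(c(TRUE, TRUE, FALSE, FALSE), times = c(tp, fp, fn, tn))
  event <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(tp, fp, fn, tn))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = frac(sum(test & event), sum(event)),
    specificity = frac(sum(!test & !event), sum(!event)),
    ppv = frac(sum(test & event), sum(test)),
    npv = frac(sum(!test & !event), sum(!test)))
}

# --- fixture builders -----------------------------------------------------

# Star-convex LV-like slice: wobbly concentric contours around a center.
make_star_slice <- function(seed, n_vertices = 180L) {
  set.seed(seed)
  center <- c(30, 30)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  wobble <- function(base_r, amp) {
    k <- sample(2:5, 2L)
    r <- base_r * (1 + amp * (cos(k[1L] * th + runif(1, 0, 2 * pi)) +
                                cos(k[2L] * th + runif(1, 0, 2 * pi))) / 2)
    cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
  }
  endo <- wobble(runif(1, 10, 14), 0.08)
  epi <- wobble(runif(1, 22, 26), 0.05)
  slice_geometry(endo, epi, pixel_spacing = 1, slice_span = 8,
                 z_index = 0L, grid_shape = c(60L, 60L))
}

# Random multi-wedge phantom for property batteries.
make_random_phantom <- function(seed, n_slices = 3L) {
  set.seed(seed)
  r1 <- runif(1, 12, 16)
  r2 <- r1 + runif(1, 7, 11)
  stack <- make_annulus_stack(n_slices = n_slices, r_endo = r1, r_epi = r2,
                              pixel_spacing = 1, slice_span = 8,
                              rv_insertion_angle = runif(1, 0, 2 * pi),
                              n_vertices = 256L, margin = 4)
  n_wedges <- sample(1:3, 1L)
  wedges <- lapply(seq_len(n_wedges), function(i) {
    wedge_spec(theta_start = runif(1, 0, 2 * pi),
               theta_span = runif(1, pi / 9, 8 * pi / 9),
               depth = runif(1, 0.15, 1))
  })
  c(list(stack = stack), apply_wedges(stack, wedges))
}

# Reference phantom: 10-slice 20/30 mm annulus, 1 mm
# pixels, a 60-degree wedge of depth 0.5 aligned to the first basal sector.
make_reference_phantom <- function() {
  stack <- make_annulus_stack(n_slices = 10L, r_endo = 20, r_epi = 30,
                              pixel_spacing = 1, slice_span = 10,
                              rv_insertion_angle = 0)
  c(list(stack = stack), apply_wedges(stack, wedge_spec(0, pi / 3, 0.5)))
}
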