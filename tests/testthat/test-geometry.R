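# LV geometry: level assignment, sector mapping, rasterization, mass.

test_that("slices are apportioned to AHA levels by thirds, remainder basal-first", {
  mk <- function(n) make_annulus_stack(n_slices = n, r_endo = 20, r_epi = 30,
                                       pixel_spacing = 2, n_vertices = 256L)
  expect_equal(assign_levels(mk(3)), c("basal", "mid", "apical"))
  expect_equal(table(assign_levels(mk(9))),
               table(rep(c("basal", "mid", "apical"), each = 3)))
  lev11 <- assign_levels(mk(11))
  expect_equal(unname(c(sum(lev11 == "basal"), sum(lev11 == "mid"),
                        sum(lev11 == "apical"))), c(4, 4, 3))
  expect_true(all(diff(match(lev11, c("basal", "mid", "apical"))) >= 0))
  expect_error(assign_levels(mk(2)), class = "scarq_mapping_error")
})

test_that("angles map to segment IDs counterclockwise from the RV insertion", {
  rv <- 0.7
  deg <- pi / 180
  expect_identical(segment_id("basal", rv + 1 * deg, rv), 1L)
  expect_identical(segment_id("mid", rv + 61 * deg, rv), 8L)
  expect_identical(segment_id("apical", rv + 359 * deg, rv), 16L)
  # wrap-around and half-open boundaries
  expect_identical(segment_id("basal", rv - 1 * deg, rv), 6L)
  expect_identical(segment_id("basal", rv, rv), 1L)
  expect_identical(segment_id("basal", rv + 60 * deg, rv), 2L)
  expect_identical(segment_id("apical", rv + 90 * deg, rv), 14L)
  # vectorized: every angle maps to exactly one ID in the level's range
  ang <- seq(0, 2 * pi, length.out = 721)
  for (lv in c("basal", "mid", "apical")) {
    ids <- segment_id(lv, ang, rv)
    rng <- switch(lv, basal = 1:6, mid = 7:12, apical = 13:16)
    expect_true(all(ids %in% rng))
  }
})

test_that("rasterized myocardial area matches closed forms on circles and squares", {
  stack <- make_annulus_stack(n_slices = 1L, r_endo = 20, r_epi = 30,
                              pixel_spacing = 1)
  myo <- rasterize_myocardium(stack)
  expect_equal(sum(myo$masks[[1L]]), pi * (30^2 - 20^2), tolerance = 0.02)

  sq <- function(half, c0) cbind(c0 + c(-half, half, half, -half),
                                 c0 + c(-half, -half, half, half))
  sl <- slice_geometry(sq(10, 30), sq(20, 30), pixel_spacing = 1,
                       slice_span = 8, grid_shape = c(60L, 60L))
  m <- rasterize_myocardium(sl)
  expect_equal(sum(m$masks[[1L]]), 1200, tolerance = 0.02)
})

test_that("degenerate contours raise geometry errors", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  ring <- function(r) cbind(30 + r * cos(th), 30 + r * sin(th))
  expect_error(
    slice_geometry(ring(20), ring(20), 1, 8, grid_shape = c(60L, 60L)),
    class = "scarq_geometry_error"
  )
  expect_error(
    slice_geometry(ring(25), ring(20), 1, 8, grid_shape = c(60L, 60L)),
    class = "scarq_geometry_error"
  )
  expect_error(slice_geometry(ring(20), ring(25), c(1, -1), 8,
                              grid_shape = c(60L, 60L)),
               class = "scarq_geometry_error")
})

test_that("LV mass matches the closed form and scales linearly with slice span", {
  stack <- make_annulus_stack(n_slices = 10L, r_endo = 20, r_epi = 30,
                              pixel_spacing = 1, slice_span = 10)
  expect_equal(lv_mass(stack), 1.05 * pi * (900 - 400) * 100 / 1000,
               tolerance = 0.02)
  stack2 <- make_annulus_stack(n_slices = 10L, r_endo = 20, r_epi = 30,
                               pixel_spacing = 1, slice_span = 20)
  expect_equal(lv_mass(stack2), 2 * lv_mass(stack), tolerance = 1e-12)
  # single slice: mass is exactly the voxel-volume definition
  one <- make_annulus_stack(n_slices = 1L, r_endo = 20, r_epi = 30,
                            pixel_spacing = 1, slice_span = 10)
  vol <- sum(rasterize_myocardium(one)$masks[[1L]]) * 1 * 1 * 10
  expect_equal(lv_mass(one), 1.05 * vol / 1000)
})

test_that("segment labels partition the myocardium pixel-exactly", {
  ph <- make_reference_phantom()
  myo <- rasterize_myocardium(ph$stack)
  levels <- assign_levels(ph$stack)
  for (i in c(1L, 5L, 10L)) {
    lab <- scarq:::.slice_segment_labels(ph$stack$slices[[i]], myo$masks[[i]],
                                         levels[i], 0)
    expect_identical(sum(tabulate(lab[myo$masks[[i]]], nbins = 16L)),
                     sum(myo$masks[[i]]))
    expect_true(all(is.na(lab[!myo$masks[[i]]])))
  }
})

test_that("rotating contours and RV insertion together leaves segment metrics unchanged", {
  delta <- 0.7
  base <- make_annulus_stack(n_slices = 3L, r_endo = 15, r_epi = 25,
                             pixel_spacing = 1, rv_insertion_angle = 0.2)
  rot <- make_annulus_stack(n_slices = 3L, r_endo = 15, r_epi = 25,
                            pixel_spacing = 1, rv_insertion_angle = 0.2 + delta)
  w0 <- wedge_spec(0.5, 1.2, 0.6)
  w1 <- wedge_spec(0.5 + delta, 1.2, 0.6)
  st0 <- segment_transmurality(base, apply_wedges(base, w0)$scar)
  st1 <- segment_transmurality(rot, apply_wedges(rot, w1)$scar)
  expect_true(all(abs(st0$stab - st1$stab) < 1, na.rm = TRUE))
  expect_true(all(abs(st0$stlb - st1$stlb) < 1, na.rm = TRUE))
})

test_that("halving pixel spacing changes LV mass by less than 1%", {
  m1 <- lv_mass(make_annulus_stack(n_slices = 2L, pixel_spacing = 1))
  m2 <- lv_mass(make_annulus_stack(n_slices = 2L, pixel_spacing = 0.5))
  expect_lt(abs(m2 - m1) / m1, 0.01)
})

test_that("rasterization agrees with an independent point-in-polygon oracle", {
  agree <- vapply(1:20, function(s) {
    sl <- make_star_slice(s)
    mine <- rasterize_myocardium(sl)$masks[[1L]]
    ref <- oracle_myocardium(sl)
    mean(mine == ref)
  }, numeric(1))
  expect_true(all(agree >= 0.995))
})
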