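# Scar burden and the four transmurality estimators.

ref <- make_reference_phantom()   # 10-slice 20/30 mm annulus, 60-deg wedge, d = 0.5
ref_myo <- rasterize_myocardium(ref$stack)
ref_seg <- segment_transmurality(ref$stack, ref$scar)

test_that("percent scar matches closed-form annular fractions", {
  empty <- scar_raster(lapply(ref_myo$masks, function(m) m & FALSE))
  expect_equal(percent_scar(empty, ref_myo), 0)
  full <- scar_raster(ref_myo$masks)
  expect_equal(percent_scar(full, ref_myo), 100)

  quarter <- apply_wedges(ref$stack, wedge_spec(0, pi / 2, 0.5))
  expect_equal(percent_scar(quarter$scar, ref_myo),
               100 * (90 / 360) * (25^2 - 20^2) / (30^2 - 20^2),
               tolerance = 0.02)
  expect_error(percent_scar(empty, scar_raster(ref_myo$masks[1:3])),
               class = "scarq_shape_error")
})

test_that("scar mass is the product of percent scar and LV mass", {
  expect_equal(scar_mass(10, 200), 20)
  expect_equal(scar_mass(0, 123), 0)
  expect_equal(scar_mass(15.1, 205), 30.955)
  summ <- summarize_patient(ref$stack, ref$scar)
  expect_equal(summ$scar_mass_g, summ$percent_scar / 100 * summ$lv_mass_g,
               tolerance = 1e-9)
})

test_that("STAB reproduces annular area ratios of wedge lesions", {
  # wedge filling one basal sector at depth 0.5: (25^2-20^2)/(30^2-20^2)
  expect_equal(ref_seg$stab[1L], 45, tolerance = 1 / 45)
  # same lesion over half the sector: half the value
  half <- apply_wedges(ref$stack, wedge_spec(0, pi / 6, 0.5))
  st <- segment_transmurality(ref$stack, half$scar)
  expect_equal(st$stab[1L], 22.5, tolerance = 1 / 22.5)
  # scar filling the whole segment scores 100
  full <- apply_wedges(ref$stack, wedge_spec(0, 2 * pi, 1))
  expect_true(all(segment_transmurality(ref$stack, full$scar)$stab == 100))
  # direct arithmetic, including the empty-segment missing rule
  expect_equal(stab(c(45, 0), c(100, 0)), c(45, NA_real_))
})

test_that("chords measure wall and scar lengths against the dense-casting oracle", {
  for (ip in c("bilinear", "nearest")) {
    ch <- cast_chords(ref$stack, ref$scar, slice = 1L,
                      theta_range = c(0, pi / 3), n_chords = 20L, interp = ip)
    expect_true(all(ch$scar_mm >= 0 & ch$scar_mm <= ch$wall_mm + 1e-9))
    expect_equal(ch$wall_mm, rep(10, nrow(ch)), tolerance = 1e-3)
    dense <- vapply(ch$angle, function(a) {
      oracle_chord(ref$stack, ref$scar$masks[[1L]], ref_myo$masks[[1L]], a,
                   K = 1e4, interp = ip)
    }, numeric(1))
    expect_true(all(abs(ch$scar_mm - dense) < 0.2))
    expect_true(all(abs(ch$scar_mm - 5) < 1))  # wedge depth 0.5 on a 10 mm wall
  }
  # chords through scar-free angles measure zero
  ch0 <- cast_chords(ref$stack, ref$scar, slice = 1L,
                     theta_range = c(pi, 4 * pi / 3), n_chords = 10L)
  expect_true(all(ch0$scar_mm == 0))
  # fully scarred wall: scar length equals wall length
  full <- apply_wedges(ref$stack, wedge_spec(0, 2 * pi, 1))
  chf <- cast_chords(ref$stack, full$scar, slice = 1L,
                     theta_range = c(0, pi / 3), n_chords = 10L)
  expect_equal(chf$scar_mm, chf$wall_mm, tolerance = 1e-9)
})

test_that("STLB averages chord transmurality, thickness-weighted", {
  expect_equal(ref_seg$stlb[1L], 50, tolerance = 1 / 50)
  half <- apply_wedges(ref$stack, wedge_spec(0, pi / 6, 0.5))
  st <- segment_transmurality(ref$stack, half$scar)
  expect_equal(st$stlb[1L], 25, tolerance = 1 / 25)
  expect_equal(ref_seg$stlb[4L], 0)   # no scar in the opposite sector
  # constant wall thickness: weighted and unweighted means agree
  ch <- cast_chords(ref$stack, ref$scar, slice = 1L, theta_range = c(0, pi / 3))
  expect_equal(stlb(ch, weighted = TRUE), stlb(ch, weighted = FALSE),
               tolerance = 1e-6)
  expect_true(is.na(stlb(data.frame(wall_mm = numeric(), scar_mm = numeric()))))
})

test_that("SMST picks the maximal chord and diverges from STLB for focal lesions", {
  # wedge covering 10% of a sector at depth 0.5: STLB ~ 5, SMST ~ full depth.
  # SMST is read from a binary raster, so its maximum carries the positive
  # extreme of the half-pixel boundary quantization (up to ~1 px / wall).
  focal <- apply_wedges(ref$stack, wedge_spec(0.02, pi / 30, 0.5))
  st <- segment_transmurality(ref$stack, focal$scar)
  expect_equal(st$stlb[1L], 5, tolerance = 0.3)
  expect_gte(st$smst[1L], 45)
  expect_lte(st$smst[1L], 50 + 100 * 1 / 10)
  expect_gt(st$smst[1L], 5 * st$stlb[1L])
  # a transmural needle a few chords wide attains (near-)maximal SMST
  needle <- apply_wedges(ref$stack, wedge_spec(0.25, pi / 30, 1))
  stn <- segment_transmurality(ref$stack, needle$scar)
  expect_gte(stn$smst[1L], 95)
  expect_equal(smst(data.frame(wall_mm = 10, scar_mm = 0)), 0)
  expect_true(is.na(smst(data.frame(wall_mm = numeric(), scar_mm = numeric()))))
})

test_that("WIT equals STAB for binary input and drops under partial-volume ramps", {
  expect_equal(ref_seg$wit, ref_seg$stab, tolerance = 1e-9)
  # explicit half-weight: all scar pixels at w = 0.5 halve WIT exactly
  mid_gray <- (1000 + 200) / 2
  intens <- lapply(ref$scar$masks, function(m) {
    v <- m * 0 + 200; v[m] <- mid_gray; v
  })
  gray <- scar_raster(ref$scar$masks, intensity = intens,
                      remote_intensity = 200, core_intensity = 1000)
  st <- segment_transmurality(ref$stack, gray)
  expect_equal(st$wit, ref_seg$stab / 2, tolerance = 1e-9)
  # partial-volume ramp at the lesion boundary reduces WIT below STAB
  ramp <- apply_wedges(ref$stack,
                       wedge_spec(0, pi / 3, 0.5, intensity = "ramp",
                                  core = 1000, remote = 200, edge_width_mm = 3))
  str <- segment_transmurality(ref$stack, ramp$scar)
  expect_lt(str$wit[1L], str$stab[1L])
  expect_gt(str$wit[1L], 0)
  # calibration must order core above remote
  expect_error(
    scar_raster(ref$scar$masks, intensity = intens,
                remote_intensity = 1000, core_intensity = 200),
    class = "scarq_calibration_error"
  )
})

test_that("quartile binning is half-open below and inclusive at the transmural cut", {
  p <- quartile_profile(c(0, 10, 30, 80))
  expect_equal(unname(p$counts), c(1, 1, 0, 1))
  expect_equal(p$total, 3)
  expect_equal(quartile_profile(rep(0, 16))$counts,
               c(`1-24` = 0L, `25-49` = 0L, `50-74` = 0L, `75-100` = 0L))
  # 75 is transmural; sub-1% values round into the first bin; NA excluded
  p2 <- quartile_profile(c(75, 74.999, 0.5, 25, 24.99, 50, 100, NA))
  expect_equal(unname(p2$counts), c(2L, 1L, 2L, 2L))
  expect_equal(p2$total, 7)
  expect_error(quartile_profile(c(10, 101)), class = "scarq_range_error")
})

test_that("patient summaries assemble burden, profiles and transmural counts", {
  empty <- scar_raster(lapply(ref_myo$masks, function(m) m & FALSE))
  s0 <- summarize_patient(ref$stack, empty)
  expect_equal(s0$percent_scar, 0)
  expect_equal(s0$scar_mass_g, 0)
  expect_true(all(vapply(s0$profiles, function(p) p$total, integer(1)) == 0))

  full <- apply_wedges(ref$stack, wedge_spec(0, 2 * pi, 1))
  s1 <- summarize_patient(ref$stack, full$scar)
  expect_equal(s1$percent_scar, 100)
  expect_true(all(s1$n_transmural == 16))
  expect_true(s1$apex_has_scar)

  sw <- summarize_patient(ref$stack, ref$scar)
  tr <- ref$truth
  expect_equal(sw$percent_scar, tr$percent_scar, tolerance = 0.02)
  expect_equal(sw$lv_mass_g, tr$lv_mass_g, tolerance = 0.02)
  expect_true(all(abs(sw$segments$stab - tr$segments$stab) < 1))
  expect_true(all(abs(sw$segments$stlb - tr$segments$stlb) < 1))
})

test_that("scar outside the myocardium is clipped with a warning", {
  leaky <- ref$scar
  leaky$masks[[1L]][1L, 1L] <- TRUE   # corner pixel, outside the annulus
  expect_warning(pct <- percent_scar(leaky, ref_myo), "clipped 1 scar pixel")
  expect_equal(pct, percent_scar(ref$scar, ref_myo))
})

test_that("deepening a wedge strictly increases every estimator", {
  vals <- lapply(c(0.25, 0.5, 0.75, 1), function(d) {
    ph <- apply_wedges(ref$stack, wedge_spec(0, pi / 3, d))
    segment_transmurality(ref$stack, ph$scar)[1L, c("stab", "stlb", "wit", "smst")]
  })
  for (m in c("stab", "stlb", "wit", "smst")) {
    v <- vapply(vals, `[[`, numeric(1), m)
    expect_true(all(diff(v) > 0), label = sprintf("%s increases with depth", m))
  }
})

test_that("endocardium-attached wedges order STAB at or below STLB", {
  for (s in 1:10) {
    ph <- make_random_phantom(s, n_slices = 3L)
    st <- segment_transmurality(ph$stack, ph$scar)
    on_scar <- which(st$has_scar)
    expect_true(all(st$stab[on_scar] <= st$stlb[on_scar] + 1),
                label = sprintf("phantom %d", s))
    expect_true(all(st$smst >= st$stlb - 1e-9, na.rm = TRUE))
  }
})
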