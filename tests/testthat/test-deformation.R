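test_that("deformation factors are exact area ratios with a first-frame reference", {
  ds <- deformation_factors(c(100, 121))
  expect_equal(ds$factors, c(1, 1.21), tolerance = 1e-15)
  expect_equal(deformation_factors(rep(250, 10))$factors, rep(1, 10))
  expect_equal(deformation_factors(c(100, 121))$factors[1], 1)
  expect_error(deformation_factors(c(100, 0, 90)), "frame 2")
  expect_error(deformation_factors(100), "at least 2")
  # big square over small square reference: ratio 4
  rig <- rig_geometry()
  rs <- render_square_sequence(0.05, 0.10, rig, seed = 1)
  areas <- areas_of(rs$sequence)
  expect_equal(deformation_factors(areas)$factors[2], 4, tolerance = 0.005)
})

test_that("equivalent-circle displacement conversion matches closed forms", {
  # r_ref = 40 mm: F_ref = pi * 40^2 at 1 mm/px
  ds <- deformation_factors(c(pi * 1600, pi * 1600 * 1.21))
  disp <- factor_to_displacement(ds, pixel_scale(1))
  expect_equal(disp, c(0, 4), tolerance = 1e-12)
  expect_equal(factor_to_displacement(deformation_factors(c(5, 5)),
                                      pixel_scale(0.5)), c(0, 0))
  # monotone in area
  ds2 <- deformation_factors(c(100, 110, 130, 160))
  d2 <- factor_to_displacement(ds2, pixel_scale(1))
  expect_true(all(diff(d2) > 0))
})

test_that("cycle splitting reports max-minus-min per complete cycle", {
  fr <- 30; pulse <- 72
  t <- (0:(5 * fr * 60 / pulse - 1)) / fr
  a <- 2.5
  s <- a * sin(2 * pi * pulse / 60 * t)
  amps <- cycle_amplitudes(s, fr, pulse)
  expect_length(amps, 5)
  expect_equal(amps, rep(2 * a, 5), tolerance = 0.02)
  expect_equal(cycle_amplitudes(rep(1.3, 100), fr, pulse),
               rep(0, floor(100 / 25)))
  # trailing partial cycle discarded
  expect_length(cycle_amplitudes(s[1:60], fr, pulse), 2)
  expect_error(cycle_amplitudes(s[1:10], fr, pulse), "insufficient")
})

test_that("phantom radial amplitude is recovered through the full chain", {
  rig <- test_rig()
  spec <- test_phantom_spec(radius = 30, amplitude = 3, n_cycles = 2,
                            noise_sd = 1, gradient = 0.05)
  ph <- render_phantom_sequence(spec, rig, 1, seed = 9)
  areas <- areas_of(ph$sequence)
  ds <- deformation_factors(areas, frame_rate = rig$fps)
  mm_px <- 1000 * rig$object_distance / default_intrinsics(rig)$fx
  disp <- factor_to_displacement(ds, pixel_scale(mm_px))
  amps <- cycle_amplitudes(disp, rig$fps, spec$pulsation_frequency)
  truth_amp <- max(ph$truth$displacement_mm_true)
  expect_equal(mean(amps), truth_amp, tolerance = 0.02)
})

test_that("average wall deformation reproduces the published per-patient summaries", {
  ref <- wall_deformation_reference()
  expected <- list(`1` = c(4.37, 0.54), `2` = c(3.97, 0.19),
                   `3` = c(3.68, 0.23), `4` = c(3.53, 0.19))
  for (p in names(expected)) {
    v <- ref$nivbs_mm[ref$patient == as.integer(p)]
    s <- summarize_wall_deformation(matrix(v, 4, 4))
    expect_equal(c(s$awd_2dp, s$sd_2dp), expected[[p]],
                 label = sprintf("patient %s", p))
    # textbook mean/SD oracle at full precision
    expect_equal(s$awd, sum(v) / 16, tolerance = 1e-12)
    expect_equal(s$sd, sqrt(sum((v - sum(v) / 16)^2) / 15), tolerance = 1e-12)
  }
  cst <- summarize_wall_deformation(matrix(2.5, 4, 4))
  expect_equal(c(cst$awd_2dp, cst$sd_2dp), c(2.5, 0))
  expect_error(summarize_wall_deformation(matrix(1, 3, 4)), "incomplete")
})

test_that("static diameter uses the caliper width averaged over cameras", {
  # filled disc of radius 40 px: caliper ~ 2 r
  xy <- expand.grid(x = 1:101, y = 1:101)
  m <- matrix(as.integer((xy$x - 51)^2 + (xy$y - 51)^2 <= 40^2), 101, 101)
  obj <- largest_object(m)
  d <- static_diameter(obj, pixel_scale(0.5))
  expect_equal(d$diameter_mm, 40, tolerance = 0.02)
  # 86 mm circular phantom recovered within 1 mm through rendering
  rig <- test_rig()
  spec <- test_phantom_spec(radius = 43, amplitude = 0, n_cycles = 1)
  ph <- render_phantom_sequence(spec, rig, 1, seed = 2)
  mm_px <- 1000 * rig$object_distance / default_intrinsics(rig)$fx
  est <- static_diameter(segment_frame(ph$sequence$frames[[1]]),
                         pixel_scale(mm_px))
  expect_equal(est$diameter_mm, 86, tolerance = 1 / 86)
  # square of side s: caliper is its pixel diagonal
  sq <- matrix(0L, 40, 40); sq[10:29, 10:29] <- 1L
  expect_equal(largest_object(sq)$max_caliper_px, 19 * sqrt(2),
               tolerance = 1e-12)
})

test_that("deformation factors are scale invariant across resolutions", {
  spec <- test_phantom_spec(radius = 35, amplitude = 4, n_cycles = 1)
  n_at <- function(w, h) {
    rig <- rig_geometry(image_width = w, image_height = h)
    ph <- render_phantom_sequence(spec, rig, 1, seed = 4)
    areas <- areas_of(ph$sequence)
    max(areas / areas[1])
  }
  n_lo <- n_at(240, 135)
  n_hi <- n_at(480, 270)
  expect_lt(abs(n_lo / n_hi - 1), 0.01)
})
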