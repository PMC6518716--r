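test_that("motionless phantom has unit deformation factors in truth and pipeline", {
  rig <- test_rig()
  spec <- test_phantom_spec(amplitude = 0, noise_sd = 2, n_cycles = 1)
  ph <- render_phantom_sequence(spec, rig, 1, seed = 11)
  expect_equal(ph$truth$n_true, rep(1, nrow(ph$truth)))
  expect_equal(ph$truth$displacement_mm_true, rep(0, nrow(ph$truth)))
  # a subset of frames is enough to exercise the estimation path
  areas <- areas_of(ph$sequence)
  n_hat <- areas / areas[1]
  expect_true(all(abs(n_hat - 1) <= 0.005))
})

test_that("uniform inflation to 1.1 r gives exact peak factor 1.21", {
  # 24 fps samples the cycle peak exactly (1.2 Hz -> peak at frame 11)
  rig <- test_rig(fps = 24)
  spec <- test_phantom_spec(radius = 30, amplitude = 3, n_cycles = 1)
  ph <- render_phantom_sequence(spec, rig, 1, seed = 1)
  expect_equal(max(ph$truth$n_true), 1.21, tolerance = 1e-12)
  expect_equal(which.max(ph$truth$n_true), 11)
})

test_that("rasterised pixel count tracks the analytic shoelace area", {
  rig <- rig_geometry()  # 480 x 270: default radius projects to > 50 px
  spec <- phantom_spec(noise_sd = 0, illumination_gradient = 0, n_cycles = 1)
  ph <- render_phantom_sequence(spec, rig, 1, seed = 5)
  pick <- c(1, 8, 13)
  areas <- vapply(ph$sequence$frames[pick],
                  function(f) segment_frame(f)$area_px, numeric(1))
  rel <- abs(areas / ph$truth$area_px2[pick] - 1)
  expect_true(all(rel < 0.01))
})

test_that("rasterisation error shrinks when linear resolution doubles", {
  err_at <- function(w, h) {
    rig <- rig_geometry(image_width = w, image_height = h)
    spec <- test_phantom_spec(radius = 25, amplitude = 0, n_cycles = 1)
    ph <- render_phantom_sequence(spec, rig, 1, seed = 3)
    abs(segment_frame(ph$sequence$frames[[1]])$area_px /
          ph$truth$area_px2[1] - 1)
  }
  e1 <- err_at(240, 135)
  e2 <- err_at(480, 270)
  expect_lt(e2, e1)
})

test_that("rendering is seed-reproducible and geometry is seed-independent", {
  rig <- test_rig()
  spec <- test_phantom_spec(noise_sd = 3, n_cycles = 1)
  a <- render_phantom_sequence(spec, rig, 1, seed = 42)
  b <- render_phantom_sequence(spec, rig, 1, seed = 42)
  expect_identical(a$sequence$frames, b$sequence$frames)
  c_ <- render_phantom_sequence(spec, rig, 1, seed = 43)
  expect_false(identical(a$sequence$frames[[1]], c_$sequence$frames[[1]]))
  # with the noise turned off the geometry is identical across seeds
  quiet <- test_phantom_spec(noise_sd = 0, n_cycles = 1)
  q1 <- render_phantom_sequence(quiet, rig, 1, seed = 1)
  q2 <- render_phantom_sequence(quiet, rig, 1, seed = 99)
  expect_identical(q1$sequence$frames, q2$sequence$frames)
  expect_identical(a$truth$area_px2, c_$truth$area_px2)
})

test_that("square sequence ground truth follows pinhole closed forms", {
  rig <- test_rig()
  rs <- render_square_sequence(0.05, 0.10, rig, seed = 1)
  expect_equal(rs$truth$n_true[2], 4, tolerance = 1e-12)
  same <- render_square_sequence(0.05, 0.05, rig, seed = 1)
  expect_equal(same$truth$n_true[2], 1, tolerance = 1e-12)
  # moving the squares from 0.30 m to 0.40 m rescales areas by (0.30/0.40)^2
  rig30 <- test_rig(object_distance = 0.30)
  rig40 <- test_rig(object_distance = 0.40)
  intr <- default_intrinsics(test_rig())
  near <- render_square_sequence(0.04, 0.08, rig30, intr = intr, seed = 1)
  far <- render_square_sequence(0.04, 0.08, rig40, intr = intr, seed = 1)
  expect_equal(far$truth$n_true[2], near$truth$n_true[2], tolerance = 1e-12)
  expect_equal(near$truth$area_px2 / far$truth$area_px2,
               rep((0.40 / 0.30)^2, 2), tolerance = 1e-12)
})

test_that("degenerate phantom and square specs are rejected", {
  rig <- test_rig()
  expect_error(phantom_spec(base_radius_mm = -5), "positive")
  expect_error(phantom_spec(pulsation_amplitude_mm = -1), "non-negative")
  expect_error(phantom_spec(foreground_level = 10, background_level = 50),
               "foreground")
  expect_error(render_phantom_sequence(test_phantom_spec(), rig,
                                       camera_index = 99), "outside the rig")
  expect_error(render_square_sequence(0.10, 0.05, rig), "side_small")
  expect_error(render_square_sequence(0.05, 5, rig), "field-of-view")
})

test_that("rig geometry validates coverage and exposes 36 default stations", {
  rig <- rig_geometry()
  st <- rig_stations(rig)
  expect_equal(nrow(st), 36)
  expect_equal(length(unique(round(st$angle_rad, 9))), 36)
  expect_error(rig_geometry(n_cameras = 4, angular_spacing = 0.7),
               "cover the full circle")
  expect_error(rig_geometry(object_distance = 0), "positive")
})
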