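intr_plain <- camera_intrinsics(fx = 450, width = 480, height = 270)
intr_barrel <- camera_intrinsics(fx = 450, k1 = -0.15, k2 = 0.02,
                                 p1 = 5e-4, p2 = -4e-4,
                                 width = 480, height = 270)

test_that("projection follows the pinhole plus distortion closed forms", {
  # optical-axis point maps to the principal point whatever the distortion
  expect_equal(unname(project_points(c(0, 0, 0.5), intr_barrel)),
               matrix(c(intr_barrel$cx, intr_barrel$cy), 1), tolerance = 1e-12)
  # pure pinhole: X = Z w -> pixel x = fx w + cx
  w <- 0.21
  p <- project_points(c(0.4 * w, 0, 0.4), intr_plain)
  expect_equal(unname(p[1, 1]), 450 * w + intr_plain$cx, tolerance = 1e-12)
  # k1 = -0.1 at normalized radius 0.5: displaced toward centre by (1 - 0.1 * 0.25)
  ik <- camera_intrinsics(fx = 450, k1 = -0.1, width = 480, height = 270)
  p <- project_points(c(0.5 * 0.4, 0, 0.4), ik)
  expect_equal(unname(p[1, 1]), 450 * 0.5 * (1 - 0.1 * 0.25) + ik$cx,
               tolerance = 1e-12)
  expect_error(project_points(c(0, 0, -1), intr_plain), "depth")
})

test_that("undistortion inverts the distortion map on the working field", {
  grid <- as.matrix(expand.grid(x = seq(60, 420, length.out = 10),
                                y = seq(40, 230, length.out = 10)))
  for (k1 in c(-0.3, -0.1, 0.15, 0.3)) {
    ik <- camera_intrinsics(fx = 450, k1 = k1, p1 = 1e-3, p2 = -5e-4,
                            width = 480, height = 270)
    # distort the grid (treat grid as undistorted pixel positions)
    xn <- (grid[, 1] - ik$cx) / ik$fx
    yn <- (grid[, 2] - ik$cy) / ik$fy
    d <- vesselmotion:::distort_normalized(xn, yn, ik)
    distorted <- cbind(ik$fx * d$x + ik$cx, ik$fy * d$y + ik$cy)
    back <- undistort_points(distorted, ik)
    expect_lt(max(abs(back - grid)), 1e-6)
  }
  # zero distortion: identity; principal point is always fixed
  expect_equal(unname(undistort_points(grid, intr_plain)), unname(grid),
               tolerance = 1e-12)
  pp <- undistort_points(c(intr_barrel$cx, intr_barrel$cy), intr_barrel)
  expect_equal(unname(pp[1, ]), c(intr_barrel$cx, intr_barrel$cy),
               tolerance = 1e-12)
})

test_that("rectification is exact for zero distortion and straightens barrel edges", {
  rig <- rig_geometry()
  img <- render_square_sequence(0.06, 0.10, rig, intr = intr_plain,
                                seed = 1)$sequence$frames[[2]]
  expect_identical(rectify_image(img, intr_plain), img)

  distorted <- render_square_sequence(0.06, 0.10, rig, intr = intr_barrel,
                                      seed = 1)$sequence$frames[[2]]
  rect <- rectify_image(distorted, intr_barrel)
  comp <- segment_frame(rect)$component
  # fit a vertical line to the left edge over the central band
  rows <- which(rowSums(comp) > 0)
  rows <- rows[rows > min(rows) + 3 & rows < max(rows) - 3]
  left <- vapply(rows, function(r) which(comp[r, ])[1], numeric(1))
  fit <- stats::lm(left ~ rows)
  expect_lt(max(abs(stats::residuals(fit))), 0.5)
  # and the segmented area matches the undistorted rendering within 1%
  ideal_area <- segment_frame(img)$area_px
  expect_lt(abs(segment_frame(rect)$area_px / ideal_area - 1), 0.01)
})

test_that("pixel scale from a reference square follows the closed form", {
  s <- pixel_scale_from_square(10000, 0.05)
  expect_equal(s$mm_per_pixel, 0.5, tolerance = 1e-12)
  # same square at double the distance: quarter area, doubled scale
  s2 <- pixel_scale_from_square(10000 / 4, 0.05)
  expect_equal(s2$mm_per_pixel, 1.0, tolerance = 1e-12)
  # cross-square consistency at one distance
  s3 <- pixel_scale_from_square(40000, 0.10)
  expect_equal(s3$mm_per_pixel, s$mm_per_pixel, tolerance = 1e-12)
  expect_error(pixel_scale_from_square(0, 0.05), "positive")
})

make_calib_views <- function(intr, noise_sd = 0, seed = 1,
                             half = c(0.08, 0.06), step = 0.02) {
  set.seed(seed)
  grid <- as.matrix(expand.grid(x = seq(-half[1], half[1], by = step),
                                y = seq(-half[2], half[2], by = step)))
  rvecs <- list(c(0.15, 0.05, 0), c(-0.2, 0.1, 0.05),
                c(0.1, -0.25, -0.1), c(0.05, 0.3, 0.2), c(-0.15, -0.2, 0.1),
                c(0.3, -0.1, 0.15), c(-0.1, 0.25, -0.2))
  tvecs <- list(c(0, 0, 0.40), c(0.02, -0.01, 0.45), c(-0.03, 0.02, 0.50),
                c(0.01, 0.03, 0.42), c(-0.01, -0.02, 0.47),
                c(0.02, 0.02, 0.43), c(-0.02, 0.01, 0.48))
  pts <- lapply(seq_along(rvecs), function(v) {
    R <- vesselmotion:::rodrigues_to_matrix(rvecs[[v]])
    P <- t(R %*% t(cbind(grid, 0)) + tvecs[[v]])
    px <- project_points(P, intr)
    px + matrix(stats::rnorm(length(px), 0, noise_sd), ncol = 2)
  })
  list(grid = grid, pts = pts)
}

test_that("calibration recovers the generating parameters from clean views", {
  true <- camera_intrinsics(fx = 460, fy = 455, cx = 242, cy = 133,
                            k1 = -0.12, k2 = 0.03, p1 = 1e-3, p2 = -8e-4,
                            width = 480, height = 270)
  v <- make_calib_views(true)
  cal <- calibrate_camera(v$grid, v$pts, c(480, 270))
  expect_lt(cal$rms, 1e-3)
  est <- cal$intrinsics
  for (f in c("fx", "fy", "cx", "cy"))
    expect_lt(abs(est[[f]] / true[[f]] - 1), 1e-3)
  expect_lt(abs(est$k1 - true$k1), 1e-3)
})

test_that("calibration on zero-distortion views estimates null coefficients", {
  true <- camera_intrinsics(fx = 450, width = 480, height = 270)
  v <- make_calib_views(true)
  cal <- calibrate_camera(v$grid, v$pts, c(480, 270))
  expect_true(all(abs(unlist(cal$intrinsics[c("k1", "k2", "k3", "p1", "p2")]))
                  < 1e-3))
})

test_that("calibration under detection noise reports noise-level RMS", {
  true <- camera_intrinsics(fx = 460, cx = 240, cy = 135, k1 = -0.12,
                            k2 = 0.02, width = 480, height = 270)
  # target filling the field of view: the k1 displacement signal (several
  # px at the frame corners) must dominate the 0.2 px detection noise,
  # and a wide radius range decorrelates the r^2/r^4/r^6 terms
  v <- make_calib_views(true, noise_sd = 0.2, seed = 4,
                        half = c(0.20, 0.14), step = 0.02)
  cal <- calibrate_camera(v$grid, v$pts, c(480, 270))
  expect_gt(cal$rms, 0.1)
  expect_lt(cal$rms, 0.4)
  expect_lt(abs(cal$intrinsics$k1 / true$k1 - 1), 0.05)
})

test_that("calibration input contracts are enforced", {
  true <- camera_intrinsics(fx = 450, width = 480, height = 270)
  v <- make_calib_views(true)
  expect_error(calibrate_camera(v$grid, v$pts[1:2], c(480, 270)), "3 views")
  expect_error(calibrate_camera(v$grid[1:4, ], lapply(v$pts, function(p) p[1:4, ]),
                                c(480, 270)), "8 points")
})

test_that("intrinsics serialise losslessly to YAML and JSON", {
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("intr.", ext))
    write_intrinsics(intr_barrel, path)
    back <- read_intrinsics(path)
    expect_equal(back[names(back) != "width" & names(back) != "height"],
                 intr_barrel[names(intr_barrel) != "width" &
                               names(intr_barrel) != "height"],
                 tolerance = 1e-9, ignore_attr = TRUE)
    unlink(path)
  }
})
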