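#' Camera intrinsics with Brown-Conrady distortion
#'
#' Bundles the pinhole parameters (focal lengths and principal point, in
#' pixels) with the five-coefficient Brown-Conrady distortion model: radial
#' terms \code{k1, k2, k3} and tangential terms \code{p1, p2}. With all five
#' coefficients zero the model reduces to a pure pinhole camera.
#'
#' Pixel coordinate convention (used everywhere in this package): origin at
#' the centre of the top-left pixel, x to the right, y down, 0-based. A
#' \code{width x height} image therefore has pixel centres at
#' \code{0 .. width-1} and \code{0 .. height-1}.
#'
#' @param fx,fy Focal lengths in pixels; both must be positive. `fy`
#'   defaults to `fx` (square pixels).
#' @param cx,cy Principal point in pixels; defaults to the image centre
#'   `(width-1)/2`, `(height-1)/2`. Must lie inside the image bounds.
#' @param k1,k2,k3 Radial distortion coefficients (dimensionless).
#' @param p1,p2 Tangential distortion coefficients (dimensionless).
#' @param width,height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy = fx, cx = (width - 1) / 2,
                              cy = (height - 1) / 2,
                              k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0,
                              width, height) {
  if (!is.numeric(fx) || !is.numeric(fy) || fx <= 0 || fy <= 0)
    stop("focal lengths fx, fy must be positive")
  if (missing(width) || missing(height) || width < 1 || height < 1)
    stop("image width and height are required")
  if (cx < 0 || cx > width - 1 || cy < 0 || cy > height - 1)
    stop("principal point (cx, cy) must lie inside the image bounds")
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy,
         k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2,
         width = as.integer(width), height = as.integer(height)),
    class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat("Camera intrinsics (", x$width, "x", x$height, " px)\n", sep = "")
  cat(sprintf("  focal length: fx = %.4g, fy = %.4g px\n", x$fx, x$fy))
  cat(sprintf("  principal point: (%.4g, %.4g) px\n", x$cx, x$cy))
  cat(sprintf("  radial k = (%.4g, %.4g, %.4g), tangential p = (%.4g, %.4g)\n",
              x$k1, x$k2, x$k3, x$p1, x$p2))
  invisible(x)
}

has_distortion <- function(intr) {
  any(abs(c(intr$k1, intr$k2, intr$k3, intr$p1, intr$p2)) > 0)
}

# Forward Brown-Conrady map on normalized coordinates.
distort_normalized <- function(xn, yn, intr) {
  r2 <- xn^2 + yn^2
  radial <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
  xd <- xn * radial + 2 * intr$p1 * xn * yn + intr$p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + 2 * intr$p2 * xn * yn + intr$p1 * (r2 + 2 * yn^2)
  list(x = xd, y = yd)
}

#' Project 3D points in the camera frame to pixel coordinates
#'
#' Central projection followed by Brown-Conrady distortion and conversion to
#' pixels: normalized coordinates `x_n = X/Z`, `y_n = Y/Z` are distorted as
#' `x_d = x_n (1 + k1 r^2 + k2 r^4 + k3 r^6) + 2 p1 x_n y_n + p2 (r^2 + 2 x_n^2)`
#' (and symmetrically for `y_d`, with `r^2 = x_n^2 + y_n^2`), then mapped to
#' `(fx x_d + cx, fy y_d + cy)`.
#'
#' @param points Numeric matrix with 3 columns (X, Y, Z in metres, camera
#'   frame; Z along the optical axis) or a length-3 vector.
#' @param intr A [camera_intrinsics()] object.
#' @return Matrix with columns `x`, `y` (pixels).
#' @export
project_points <- function(points, intr) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (ncol(points) != 3) stop("points must have 3 columns (X, Y, Z)")
  if (any(points[, 3] <= 0))
    stop("cannot project points with non-positive depth Z")
  xn <- points[, 1] / points[, 3]
  yn <- points[, 2] / points[, 3]
  d <- distort_normalized(xn, yn, intr)
  cbind(x = intr$fx * d$x + intr$cx, y = intr$fy * d$y + intr$cy)
}

#' Invert the distortion map for a set of pixel coordinates
#'
#' Undoes radial and tangential distortion by fixed-point iteration in
#' normalized coordinates: starting from the distorted position, the radial
#' factor and tangential shift are re-evaluated at the current estimate
#' until the forward map reproduces the input within `tol`.
#'
#' @param pixels Matrix with columns x, y (pixels, distorted) or a length-2
#'   vector.
#' @param intr A [camera_intrinsics()] object.
#' @param tol Convergence tolerance in normalized coordinates.
#' @param max_iter Maximum number of fixed-point iterations.
#' @return Matrix of undistorted pixel coordinates.
#' @export
undistort_points <- function(pixels, intr, tol = 1e-8, max_iter = 50L) {
  if (tol <= 0) stop("tol must be positive")
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  xd <- (pixels[, 1] - intr$cx) / intr$fx
  yd <- (pixels[, 2] - intr$cy) / intr$fy
  xn <- xd
  yn <- yd
  for (i in seq_len(max_iter)) {
    r2 <- xn^2 + yn^2
    radial <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
    dx <- 2 * intr$p1 * xn * yn + intr$p2 * (r2 + 2 * xn^2)
    dy <- 2 * intr$p2 * xn * yn + intr$p1 * (r2 + 2 * yn^2)
    xn_new <- (xd - dx) / radial
    yn_new <- (yd - dy) / radial
    delta <- max(abs(xn_new - xn), abs(yn_new - yn))
    xn <- xn_new
    yn <- yn_new
    if (delta < tol) break
  }
  d <- distort_normalized(xn, yn, intr)
  resid <- max(abs(d$x - xd), abs(d$y - yd))
  if (resid >= tol)
    stop(sprintf(
      "undistort_points did not converge after %d iterations (residual %.3g)",
      max_iter, resid))
  cbind(x = intr$fx * xn + intr$cx, y = intr$fy * yn + intr$cy)
}

# Bilinear sampling of image (H x W matrix, 0-based pixel coords).
# Out-of-bounds samples return `fill`.
bilinear_sample <- function(image, x, y, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  x0 <- floor(x); y0 <- floor(y)
  ax <- x - x0; ay <- y - y0
  out <- rep(fill, length(x))
  ok <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
  # clamp corner reads; weight of any clamped corner is handled by validity
  gv <- function(ix, iy) {
    v <- rep(fill, length(ix))
    inb <- ix >= 0 & ix <= w - 1 & iy >= 0 & iy <= h - 1
    v[inb] <- image[cbind(iy[inb] + 1, ix[inb] + 1)]
    v
  }
  if (any(ok)) {
    xs <- x0[ok]; ys <- y0[ok]; axs <- ax[ok]; ays <- ay[ok]
    v00 <- gv(xs, ys);         v10 <- gv(xs + 1, ys)
    v01 <- gv(xs, ys + 1);     v11 <- gv(xs + 1, ys + 1)
    out[ok] <- (1 - axs) * (1 - ays) * v00 + axs * (1 - ays) * v10 +
      (1 - axs) * ays * v01 + axs * ays * v11
  }
  out
}

#' Rectify (undistort) an image
#'
#' Resamples a frame so that the lens distortion described by `intr` is
#' removed and straight scene lines appear straight. Inverse mapping is
#' used: for every output pixel the forward distortion model gives the
#' source location in the input frame, which is sampled bilinearly.
#' Out-of-bounds sources are filled with 0 (dark background).
#'
#' With all distortion coefficients zero the input is returned unchanged.
#'
#' @param image Grayscale frame: numeric matrix, rows = y, columns = x.
#' @param intr A [camera_intrinsics()] object.
#' @return Rectified frame of the same size.
#' @export
rectify_image <- function(image, intr) {
  if (!is.matrix(image) || length(image) == 0) stop("image must be a non-empty matrix")
  if (!has_distortion(intr)) return(image)
  h <- nrow(image); w <- ncol(image)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  xn <- (xs - intr$cx) / intr$fx
  yn <- (ys - intr$cy) / intr$fy
  d <- distort_normalized(xn, yn, intr)
  sx <- intr$fx * d$x + intr$cx
  sy <- intr$fy * d$y + intr$cy
  vals <- bilinear_sample(image, sx, sy, fill = 0)
  matrix(vals, nrow = h, ncol = w)
}

#' Millimetre-per-pixel scale at the object plane
#'
#' Under the pinhole model a length L (m) at distance Z (m) spans
#' `f * L / Z` pixels, so the scale at the object plane is
#' `mm_per_pixel = 1000 * Z / f`.
#'
#' @param mm_per_pixel Millimetres per pixel at the object plane.
#' @param object_distance Distance camera-to-object plane in metres.
#' @return An object of class `pixel_scale`.
#' @export
pixel_scale <- function(mm_per_pixel, object_distance = NA_real_) {
  if (!is.numeric(mm_per_pixel) || mm_per_pixel <= 0)
    stop("mm_per_pixel must be positive")
  structure(list(mm_per_pixel = mm_per_pixel,
                 object_distance = object_distance),
            class = "pixel_scale")
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("Pixel scale: %.6g mm/px", x$mm_per_pixel))
  if (is.finite(x$object_distance))
    cat(sprintf(" at %.3g m object distance", x$object_distance))
  cat("\n")
  invisible(x)
}

#' Derive the pixel scale from a square of known size
#'
#' A planar square of known physical side imaged face-on gives the scale at
#' its plane directly: `mm_per_pixel = 1000 * true_side / sqrt(area_px)`.
#'
#' @param square_area_px Measured square area in px^2 (must be positive).
#' @param true_side Physical side length of the square in metres.
#' @param object_distance Optional object distance (metres), recorded for
#'   bookkeeping.
#' @return A [pixel_scale()] object.
#' @export
pixel_scale_from_square <- function(square_area_px, true_side,
                                    object_distance = NA_real_) {
  if (!is.numeric(square_area_px) || square_area_px <= 0)
    stop("square area must be positive")
  if (true_side <= 0) stop("true_side must be positive")
  pixel_scale(1000 * true_side / sqrt(square_area_px), object_distance)
}

#' Write camera intrinsics to YAML or JSON
#'
#' @param intr A [camera_intrinsics()] object.
#' @param path Output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_intrinsics <- function(intr, path) {
  fields <- list(fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
                 k1 = intr$k1, k2 = intr$k2, k3 = intr$k3,
                 p1 = intr$p1, p2 = intr$p2,
                 image_width = intr$width, image_height = intr$height)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(fields, path)
  } else {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read camera intrinsics from YAML or JSON
#'
#' @param path File written by [write_intrinsics()] (or following the same
#'   schema).
#' @return A [camera_intrinsics()] object.
#' @export
read_intrinsics <- function(path) {
  f <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(fx = f$fx, fy = f$fy, cx = f$cx, cy = f$cy,
                    k1 = f$k1, k2 = f$k2, k3 = f$k3, p1 = f$p1, p2 = f$p2,
                    width = f$image_width, height = f$image_height)
}
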