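# Planar-target camera calibration: closed-form homography initialisation
# followed by nonlinear least-squares refinement of intrinsics, distortion
# and per-view poses.

# Rodrigues rotation-vector -> matrix.
rodrigues_to_matrix <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-12) return(diag(3))
  k <- rvec / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

matrix_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

# Normalized DLT homography from planar points (Nx2) to pixels (Nx2).
estimate_homography <- function(obj, img) {
  n <- nrow(obj)
  norm_pts <- function(p) {
    mu <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, mu)^2))
    s <- sqrt(2) / mean(d)
    Tm <- matrix(c(s, 0, 0, 0, s, 0, -s * mu[1], -s * mu[2], 1), 3, 3)
    list(T = Tm, p = cbind(s * (p[, 1] - mu[1]), s * (p[, 2] - mu[2])))
  }
  no <- norm_pts(obj); ni <- norm_pts(img)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(no$p[i, ], 1)
    u <- ni$p[i, 1]; v <- ni$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(ni$T) %*% H %*% no$T
  H / H[3, 3]
}

# Zhang closed-form intrinsics from a set of plane-to-image homographies.
zhang_init <- function(Hs) {
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))
  }))
  sv <- svd(V)
  if (sv$d[5] / sv$d[1] < 1e-10)
    stop("degenerate calibration configuration: views give a rank-deficient system (near-coplanar poses?)")
  b <- sv$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  cy <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lambda <- B33 - (B13^2 + cy * (B12 * B13 - B11 * B23)) / B11
  fx2 <- lambda / B11
  fy2 <- lambda * B11 / (B11 * B22 - B12^2)
  if (fx2 <= 0 || fy2 <= 0)
    stop("degenerate calibration configuration: closed-form focal lengths are not real")
  fx <- sqrt(fx2); fy <- sqrt(fy2)
  cx <- -B13 * fx^2 / lambda
  list(fx = fx, fy = fy, cx = cx, cy = cy)
}

# Pose (R, t) of a plane from its homography and the camera matrix.
pose_from_homography <- function(H, K) {
  A <- solve(K) %*% H
  l <- 1 / sqrt(sum(A[, 1]^2))
  r1 <- A[, 1] * l
  r2 <- A[, 2] * l
  t <- A[, 3] * l
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R <- cbind(r1, r2, r3)
  # project onto SO(3)
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  if (t[3] < 0) { R[, 1:2] <- -R[, 1:2]; t <- -t }
  list(R = R, t = t)
}

#' Calibrate a camera from views of a planar target
#'
#' Estimates the pinhole intrinsics and the five Brown-Conrady distortion
#' coefficients from at least three views of a known planar grid. A
#' closed-form homography-based initialisation of `fx, fy, cx, cy` is
#' refined together with `k1, k2, k3, p1, p2` and the per-view poses by
#' Levenberg-Marquardt minimisation of the reprojection error.
#'
#' @param object_points Matrix with 2 columns: planar target coordinates in
#'   metres (target plane Z = 0), at least 8 points.
#' @param image_points List with one matrix (same row count, columns x, y in
#'   pixels) per view; at least 3 views with non-degenerate poses.
#' @param image_size Length-2 integer vector `c(width, height)` in pixels.
#' @param rms_warn Warn if the final RMS reprojection error exceeds this
#'   many pixels.
#' @return An object of class `camera_calibration`: fields `intrinsics`
#'   (a [camera_intrinsics()]), `rms` (overall RMS reprojection error, px),
#'   `per_view_rms`, `n_views`, `n_points`.
#' @export
calibrate_camera <- function(object_points, image_points, image_size,
                             rms_warn = 1) {
  if (is.null(dim(object_points)) || ncol(object_points) != 2)
    stop("object_points must be an N x 2 matrix of planar coordinates")
  if (!is.list(image_points) || length(image_points) < 3)
    stop("at least 3 views of the planar target are required")
  if (nrow(object_points) < 8)
    stop("at least 8 points per view are required")
  for (ip in image_points)
    if (nrow(ip) != nrow(object_points))
      stop("each view must detect every target point")

  Hs <- lapply(image_points, function(ip) estimate_homography(object_points, ip))
  init <- zhang_init(Hs)
  K <- matrix(c(init$fx, 0, 0, 0, init$fy, 0, init$cx, init$cy, 1), 3, 3)
  poses <- lapply(Hs, pose_from_homography, K = K)

  n_views <- length(image_points)
  n_pts <- nrow(object_points)
  obj3 <- cbind(object_points, 0)

  pack <- function(intr_par, poses) {
    c(intr_par, unlist(lapply(poses, function(p) c(matrix_to_rodrigues(p$R), p$t))))
  }
  theta0 <- pack(c(init$fx, init$fy, init$cx, init$cy, 0, 0, 0, 0, 0), poses)

  residual_fn <- function(theta) {
    intr <- camera_intrinsics(fx = theta[1], fy = theta[2],
                              cx = min(max(theta[3], 0), image_size[1] - 1),
                              cy = min(max(theta[4], 0), image_size[2] - 1),
                              k1 = theta[5], k2 = theta[6], k3 = theta[7],
                              p1 = theta[8], p2 = theta[9],
                              width = image_size[1], height = image_size[2])
    res <- numeric(0)
    for (v in seq_len(n_views)) {
      off <- 9 + (v - 1) * 6
      R <- rodrigues_to_matrix(theta[off + 1:3])
      t <- theta[off + 4:6]
      cam_pts <- t(R %*% t(obj3) + t)
      proj <- project_points(cam_pts, intr)
      res <- c(res, as.numeric(proj - image_points[[v]]))
    }
    res
  }

  fit <- minpack.lm::nls.lm(
    par = theta0, fn = residual_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  theta <- fit$par
  intr <- camera_intrinsics(fx = theta[1], fy = theta[2],
                            cx = theta[3], cy = theta[4],
                            k1 = theta[5], k2 = theta[6], k3 = theta[7],
                            p1 = theta[8], p2 = theta[9],
                            width = image_size[1], height = image_size[2])
  res <- residual_fn(theta)
  per_view <- vapply(seq_len(n_views), function(v) {
    idx <- (v - 1) * 2 * n_pts + seq_len(2 * n_pts)
    sqrt(mean(res[idx]^2))
  }, numeric(1))
  rms <- sqrt(mean(res^2))
  if (rms > rms_warn)
    warning(sprintf("calibration RMS reprojection error %.3g px exceeds %.3g px",
                    rms, rms_warn))
  structure(list(intrinsics = intr, rms = rms, per_view_rms = per_view,
                 n_views = n_views, n_points = n_pts),
            class = "camera_calibration")
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("Planar-target calibration: %d views x %d points\n",
              x$n_views, x$n_points))
  cat(sprintf("  RMS reprojection error: %.4g px\n", x$rms))
  print(x$intrinsics)
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' @param calib A `camera_calibration` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(calib, path) {
  i <- calib$intrinsics
  jsonlite::write_json(
    list(intrinsics = list(fx = i$fx, fy = i$fy, cx = i$cx, cy = i$cy,
                           k1 = i$k1, k2 = i$k2, k3 = i$k3,
                           p1 = i$p1, p2 = i$p2,
                           image_width = i$width, image_height = i$height),
         rms_px = calib$rms, per_view_rms_px = calib$per_view_rms,
         n_views = calib$n_views, n_points = calib$n_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
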