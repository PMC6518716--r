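#' Convert a frame to 8-bit grayscale
#'
#' 3-channel input is combined with the fixed luma weights
#' 0.299 / 0.587 / 0.114 and rounded half-up to 8 bits; grayscale input
#' passes through unchanged.
#'
#' @param frame Numeric matrix (grayscale) or H x W x 3 array (RGB), 8-bit
#'   values.
#' @return Numeric matrix of 8-bit gray levels.
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3) {
    h <- dim(frame)[1]; w <- dim(frame)[2]
    if (dim(frame)[3] == 1) return(matrix(frame[, , 1], h, w))
    if (dim(frame)[3] == 3) {
      g <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
      return(matrix(floor(g + 0.5), h, w))
    }
  }
  stop("unsupported image format: expected a matrix or an H x W x 1/3 array")
}

#' Otsu's threshold of an 8-bit grayscale image
#'
#' Returns the integer threshold `t` in 0..255 maximising the between-class
#' variance `w0(t) w1(t) (mu0(t) - mu1(t))^2` of the 256-bin histogram,
#' which equivalently minimises the pooled within-class variance of the
#' two pixel groups. Pixels strictly greater than `t` are foreground. Ties
#' are broken by the smallest maximising threshold.
#'
#' @param image Numeric matrix of 8-bit gray values.
#' @return Integer threshold in 0..255.
#' @export
otsu_threshold <- function(image) {
  v <- as.integer(round(image))
  if (length(unique(v)) < 2)
    stop("degenerate histogram: image has fewer than 2 distinct gray levels")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  # class 0 = pixels <= t, class 1 = pixels > t, for t = 0..254
  w0 <- cumsum(p)[1:255]
  mu_t <- cumsum(p * levels)[1:255]
  mu_total <- sum(p * levels)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_total * w0[valid] - mu_t[valid])^2 /
    (w0[valid] * w1[valid])
  which.max(sigma_b) - 1L  # smallest maximizer; which.max takes the first
}

#' Binarise a grayscale frame
#'
#' @param image Numeric matrix of gray values.
#' @param threshold Threshold level; pixels strictly greater are foreground
#'   (1), others background (0). Defaults to [otsu_threshold()].
#' @return Integer 0/1 matrix of the same size.
#' @export
binarize <- function(image, threshold = otsu_threshold(image)) {
  mask <- matrix(0L, nrow = nrow(image), ncol = ncol(image))
  mask[image > threshold] <- 1L
  mask
}

# 8-connected component labels of a 0/1 mask via the pixel adjacency graph.
label_components <- function(mask) {
  idx <- which(mask == 1L)
  if (length(idx) == 0) return(list(labels = integer(0), idx = idx))
  h <- nrow(mask); w <- ncol(mask)
  pos <- seq_along(idx)
  lut <- integer(h * w)
  lut[idx] <- pos
  row <- ((idx - 1) %% h) + 1
  col <- ((idx - 1) %/% h) + 1
  edges <- NULL
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    nr <- row + d[1]; nc <- col + d[2]
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    nidx <- (nc[ok] - 1) * h + nr[ok]
    nbr <- lut[nidx]
    hit <- nbr > 0
    if (any(hit))
      edges <- rbind(edges, cbind(pos[ok][hit], nbr[hit]))
  }
  if (is.null(edges)) {
    labels <- pos  # all isolated pixels
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    labels <- igraph::components(g)$membership[pos]
  }
  list(labels = labels, idx = idx, row = row, col = col)
}

# Moore-neighbour contour tracing of the component containing `start_rc`
# (1-based row/col of its topmost-leftmost pixel). Returns the ordered
# closed boundary as 0-based (x, y) pixel coordinates.
trace_contour <- function(in_comp, start_rc) {
  h <- nrow(in_comp); w <- ncol(in_comp)
  fg <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && in_comp[r, c]
  # neighbour directions clockwise on screen, starting at W (y down)
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dir_of <- function(from, to) {
    which(dr == to[1] - from[1] & dc == to[2] - from[2])
  }
  p <- start_rc
  scan_from <- 1L  # start pixel is topmost-leftmost: its W neighbour is background
  contour_r <- p[1]; contour_c <- p[2]
  init_state <- c(p, scan_from)
  max_steps <- 4L * sum(in_comp) + 8L
  for (step in seq_len(max_steps)) {
    found_d <- 0L
    for (k in 0:7) {
      d <- ((scan_from - 1 + k) %% 8) + 1
      if (fg(p[1] + dr[d], p[2] + dc[d])) { found_d <- d; break }
    }
    if (found_d == 0L) break  # isolated pixel
    prev_d <- ((found_d - 2) %% 8) + 1  # neighbour examined just before
    prev_px <- c(p[1] + dr[prev_d], p[2] + dc[prev_d])
    q <- c(p[1] + dr[found_d], p[2] + dc[found_d])
    next_scan <- dir_of(q, prev_px)
    if (all(c(q, next_scan) == init_state)) break
    contour_r <- c(contour_r, q[1]); contour_c <- c(contour_c, q[2])
    p <- q
    scan_from <- next_scan
  }
  cbind(x = contour_c - 1, y = contour_r - 1)
}

#' Measure the largest bright object in a binary mask
#'
#' Finds connected components with 8-connectivity, selects the largest by
#' pixel count (ties broken by the smallest top-left bounding-box corner in
#' row-major order), and returns its pixel-count area, traced boundary
#' contour, bounding box and maximum caliper width (largest point-pair
#' distance of the contour).
#'
#' @param mask Integer 0/1 matrix (1 = foreground), e.g. from [binarize()].
#' @return An object of class `object_measure`: `area_px` (integer pixel
#'   count), `contour` (matrix of 0-based x, y boundary pixel coordinates,
#'   ordered), `bbox` (xmin, xmax, ymin, ymax), `max_caliper_px`,
#'   `component` (logical matrix of the selected component).
#' @export
largest_object <- function(mask) {
  lab <- label_components(mask)
  if (length(lab$idx) == 0) stop("no object: mask has no foreground pixels")
  sizes <- tabulate(lab$labels)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: smallest top-left bbox corner, row-major (y then x)
    key <- vapply(best, function(b) {
      sel <- lab$labels == b
      min((lab$row[sel] - 1) * ncol(mask) * 0 + (lab$row[sel] - 1)) * 1e9 +
        min(lab$col[sel] - 1)
    }, numeric(1))
    best <- best[which.min(key)]
  }
  sel <- lab$labels == best
  rows <- lab$row[sel]; cols <- lab$col[sel]
  comp <- matrix(FALSE, nrow = nrow(mask), ncol = ncol(mask))
  comp[cbind(rows, cols)] <- TRUE
  # start pixel: topmost, then leftmost
  rmin <- min(rows)
  cmin <- min(cols[rows == rmin])
  contour <- trace_contour(comp, c(rmin, cmin))
  pts <- unique(contour)
  caliper <- if (nrow(pts) == 1) 0 else {
    hull <- if (nrow(pts) > 2) pts[grDevices::chull(pts), , drop = FALSE] else pts
    max(stats::dist(hull))
  }
  structure(list(area_px = as.integer(sum(sel)),
                 contour = contour,
                 bbox = c(xmin = min(cols) - 1L, xmax = max(cols) - 1L,
                          ymin = min(rows) - 1L, ymax = max(rows) - 1L),
                 max_caliper_px = caliper,
                 component = comp),
            class = "object_measure")
}

#' @export
print.object_measure <- function(x, ...) {
  cat(sprintf("Largest object: %d px^2, caliper %.2f px, bbox x [%d, %d] y [%d, %d]\n",
              x$area_px, x$max_caliper_px,
              x$bbox["xmin"], x$bbox["xmax"], x$bbox["ymin"], x$bbox["ymax"]))
  invisible(x)
}

#' Segment a frame and measure the largest object
#'
#' Convenience wrapper chaining [to_grayscale()], [otsu_threshold()],
#' [binarize()], optional small-object removal and [largest_object()].
#'
#' @param frame Grayscale matrix or RGB array.
#' @param min_object_px Remove foreground components smaller than this many
#'   pixels before selecting the largest object (0 = no cleanup, the
#'   default).
#' @return An `object_measure`.
#' @export
segment_frame <- function(frame, min_object_px = 0) {
  g <- to_grayscale(frame)
  mask <- binarize(g)
  if (min_object_px > 0) {
    lab <- label_components(mask)
    sizes <- tabulate(lab$labels)
    drop <- which(sizes < min_object_px)
    if (length(drop))
      mask[lab$idx[lab$labels %in% drop]] <- 0L
  }
  largest_object(mask)
}

#' Write a binary mask as a PNG (0/255)
#'
#' @param mask 0/1 integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
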