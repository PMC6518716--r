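# Independent oracles and small fixtures shared across the suite.

# Exhaustive Otsu oracle: scans all 256 candidate thresholds, computing the
# between-class variance directly from the raw pixel values (no histogram
# recursion shared with the implementation). Smallest maximizer wins.
otsu_brute_force <- function(image) {
  v <- as.integer(round(image))
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:255) {
    g0 <- v[v <= t]
    g1 <- v[v > t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(v)
    w1 <- length(g1) / length(v)
    s <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

# Queue-based flood fill, 8-connectivity: returns the component label matrix.
flood_fill_labels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask == 1L)) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1) %% h) + 1
      c <- ((p - 1) %/% h) + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        q <- (cc - 1) * h + rr
        if (mask[q] == 1L && labels[q] == 0L) {
          labels[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# Small fast rig used throughout the unit tests.
test_rig <- function(...) rig_geometry(image_width = 240, image_height = 135, ...)

# Uniform circular phantom with configurable noise, defaulting to quiet
# single-cycle sequences so unit tests run in well under a second each.
test_phantom_spec <- function(radius = 30, amplitude = 3, n_cycles = 1,
                              noise_sd = 0, gradient = 0, ...) {
  phantom_spec(base_radius_mm = radius, pulsation_amplitude_mm = amplitude,
               n_cycles = n_cycles, noise_sd = noise_sd,
               illumination_gradient = gradient, ...)
}

areas_of <- function(seq, intr = NULL) {
  vapply(seq$frames, function(f) {
    if (!is.null(intr)) f <- rectify_image(f, intr)
    segment_frame(f)$area_px
  }, numeric(1))
}
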