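# geometric fixtures and independent oracles, all built in code

circle_contour <- function(r = 1, n = 256, start_angle = 0, center = c(0, 0)) {
  t <- seq(start_angle, start_angle + 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + r * cos(t), y = center[2] + r * sin(t))
}

ellipse_contour <- function(a = 2, b = 1, n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = a * cos(t), y = b * sin(t))
}

# closed pixel path around a filled s x s square with lower-left corner (x0, y0)
square_pixel_path <- function(s, x0 = 0, y0 = 0) {
  k <- s - 1
  rbind(cbind(x0 + 0:k, y0),
        cbind(x0 + k, y0 + 1:k),
        cbind(x0 + (k - 1):0, y0 + k),
        cbind(x0, y0 + (k - 1):1))
}

# independent EFD oracle: trapezoid quadrature of the Fourier integrals
# (2/T) int x(t) cos(2 pi n t / T) dt over a dense arc-length resampling
efd_quadrature_oracle <- function(contour, n_harmonics, n_samples = 200000) {
  p <- rbind(contour, contour[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  tt <- c(0, cumsum(seg))
  total <- tt[length(tt)]
  s <- seq(0, total, length.out = n_samples + 1)
  x <- stats::approx(tt, p[, 1], xout = s)$y
  y <- stats::approx(tt, p[, 2], xout = s)$y
  w <- 2 * pi * s / total
  h <- total / n_samples
  trapz <- function(f) (sum(f) - (f[1] + f[length(f)]) / 2) * h
  t(vapply(seq_len(n_harmonics), function(n) {
    c(a = 2 / total * trapz(x * cos(n * w)),
      b = 2 / total * trapz(x * sin(n * w)),
      c = 2 / total * trapz(y * cos(n * w)),
      d = 2 / total * trapz(y * sin(n * w)))
  }, numeric(4)))
}

# mean distance from points to a closed polyline (min over segments)
mean_dist_to_polygon <- function(points, polygon) {
  p <- rbind(polygon, polygon[1, , drop = FALSE])
  a <- p[-nrow(p), , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  d <- vapply(seq_len(nrow(points)), function(i) {
    ap <- sweep(a, 2, points[i, ], `-`) * -1
    t <- pmin(pmax(rowSums(ap * ab) / pmax(len2, 1e-300), 0), 1)
    proj <- a + ab * t
    sqrt(min(rowSums(sweep(proj, 2, points[i, ], `-`)^2)))
  }, numeric(1))
  mean(d)
}

# RMS error in parameter space between a truncated reconstruction and the
# source contour resampled at uniform arc length (monotone in harmonics by
# construction of the Fourier series)
recon_rms_error <- function(e, contour, n_harmonics, n_points = 1024) {
  rec <- reconstruct_contour(e, n_points = n_points, n_harmonics = n_harmonics)
  p <- rbind(contour, contour[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  tt <- c(0, cumsum(seg))
  s <- seq(0, tt[length(tt)], length.out = n_points + 1)[-(n_points + 1)]
  src <- cbind(stats::approx(tt, p[, 1], xout = s)$y,
               stats::approx(tt, p[, 2], xout = s)$y)
  sqrt(mean(rowSums((rec - src)^2)))
}

# a small noiseless leaf config for geometric tests
quiet_config <- function(...) {
  synth_config(fa_noise_sd = 0, digitization_noise_sd = 0, ...)
}

# memoized mid-size labeled dataset shared by the acceptance checks:
# 40 shoots x 8 nodes under the default study conditions (delay = 1.5)
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(synth_config(n_shoots = 40, nodes_per_shoot = 8,
                                          seed = 20260901))
      res <- suppressMessages(
        run_pipeline(ds$records, config = pipeline_config(seed = 1, plots = FALSE)))
      cache <<- list(ds = ds, res = res)
    }
    cache
  }
})
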