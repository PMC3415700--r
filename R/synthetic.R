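#' Synthetic two-sided leaf datasets
#'
#' Generates labeled abaxial-top / adaxial-bottom silhouette pairs with the
#' statistical structure a resupinate-leaf asymmetry study assumes: leaf size
#' and shape mature logistically along the node series (node 1 nearest the
#' apex), every leaf carries a fixed-handedness midline bend whose magnitude
#' grows through the series, and the developmental curves of clockwise (CL)
#' shoots are delayed by `delay` nodes relative to counter-clockwise (CC)
#' shoots, so that at equal nodes CC leaves are larger, more mature in shape
#' and more asymmetric — converging late in the series.
#'
#' @section Leaf geometry:
#' The base outline is a petiole segment of length fraction \eqn{\rho(node)}
#' plus a lanceolate blade with half-width profile
#' \eqn{w(u) = W \sin(\pi u^q)} along relative blade position \eqn{u}; the
#' distal-shift exponent \eqn{q(node) \ge 1} moves laminar outgrowth toward
#' the tip as leaves mature. Directional asymmetry is a midline bend
#' \eqn{y \mapsto y + \kappa x^2 / L} (a shear, so it cannot self-intersect
#' the outline), with \eqn{\kappa} = handedness x logistic(node) plus a
#' per-leaf fluctuating term of SD `fa_noise_sd`. The adaxial-bottom outline
#' is the exact mirror of the abaxial-top outline; each emitted image then
#' receives independent digitization jitter (Gaussian, smoothed along arc
#' length with correlation length 5% of the perimeter, so outlines stay
#' simple).
#'
#' @param n_shoots Number of shoots.
#' @param nodes_per_shoot Usable nodes per shoot (<= 16).
#' @param phyllotaxy_ratio Probability that a shoot is CL (default 0.5).
#' @param blade_length Logistic size curve: list `L_min`, `L_max` (cm),
#'   `midpoint` (node), `slope`.
#' @param delay Developmental delay of CL shoots, in nodes (>= 0). `delay = 0`
#'   makes the CL and CC populations statistically identical.
#' @param petiole_fraction Logistic curve of petiole length fraction: list
#'   `min`, `max`, `midpoint`, `slope`.
#' @param distal_shift Logistic curve of the blade exponent q: list `q_min`,
#'   `q_max`, `midpoint`, `slope`.
#' @param bend Logistic bend-amplitude curve: list `kappa_max`, `midpoint`,
#'   `slope`.
#' @param bend_handedness Fixed sign of the directional bend (+1 or -1); all
#'   leaves bend the same way, the flattened analogue of an invariant
#'   resupination direction.
#' @param blade_aspect Maximum blade width as a fraction of blade length.
#' @param fa_noise_sd SD of the per-leaf fluctuating (random) asymmetry added
#'   to kappa.
#' @param digitization_noise_sd SD (cm) of per-image contour jitter.
#' @param n_profile Sample points along each side of the outline.
#' @param dpi Rasterization resolution for emitted mask images.
#' @param seed Integer seed; every draw derives deterministically from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_shoots = 12,
                         nodes_per_shoot = 8,
                         phyllotaxy_ratio = 0.5,
                         blade_length = list(L_min = 2.5, L_max = 12,
                                             midpoint = 4, slope = 0.7),
                         delay = 1.5,
                         petiole_fraction = list(min = 0.05, max = 0.25,
                                                 midpoint = 4, slope = 0.7),
                         distal_shift = list(q_min = 1, q_max = 1.8,
                                             midpoint = 4, slope = 0.7),
                         bend = list(kappa_max = 0.18, midpoint = 4.5, slope = 0.9),
                         bend_handedness = 1,
                         blade_aspect = 0.22,
                         fa_noise_sd = 0.03,
                         digitization_noise_sd = 0.02,
                         n_profile = 100,
                         dpi = 150,
                         seed = 1) {
  stopifnot(nodes_per_shoot >= 1, nodes_per_shoot <= 16,
            phyllotaxy_ratio >= 0, phyllotaxy_ratio <= 1,
            delay >= 0, bend_handedness %in% c(-1, 1), dpi > 0)
  structure(as.list(environment()), class = "synth_config")
}

logistic_curve <- function(n_eff, lo, hi, midpoint, slope) {
  lo + (hi - lo) * stats::plogis(slope * (n_eff - midpoint))
}

# developmental curve values for one leaf; CL shoots are delayed
leaf_truth_params <- function(node, phyllotaxy, config) {
  n_eff <- node - config$delay * (phyllotaxy == "CL")
  list(
    length_cm = logistic_curve(n_eff, config$blade_length$L_min,
                               config$blade_length$L_max,
                               config$blade_length$midpoint,
                               config$blade_length$slope),
    petiole_fraction = logistic_curve(n_eff, config$petiole_fraction$min,
                                      config$petiole_fraction$max,
                                      config$petiole_fraction$midpoint,
                                      config$petiole_fraction$slope),
    distal_exponent = logistic_curve(n_eff, config$distal_shift$q_min,
                                     config$distal_shift$q_max,
                                     config$distal_shift$midpoint,
                                     config$distal_shift$slope),
    kappa_directional = config$bend_handedness *
      logistic_curve(n_eff, 0, config$bend$kappa_max,
                     config$bend$midpoint, config$bend$slope)
  )
}

# half-width profile of the base outline on an x grid (cm)
leaf_half_width <- function(xs, L, rho, q, blade_aspect) {
  x_p <- rho * L
  wp <- 0.015 * L + 0.02
  W <- blade_aspect * L / 2
  h <- numeric(length(xs))
  pet <- xs < x_p
  h[pet] <- wp
  u <- (xs[!pet] - x_p) / (L - x_p)
  h[!pet] <- W * sin(pi * u^q) + wp * exp(-u / 0.08)
  h[length(h)] <- 0 # sharp tip
  h
}

# circularly smoothed Gaussian displacement field of unit SD
smoothed_noise <- function(n, corr_frac = 0.05) {
  m <- max(1, round(corr_frac * n))
  half <- min(3L * m, (n - 1L) %/% 2L)
  ker <- stats::dnorm(seq(-half, half), sd = m)
  ker <- ker / sum(ker)
  z <- as.numeric(stats::filter(stats::rnorm(n), ker, circular = TRUE))
  s <- stats::sd(z)
  if (s < .Machine$double.eps) rep(0, n) else (z - mean(z)) / s
}

add_digitization_noise <- function(contour, sd, corr_frac = 0.05) {
  if (sd <= 0) return(contour)
  n <- nrow(contour)
  contour[, 1] <- contour[, 1] + sd * smoothed_noise(n, corr_frac)
  contour[, 2] <- contour[, 2] + sd * smoothed_noise(n, corr_frac)
  contour
}

#' Generate one synthetic leaf (both faces)
#'
#' @param node Node position (1 = nearest apex).
#' @param phyllotaxy `"CL"` or `"CC"`.
#' @param config A [synth_config()].
#' @param seed Optional integer seed for this leaf's random draws; `NULL`
#'   uses the current RNG stream.
#' @return List with `ab_top` and `ad_bottom` contour matrices (cm units,
#'   proximal end at the origin, tip toward +x before normalization) and a
#'   one-row `truth` tibble of the injected parameters (`kappa` includes the
#'   fluctuating term; `area_cm2` is the analytic outline area).
#' @export
generate_leaf_outline <- function(node, phyllotaxy, config = synth_config(),
                                  seed = NULL) {
  stopifnot(node >= 1, phyllotaxy %in% c("CL", "CC"))
  if (!is.null(seed)) set.seed(seed)
  p <- leaf_truth_params(node, phyllotaxy, config)
  kappa <- p$kappa_directional + stats::rnorm(1, 0, config$fa_noise_sd)
  L <- p$length_cm
  x_p <- p$petiole_fraction * L
  n_pet <- max(3L, ceiling(config$n_profile * p$petiole_fraction))
  xs <- unique(c(seq(0, x_p, length.out = n_pet),
                 seq(x_p, L, length.out = config$n_profile)))
  h <- leaf_half_width(xs, L, p$petiole_fraction, p$distal_exponent,
                       config$blade_aspect)
  m <- length(xs)
  base <- rbind(cbind(x = xs, y = -h),
                cbind(x = rev(xs[-m]), y = rev(h[-m])))
  base[, 2] <- base[, 2] + kappa * base[, 1]^2 / L # directional bend (shear)
  area <- analytic_leaf_area(L, p$petiole_fraction, p$distal_exponent,
                             config$blade_aspect)
  ab <- as_contour(add_digitization_noise(base, config$digitization_noise_sd))
  mirrored <- base
  mirrored[, 2] <- -mirrored[, 2]
  ad <- as_contour(add_digitization_noise(mirrored, config$digitization_noise_sd))
  for (ct in list(ab, ad)) {
    if (!contour_is_simple(ct)) {
      stop("generated outline self-intersects (kappa = ", signif(kappa, 4), ")",
           call. = FALSE)
    }
  }
  truth <- tibble::tibble(node = node, phyllotaxy = phyllotaxy,
                          kappa = kappa, kappa_directional = p$kappa_directional,
                          length_cm = L, petiole_fraction = p$petiole_fraction,
                          distal_exponent = p$distal_exponent, area_cm2 = area)
  list(ab_top = ab, ad_bottom = ad, truth = truth)
}

# area under the analytic half-width profile (the bend is a shear and the
# digitization jitter is zero-mean, so this is the expected outline area)
analytic_leaf_area <- function(L, rho, q, blade_aspect) {
  xs <- seq(0, L, length.out = 2001)
  h <- leaf_half_width(xs, L, rho, q, blade_aspect)
  2 * sum((h[-1] + h[-length(h)]) / 2 * diff(xs))
}

#' Generate a full synthetic leaf dataset
#'
#' Emits `n_shoots` shoots (one phyllotactic direction per shoot, drawn
#' Bernoulli(`phyllotaxy_ratio`)), nodes `1..nodes_per_shoot`, two outlines
#' per leaf. Each leaf's random draws come from a seed derived from
#' `config$seed` and the (shoot, node) stratum only, so with `delay = 0` the
#' CL and CC populations are draw-for-draw identical. With `dir` set, masks
#' are rasterized at `config$dpi` and written as PNG files together with the
#' metadata and truth CSVs, in exactly the format [read_leaf_dataset()]
#' consumes.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory for PNG masks + `metadata.csv` +
#'   `truth.csv`.
#' @param randomize_handedness Draw each leaf's bend sign at random (+1/-1)
#'   instead of the fixed handedness — a fluctuating-asymmetry control in
#'   which mirror-pair averaging cancels the population mean asymmetry.
#' @return List with `records` (tibble: one row per leaf side, with
#'   `contour` list-column and measured `area_cm2`) and `truth` (one row per
#'   leaf). When `dir` is given, `records$file` names the emitted PNGs and
#'   areas are measured from the rasterized masks.
#' @export
generate_dataset <- function(config = synth_config(), dir = NULL,
                             randomize_handedness = FALSE) {
  set.seed(config$seed)
  phy <- ifelse(stats::runif(config$n_shoots) < config$phyllotaxy_ratio, "CL", "CC")
  shoot_ids <- sprintf("S%03d", seq_len(config$n_shoots))
  write_images <- !is.null(dir)
  if (write_images) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- list(); truths <- list(); k <- 0L
  for (i in seq_len(config$n_shoots)) {
    for (node in seq_len(config$nodes_per_shoot)) {
      leaf_seed <- (config$seed * 100003 + i * 1009 + node * 101) %%
        .Machine$integer.max
      cfg <- config
      if (randomize_handedness) {
        set.seed(leaf_seed + 7L)
        cfg$bend_handedness <- sample(c(-1, 1), 1)
      }
      leaf <- generate_leaf_outline(node, phy[i], cfg, seed = leaf_seed)
      k <- k + 1L
      truths[[k]] <- dplyr::mutate(leaf$truth, shoot_id = shoot_ids[i],
                                   .before = 1)
      rec <- tibble::tibble(
        shoot_id = shoot_ids[i], node = node, phyllotaxy = phy[i],
        side = c("ab_top", "ad_bottom"), dpi = config$dpi,
        area_cm2 = c(contour_area(leaf$ab_top), contour_area(leaf$ad_bottom)),
        contour = list(leaf$ab_top, leaf$ad_bottom))
      if (write_images) {
        rec$file <- sprintf("%s_%s_%s.png", shoot_ids[i],
                            node_to_roman(node), rec$side)
        for (j in 1:2) {
          mask <- rasterize_outline(rec$contour[[j]], config$dpi)
          rec$area_cm2[j] <- compute_area_cm2(mask)
          png::writePNG(mask * 1, file.path(dir, rec$file[j]))
        }
      }
      records[[k]] <- rec
    }
  }
  records <- dplyr::bind_rows(records)
  truth <- dplyr::bind_rows(truths)
  if (write_images) {
    readr::write_csv(dplyr::select(records, "file", "shoot_id", "node",
                                   "phyllotaxy", "side", "dpi"),
                     file.path(dir, "metadata.csv"))
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  list(records = records, truth = truth, dir = dir)
}

#' Rasterize a polygon outline to a binary mask
#'
#' Scanline conversion of a simple closed polygon in cm coordinates to a
#' logical pixel grid at the given resolution (even-odd rule, pixel centers
#' at integer coordinates, image convention: row 1 = top).
#'
#' @param contour Contour matrix in cm.
#' @param dpi Pixels per inch.
#' @param margin Background border in pixels (default 3).
#' @return Logical matrix with attribute `dpi`. Errors on self-intersecting
#'   polygons.
#' @export
rasterize_outline <- function(contour, dpi, margin = 3) {
  contour <- as_contour(contour)
  if (!contour_is_simple(contour)) {
    stop("cannot rasterize a self-intersecting polygon", call. = FALSE)
  }
  s <- dpi / 2.54
  px <- contour[, 1] * s
  py <- contour[, 2] * s
  px <- px - floor(min(px)) + margin
  py <- py - floor(min(py)) + margin
  nc <- ceiling(max(px)) + margin + 1L
  nr <- ceiling(max(py)) + margin + 1L
  x1 <- px; y1 <- py
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  grid <- matrix(FALSE, nr, nc) # row r of grid = y = r - 1
  for (r in seq_len(nr)) {
    yc <- r - 1
    cr <- (y1 <= yc) != (y2 <= yc)
    if (!any(cr)) next
    xc <- sort(x1[cr] + (yc - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr]))
    for (j in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[j]); hi <- floor(xc[j + 1])
      if (xc[j + 1] == floor(xc[j + 1])) hi <- hi - 1 # right edge exclusive
      if (hi >= lo) grid[r, (lo:hi) + 1L] <- TRUE
    }
  }
  mask <- grid[nr:1, , drop = FALSE] # to image convention (row 1 = top)
  attr(mask, "dpi") <- dpi
  mask
}
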