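test_that("circle and ellipse closed forms are recovered", {
  e <- compute_efd(circle_contour(r = 3, n = 256), n_harmonics = 8)
  expect_equal(unname(e$coef[1, ]), c(3, 0, 0, 3), tolerance = 1e-3)
  expect_lt(max(abs(e$coef[-1, ])), 1e-3 * 3)
  expect_equal(c(e$a0, e$c0), c(0, 0), tolerance = 1e-6)

  # arc-length parametrization of an ellipse: the truncated series still
  # reproduces the exact geometry even though harmonic energy spreads upward
  e2 <- compute_efd(ellipse_contour(2, 1, n = 512), n_harmonics = 20)
  rec <- reconstruct_contour(e2, 1024)
  expect_equal(max(rec[, 1]), 2, tolerance = 1e-3)
  expect_equal(max(rec[, 2]), 1, tolerance = 1e-3)
  expect_equal(unname(e2$coef[1, 2:3]), c(0, 0), tolerance = 1e-10)
  oracle <- efd_quadrature_oracle(ellipse_contour(2, 1, n = 512), 20)
  expect_lt(max(abs(e2$coef - oracle)), 1e-5)
})

test_that("polygon coefficients match independent quadrature on the unit square", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  e <- compute_efd(sq, n_harmonics = 10)
  oracle <- efd_quadrature_oracle(sq, 10)
  expect_lt(max(abs(e$coef - oracle)), 1e-6)
})

test_that("normalization fixes the first harmonic and is invariant to similarity transforms", {
  leaf <- generate_leaf_outline(6, "CC", quiet_config(), seed = 21)
  P <- leaf$ab_top
  ne <- normalize_efd(compute_efd(P, 20))
  expect_equal(unname(ne$coef[1, ]), c(1, 0, 0, unname(ne$coef[1, 4])))
  expect_lte(abs(ne$coef[1, 4]), 1)
  expect_true(ne$normalized)

  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  P2 <- t(R %*% t(P)) * 3
  P2 <- sweep(P2, 2, c(5, -2), `+`)
  P2 <- rbind(P2[101:nrow(P2), ], P2[1:100, ]) # new starting vertex
  ne2 <- normalize_efd(compute_efd(P2, 20))
  expect_lt(max(abs(ne$coef - ne2$coef)), 1e-6)
  expect_equal(unname(ne2$scale / ne$scale), 3, tolerance = 1e-6)
})

test_that("a circle normalizes to a1 = d1 = 1 under CCW traversal", {
  ne <- normalize_efd(compute_efd(circle_contour(5, 256), 6))
  expect_equal(unname(ne$coef[1, ]), c(1, 0, 0, 1), tolerance = 1e-3)
})

test_that("the proximal point controls the 180-degree orientation", {
  leaf <- generate_leaf_outline(6, "CL", quiet_config(), seed = 2)
  e <- compute_efd(leaf$ab_top, 20)
  # petiole base is at the origin in generator coordinates
  ne_prox <- normalize_efd(e, proximal_point = c(0, 0))
  ne_auto <- normalize_efd(e)
  expect_lt(max(abs(ne_prox$coef - ne_auto$coef)), 1e-9)
  # reconstructed outline has its long tail (petiole) at negative x
  rec <- reconstruct_contour(ne_prox, 256)
  expect_gt(abs(min(rec[, 1])), abs(max(rec[, 1])) - 1e-9)
})

test_that("mirroring obeys the exact coefficient sign law", {
  leaf <- generate_leaf_outline(5, "CC", quiet_config(), seed = 8)
  ne <- normalize_efd(compute_efd(leaf$ab_top, 20))
  m <- mirror_efd(ne)
  expect_identical(m$coef[, c(1, 4)], ne$coef[, c(1, 4)]) # a, d invariant
  expect_identical(m$coef[, c(2, 3)], -ne$coef[, c(2, 3)]) # b, c negated
  expect_identical(mirror_efd(m)$coef, ne$coef) # involution
  # symmetric outline is a fixed point
  ell <- normalize_efd(compute_efd(ellipse_contour(2, 1, 256), 20))
  expect_equal(mirror_efd(ell)$coef, ell$coef, tolerance = 1e-12)
})

test_that("mirror_efd matches a pixel-level vertical flip of the mask", {
  leaf <- generate_leaf_outline(5, "CC", quiet_config(), seed = 12)
  mask <- rasterize_outline(leaf$ab_top, 150)
  flipped <- mask[nrow(mask):1, , drop = FALSE]
  ne <- normalize_efd(compute_efd(extract_contour(mask), 20))
  ne_flip <- normalize_efd(compute_efd(extract_contour(flipped), 20))
  expect_lt(max(abs(mirror_efd(ne)$coef - ne_flip$coef)), 1e-4)
})

test_that("split_coefficients partitions the coefficient set with the sign law", {
  leaf <- generate_leaf_outline(4, "CC", quiet_config(), seed = 30)
  ne <- normalize_efd(compute_efd(leaf$ab_top, 20))
  s <- split_coefficients(ne)
  expect_length(s$symmetric, 40)
  expect_length(s$asymmetric, 40)
  expect_setequal(c(names(s$symmetric), names(s$asymmetric)),
                  c(t(outer(c("a", "b", "c", "d"), 1:20, paste0))))
  sm <- split_coefficients(mirror_efd(ne))
  expect_identical(sm$symmetric, s$symmetric)
  expect_identical(sm$asymmetric, -s$asymmetric)
  # symmetric outline has a null asymmetric vector
  ell <- normalize_efd(compute_efd(ellipse_contour(3, 1, 256), 20))
  expect_lt(max(abs(split_coefficients(ell)$asymmetric)), 1e-6)
  expect_error(split_coefficients(compute_efd(leaf$ab_top, 20)), "normalized")
})

test_that("mean_efd averages coefficients and cancels mirror pairs", {
  leaf <- generate_leaf_outline(5, "CC", quiet_config(), seed = 14)
  ne <- normalize_efd(compute_efd(leaf$ab_top, 20))
  expect_equal(mean_efd(list(ne, ne, ne))$coef, ne$coef, tolerance = 1e-14)
  m <- mean_efd(list(ne, mirror_efd(ne)))
  expect_true(all(m$coef[, c("b", "c")] == 0)) # exact cancellation
  expect_identical(m$coef[, c("a", "d")], ne$coef[, c("a", "d")])
  expect_error(mean_efd(list()), "empty")
})

test_that("opposite-handedness populations average to a symmetric mean outline", {
  cfg <- synth_config(n_shoots = 24, nodes_per_shoot = 4, seed = 99)
  ds <- generate_dataset(cfg, randomize_handedness = TRUE)
  ab <- ds$records[ds$records$side == "ab_top", ]
  efds <- lapply(ab$contour, function(ct) normalize_efd(compute_efd(ct, 20)))
  m <- mean_efd(efds)
  asym <- do.call(rbind, lapply(efds, function(e) split_coefficients(e)$asymmetric))
  se <- apply(asym, 2, stats::sd) / sqrt(nrow(asym))
  expect_true(all(abs(c(m$coef[, "b"], m$coef[, "c"])) <= 3 * pmax(se, 1e-12)))
})

test_that("reconstruction inverts the transform and converges with harmonics", {
  # harmonic-1-only set is an ellipse with the stated semi-axes
  coef <- matrix(0, 5, 4)
  coef[1, ] <- c(1, 0, 0, 0.5)
  e1 <- leafasym:::new_efd(coef, normalized = TRUE)
  rec <- reconstruct_contour(e1, 360)
  expect_equal(max(rec[, 1]), 1, tolerance = 1e-6)
  expect_equal(max(rec[, 2]), 0.5, tolerance = 1e-6)

  leaf <- generate_leaf_outline(6, "CC", quiet_config(), seed = 17)
  e <- compute_efd(leaf$ab_top, 20)
  errs <- vapply(1:20, function(h) recon_rms_error(e, leaf$ab_top, h), numeric(1))
  expect_true(all(diff(errs) <= 1e-9)) # monotone non-increasing
  semi_major <- normalize_efd(e)$scale
  d20 <- mean_dist_to_polygon(reconstruct_contour(e, 512), leaf$ab_top)
  expect_lt(d20 / semi_major, 0.015)
})

test_that("degenerate contours are rejected", {
  expect_error(compute_efd(rbind(c(0, 0), c(0, 0), c(0, 0))), "at least 3")
  expect_error(as_contour(rbind(c(0, 0), c(1, 0))), "at least 3")
})
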