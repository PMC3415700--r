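#' Elliptic Fourier descriptors
#'
#' A closed contour \eqn{(x(t), y(t))} is represented by truncated Fourier
#' series of its coordinates along normalized arc length \eqn{t \in [0, 2\pi)}:
#' \deqn{x(t) = a_0 + \sum_n a_n \cos(nt) + b_n \sin(nt), \quad
#'       y(t) = c_0 + \sum_n c_n \cos(nt) + d_n \sin(nt).}
#' Harmonic coefficients are computed with the Kuhl-Giardina closed form for
#' piecewise-linear contours. After normalization (first-harmonic ellipse:
#' starting phase, rotation and size removed; proximal-distal axis mapped to
#' the x-axis with the leaf tip at +x), the \eqn{a, d} coefficients carry
#' bilaterally symmetric shape variation and the \eqn{b, c} coefficients carry
#' asymmetric variation: mirroring a normalized outline about its
#' proximal-distal axis leaves \eqn{a, d} unchanged and negates \eqn{b, c}.
#' Reflection is deliberately never normalized away, so chirality — the signal
#' of interest in asymmetry studies — is preserved.
#'
#' An `efd` object is a list with elements `coef` (n_harmonics x 4 matrix,
#' columns `a`, `b`, `c`, `d`), `a0`, `c0` (centroid terms), `n_harmonics`,
#' `normalized`, and, once normalized, `scale` (semi-major axis length
#' removed), `orientation` and `phase` (radians removed).
#'
#' @name efd
NULL

new_efd <- function(coef, a0 = 0, c0 = 0, normalized = FALSE,
                    scale = NA_real_, orientation = NA_real_, phase = NA_real_) {
  colnames(coef) <- c("a", "b", "c", "d")
  structure(list(coef = coef, a0 = a0, c0 = c0,
                 n_harmonics = nrow(coef), normalized = normalized,
                 scale = scale, orientation = orientation, phase = phase),
            class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat("Elliptic Fourier descriptors: ", x$n_harmonics, " harmonics, ",
      if (x$normalized) "normalized" else "raw", "\n", sep = "")
  print(utils::head(round(x$coef, 4), 3))
  if (x$n_harmonics > 3) cat("... (", x$n_harmonics - 3, " more harmonics)\n", sep = "")
  invisible(x)
}

#' Compute elliptic Fourier descriptors of a closed contour
#'
#' Uses the closed-form Kuhl-Giardina coefficients of a piecewise-linear,
#' arc-length parametrized contour. The contour must be traversed
#' counter-clockwise; the centroid (DC) terms are stored separately in `a0`,
#' `c0` and play no part in shape analysis.
#'
#' @param contour Contour matrix (columns `x`, `y`; see [as_contour()]).
#' @param n_harmonics Number of harmonics (default 20).
#' @return An unnormalized `efd` object.
#' @export
compute_efd <- function(contour, n_harmonics = 20) {
  contour <- as_contour(contour, ccw = TRUE)
  p <- rbind(contour, contour[1, , drop = FALSE])
  dx <- diff(p[, 1]); dy <- diff(p[, 2])
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (!length(dt) || sum(dt) <= 0) {
    stop("degenerate contour: zero perimeter", call. = FALSE)
  }
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  total <- t1[length(t1)]
  n <- seq_len(n_harmonics)
  w <- 2 * pi / total
  dcos <- cos(outer(n, t1) * w) - cos(outer(n, t0) * w)
  dsin <- sin(outer(n, t1) * w) - sin(outer(n, t0) * w)
  k <- total / (2 * pi^2 * n^2)
  vx <- dx / dt; vy <- dy / dt
  coef <- cbind(a = k * as.vector(dcos %*% vx),
                b = k * as.vector(dsin %*% vx),
                c = k * as.vector(dcos %*% vy),
                d = k * as.vector(dsin %*% vy))
  x0 <- p[-nrow(p), 1][keep]; y0 <- p[-nrow(p), 2][keep]
  x1 <- p[-1, 1][keep]; y1 <- p[-1, 2][keep]
  a0 <- sum(dt * (x0 + x1) / 2) / total
  c0 <- sum(dt * (y0 + y1) / 2) / total
  new_efd(coef, a0 = a0, c0 = c0)
}

# starting-point phase shift t -> t + phi: per harmonic n the coefficient
# matrix is post-multiplied by the rotation of angle n*phi
shift_phase <- function(coef, phi) {
  n <- seq_len(nrow(coef))
  cs <- cos(n * phi); sn <- sin(n * phi)
  cbind(a = coef[, 1] * cs + coef[, 2] * sn,
        b = -coef[, 1] * sn + coef[, 2] * cs,
        c = coef[, 3] * cs + coef[, 4] * sn,
        d = -coef[, 3] * sn + coef[, 4] * cs)
}

# spatial rotation of the shape by -psi (pre-multiplication by R(-psi))
rotate_shape <- function(coef, psi) {
  cs <- cos(psi); sn <- sin(psi)
  cbind(a = cs * coef[, 1] + sn * coef[, 3],
        b = cs * coef[, 2] + sn * coef[, 4],
        c = -sn * coef[, 1] + cs * coef[, 3],
        d = -sn * coef[, 2] + cs * coef[, 4])
}

# combined 180 deg spatial rotation + half-period phase shift; leaves the
# (already diagonal) first harmonic untouched and negates even harmonics
flip_180 <- function(coef) coef * (-1)^(seq_len(nrow(coef)) + 1)

#' Normalize elliptic Fourier descriptors
#'
#' Removes starting-point phase and in-plane rotation via the first-harmonic
#' ellipse and removes size by dividing all coefficients by the semi-major
#' axis length, so that \eqn{a_1 = 1}, \eqn{b_1 = c_1 = 0} and
#' \eqn{|d_1| \le 1}. The remaining 180-degree ambiguity of the major axis is
#' resolved with the proximal point (petiole base): the proximal end of the
#' leaf maps to negative x, the tip to +x. Reflection is never applied, so
#' the chirality of the outline is preserved.
#'
#' @param e Unnormalized `efd` object.
#' @param proximal_point Optional (x, y) coordinate on or near the petiole
#'   base, in the same coordinates as the source contour. When `NULL`
#'   (default) the proximal end is auto-detected as the outline extremity
#'   farthest from the centroid along the major axis.
#' @return A normalized `efd` object recording the removed `scale`,
#'   `orientation` and `phase`.
#' @export
normalize_efd <- function(e, proximal_point = NULL) {
  stopifnot(inherits(e, "efd"))
  if (isTRUE(e$normalized)) return(e)
  M <- e$coef
  a1 <- M[1, 1]; b1 <- M[1, 2]; c1 <- M[1, 3]; d1 <- M[1, 4]
  # phase putting t = 0 on an extremum of the first-harmonic ellipse
  phi <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  M2 <- shift_phase(M, phi)
  if (sum(M2[1, c(1, 3)]^2) < sum(M2[1, c(2, 4)]^2)) { # minor axis: advance 90 deg
    phi <- phi + pi / 2
    M2 <- shift_phase(M, phi)
  }
  psi <- atan2(M2[1, 3], M2[1, 1])
  M2 <- rotate_shape(M2, psi)
  scale <- unname(M2[1, 1])
  if (!is.finite(scale) || scale <= .Machine$double.eps) {
    stop("degenerate first harmonic: semi-major axis is zero", call. = FALSE)
  }
  M2 <- M2 / scale
  flipped <- FALSE
  if (!is.null(proximal_point)) {
    q <- rotate_shape_point(proximal_point - c(e$a0, e$c0), psi) / scale
    flipped <- q[1] > 0
  } else {
    pts <- efd_curve(M2, 0, 0, 256)
    flipped <- abs(max(pts[, 1])) > abs(min(pts[, 1]))
  }
  if (flipped) {
    M2 <- flip_180(M2)
    phi <- phi + pi
    psi <- psi + pi
  }
  new_efd(M2, a0 = 0, c0 = 0, normalized = TRUE,
          scale = scale, orientation = psi, phase = phi)
}

rotate_shape_point <- function(p, psi) {
  c(cos(psi) * p[1] + sin(psi) * p[2], -sin(psi) * p[1] + cos(psi) * p[2])
}

#' Mirror an outline in coefficient space
#'
#' Reflects a normalized outline about its proximal-distal axis (the x-axis)
#' and re-orients the traversal counter-clockwise. In coefficient space this
#' is exactly \eqn{(a, b, c, d) \to (a, -b, -c, d)} per harmonic: the
#' symmetric coefficients are invariant and the asymmetric ones negate.
#' `mirror_efd(mirror_efd(e))` is the identity.
#'
#' @param e Normalized `efd` object.
#' @return The mirrored `efd`.
#' @export
mirror_efd <- function(e) {
  stopifnot(inherits(e, "efd"))
  if (!isTRUE(e$normalized)) {
    stop("mirror_efd() expects a normalized efd (the mirror axis is the ",
         "normalized proximal-distal axis)", call. = FALSE)
  }
  e$coef <- e$coef * matrix(c(1, -1, -1, 1), nrow(e$coef), 4, byrow = TRUE)
  e
}

#' Split coefficients into symmetric and asymmetric vectors
#'
#' Symmetric shape variation lives in the `a` and `d` coefficients,
#' asymmetric variation in `b` and `c`.
#'
#' @param e Normalized `efd` object.
#' @param drop_fixed Drop the elements fixed by normalization
#'   (\eqn{a_1 = 1}, \eqn{b_1 = c_1 = 0})? Default `FALSE`; the PCA layer
#'   drops them as zero-variance columns.
#' @return List with named numeric vectors `symmetric`
#'   (\eqn{a_1..a_n, d_1..d_n}) and `asymmetric` (\eqn{b_1..b_n, c_1..c_n}).
#' @export
split_coefficients <- function(e, drop_fixed = FALSE) {
  stopifnot(inherits(e, "efd"))
  if (!isTRUE(e$normalized)) {
    stop("split_coefficients() expects normalized coefficients", call. = FALSE)
  }
  n <- e$n_harmonics
  sym <- c(e$coef[, "a"], e$coef[, "d"])
  asym <- c(e$coef[, "b"], e$coef[, "c"])
  names(sym) <- c(paste0("a", seq_len(n)), paste0("d", seq_len(n)))
  names(asym) <- c(paste0("b", seq_len(n)), paste0("c", seq_len(n)))
  if (drop_fixed) {
    sym <- sym[-1]                    # a1 == 1
    asym <- asym[-c(1, n + 1)]        # b1 == c1 == 0
  }
  list(symmetric = sym, asymmetric = asym)
}

#' Average elliptic Fourier descriptors
#'
#' Element-wise arithmetic mean of coefficient matrices. Averaging an outline
#' with its mirror image cancels the asymmetric (`b`, `c`) coefficients
#' exactly, which is the basis of the mirror-pair test for intrinsic
#' asymmetry: fluctuating asymmetry averages out, directional asymmetry does
#' not.
#'
#' @param es List of normalized `efd` objects with equal harmonic counts.
#' @return The mean `efd`.
#' @export
mean_efd <- function(es) {
  if (!length(es)) stop("cannot average an empty collection of EFDs", call. = FALSE)
  stopifnot(all(vapply(es, inherits, logical(1), "efd")))
  nh <- unique(vapply(es, function(e) e$n_harmonics, integer(1)))
  if (length(nh) != 1) stop("harmonic counts differ across EFDs", call. = FALSE)
  if (!all(vapply(es, function(e) isTRUE(e$normalized), logical(1)))) {
    stop("mean_efd() expects normalized EFDs", call. = FALSE)
  }
  coef <- Reduce(`+`, lapply(es, `[[`, "coef")) / length(es)
  new_efd(coef, normalized = TRUE)
}

# evaluate the truncated series on a uniform parameter grid
efd_curve <- function(coef, a0, c0, n_points) {
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  n <- seq_len(nrow(coef))
  C <- cos(outer(t, n)); S <- sin(outer(t, n))
  cbind(x = a0 + as.vector(C %*% coef[, 1] + S %*% coef[, 2]),
        y = c0 + as.vector(C %*% coef[, 3] + S %*% coef[, 4]))
}

#' Reconstruct a contour from elliptic Fourier descriptors
#'
#' Inverse Fourier transformation: sums the harmonic series on a uniform
#' parameter grid over \eqn{[0, 2\pi)}.
#'
#' @param e `efd` object (raw or normalized).
#' @param n_points Number of points to sample (default 512).
#' @param n_harmonics Optionally truncate to the first `n_harmonics`
#'   harmonics.
#' @return Contour matrix with `n_points` rows.
#' @export
reconstruct_contour <- function(e, n_points = 512, n_harmonics = NULL) {
  stopifnot(inherits(e, "efd"), n_points >= 3)
  coef <- e$coef
  if (!is.null(n_harmonics)) {
    stopifnot(n_harmonics >= 1, n_harmonics <= nrow(coef))
    coef <- coef[seq_len(n_harmonics), , drop = FALSE]
  }
  efd_curve(coef, e$a0, e$c0, n_points)
}

#' Add normalized EFDs to a leaf dataset
#'
#' Maps [compute_efd()] + [normalize_efd()] over the `contour` list-column of
#' a leaf tibble (see [read_leaf_dataset()] or [generate_dataset()]).
#'
#' @param tbl Tibble with a `contour` list-column.
#' @param n_harmonics Harmonics to keep (default 20).
#' @param proximal_points Optional list of per-row proximal points passed to
#'   [normalize_efd()]; `NULL` auto-detects.
#' @return `tbl` with an added `efd` list-column.
#' @export
add_efd <- function(tbl, n_harmonics = 20, proximal_points = NULL) {
  stopifnot("contour" %in% names(tbl))
  efds <- purrr::map2(tbl$contour,
                      proximal_points %||% vector("list", nrow(tbl)),
                      function(ct, pp) {
                        normalize_efd(compute_efd(ct, n_harmonics), proximal_point = pp)
                      })
  dplyr::mutate(tbl, efd = efds)
}

#' Extract a coefficient matrix from EFDs
#'
#' Rows are outlines, columns are named coefficients of the requested
#' subspace. Elements fixed by normalization (`a1`, `b1`, `c1`) are dropped
#' by default since they are constant across outlines.
#'
#' @param efds List of normalized `efd` objects, or a tibble with an `efd`
#'   list-column.
#' @param subspace `"asymmetric"` (`b`, `c` coefficients), `"symmetric"`
#'   (`a`, `d`) or `"all"`.
#' @param drop_fixed Drop `a1`, `b1`, `c1`? Default `TRUE`.
#' @return Numeric matrix with named columns.
#' @export
coef_matrix <- function(efds, subspace = c("asymmetric", "symmetric", "all"),
                        drop_fixed = TRUE) {
  subspace <- match.arg(subspace)
  if (is.data.frame(efds)) efds <- efds$efd
  rows <- lapply(efds, function(e) {
    s <- split_coefficients(e, drop_fixed = drop_fixed)
    switch(subspace,
           asymmetric = s$asymmetric,
           symmetric = s$symmetric,
           all = c(s$symmetric, s$asymmetric))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
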