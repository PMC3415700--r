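#' Principal component analysis of shape coefficients
#'
#' Covariance PCA (no column scaling: normalized Fourier coefficients are
#' already commensurate after size removal) of either the asymmetric
#' (\eqn{b, c}) or symmetric (\eqn{a, d}) coefficient subspace. Eigenvector
#' signs are fixed deterministically: the largest-magnitude element of each
#' loading is made positive, so score signs are reproducible across runs and
#' platforms.
#'
#' For the asymmetric analysis both leaf faces (abaxial-top and
#' adaxial-bottom) are pooled, so every leaf contributes a mirror pair and
#' purely directional asymmetry appears as paired scores of opposite sign.
#' The symmetric analysis conventionally uses abaxial-top outlines only.
#'
#' @param x A tibble with an `efd` list-column (see [add_efd()]), a list of
#'   normalized `efd` objects, or a numeric coefficient matrix
#'   (observations x coefficients).
#' @param subspace `"asymmetric"` or `"symmetric"`.
#' @param n_components Number of leading components to report on (default 4).
#' @return A `shape_pca` object: list with `subspace`, `mean` (subspace mean
#'   vector), `loadings` (orthonormal columns, all components), `eigenvalues`,
#'   `percent_variance` (sums to 100), `n_components`, `n_obs`, and
#'   `full_mean` (mean harmonic coefficient matrix, used to re-embed
#'   reconstructions; `NULL` when fitted from a bare matrix).
#' @export
fit_shape_pca <- function(x, subspace = c("asymmetric", "symmetric"),
                          n_components = 4) {
  subspace <- match.arg(subspace)
  full_mean <- NULL
  if (is.matrix(x) && is.numeric(x)) {
    mat <- x
  } else {
    efds <- if (is.data.frame(x)) x$efd else x
    mat <- coef_matrix(efds, subspace = subspace)
    full_mean <- Reduce(`+`, lapply(efds, `[[`, "coef")) / length(efds)
  }
  if (nrow(mat) < 2) stop("PCA needs at least 2 observations", call. = FALSE)
  if (all(apply(mat, 2, stats::var) < .Machine$double.eps)) {
    stop("zero variance: all observations are identical", call. = FALSE)
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  # deterministic sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) pc$rotation[, j] <- -pc$rotation[, j]
  }
  eig <- pc$sdev^2
  structure(list(subspace = subspace,
                 mean = pc$center,
                 loadings = pc$rotation,
                 eigenvalues = eig,
                 percent_variance = 100 * eig / sum(eig),
                 n_components = min(n_components, length(eig)),
                 n_obs = nrow(mat),
                 full_mean = full_mean),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- x$n_components
  cat("Shape PCA (", x$subspace, " subspace): ", x$n_obs, " outlines, ",
      length(x$mean), " coefficients\n", sep = "")
  cat("  PC1-", k, " percent variance: ",
      paste(sprintf("%.1f", x$percent_variance[seq_len(k)]), collapse = ", "),
      " (cumulative ", sprintf("%.1f", sum(x$percent_variance[seq_len(k)])), "%)\n",
      sep = "")
  invisible(x)
}

#' Score outlines on a fitted shape PCA
#'
#' Projects centered coefficient vectors onto the model loadings.
#'
#' @param object A `shape_pca` model.
#' @param newdata A tibble with an `efd` list-column, a list of normalized
#'   `efd` objects, a single `efd`, or a coefficient matrix matching the
#'   model's subspace.
#' @param n_components Number of score columns (default: the model's).
#' @param ... Unused.
#' @return Tibble of scores with columns `PC1..PCk`.
#' @export
predict.shape_pca <- function(object, newdata, n_components = object$n_components, ...) {
  if (inherits(newdata, "efd")) newdata <- list(newdata)
  mat <- if (is.matrix(newdata) && is.numeric(newdata)) newdata else
    coef_matrix(if (is.data.frame(newdata)) newdata$efd else newdata,
                subspace = object$subspace)
  if (ncol(mat) != length(object$mean)) {
    stop("coefficient count (", ncol(mat), ") does not match the model (",
         length(object$mean), "); harmonic-count mismatch?", call. = FALSE)
  }
  sc <- sweep(mat, 2, object$mean) %*% object$loadings[, seq_len(n_components), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(n_components))
  tibble::as_tibble(sc)
}

#' @rdname predict.shape_pca
#' @param model A `shape_pca` model.
#' @param e What to score (see `newdata` above).
#' @export
score_pca <- function(model, e, n_components = model$n_components) {
  predict(model, e, n_components = n_components)
}

#' Reconstruct the outline at k standard deviations along a PC
#'
#' Builds the coefficient vector `mean + k * sqrt(eigenvalue) * loading`,
#' re-embeds it into a full coefficient set (the other subspace held at its
#' mean, normalization constants restored), and inverse-transforms it to a
#' contour. `k = 0` returns the mean shape.
#'
#' @param model `shape_pca` fitted from EFDs (not a bare matrix).
#' @param pc Component index.
#' @param k Standard-deviation multiplier, typically -2 or +2.
#' @param n_points Points in the reconstructed contour (default 512).
#' @return Contour matrix.
#' @export
reconstruct_at_sd <- function(model, pc, k, n_points = 512) {
  stopifnot(inherits(model, "shape_pca"))
  if (is.null(model$full_mean)) {
    stop("model was fitted from a bare matrix; refit from EFDs to reconstruct shapes",
         call. = FALSE)
  }
  if (pc < 1 || pc > ncol(model$loadings)) {
    stop("`pc` must be between 1 and ", ncol(model$loadings), call. = FALSE)
  }
  vec <- model$mean + k * sqrt(model$eigenvalues[pc]) * model$loadings[, pc]
  coef <- model$full_mean
  nh <- nrow(coef)
  if (model$subspace == "asymmetric") {
    # vec = (b2..b_nh, c2..c_nh); b1 = c1 = 0 by normalization
    coef[, "b"] <- c(0, vec[seq_len(nh - 1)])
    coef[, "c"] <- c(0, vec[nh - 1 + seq_len(nh - 1)])
  } else {
    # vec = (a2..a_nh, d1..d_nh); a1 = 1 by normalization
    coef[, "a"] <- c(1, vec[seq_len(nh - 1)])
    coef[, "d"] <- vec[nh - 1 + seq_len(nh)]
  }
  e <- new_efd(coef, normalized = TRUE)
  reconstruct_contour(e, n_points = n_points)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a shape PCA
#'
#' @param x `shape_pca` object.
#' @param ... Unused.
#' @return One row per component: `component`, `eigenvalue`,
#'   `percent_variance`, `cumulative_percent`.
#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 percent_variance = x$percent_variance,
                 cumulative_percent = cumsum(x$percent_variance))
}

#' @rdname tidy.shape_pca
#' @method glance shape_pca
#' @export
glance.shape_pca <- function(x, ...) {
  k <- x$n_components
  tibble::tibble(subspace = x$subspace,
                 n_obs = x$n_obs,
                 n_coefficients = length(x$mean),
                 pc1_percent = x$percent_variance[1],
                 cumulative_percent = sum(x$percent_variance[seq_len(k)]),
                 n_components = k)
}

#' Scree plot of a shape PCA
#'
#' @param object `shape_pca` object.
#' @param n_components Components to show (default 8).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, n_components = 8, ...) {
  d <- utils::head(tidy(object), n_components)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$component), y = .data$percent_variance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Principal component", y = "Percent variance",
                  title = paste0(object$subspace, " shape variance")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Gallery of mean +/- k SD outline reconstructions
#'
#' Reconstructs the outline at `-k`, `0` and `+k` standard deviations along
#' each of the leading components, the standard visualization of what each
#' PC encodes.
#'
#' @param model `shape_pca` fitted from EFDs.
#' @param pcs Components to show (default `1:model$n_components`).
#' @param k Standard-deviation multiplier (default 2).
#' @param n_points Contour sampling (default 256).
#' @return A ggplot, faceted by component.
#' @export
plot_pc_shapes <- function(model, pcs = seq_len(model$n_components), k = 2,
                           n_points = 256) {
  d <- purrr::map_dfr(pcs, function(pc) {
    purrr::map_dfr(c(-k, 0, k), function(kk) {
      ct <- reconstruct_at_sd(model, pc, kk, n_points = n_points)
      tibble::tibble(pc = paste0("PC", pc), sd = sprintf("%+g SD", kk),
                     x = c(ct[, 1], ct[1, 1]), y = c(ct[, 2], ct[1, 2]))
    })
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$sd)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~pc) +
    ggplot2::labs(title = paste0(model$subspace, " PCs: mean and ±", k, " SD"),
                  colour = NULL) +
    ggplot2::theme_void()
}
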