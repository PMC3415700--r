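#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis, serializable to YAML
#' and round-trippable through [read_pipeline_config()].
#'
#' @param n_harmonics Harmonics kept in the Fourier expansion (default 20).
#' @param n_components Principal components retained per subspace (default 4).
#' @param alpha ANOVA term-retention threshold (default 0.05).
#' @param loess_span,loess_degree Loess trend parameters (defaults 0.75, 2).
#' @param seed Integer seed for any randomness (default 1).
#' @param plots Write figure files? Default `TRUE`.
#' @param foreground Mask polarity for [load_mask()] (default `"nonzero"`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_harmonics = 20, n_components = 4, alpha = 0.05,
                            loess_span = 0.75, loess_degree = 2, seed = 1,
                            plots = TRUE, foreground = "nonzero") {
  structure(list(n_harmonics = n_harmonics, n_components = n_components,
                 alpha = alpha, loess_span = loess_span,
                 loess_degree = loess_degree, seed = seed, plots = plots,
                 foreground = foreground),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' Run the full leaf-asymmetry analysis
#'
#' Orchestrates every stage on a loaded (or synthetic) dataset: normalized
#' EFDs, asymmetric PCA (both faces pooled) and symmetric PCA (abaxial-top
#' only), PC scoring, the long-format analysis table, backward-selected
#' factorial ANOVAs for every response with forward verification, the
#' chi-square test of shoot phyllotaxy frequency, loess trends of each score
#' along the node series, and (optionally) figures. All tabular artifacts are
#' written as CSV under `out_dir`; the selection traces go to a plain-text
#' log.
#'
#' @param records Leaf tibble from [read_leaf_dataset()] or
#'   `generate_dataset()$records`.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param config A [pipeline_config()].
#' @return A `leaf_pipeline` list: `records` (with `efd` column), `pca_asym`,
#'   `pca_sym`, `scores`, `analysis_table`, `anova_fits` (named list),
#'   `forward_ok` (named logical), `chi_square`, `trends`, `tables`
#'   (formatted ANOVA tables), `config`.
#' @export
run_pipeline <- function(records, out_dir = NULL, config = pipeline_config()) {
  set.seed(config$seed)
  stage <- function(name) message("[leafasym] ", name)
  wrap <- function(name, expr) {
    stage(name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  records <- wrap("elliptic Fourier descriptors",
                  add_efd(records, n_harmonics = config$n_harmonics))
  pca_asym <- wrap("asymmetric PCA",
                   fit_shape_pca(records, "asymmetric",
                                 n_components = config$n_components))
  ab <- records[records$side == "ab_top", ]
  pca_sym <- wrap("symmetric PCA",
                  fit_shape_pca(ab, "symmetric", n_components = config$n_components))
  scores <- wrap("scoring", {
    asym <- score_pca(pca_asym, records)
    names(asym) <- paste0("asym", names(asym))
    sym <- score_pca(pca_sym, ab)
    names(sym) <- paste0("sym", names(sym))
    dplyr::bind_cols(records[c("shoot_id", "node", "side")], asym) |>
      dplyr::left_join(dplyr::bind_cols(ab[c("shoot_id", "node", "side")], sym),
                       by = c("shoot_id", "node", "side"))
  })
  tbl <- wrap("analysis table", build_analysis_table(records, scores))
  responses <- c(paste0("asymPC", seq_len(config$n_components)),
                 paste0("symPC", seq_len(config$n_components)), "area_cm2")
  fits <- wrap("factorial ANOVA with backward selection",
               lapply(stats::setNames(responses, responses), function(r) {
                 fit_anova(tbl, r, alpha = config$alpha)
               }))
  fwd <- wrap("forward verification",
              vapply(fits, function(f) as.logical(forward_check(f, tbl)), logical(1)))
  chi <- wrap("phyllotaxy direction chi-square", {
    shoots <- dplyr::distinct(records, .data$shoot_id, .data$phyllotaxy)
    chi_square_direction(sum(shoots$phyllotaxy == "CL"),
                         sum(shoots$phyllotaxy == "CC"))
  })
  trends <- wrap("loess trends", {
    ab_tbl <- tbl[tbl$side == "ab_top", ]
    lapply(stats::setNames(responses, responses), function(r) {
      ok <- !is.na(ab_tbl[[r]])
      loess_trend(ab_tbl$node[ok], ab_tbl[[r]][ok],
                  span = config$loess_span, degree = config$loess_degree)
    })
  })
  tables <- export_anova_tables(fits)
  out <- structure(list(records = records, pca_asym = pca_asym, pca_sym = pca_sym,
                        scores = scores, analysis_table = tbl, anova_fits = fits,
                        forward_ok = fwd, chi_square = chi, trends = trends,
                        tables = tables, config = config),
                   class = "leaf_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coefs <- coef_matrix(out$records$efd, "all", drop_fixed = FALSE)
  readr::write_csv(dplyr::bind_cols(out$records[c("shoot_id", "node", "side")],
                                    tibble::as_tibble(coefs)),
                   file.path(out_dir, "coefficients.csv"))
  readr::write_csv(out$scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(dplyr::select(out$analysis_table, -dplyr::any_of("contour")),
                   file.path(out_dir, "analysis_table.csv"))
  readr::write_csv(out$tables$asymmetric, file.path(out_dir, "anova_asymmetric.csv"))
  readr::write_csv(out$tables$symmetric, file.path(out_dir, "anova_symmetric.csv"))
  readr::write_csv(out$chi_square, file.path(out_dir, "chi_square.csv"))
  readr::write_csv(purrr::imap_dfr(out$trends, function(tr, nm) {
    dplyr::mutate(tibble::as_tibble(tr), response = nm, .before = 1)
  }), file.path(out_dir, "trend_curves.csv"))
  trace_lines <- unlist(purrr::imap(out$anova_fits, function(f, nm) {
    c(paste0("== ", nm, " =="),
      sprintf("  step %d: %s %s (p = %.4g)", f$selection_trace$step,
              f$selection_trace$action, f$selection_trace$term,
              f$selection_trace$p.value),
      paste0("  forward check: ",
             ifelse(out$forward_ok[[nm]], "consistent", "INCONSISTENT")))
  }))
  writeLines(trace_lines, file.path(out_dir, "selection_trace.log"))
  if (isTRUE(out$config$plots)) {
    ggplot2::ggsave(file.path(out_dir, "scree_asymmetric.pdf"),
                    autoplot(out$pca_asym), width = 5, height = 4)
    ggplot2::ggsave(file.path(out_dir, "scree_symmetric.pdf"),
                    autoplot(out$pca_sym), width = 5, height = 4)
    ggplot2::ggsave(file.path(out_dir, "pc_shapes_asymmetric.pdf"),
                    plot_pc_shapes(out$pca_asym), width = 7, height = 6)
    ggplot2::ggsave(file.path(out_dir, "mean_outlines.pdf"),
                    superimpose_mean_outlines(split(out$records$efd,
                                                    out$records$side)),
                    width = 7, height = 4)
  }
  invisible(out_dir)
}

#' @export
print.leaf_pipeline <- function(x, ...) {
  cat("leafasym pipeline result: ", nrow(x$records), " outlines, ",
      length(unique(x$records$shoot_id)), " shoots\n", sep = "")
  cat("  asymmetric PC1 ", sprintf("%.1f", x$pca_asym$percent_variance[1]),
      "% | symmetric PC1 ", sprintf("%.1f", x$pca_sym$percent_variance[1]),
      "% of variance\n", sep = "")
  invisible(x)
}

#' Superimpose group-mean outlines
#'
#' Averages the EFDs within each group, reconstructs the mean outlines and
#' overplots them in both layer orders (the two stacking orders make
#' whichever outline is on top visible where the groups differ — mirror
#' pairs of a directionally asymmetric population do not coincide).
#'
#' @param groups Named list of lists of normalized `efd` objects (e.g.
#'   `split(records$efd, records$side)`).
#' @param n_points Reconstruction sampling (default 512).
#' @return A ggplot faceted by layer order.
#' @export
superimpose_mean_outlines <- function(groups, n_points = 512) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  if (any(!lengths(groups))) stop("empty group in `groups`", call. = FALSE)
  means <- lapply(groups, function(g) mean_efd(g))
  d <- purrr::imap_dfr(means, function(e, nm) {
    ct <- reconstruct_contour(e, n_points = n_points)
    tibble::tibble(group = nm, x = c(ct[, 1], ct[1, 1]), y = c(ct[, 2], ct[1, 2]))
  })
  ord <- names(groups)
  d2 <- dplyr::bind_rows(
    dplyr::mutate(d, panel = paste(ord, collapse = " over "),
                  group = factor(.data$group, levels = rev(ord))),
    dplyr::mutate(d, panel = paste(rev(ord), collapse = " over "),
                  group = factor(.data$group, levels = ord)))
  ggplot2::ggplot(d2, ggplot2::aes(.data$x, .data$y, colour = .data$group,
                                   group = .data$group)) +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(colour = NULL, x = NULL, y = NULL,
                  title = "Superimposed mean outlines") +
    ggplot2::theme_void()
}

#' Format ANOVA fits as publication-style tables
#'
#' One row per factor of the full factorial, one column per response;
#' non-retained terms are rendered `"ns"`, retained terms show the final
#' model p-value. Responses are split into the asymmetric table (with the
#' leaf-face factor) and the symmetric + area table.
#'
#' @param fits Named list of `anova_fit` objects.
#' @return List of two tibbles, `asymmetric` and `symmetric`.
#' @export
export_anova_tables <- function(fits) {
  fmt <- function(fit, terms) {
    vapply(terms, function(tm) {
      i <- match(tm, fit$term_stats$term)
      if (is.na(i) || !(tm %in% fit$retained_terms)) return("ns")
      p <- fit$term_stats$p.value[i]
      # terms kept only to support a retained interaction are reported "ns"
      if (is.na(p) || p > fit$alpha) "ns" else sprintf("%.2g", p)
    }, character(1))
  }
  one_table <- function(sub_fits) {
    if (!length(sub_fits)) return(tibble::tibble())
    terms <- attr(stats::terms(stats::as.formula(paste(
      "~", paste(sub_fits[[1]]$factors, collapse = " * ")))), "term.labels")
    cols <- lapply(sub_fits, fmt, terms = terms)
    dplyr::bind_cols(tibble::tibble(Factor = pretty_term(terms)),
                     tibble::as_tibble(cols))
  }
  is_asym <- vapply(fits, function(f) "side" %in% f$factors, logical(1))
  list(asymmetric = one_table(fits[is_asym]),
       symmetric = one_table(fits[!is_asym]))
}

pretty_term <- function(terms) {
  out <- gsub("side", "AdAb", terms, fixed = TRUE)
  sub("^position", "Position", sub("^phyllotaxy", "Phyllotaxy", out))
}
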