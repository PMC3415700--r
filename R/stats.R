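#' Chi-square test of phyllotactic-direction frequency
#'
#' Pearson goodness-of-fit of observed clockwise / counter-clockwise shoot
#' counts against an expected 50:50 split, with 1 degree of freedom and a
#' two-tailed p-value from the chi-square survival function. No continuity
#' correction is applied.
#'
#' @param n_cl,n_cc Nonnegative integer counts of clockwise and
#'   counter-clockwise shoots (not both zero).
#' @return Tibble with `statistic` (chi-square), `df`, `p.value`, and the
#'   input counts.
#' @examples
#' chi_square_direction(100, 109)
#' @export
chi_square_direction <- function(n_cl, n_cc) {
  if (any(c(n_cl, n_cc) < 0) || any(c(n_cl, n_cc) != round(c(n_cl, n_cc)))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  n <- n_cl + n_cc
  if (n == 0) stop("both counts are zero", call. = FALSE)
  expected <- n / 2
  chi2 <- sum((c(n_cl, n_cc) - expected)^2 / expected)
  tibble::tibble(statistic = chi2, df = 1L,
                 p.value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 n_cl = n_cl, n_cc = n_cc)
}

#' Assemble the long-format analysis table
#'
#' Joins leaf records with per-outline PC scores into the table the factorial
#' models are fitted on: one row per scanned leaf side, with node position as
#' an ordered factor, phyllotactic direction, leaf face (`side`, the "AdAb"
#' factor), area, asymmetric PC scores for every row and symmetric PC scores
#' attached to abaxial-top rows only.
#'
#' @param records Tibble of leaf records (`shoot_id`, `node`, `phyllotaxy`,
#'   `side`, `area_cm2`, ...).
#' @param scores Tibble keyed by `shoot_id`, `node`, `side` with score
#'   columns `asymPC1..k` (and optionally `symPC1..k`, which may be `NA` on
#'   `ad_bottom` rows).
#' @return Tibble with one row per (leaf, side). Nodes lacking an
#'   `ad_bottom` scan contribute a single row and a warning.
#' @export
build_analysis_table <- function(records, scores) {
  key <- c("shoot_id", "node", "side")
  if (anyDuplicated(records[key])) stop("duplicate keys in `records`", call. = FALSE)
  if (anyDuplicated(scores[key])) stop("duplicate keys in `scores`", call. = FALSE)
  orphans <- dplyr::anti_join(scores, records, by = key)
  if (nrow(orphans) > 0) {
    stop(nrow(orphans), " score row(s) have no matching leaf record", call. = FALSE)
  }
  tbl <- dplyr::inner_join(
    dplyr::select(records, dplyr::all_of(c(key, "phyllotaxy", "area_cm2"))),
    scores, by = key)
  missing_pairs <- tbl |>
    dplyr::count(.data$shoot_id, .data$node) |>
    dplyr::filter(.data$n < 2)
  if (nrow(missing_pairs) > 0) {
    warning(nrow(missing_pairs), " leaf/leaves lack an ad_bottom scan; ",
            "they contribute one row each", call. = FALSE)
  }
  tbl |>
    dplyr::mutate(position = factor(.data$node, levels = sort(unique(.data$node)),
                                    ordered = TRUE),
                  phyllotaxy = factor(.data$phyllotaxy, levels = c("CL", "CC")),
                  side = factor(.data$side, levels = c("ab_top", "ad_bottom"))) |>
    dplyr::relocate("position", .after = "node")
}

#' Factorial ANOVA with backward single-term model selection
#'
#' Starts from the full factorial model and repeatedly removes the least
#' significant droppable term — the term with the largest nested-model F-test
#' p-value above `alpha`, among terms whose removal respects marginality (no
#' interaction is orphaned). Ties are broken by dropping the higher-order
#' term first, then lexicographically. Per-term statistics of the final model
#' are marginal (type-II) F-tests, so terms kept only to support a retained
#' interaction still receive an honest p-value.
#'
#' @param table Long-format analysis table (see [build_analysis_table()]).
#' @param response Response column name (e.g. `"asymPC1"`, `"symPC1"`,
#'   `"area_cm2"`).
#' @param factors Character vector of factor columns forming the full
#'   factorial. Default: `position * phyllotaxy * side` for asymmetric PC
#'   responses, `position * phyllotaxy` otherwise (the leaf face is
#'   irrelevant to symmetric shape and area).
#' @param alpha Retention threshold for the nested F-tests (default 0.05).
#' @return An `anova_fit` object: list with `response`, `factors`,
#'   `retained_terms`, `term_stats` (tibble: term, df, sumsq, statistic,
#'   p.value), `selection_trace` (tibble: step, term, p.value, action),
#'   `model` (the final `lm`), `alpha`.
#' @export
fit_anova <- function(table, response, factors = NULL, alpha = 0.05) {
  if (is.null(factors)) {
    factors <- if (grepl("^asym", response)) c("position", "phyllotaxy", "side")
               else c("position", "phyllotaxy")
  }
  stopifnot(response %in% names(table), all(factors %in% names(table)))
  dat <- table[stats::complete.cases(table[c(response, factors)]), , drop = FALSE]
  dat <- droplevels(dat)
  if (!is.numeric(dat[[response]])) stop("response must be numeric", call. = FALSE)
  for (f in factors) {
    if (length(unique(dat[[f]])) < 2) {
      stop("factor `", f, "` has fewer than 2 levels", call. = FALSE)
    }
  }
  full <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  fit <- stats::lm(full, data = dat)
  if (anyNA(stats::coef(fit))) {
    lbl <- attr(stats::terms(fit), "term.labels")
    bad <- unique(lbl[fit$assign[is.na(stats::coef(fit))]])
    stop("rank-deficient design: term(s) ", paste(bad, collapse = ", "),
         " cannot be estimated (empty cells)", call. = FALSE)
  }
  trace <- list()
  step <- 0L
  repeat {
    if (!length(attr(stats::terms(fit), "term.labels"))) break
    d1 <- stats::drop1(fit, test = "F")
    cand <- rownames(d1)[-1]
    pvals <- d1[["Pr(>F)"]][-1]
    # degenerate nested comparisons on (near-)perfect fits: a term whose
    # removal changes the RSS only at rounding-error scale is droppable,
    # whatever the F ratio of the two vanishing quantities says
    ss <- d1[["Sum of Sq"]][-1]
    tss <- sum((dat[[response]] - mean(dat[[response]]))^2)
    pvals[is.na(pvals) | ss < 1e-8 * tss] <- 1
    drop_ok <- which(pvals > alpha)
    if (!length(drop_ok)) break
    ord <- order(-pvals[drop_ok],
                 -vapply(strsplit(cand[drop_ok], ":", fixed = TRUE), length, integer(1)),
                 cand[drop_ok])
    pick <- drop_ok[ord[1]]
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, term = cand[pick],
                                    p.value = pvals[pick], action = "drop")
    fit <- stats::update(fit, stats::as.formula(paste(". ~ . -", cand[pick])))
  }
  retained <- attr(stats::terms(fit), "term.labels")
  term_stats <- final_term_stats(fit)
  if (nrow(term_stats)) {
    trace <- c(trace, list(tibble::tibble(step = step + seq_len(nrow(term_stats)),
                                          term = term_stats$term,
                                          p.value = term_stats$p.value,
                                          action = "retain")))
  }
  structure(list(response = response, factors = factors,
                 retained_terms = retained,
                 term_stats = term_stats,
                 selection_trace = dplyr::bind_rows(trace),
                 model = fit, alpha = alpha, n_obs = nrow(dat)),
            class = "anova_fit")
}

# marginal (type II) per-term F tests of the final model
final_term_stats <- function(fit) {
  lbl <- attr(stats::terms(fit), "term.labels")
  if (!length(lbl)) {
    return(tibble::tibble(term = character(), df = numeric(), sumsq = numeric(),
                          statistic = numeric(), p.value = numeric()))
  }
  a <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (is.null(a)) {
    # zero residual sum of squares (perfect fit): the nested F test diverges
    return(tibble::tibble(term = lbl, df = NA_real_, sumsq = NA_real_,
                          statistic = Inf, p.value = 0))
  }
  keep <- rownames(a) != "Residuals"
  tibble::tibble(term = rownames(a)[keep],
                 df = a$Df[keep],
                 sumsq = a[["Sum Sq"]][keep],
                 statistic = a[["F value"]][keep],
                 p.value = a[["Pr(>F)"]][keep])
}

#' @export
print.anova_fit <- function(x, ...) {
  cat("Backward-selected factorial ANOVA: ", x$response, " ~ ",
      paste(x$factors, collapse = " * "), " (alpha = ", x$alpha, ")\n", sep = "")
  if (length(x$retained_terms)) {
    cat("Retained:", paste(x$retained_terms, collapse = ", "), "\n")
    print(as.data.frame(x$term_stats), digits = 3)
  } else {
    cat("Retained: intercept only\n")
  }
  invisible(x)
}

#' @rdname tidy.shape_pca
#' @method tidy anova_fit
#' @export
tidy.anova_fit <- function(x, ...) x$term_stats

#' @rdname tidy.shape_pca
#' @method glance anova_fit
#' @export
glance.anova_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(response = x$response,
                 n_obs = x$n_obs,
                 n_terms_retained = length(x$retained_terms),
                 r.squared = s$r.squared,
                 sigma = s$sigma,
                 alpha = x$alpha)
}

#' Forward verification of a backward-selected model
#'
#' Checks, by single-term additions that respect marginality, that no
#' excluded term would be significant if added to the final model.
#'
#' @param fit An `anova_fit`.
#' @param table The table the fit was produced on.
#' @param alpha Threshold (default: the fit's).
#' @return `TRUE` if no addable term reaches `p <= alpha`; otherwise `FALSE`
#'   with the offending terms in attribute `"offending"`.
#' @export
forward_check <- function(fit, table, alpha = fit$alpha) {
  stopifnot(inherits(fit, "anova_fit"))
  all_terms <- attr(stats::terms(stats::as.formula(
    paste(fit$response, "~", paste(fit$factors, collapse = " * "))
  )), "term.labels")
  excluded <- setdiff(all_terms, fit$retained_terms)
  # marginality: a term may be added only if all lower-order parents are present
  addable <- Filter(function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1) return(TRUE)
    parents <- unlist(lapply(seq_len(length(parts) - 1), function(k) {
      utils::combn(parts, k, paste, collapse = ":")
    }))
    all(parents %in% fit$retained_terms)
  }, excluded)
  if (!length(addable)) return(structure(TRUE, offending = character()))
  a1 <- stats::add1(fit$model,
                    scope = stats::as.formula(paste("~ . +", paste(addable, collapse = " + "))),
                    test = "F")
  pvals <- a1[["Pr(>F)"]][-1]
  # same degeneracy guard as the backward pass: an addition that reduces the
  # RSS only at rounding-error scale is not a real improvement
  y <- stats::model.response(stats::model.frame(fit$model))
  tss <- sum((y - mean(y))^2)
  ss <- abs(a1[["Sum of Sq"]][-1])
  offending <- rownames(a1)[-1][!is.na(pvals) & pvals <= alpha & ss >= 1e-8 * tss]
  structure(length(offending) == 0, offending = offending)
}

#' Loess trend of scores along the node series
#'
#' Locally weighted polynomial regression (tricube weights) of a response
#' against node position, evaluated on the observed node grid with pointwise
#' standard errors, as used to summarize PC scores and area through the leaf
#' series.
#'
#' @param x Numeric node positions.
#' @param y Numeric response.
#' @param span Loess span (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @return A `trend_curve` tibble: `x`, `fitted`, `se`, with attributes
#'   `span` and `degree`.
#' @export
loess_trend <- function(x, y, span = 0.75, degree = 2) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < degree + 2) {
    stop("need at least degree + 2 distinct x values", call. = FALSE)
  }
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  grid <- sort(unique(x))
  pr <- stats::predict(fit, newdata = data.frame(x = grid), se = TRUE)
  structure(tibble::tibble(x = grid, fitted = as.numeric(pr$fit),
                           se = as.numeric(pr$se.fit)),
            span = span, degree = degree,
            class = c("trend_curve", class(tibble::tibble())))
}

#' Plot a loess trend with its standard-error band
#'
#' @param object A `trend_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trend_curve
#' @export
autoplot.trend_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$fitted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fitted - .data$se,
                                      ymax = .data$fitted + .data$se),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Node position (1 = nearest apex)", y = "Fitted trend") +
    ggplot2::theme_minimal()
}
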