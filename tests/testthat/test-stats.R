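test_that("phyllotaxy chi-square reproduces the worked example and closed forms", {
  res <- chi_square_direction(100, 109)
  expect_equal(round(res$statistic, 3), 0.388)
  expect_equal(round(res$p.value, 4), 0.5336)
  expect_equal(res$df, 1L)

  expect_equal(chi_square_direction(50, 50)$statistic, 0)
  expect_equal(chi_square_direction(50, 50)$p.value, 1)

  res2 <- chi_square_direction(60, 40)
  expect_equal(res2$statistic, 4)
  expect_equal(res2$p.value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)

  # agrees with the stock Pearson test
  ref <- suppressWarnings(chisq.test(c(60, 40), p = c(0.5, 0.5), correct = FALSE))
  expect_equal(res2$statistic, unname(ref$statistic))

  expect_error(chi_square_direction(0, 0), "zero")
  expect_error(chi_square_direction(-1, 5), "nonnegative")
})

test_that("chi-square is never blind to what the exact binomial flags (n <= 30)", {
  # the uncorrected Pearson statistic is anti-conservative near the threshold:
  # every qualitative disagreement with the exact binomial test is a case where
  # chi-square rejects and the exact test does not, never the reverse
  for (n in 1:30) {
    for (k in 0:n) {
      p_chi <- chi_square_direction(k, n - k)$p.value
      p_exact <- binom.test(k, n)$p.value
      if (p_exact < 0.05) expect_lt(p_chi, 0.05)
      if ((p_chi < 0.05) != (p_exact < 0.05)) expect_lt(p_chi, p_exact)
    }
  }
})

test_that("analysis table assembly counts, validates and warns", {
  rec <- tidyr::expand_grid(shoot_id = c("S1", "S2"), node = 1:3,
                            side = c("ab_top", "ad_bottom"))
  rec$phyllotaxy <- ifelse(rec$shoot_id == "S1", "CL", "CC")
  rec$area_cm2 <- seq_len(nrow(rec))
  sc <- dplyr::mutate(rec[c("shoot_id", "node", "side")],
                      asymPC1 = rnorm(dplyr::n()))
  tbl <- build_analysis_table(rec, sc)
  expect_equal(nrow(tbl), 12) # 2 shoots x 3 nodes x 2 sides
  expect_s3_class(tbl$position, "ordered")
  expect_equal(levels(tbl$side), c("ab_top", "ad_bottom"))

  expect_warning(build_analysis_table(rec[-2, ], sc[-2, ]), "ad_bottom")
  expect_error(build_analysis_table(rec, sc[c(1, 1:12), ]), "duplicate")
  orphan <- sc
  orphan$node[1] <- 99L
  expect_error(build_analysis_table(rec, orphan), "no matching")
})

test_that("noiseless constructed signal retains exactly its generating terms", {
  d <- tidyr::expand_grid(position = factor(1:4, ordered = TRUE),
                          phyllotaxy = factor(c("CL", "CC")),
                          side = factor(c("ab_top", "ad_bottom")),
                          rep = 1:5)
  d$y <- as.integer(d$position) + 2 * (d$side == "ad_bottom") +
    as.integer(d$position) * (d$side == "ad_bottom")
  fit <- fit_anova(d, "y", factors = c("position", "phyllotaxy", "side"))
  expect_setequal(fit$retained_terms, c("position", "side", "position:side"))
  expect_true(as.logical(forward_check(fit, d)))
})

test_that("selection trace reconstructs the retained model deterministically", {
  set.seed(31)
  d <- tidyr::expand_grid(position = factor(1:4, ordered = TRUE),
                          phyllotaxy = factor(c("CL", "CC")), rep = 1:10)
  d$y <- as.integer(d$position) + rnorm(nrow(d), sd = 0.5)
  fit <- fit_anova(d, "y", factors = c("position", "phyllotaxy"))
  dropped <- fit$selection_trace$term[fit$selection_trace$action == "drop"]
  full_terms <- c("position", "phyllotaxy", "position:phyllotaxy")
  expect_setequal(c(dropped, fit$retained_terms), full_terms)
  # higher-order terms leave before the main effects they contain
  if ("position:phyllotaxy" %in% dropped && "phyllotaxy" %in% dropped) {
    expect_lt(which(dropped == "position:phyllotaxy"),
              which(dropped == "phyllotaxy"))
  }
  # replaying the drops on the full model reproduces the retained set
  expect_setequal(fit$retained_terms, setdiff(full_terms, dropped))
})

test_that("type-I retention rate under the null matches alpha", {
  set.seed(500)
  alpha <- 0.05
  retained <- vapply(1:500, function(i) {
    d <- data.frame(g = factor(rep(c("a", "b"), each = 100)), y = rnorm(200))
    length(fit_anova(d, "y", factors = "g", alpha = alpha)$retained_terms) > 0
  }, logical(1))
  expect_lt(abs(mean(retained) - alpha), 0.03)
})

test_that("power at standardized effect 1.0 with n = 50 per group is near 1", {
  set.seed(501)
  kept <- vapply(1:500, function(i) {
    d <- data.frame(g = factor(rep(c("a", "b"), each = 50)),
                    y = rnorm(100) + rep(c(0, 1), each = 50))
    "g" %in% fit_anova(d, "y", factors = "g")$retained_terms
  }, logical(1))
  expect_gte(mean(kept), 0.99)
})

test_that("rank-deficient designs fail naming the inestimable term", {
  d <- tidyr::expand_grid(position = factor(1:2), phyllotaxy = factor(c("CL", "CC")),
                          rep = 1:4)
  d <- d[!(d$position == 2 & d$phyllotaxy == "CC"), ] # empty cell
  d$y <- rnorm(nrow(d))
  expect_error(fit_anova(d, "y", factors = c("position", "phyllotaxy")),
               "position:phyllotaxy")
})

test_that("forward check flags a term the backward pass missed", {
  set.seed(61)
  d <- data.frame(g = factor(rep(c("a", "b"), each = 40)))
  d$y <- rnorm(80) + 0.6 * (d$g == "b") # moderate effect, p around 0.01
  strict <- fit_anova(d, "y", factors = "g", alpha = 0.001) # too strict: drops g
  expect_length(strict$retained_terms, 0)
  chk <- forward_check(strict, d, alpha = 0.05)
  expect_false(as.logical(chk))
  expect_equal(attr(chk, "offending"), "g")
})

test_that("forward check accepts an intercept-only fit on pure noise at roughly 1 - alpha", {
  set.seed(71)
  ok <- vapply(1:200, function(i) {
    d <- data.frame(g = factor(rep(c("a", "b"), each = 50)), y = rnorm(100))
    fit <- fit_anova(d, "y", factors = "g")
    if (length(fit$retained_terms)) return(NA)
    as.logical(forward_check(fit, d))
  }, logical(1))
  # intercept-only is reached in about (1 - alpha) of replicates, and for a
  # single-factor scope the add-back F test is the same nested comparison as
  # the drop, so the forward check is then always consistent
  expect_lt(abs(mean(!is.na(ok)) - 0.95), 0.05)
  expect_true(all(ok[!is.na(ok)]))
})

test_that("loess trends: polynomial exactness, constant data, quadratic recovery", {
  x <- rep(1:8, each = 5)
  y <- 2 + 3 * x
  tr <- loess_trend(x, y, degree = 1)
  expect_equal(tr$fitted, 2 + 3 * sort(unique(x)), tolerance = 1e-8)

  yc <- rep(5, length(x))
  trc <- loess_trend(x, yc)
  expect_equal(trc$fitted, rep(5, 8), tolerance = 1e-8)
  expect_true(all(trc$se >= 0))

  set.seed(9)
  xq <- rep(seq(0, 4, by = 0.5), each = 6)
  truth <- (xq - 2)^2
  yq <- truth + rnorm(length(xq), sd = 0.3)
  tr2 <- loess_trend(xq, yq)
  lin <- lm(yq ~ xq)
  grid <- sort(unique(xq))
  err_loess <- max(abs(tr2$fitted - (grid - 2)^2))
  err_lin <- max(abs(predict(lin, data.frame(xq = grid)) - (grid - 2)^2))
  expect_lt(err_loess, err_lin)
  expect_error(loess_trend(c(1, 1, 2, 2), c(1, 2, 3, 4)), "distinct")
  expect_s3_class(autoplot(tr2), "ggplot")
})
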