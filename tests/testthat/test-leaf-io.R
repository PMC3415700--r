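test_that("load_mask handles degenerate and simple images", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 10, 10), f)
  expect_error(load_mask(f, dpi = 300), "empty foreground")

  img <- matrix(0, 10, 10)
  img[3:7, 4:8] <- 1
  png::writePNG(img, f)
  m <- load_mask(f, dpi = 300)
  expect_equal(sum(m), 25)
  expect_equal(attr(m, "dpi"), 300)

  # polarity flag: dark leaf on white paper
  png::writePNG(1 - img, f)
  expect_equal(sum(load_mask(f, dpi = 300, foreground = "zero")), 25)

  # two comparable components is an error naming the count
  img2 <- matrix(0, 20, 20)
  img2[2:8, 2:8] <- 1
  img2[12:18, 12:18] <- 1
  png::writePNG(img2, f)
  expect_error(load_mask(f, dpi = 300), "2 foreground components")

  expect_error(load_mask(f, dpi = -1), "dpi")
})

test_that("rasterized leaves load back with the rasterizer's pixel count", {
  leaf <- generate_leaf_outline(3, "CC", quiet_config(), seed = 5)
  mask <- rasterize_outline(leaf$ab_top, 150)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(mask * 1, f)
  m <- load_mask(f, dpi = 150)
  expect_identical(sum(m), sum(mask))
})

test_that("small extra components are dropped with a warning", {
  img <- matrix(0, 40, 40)
  img[5:30, 5:30] <- 1 # 676 px
  img[36, 36] <- 1     # 1 px of dust (< 1%)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, f)
  expect_warning(m <- load_mask(f, dpi = 300), "dust")
  expect_equal(sum(m), 676)
})

test_that("extract_contour traces a filled square as its 16-pixel boundary", {
  mask <- matrix(FALSE, 9, 9)
  mask[3:7, 3:7] <- TRUE
  ct <- extract_contour(mask)
  expect_equal(nrow(ct), 16)
  expect_equal(contour_area(ct), 16) # shoelace of the center path of a 5x5 block
  # brute-force boundary enumeration: every traced pixel has a background 8-neighbour
  expect_true(all(ct[, 1] %in% 2:6 & ct[, 2] %in% 2:6))
  expect_true(all(ct[, 1] %in% c(2, 6) | ct[, 2] %in% c(2, 6)))
})

test_that("extract_contour rejects tiny and clipped components", {
  tiny <- matrix(FALSE, 5, 5)
  tiny[3, 3] <- TRUE
  expect_error(extract_contour(tiny), "too small")
  clipped <- matrix(FALSE, 6, 6)
  clipped[1:4, 2:5] <- TRUE
  expect_error(extract_contour(clipped), "clipped")
})

test_that("disk contour area is within 2% of pi r^2", {
  r <- 50
  xy <- expand.grid(x = 1:120, y = 1:120)
  mask <- matrix((xy$x - 60)^2 + (xy$y - 60)^2 <= r^2, 120, 120)
  ct <- extract_contour(mask)
  expect_lt(abs(contour_area(ct) - pi * r^2) / (pi * r^2), 0.02)
})

test_that("area unit conversion is exact", {
  mask <- matrix(TRUE, 300, 300) # one square inch at 300 dpi
  expect_equal(sum(mask) * (2.54 / 300)^2, 6.4516)
  expect_equal(compute_area_cm2(mask, 300), 6.4516)
  expect_equal(compute_area_cm2(matrix(FALSE, 5, 5), 300), 0)
  expect_error(compute_area_cm2(mask, 0), "positive")
})

test_that("node labels parse and round-trip as roman numerals", {
  expect_equal(parse_node_label("i"), 1L)
  expect_equal(parse_node_label("xvi"), 16L)
  expect_equal(parse_node_label("iv"), 4L)
  expect_equal(parse_node_label("7"), 7L)
  expect_equal(parse_node_label(node_to_roman(1:16)), 1:16)
  expect_error(parse_node_label("xvii"), "accepted forms")
  expect_error(parse_node_label("leaf3"), "accepted forms")
})

test_that("a generated dataset on disk reads back consistently", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_shoots = 2, nodes_per_shoot = 3, dpi = 60, seed = 11)
  ds <- generate_dataset(cfg, dir = dir)
  expect_equal(nrow(ds$records), 12) # 2 shoots x 3 nodes x 2 sides
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- read_leaf_dataset(file.path(dir, "metadata.csv"))
  expect_equal(nrow(back), 12)
  expect_equal(back$area_cm2, ds$records$area_cm2, tolerance = 1e-12)
  expect_equal(sort(unique(back$node)), 1:3)
})

test_that("record-structure invariants are enforced", {
  tbl <- tibble::tibble(shoot_id = "S1", node = 1L, phyllotaxy = "CL",
                        side = c("ab_top", "ab_top"), dpi = 300)
  expect_error(leafasym:::validate_leaf_records(tbl), "duplicate")
  tbl2 <- tibble::tibble(shoot_id = "S1", node = 1L, phyllotaxy = "CL",
                         side = "ad_bottom", dpi = 300)
  expect_error(leafasym:::validate_leaf_records(tbl2), "ab_top")
})
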