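test_that("polygon area fraction counts collagen pixels by center inclusion", {
  all_poly <- rect_poly(1, 1, 10, 10)
  img_all <- toy_section(10, 10, collagen_idx = 1:100)
  expect_equal(polygon_area_fraction(img_all, all_poly), 1.0)
  img_none <- toy_section(10, 10)
  expect_equal(polygon_area_fraction(img_none, all_poly), 0.0)
  img_25 <- toy_section(10, 10, collagen_idx = 1:25)
  expect_equal(polygon_area_fraction(img_25, all_poly), 0.25)
  # empty interior
  tiny <- cbind(c(0.1, 0.2, 0.2), c(0.1, 0.1, 0.2))
  expect_error(polygon_area_fraction(img_all, tiny), "no pixel centers")
})

test_that("partial polygons select the right pixel subset", {
  img <- toy_section(10, 10, collagen_idx = which(
    matrix(rep(1:10, each = 10), 10) <= 5))  # columns 1..5 collagen
  expect_equal(polygon_area_fraction(img, rect_poly(1, 1, 5, 10)), 1.0)
  expect_equal(polygon_area_fraction(img, rect_poly(6, 1, 10, 10)), 0.0)
  expect_equal(polygon_area_fraction(img, rect_poly(1, 1, 10, 10)), 0.5)
})

test_that("bundle fraction is the mean of the two segmentations", {
  expect_equal(bundle_collagen_fraction(0.06, 0.046), 0.053)
  expect_equal(bundle_collagen_fraction(0.3, 0.3), 0.3)
  expect_equal(bundle_collagen_fraction(0.0, 1.0), 0.5)
  expect_error(bundle_collagen_fraction(-0.1, 0.5), "\\[0, 1\\]")
  # bracketing by construction
  set.seed(4)
  for (i in 1:10) {
    f <- sort(runif(2))
    m <- bundle_collagen_fraction(f[1], f[2])
    expect_gte(m, f[1]); expect_lte(m, f[2])
  }
})

test_that("an all-collagen annulus makes the external fraction larger", {
  # fiber disk in the middle, pure collagen ring between inner and outer box
  img <- toy_section(30, 30, fibers = list(c(15, 15, 6)))
  inner <- rect_poly(8, 8, 22, 22)
  outer <- rect_poly(4, 4, 26, 26)
  m_in <- .polygon_pixel_mask_test(img, inner)
  ann <- .polygon_pixel_mask_test(img, outer) & !m_in
  mask <- img$collagen_mask
  mask[ann] <- TRUE
  img2 <- section_image(mask, img$fiber_labels)
  expect_gte(polygon_area_fraction(img2, outer),
             polygon_area_fraction(img2, inner))
})

test_that("fractions are invariant to translation and 90-degree rotation", {
  set.seed(12)
  img <- toy_section(20, 20, collagen_idx = sample(400, 60))
  # generic vertices: no pixel center lies exactly on an edge, so the
  # half-open boundary rule cannot break the symmetry
  poly <- cbind(c(3.3, 16.2, 12.7, 4.1), c(4.4, 5.2, 17.3, 15.1))
  f0 <- polygon_area_fraction(img, poly)
  # translate raster and polygon together by (+5, +3)
  big <- matrix(FALSE, 30, 30)
  big[(1:20) + 3, (1:20) + 5] <- img$collagen_mask
  img_t <- section_image(big, matrix(0L, 30, 30))
  poly_t <- cbind(poly[, 1] + 5, poly[, 2] + 3)
  expect_equal(polygon_area_fraction(img_t, poly_t), f0)
  # rotate 90 degrees: (x, y) -> (nr + 1 - y, x) matches matrix transpose-flip
  rot <- t(img$collagen_mask)[, nrow(img$collagen_mask):1, drop = FALSE]
  img_r <- section_image(rot, matrix(0L, nrow(rot), ncol(rot)))
  poly_r <- cbind(nrow(img$collagen_mask) + 1 - poly[, 2], poly[, 1])
  expect_equal(polygon_area_fraction(img_r, poly_r), f0)
})

test_that("fibers are counted by pixel majority inside the polygon", {
  img <- toy_section(40, 80, fibers = list(
    c(12, 12, 4), c(24, 12, 4), c(12, 26, 4), c(24, 26, 4),
    c(40, 12, 4), c(52, 12, 4), c(40, 26, 4), c(52, 26, 4)))
  expect_equal(count_fibers(img, rect_poly(1, 1, 60, 38)), 8L)
  expect_equal(count_fibers(img, rect_poly(62, 1, 80, 38)), 0L)
  # straddling fiber: ~60% of its pixels inside is counted, ~40% is not
  one <- toy_section(20, 20, fibers = list(c(10, 10, 4)))
  expect_equal(count_fibers(one, rect_poly(1, 1, 11, 20)), 1L)
  expect_equal(count_fibers(one, rect_poly(1, 1, 9, 20)), 0L)
})

test_that("section images round-trip through PNG rasters", {
  set.seed(31)
  g <- generate_section_image(5, 0.08, seed = 3, fiber_radius_px = 8)
  mp <- withr::local_tempfile(fileext = ".png")
  lp <- withr::local_tempfile(fileext = ".png")
  write_section_image(g$image, mp, lp)
  back <- read_section_image(mp, lp)
  expect_equal(back$collagen_mask, g$image$collagen_mask)
  expect_equal(back$fiber_labels, g$image$fiber_labels)
})

test_that("polygon CSVs load as named vertex lists", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(polygon = rep(c("A", "B"), each = 3),
                   x_px = c(1, 5, 3, 0, 6, 3), y_px = c(1, 1, 5, 0, 0, 7))
  write.csv(df, f, row.names = FALSE)
  polys <- read_polygons_csv(f)
  expect_named(polys, c("A", "B"))
  expect_equal(dim(polys$A), c(3L, 2L))
})

test_that("measure_bundle ties the pieces together", {
  g <- generate_section_image(6, 0.05, seed = 2)
  m <- measure_bundle(g$image, g$segmentation)
  expect_gte(m$collagen_fraction, min(m$frac_A, m$frac_B))
  expect_lte(m$collagen_fraction, max(m$frac_A, m$frac_B))
  expect_equal(m$n_fibers, 6L)
})
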