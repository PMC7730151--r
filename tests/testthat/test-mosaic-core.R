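test_that("write/read round trip preserves cells, mask and metadata", {
  m <- square_mosaic(x = c(0.125, 0.5, 0.8125), y = c(0.25, 0.5, 0.75),
                     nucleus_area = c(80, 100, 120), retina_id = "rt1",
                     group = "OHT", timepoint_days = 7)
  for (ext in c("pgm", "png")) {
    d <- withr::local_tempdir()
    paths <- file.path(d, c("cells.csv", paste0("mask.", ext), "meta.yaml"))
    write_mosaic(m, paths[1], paths[2], paths[3])
    m2 <- read_mosaic(paths[1], paths[2], paths[3])
    expect_equal(m2$cells$x, m$cells$x, tolerance = 1e-12)
    expect_equal(m2$cells$y, m$cells$y, tolerance = 1e-12)
    expect_identical(m2$cells$nucleus_area, m$cells$nucleus_area)
    expect_identical(m2$mask, m$mask)
    expect_identical(m2$retina_id, "rt1")
    expect_identical(m2$group, "OHT")
    expect_equal(m2$timepoint_days, 7)
    expect_equal(m2$onh, m$onh, tolerance = 1e-12)
  }
})

test_that("round trip through a synthetic mosaic preserves every cell", {
  m <- generate_healthy(small_params(), seed = 11)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("cells.csv", "mask.pgm", "meta.yaml"))
  write_mosaic(m, paths[1], paths[2], paths[3])
  # keep cells whose centres quantise onto boundary pixels of the raster mask
  m2 <- read_mosaic(paths[1], paths[2], paths[3], mask_policy = "keep")
  expect_identical(nrow(m2$cells), nrow(m$cells))
  expect_equal(m2$cells$x, m$cells$x, tolerance = 1e-12)
  expect_equal(m2$cells$cytoplasm_area, m$cells$cytoplasm_area,
               tolerance = 1e-12)
})

test_that("cells on masked-out pixels follow the mask policy", {
  mask <- matrix(TRUE, 100, 100)
  mask[, 51:100] <- FALSE  # right half masked out
  cells <- data.frame(cell_id = 1:2, channel = "brn3a",
                      x = c(0.25, 0.75), y = c(0.5, 0.5),
                      nucleus_area = 100, cytoplasm_area = NA)
  expect_warning(
    m <- retinal_mosaic(cells, mask, 10, onh = c(0.25, 0.5)),
    "rejected")
  expect_identical(nrow(m$cells), 1L)
  expect_equal(m$cells$x, 0.25)
  m2 <- retinal_mosaic(cells, mask, 10, onh = c(0.25, 0.5),
                       mask_policy = "keep")
  expect_identical(nrow(m2$cells), 2L)
  # all cells outside -> empty-mosaic error
  far <- transform(cells, x = c(0.6, 0.75))
  expect_error(suppressWarnings(
    retinal_mosaic(far, mask, 10, onh = c(0.25, 0.5))), "no cell")
})

test_that("cell table validation rejects bad schemas and areas", {
  mask <- matrix(TRUE, 10, 10)
  bad <- data.frame(cell_id = 1, channel = "brn3a", x = 0.05, y = 0.05)
  expect_error(retinal_mosaic(bad, mask, 10, onh = c(0.05, 0.05)),
               "schema error")
  neg <- data.frame(cell_id = 1, channel = "brn3a", x = 0.05, y = 0.05,
                    nucleus_area = -5, cytoplasm_area = NA)
  expect_error(retinal_mosaic(neg, mask, 10, onh = c(0.05, 0.05)),
               "validation error")
})

test_that("mask_area is pixel count times squared scale", {
  m <- square_mosaic(0.5, 0.5, side_mm = 1, um_per_px = 20)  # 50x50 px
  expect_identical(dim(m$mask), c(50L, 50L))
  expect_equal(mask_area(m), 1.0)
  half <- m
  half$mask[1:25, ] <- FALSE
  expect_equal(mask_area(half), 0.5)
})

test_that("disc mask area approaches the analytic circle area", {
  # disc of radius 100 px at 10 um/px = 1 mm radius -> pi mm^2
  px <- 10 / 1000
  g <- expand.grid(r = 1:220, c = 1:220)
  d2 <- ((g$c - 110.5)^2 + (g$r - 110.5)^2) * px^2
  mask <- matrix(d2 <= 1, 220, 220)
  cells <- data.frame(cell_id = 1, channel = "brn3a", x = 1.105, y = 1.105,
                      nucleus_area = 100, cytoplasm_area = NA)
  m <- retinal_mosaic(cells, mask, 10, onh = c(1.105, 1.105))
  # one-pixel boundary tolerance: perimeter x pixel size
  expect_lt(abs(mask_area(m) - pi), 2 * pi * 1 * px)
})

test_that("mask_area is invariant under raster translation", {
  base <- matrix(FALSE, 60, 60); base[10:30, 10:40] <- TRUE
  shifted <- matrix(FALSE, 60, 60); shifted[25:45, 15:45] <- TRUE
  cells <- data.frame(cell_id = 1, channel = "brn3a", x = 0.2, y = 0.4,
                      nucleus_area = 100, cytoplasm_area = NA)
  m1 <- retinal_mosaic(cells, base, 10, onh = c(0.2, 0.4))
  m2 <- suppressWarnings(retinal_mosaic(cells, shifted, 10, onh = c(0.2, 0.4),
                                        mask_policy = "keep"))
  expect_equal(mask_area(m1), mask_area(m2))
})

test_that("overall_density divides channel counts by mask area", {
  m <- square_mosaic(runif(200), runif(200), side_mm = 1)
  expect_equal(overall_density(m), 200)
  expect_equal(overall_density(m, channel = "rbpms"), 0)
})

test_that("realized density of a generated mosaic matches the target", {
  p <- small_params()
  m <- generate_healthy(p, seed = 5)
  n <- sum(m$cells$channel == "brn3a")
  lambda <- p$target_density * mask_area(m)
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
})

test_that("cohorts enforce unique retina ids", {
  m <- square_mosaic(0.5, 0.5, retina_id = "dup")
  expect_error(cohort(list(m, m)), "unique")
})
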