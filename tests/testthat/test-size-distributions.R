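test_that("the default scheme reproduces the quoted band boundaries", {
  s <- binning_scheme()
  expect_identical(s$n_bins, 25L)
  expect_equal(s$edges[1], 0)
  expect_equal(s$edges[26], 238.0)
  # 57.12, 104.72, 133.28, 142.80 round to the 57/105/133/143 um^2 bands
  expect_equal(round(s$edges[c(7, 12, 15, 16)]), c(57, 105, 133, 143))
})

test_that("histogram densities are counts over mask area", {
  m <- square_mosaic(c(0.3, 0.7), c(0.5, 0.5), nucleus_area = 60)
  h <- bin_density_histogram(m)
  expect_equal(mask_area(m), 1)
  expect_equal(h$density[7], 2)  # 57.12 <= 60 < 66.64
  expect_equal(sum(h$density), 2)
  expect_identical(h$overflow_count, 0L)

  # overflow cells tallied separately
  m2 <- square_mosaic(c(0.3, 0.7), c(0.5, 0.5), nucleus_area = c(60, 500))
  h2 <- bin_density_histogram(m2)
  expect_identical(h2$overflow_count, 1L)
  expect_equal(sum(h2$density) * h2$mask_area_mm2, 1)

  expect_error(binning_scheme(bin_width_um2 = 0))
})

test_that("a mosaic with no analysis-channel cells gives a zero histogram", {
  m <- square_mosaic(0.5, 0.5, channel = "rbpms", nucleus_area = NA,
                     cytoplasm_area = 150)
  h <- bin_density_histogram(m)
  expect_true(all(h$density == 0))
  expect_error(pdf_from_mosaic(m), "no in-range cells")
})

test_that("histogram counts are recovered exactly from densities", {
  m <- generate_healthy(small_params(), seed = 31)
  h <- bin_density_histogram(m)
  expect_identical(round(h$density * h$mask_area_mm2), as.numeric(h$counts))
  expect_identical(sum(h$counts) + h$overflow_count,
                   sum(m$cells$channel == "brn3a"))
})

test_that("PDFs normalise and are invariant to mask rescaling", {
  m <- generate_healthy(small_params(), seed = 32)
  p <- pdf_from_mosaic(m)
  expect_equal(sum(p$probability), 1, tolerance = 1e-12)
  expect_true(all(p$probability >= 0))

  # doubling the pixel scale inflates mask area: histogram changes, PDF not
  m2 <- m
  m2$um_per_px <- m$um_per_px * 2
  h1 <- bin_density_histogram(m); h2 <- bin_density_histogram(m2)
  expect_equal(h2$density, h1$density / 4)
  expect_equal(pdf_from_mosaic(m2)$probability, p$probability)
})

test_that("uniform areas give near-uniform bin probabilities", {
  set.seed(33)
  n <- 10000
  m <- square_mosaic(runif(n, 0.05, 0.95), runif(n, 0.05, 0.95),
                     nucleus_area = runif(n, 0, 238))
  p <- pdf_from_mosaic(m)
  se <- sqrt(0.04 * 0.96 / n)
  expect_true(all(abs(p$probability - 0.04) < 3 * se + 1e-9))
})

test_that("group means average per bin with sd/sqrt(n) errors", {
  m <- generate_healthy(small_params(), seed = 34)
  p <- pdf_from_mosaic(m)
  gm <- group_mean(list(p, p))
  expect_equal(gm$mean, p$probability)
  expect_true(all(gm$se == 0))

  two_bin <- function(pr) structure(
    list(scheme = binning_scheme(2, 10), probability = pr, n_cells = 10),
    class = "size_pdf")
  gm2 <- group_mean(list(two_bin(c(0.4, 0.6)), two_bin(c(0.6, 0.4))))
  expect_equal(gm2$mean, c(0.5, 0.5))
  expect_equal(gm2$se, c(0.1, 0.1))

  expect_error(group_mean(list(p)), "at least 2")
  q <- pdf_from_mosaic(m, binning_scheme(n_bins = 10, bin_width_um2 = 23.8))
  expect_error(group_mean(list(p, q)), "mixed")
})

test_that("difference-PDFs are zero-sum and directionally correct", {
  m1 <- generate_healthy(small_params(), seed = 35)
  m2 <- generate_healthy(small_params(), seed = 36)
  gm <- group_mean(lapply(list(m1, m2), pdf_from_mosaic))
  d0 <- pdf_difference(gm, gm)
  expect_true(all(d0$difference == 0))

  # small-cell-biased loss: probability shifts from small to large bins
  scheme <- binning_scheme()
  ip <- injury_params(scheme,
                      hazard_per_day = c(rep(0.2, 10), rep(0, 15)),
                      plateau_fraction = 0)
  inj <- lapply(list(m1, m2), function(m)
    suppressWarnings(apply_injury(m, ip, 21, seed = 40 + nrow(m$cells))))
  gmi <- group_mean(lapply(inj, pdf_from_mosaic))
  d <- pdf_difference(gmi, gm)
  expect_equal(sum(d$difference), 0, tolerance = 1e-12)
  expect_true(all(d$difference[1:10] <= 0))
  expect_true(sum(d$difference[11:25]) > 0)
})

test_that("per-bin Welch comparisons flag only real shifts", {
  m <- lapply(301:308, function(s) generate_healthy(small_params(), seed = s))
  hists <- lapply(m, bin_density_histogram)
  null_cmp <- per_bin_comparison(hists[1:4], hists[5:8])
  expect_false(any(null_cmp$significant, na.rm = TRUE))

  # degenerate variance in both groups: p undefined, not significant
  same <- per_bin_comparison(list(hists[[1]], hists[[1]]),
                             list(hists[[1]], hists[[1]]))
  expect_true(all(is.na(same$p_value)))
  expect_false(any(same$significant))

  # a 10-sd shift in one bin must be detected
  shift <- hists[5:8]
  pooled_sd <- sd(vapply(hists, function(h) h$density[8], numeric(1)))
  for (i in seq_along(shift)) shift[[i]]$density[8] <-
      shift[[i]]$density[8] + 10 * pooled_sd
  cmp <- per_bin_comparison(hists[1:4], shift)
  expect_true(cmp$significant[8])
  expect_error(per_bin_comparison(hists[1], hists[2:3]), "at least 2")
})
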