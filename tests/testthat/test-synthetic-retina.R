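test_that("generation is deterministic for a fixed seed", {
  p <- small_params()
  m1 <- generate_healthy(p, seed = 3)
  m2 <- generate_healthy(p, seed = 3)
  expect_identical(m1, m2)
  m3 <- generate_healthy(p, seed = 4)
  expect_false(nrow(m3$cells) == nrow(m1$cells) &&
                 all(m3$cells$x == m1$cells$x))
})

test_that("hard-core inhibition is respected exactly", {
  p <- healthy_params(retina_radius_mm = 0.8, onh_radius_mm = 0.2,
                      target_density = 2200, inhibition_radius_um = 9)
  for (seed in 1:3) {
    m <- generate_healthy(p, seed = seed)
    b <- m$cells[m$cells$channel == "brn3a", ]
    expect_lte(nrow(b), 5000)
    d <- dist(cbind(b$x, b$y))
    expect_gte(min(d) * 1000, p$inhibition_radius_um)
  }
})

test_that("exhausted packing budget fails with an error naming the bound", {
  p <- healthy_params(retina_radius_mm = 0.5, onh_radius_mm = 0.1,
                      target_density = 4000, inhibition_radius_um = 7.5)
  expect_error(generate_healthy(p, seed = 1, max_attempts_per_cell = 1),
               "packing failure.*attempts")
})

test_that("realized density tracks the target within 5% across seeds", {
  p <- healthy_params()  # rat preset: 4.5 mm, 2200/mm^2
  dens <- vapply(1:10, function(s)
    overall_density(generate_healthy(p, seed = s)), numeric(1))
  expect_lt(abs(mean(dens) - p$target_density) / p$target_density, 0.05)
})

test_that("nucleus area correlates with eccentricity near the naive value", {
  p <- healthy_params()  # rat preset
  rhos <- vapply(1:20, function(s)
    size_eccentricity_correlation(generate_healthy(p, seed = s))$rho,
    numeric(1))
  expect_true(all(rhos > 0))
  expect_lt(abs(mean(rhos) - 0.26), 0.10)
})

test_that("per-cell cytoplasm/nucleus ratio has the configured mean", {
  p <- small_params()
  m <- generate_healthy(p, seed = 9)
  cells <- m$cells
  br <- cells[cells$channel == "brn3a", ]
  rb <- cells[cells$channel == "rbpms" & !is.na(cells$pair_id), ]
  ratio <- rb$cytoplasm_area[order(rb$pair_id)] /
    br$nucleus_area[order(br$pair_id)]
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - p$cn_ratio_true), 3 * se)
})

test_that("zero hazard leaves the mosaic unchanged", {
  m <- generate_healthy(small_params(), seed = 2)
  ip <- injury_params(hazard_per_day = 0, plateau_fraction = 0)
  out <- suppressWarnings(apply_injury(m, ip, 21, seed = 5))
  expect_identical(out$cells$x, m$cells$x)
  expect_identical(out$cells$nucleus_area, m$cells$nucleus_area)
  expect_identical(out$timepoint_days, 21)
})

test_that("single-bin survival matches the closed form", {
  m <- generate_healthy(small_params(), seed = 6)
  scheme1 <- binning_scheme(n_bins = 1, bin_width_um2 = 1000)
  ip <- injury_params(scheme1, hazard_per_day = log(2) / 7,
                      plateau_fraction = 0)
  out <- apply_injury(m, ip, 7, seed = 8)
  n0 <- sum(m$cells$channel == "brn3a")
  n1 <- sum(out$cells$channel == "brn3a")
  expect_lt(abs(n1 / n0 - 0.5), 3 * sqrt(0.25 / n0))
  expect_lte(nrow(out$cells), nrow(m$cells))
})

test_that("superior hazard multiplier 2 gives the ~2/3 sectorial split", {
  m <- generate_healthy(small_params(), seed = 12)
  scheme1 <- binning_scheme(n_bins = 1, bin_width_um2 = 1000)
  # small k*t keeps the split in the proportional-hazard regime
  ip <- injury_params(scheme1, hazard_per_day = 0.05, plateau_fraction = 0,
                      superior_hazard_multiplier = 2)
  out <- apply_injury(m, ip, 1, seed = 13)
  lost <- m$cells[m$cells$channel == "brn3a" &
                    !(m$cells$cell_id %in% out$cells$cell_id), ]
  m_lost <- m
  m_lost$cells <- lost
  qs_lost <- quadrant_split(m_lost)
  n_sup <- nrow(qs_lost$superior$cells)
  n_inf <- nrow(qs_lost$inferior$cells)
  frac <- n_sup / (n_sup + n_inf)
  expect_lt(abs(frac - 2 / 3),
            3 * sqrt(2 / 9 / (n_sup + n_inf)) + 0.01)
})

test_that("swelling and pre-death shrinkage modulate observed areas", {
  m <- generate_healthy(small_params(), seed = 21)
  scheme1 <- binning_scheme(n_bins = 1, bin_width_um2 = 1000)
  ip <- injury_params(scheme1, hazard_per_day = 0.05, plateau_fraction = 0,
                      swell_fraction = 0.5, swell_multiplier = 1.3,
                      swell_onset_day = 1, swell_resolution_day = 7,
                      shrink_multiplier = 0.7, shrink_lead_days = 3)
  out <- apply_injury(m, ip, 3, seed = 22)
  base <- m$cells[match(out$cells$cell_id, m$cells$cell_id), ]
  ratio <- out$cells$nucleus_area / base$nucleus_area
  ratio <- ratio[!is.na(ratio)]
  expect_setequal(round(unique(ratio), 10), c(1, 1.3, 0.7))
  # outside the swelling window no cell is swollen
  out2 <- apply_injury(m, ip, 10, seed = 22)
  base2 <- m$cells[match(out2$cells$cell_id, m$cells$cell_id), ]
  r2 <- out2$cells$nucleus_area / base2$nucleus_area
  expect_true(all(round(r2[!is.na(r2)], 10) %in% c(1, 0.7)))
})

test_that("cohort generation follows the design and is reproducible", {
  p <- small_params()
  ip <- injury_params(hazard_per_day = 0.03, plateau_fraction = 0.2)
  des <- list(naive = c(0, 0, 0))
  ch <- generate_cohort(p, ip, des, seed = 1)
  expect_length(ch$mosaics, 3)
  expect_true(all(vapply(ch$mosaics, function(m) m$timepoint_days,
                         numeric(1)) == 0))

  des2 <- list(naive = c(0, 0), pONT = c(3, 7, 21, 56))
  ch2 <- suppressWarnings(generate_cohort(p, ip, des2, seed = 2))
  tps <- vapply(cohort_mosaics(ch2, group = "pONT"),
                function(m) m$timepoint_days, numeric(1))
  expect_setequal(tps, c(3, 7, 21, 56))
  ch2b <- suppressWarnings(generate_cohort(p, ip, des2, seed = 2))
  expect_identical(ch2, ch2b)
  ch3 <- suppressWarnings(generate_cohort(p, ip, des2, seed = 3))
  expect_false(identical(ch2, ch3))

  expect_error(generate_cohort(p, ip, list(), seed = 1), "empty design")
  expect_error(generate_cohort(p, ip, list(glaucoma = 0), seed = 1),
               "unknown group")
})

test_that("presets assemble coherent configurations", {
  for (nm in c("naive-rat", "rat-oht", "rat-pont", "mouse-onc")) {
    pre <- mosaic_preset(nm, n_replicates = 2)
    expect_s3_class(pre$healthy, "healthy_params")
    if (nm != "naive-rat") {
      expect_s3_class(pre$injury, "injury_params")
      # hazards decrease with size bin: smaller cells lost faster
      expect_true(all(diff(pre$injury$hazard_per_day) < 0))
    }
  }
  pont <- mosaic_preset("rat-pont")
  expect_setequal(unique(pont$design$pONT), c(3, 7, 21, 56))
})
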