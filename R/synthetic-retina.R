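#' Parameters of the healthy synthetic retina
#'
#' The generator emulates the statistical structure of a naive rodent
#' wholemount: a quasi-regular (hard-core) RGC mosaic on an annulus (retina
#' disc minus ONH disc), a right-skewed nucleus-area distribution whose mean
#' increases linearly with eccentricity, and a paired cytoplasmic (RBPMS)
#' channel whose area is a fixed multiple of the nucleus area plus
#' multiplicative noise, with a small fraction of RBPMS-only cells.
#'
#' Defaults are the rat wholemount conditions: radius 4.5 mm, 2,200 RGC/mm^2,
#' CN ratio 2.43 and ~3% RBPMS-only cells; the eccentricity slope of the
#' area law is set so that the Spearman correlation between nucleus area and
#' ONH distance is about 0.26 in naive tissue.
#'
#' @param retina_radius_mm wholemount radius.
#' @param onh_radius_mm optic nerve head radius (cell-free central disc).
#' @param target_density RGC density, cells/mm^2.
#' @param inhibition_radius_um hard-core minimum inter-cell distance, um.
#' @param area_base_um2 mean nucleus area at the ONH rim, um^2.
#' @param area_slope_um2_per_mm increase of mean nucleus area per mm of
#'   eccentricity.
#' @param area_sdlog log-normal shape parameter of nucleus area.
#' @param cn_ratio_true true cytoplasm/nucleus area ratio.
#' @param cn_noise_sd multiplicative noise SD on cytoplasm area (fraction).
#' @param unmatched_fraction fraction of RBPMS-only (Brn3a-negative) cells.
#' @param match_jitter_sd_um SD of the RBPMS centroid jitter relative to the
#'   matched Brn3a centroid, um.
#' @param um_per_px raster scale of the generated mask.
#' @return A `healthy_params` list.
#' @export
healthy_params <- function(retina_radius_mm = 4.5, onh_radius_mm = 0.4,
                           target_density = 2200, inhibition_radius_um = 9,
                           area_base_um2 = 60, area_slope_um2_per_mm = 8,
                           area_sdlog = 0.35, cn_ratio_true = 2.43,
                           cn_noise_sd = 0.10, unmatched_fraction = 0.03,
                           match_jitter_sd_um = 1.0, um_per_px = 10) {
  p <- list(retina_radius_mm = retina_radius_mm, onh_radius_mm = onh_radius_mm,
            target_density = target_density,
            inhibition_radius_um = inhibition_radius_um,
            area_base_um2 = area_base_um2,
            area_slope_um2_per_mm = area_slope_um2_per_mm,
            area_sdlog = area_sdlog, cn_ratio_true = cn_ratio_true,
            cn_noise_sd = cn_noise_sd, unmatched_fraction = unmatched_fraction,
            match_jitter_sd_um = match_jitter_sd_um, um_per_px = um_per_px)
  stopifnot(retina_radius_mm > 0, onh_radius_mm > 0,
            onh_radius_mm < retina_radius_mm, target_density > 0,
            inhibition_radius_um >= 0, area_base_um2 > 0, area_sdlog > 0,
            cn_ratio_true > 0, cn_noise_sd >= 0,
            unmatched_fraction >= 0, unmatched_fraction <= 0.2)
  # hard-core radius must leave room below the mean Poisson NN spacing
  mean_nnd_um <- 0.5 / sqrt(target_density) * UM_PER_MM
  if (inhibition_radius_um >= mean_nnd_um)
    stop(sprintf(
      "inhibition radius %.1f um >= mean NN spacing %.1f um at this density",
      inhibition_radius_um, mean_nnd_um))
  class(p) <- "healthy_params"
  p
}

#' Parameters of the synthetic injury model
#'
#' Injury is a per-cell survival draw: a cell in size bin b survives to day t
#' with probability `P_b + (1 - P_b) * exp(-k_b * m * t)`, where `m` is the
#' superior-quadrant hazard multiplier (sectorial injury, as in partial optic
#' nerve transection where directly severed dorsal axons concentrate primary
#' degeneration superiorly). Survivors may transiently swell; cells within
#' `shrink_lead_days` of their death time are observed shrunken
#' (pre-apoptotic atrophy).
#'
#' @param scheme a [binning_scheme()] defining the size bins of the hazard.
#' @param hazard_per_day numeric vector, per-bin rate constant k_b (1/day);
#'   recycled to `scheme$n_bins`. Cells above the last bin edge use the
#'   terminal bin's hazard.
#' @param plateau_fraction numeric vector in \[0,1\], per-bin resistant
#'   fraction P_b; recycled.
#' @param swell_fraction,swell_multiplier,swell_onset_day,swell_resolution_day
#'   transient swelling of a random subset of survivors.
#' @param shrink_multiplier,shrink_lead_days pre-death shrinkage.
#' @param superior_hazard_multiplier hazard multiplier in the superior
#'   quadrant (1 = spatially uniform injury).
#' @param seed integer seed used by [apply_injury()] when its own `seed`
#'   argument is `NULL`.
#' @return An `injury_params` list.
#' @export
injury_params <- function(scheme = binning_scheme(),
                          hazard_per_day = 0.05, plateau_fraction = 0.1,
                          swell_fraction = 0, swell_multiplier = 1.3,
                          swell_onset_day = 1, swell_resolution_day = 7,
                          shrink_multiplier = 0.7, shrink_lead_days = 0,
                          superior_hazard_multiplier = 1, seed = NULL) {
  hazard_per_day <- rep_len(hazard_per_day, scheme$n_bins)
  plateau_fraction <- rep_len(plateau_fraction, scheme$n_bins)
  stopifnot(all(hazard_per_day >= 0),
            all(plateau_fraction >= 0 & plateau_fraction <= 1),
            swell_fraction >= 0, swell_fraction <= 1, swell_multiplier > 0,
            shrink_multiplier > 0, shrink_lead_days >= 0,
            superior_hazard_multiplier > 0)
  structure(list(scheme = scheme, hazard_per_day = hazard_per_day,
                 plateau_fraction = plateau_fraction,
                 swell_fraction = swell_fraction,
                 swell_multiplier = swell_multiplier,
                 swell_onset_day = swell_onset_day,
                 swell_resolution_day = swell_resolution_day,
                 shrink_multiplier = shrink_multiplier,
                 shrink_lead_days = shrink_lead_days,
                 superior_hazard_multiplier = superior_hazard_multiplier,
                 seed = seed),
            class = "injury_params")
}

#' Generate a healthy synthetic mosaic
#'
#' Cells are placed by random sequential adsorption (hard-core sequential
#' inhibition) on the annulus between the ONH and the retinal rim. Nucleus
#' areas are log-normal with the location parameter tied linearly to
#' eccentricity. Each Brn3a cell gets a paired RBPMS detection at a jittered
#' position with cytoplasm area `cn_ratio_true * nucleus_area * (1 + noise)`,
#' and `unmatched_fraction` extra RBPMS-only cells are added.
#'
#' @param params a [healthy_params()].
#' @param seed integer seed (`NULL` = use the current RNG state, e.g. inside
#'   a stream managed by [generate_cohort()]).
#' @param retina_id,group,timepoint_days metadata for the result.
#' @param max_attempts_per_cell proposal budget of the sequential-inhibition
#'   sampler, per requested cell.
#' @return A [retinal_mosaic()].
#' @export
generate_healthy <- function(params, seed = NULL, retina_id = "synthetic",
                             group = "naive", timepoint_days = 0,
                             max_attempts_per_cell = 200) {
  stopifnot(inherits(params, "healthy_params"))
  if (!is.null(seed)) set.seed(seed)
  R <- params$retina_radius_mm
  r0 <- params$onh_radius_mm
  ann_area <- pi * (R^2 - r0^2)
  n <- round(params$target_density * ann_area)

  inhib_mm <- params$inhibition_radius_um / UM_PER_MM
  max_att <- max_attempts_per_cell * n
  pts <- rsa_annulus_cpp(n, R, r0, inhib_mm, max_att)
  if (nrow(pts) < n)
    stop(sprintf(paste0("packing failure: placed %d of %d cells within %g ",
                        "proposal attempts; lower target_density or ",
                        "inhibition_radius_um"), nrow(pts), n, max_att))

  # centre the annulus on the image centre (ONH at image centre)
  cx <- R
  x <- pts[, 1] + cx
  y <- pts[, 2] + cx
  ecc <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  nuc <- rlnorm_mean(params$area_base_um2 +
                       params$area_slope_um2_per_mm * ecc,
                     params$area_sdlog)

  jit <- params$match_jitter_sd_um / UM_PER_MM
  cyt <- params$cn_ratio_true * nuc *
    pmax(0.05, 1 + rnorm(n, 0, params$cn_noise_sd))

  n_un <- round(params$unmatched_fraction * n)
  if (n_un > 0) {
    upts <- rsa_annulus_cpp(n_un, R, r0, 0, n_un)
    ux <- upts[, 1] + cx; uy <- upts[, 2] + cx
    uecc <- sqrt(upts[, 1]^2 + upts[, 2]^2)
    unuc <- rlnorm_mean(params$area_base_um2 +
                          params$area_slope_um2_per_mm * uecc,
                        params$area_sdlog)
    ucyt <- params$cn_ratio_true * unuc *
      pmax(0.05, 1 + rnorm(n_un, 0, params$cn_noise_sd))
  }

  cells <- rbind(
    data.frame(cell_id = seq_len(n), channel = "brn3a", x = x, y = y,
               nucleus_area = nuc, cytoplasm_area = NA_real_,
               pair_id = seq_len(n), stringsAsFactors = FALSE),
    data.frame(cell_id = n + seq_len(n), channel = "rbpms",
               x = x + rnorm(n, 0, jit), y = y + rnorm(n, 0, jit),
               nucleus_area = NA_real_, cytoplasm_area = cyt,
               pair_id = seq_len(n), stringsAsFactors = FALSE))
  if (n_un > 0)
    cells <- rbind(cells, data.frame(
      cell_id = 2L * n + seq_len(n_un), channel = "rbpms", x = ux, y = uy,
      nucleus_area = NA_real_, cytoplasm_area = ucyt, pair_id = NA_integer_,
      stringsAsFactors = FALSE))

  mask <- annulus_mask(R, r0, params$um_per_px)
  retinal_mosaic(cells, mask, params$um_per_px, onh = c(cx, cx),
                 retina_id = retina_id, group = group,
                 timepoint_days = timepoint_days, mask_policy = "keep")
}

# log-normal draw with prescribed arithmetic mean and shape sdlog
rlnorm_mean <- function(mean, sdlog) {
  rlnorm(length(mean), meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

annulus_mask <- function(R, r0, um_per_px) {
  s <- um_per_px / UM_PER_MM
  npx <- ceiling(2 * R / s)
  cx <- R / s + 0.5  # pixel-centre coordinates of the image centre
  col <- matrix(rep(seq_len(npx), each = npx), nrow = npx)
  row <- matrix(rep(seq_len(npx), times = npx), nrow = npx)
  d2 <- ((col - cx)^2 + (row - cx)^2) * s^2
  d2 <= R^2 & d2 >= r0^2
}

#' Apply a synthetic injury to a healthy mosaic
#'
#' Each Brn3a cell receives a latent uniform draw that fixes its death time
#' under the survival curve `S(t) = P_b + (1 - P_b) exp(-k_b m t)` (m =
#' superior hazard multiplier inside the superior quadrant). Cells dead by
#' `timepoint_days` are removed together with their paired RBPMS detection;
#' RBPMS-only cells use the hazard of their implied nucleus size
#' (cytoplasm / CN ratio). Surviving cells selected for swelling have their
#' areas multiplied while `timepoint_days` lies in the swelling window, and
#' cells due to die within `shrink_lead_days` are observed with the shrink
#' multiplier applied.
#'
#' @param mosaic a healthy baseline [retinal_mosaic()].
#' @param params an [injury_params()].
#' @param timepoint_days observation time, days >= 0.
#' @param seed integer seed; default `params$seed`; `NULL` = current RNG
#'   state.
#' @param group group label for the returned mosaic.
#' @param cn_ratio_true CN ratio used to impute nucleus size of RBPMS-only
#'   cells.
#' @return A [retinal_mosaic()] at `timepoint_days`.
#' @export
apply_injury <- function(mosaic, params, timepoint_days,
                         seed = params$seed, group = mosaic$group,
                         cn_ratio_true = 2.43) {
  stopifnot(inherits(params, "injury_params"), timepoint_days >= 0)
  if (!is.null(seed)) set.seed(seed)
  cells <- mosaic$cells
  t <- timepoint_days

  eff_area <- ifelse(is.na(cells$nucleus_area),
                     cells$cytoplasm_area / cn_ratio_true,
                     cells$nucleus_area)
  bin <- bin_index(eff_area, params$scheme)
  over <- !is.na(bin) & bin > params$scheme$n_bins
  if (any(over))
    warning(sprintf("%d cell(s) beyond the binning range assigned to the terminal bin",
                    sum(over)))
  bin <- pmin(pmax(bin, 1L), params$scheme$n_bins)

  k <- params$hazard_per_day[bin]
  P <- params$plateau_fraction[bin]
  sup <- in_superior_quadrant(cells$x, cells$y, mosaic$onh)
  m <- ifelse(sup, params$superior_hazard_multiplier, 1)

  # one latent uniform per matched pair so a cell and its cytoplasmic
  # detection live and die together
  has_pair <- "pair_id" %in% names(cells) && !all(is.na(cells$pair_id))
  if (has_pair) {
    key <- ifelse(is.na(cells$pair_id),
                  paste0("u", cells$cell_id), paste0("p", cells$pair_id))
  } else key <- paste0("u", cells$cell_id)
  ukey <- unique(key)
  u_draw <- setNames(runif(length(ukey)), ukey)
  u <- u_draw[key]

  # death time: S(death) = u  =>  death = -log((u - P)/(1 - P)) / (k m)
  km <- k * m
  death <- rep(Inf, nrow(cells))
  dying <- u > P & km > 0 & P < 1
  death[dying] <- -log((u[dying] - P[dying]) / (1 - P[dying])) / km[dying]

  alive <- death > t
  swollen <- runif(length(ukey)) < params$swell_fraction
  names(swollen) <- ukey
  sw <- swollen[key] & alive &
    t >= params$swell_onset_day & t <= params$swell_resolution_day
  shrink <- alive & (death - t) <= params$shrink_lead_days & is.finite(death)

  mult <- rep(1, nrow(cells))
  mult[sw] <- params$swell_multiplier
  mult[shrink] <- params$shrink_multiplier  # shrinkage overrides swelling

  cells$nucleus_area <- cells$nucleus_area * mult
  cells$cytoplasm_area <- cells$cytoplasm_area * mult
  cells <- cells[alive, , drop = FALSE]
  rownames(cells) <- NULL
  if (nrow(cells) == 0L) stop("injury removed every cell")

  out <- mosaic
  out$cells <- cells
  out$group <- group
  out$timepoint_days <- t
  out
}

in_superior_quadrant <- function(x, y, onh) {
  dx <- x - onh[1]; dy <- y - onh[2]
  # 90-degree sector centred on +y (superior after the load-time flip)
  dy > 0 & abs(dx) <= dy
}

#' Generate a synthetic cohort
#'
#' One independent healthy baseline per animal; injury applied per (group,
#' timepoint). Randomness is organised as one L'Ecuyer-CMRG stream per
#' retina, split deterministically from `seed`, so any retina's data is
#' reproducible regardless of generation order.
#'
#' @param healthy a [healthy_params()].
#' @param injury an [injury_params()] (used for every non-naive group).
#' @param design named list mapping group name to a vector of timepoints in
#'   days; repeats mean replicate animals, e.g.
#'   `list(naive = c(0, 0, 0), pONT = rep(c(3, 7, 21, 56), each = 2))`.
#' @param seed integer master seed.
#' @return An `rgc_cohort`.
#' @export
generate_cohort <- function(healthy, injury, design, seed = 1) {
  if (length(design) == 0) stop("empty design")
  if (is.null(names(design)) || any(names(design) == ""))
    stop("design must be a named list: group -> timepoints")
  bad <- setdiff(names(design), c("naive", "OHT", "pONT", "ONC"))
  if (length(bad))
    stop("unknown group(s) in design: ", paste(bad, collapse = ", "))
  plan <- do.call(rbind, lapply(names(design), function(g) {
    tp <- design[[g]]
    if (length(tp) < 1) stop("group '", g, "' has no timepoints")
    data.frame(group = g, timepoint = as.numeric(tp))
  }))
  plan$rep <- stats::ave(seq_len(nrow(plan)),
                         paste(plan$group, plan$timepoint), FUN = seq_along)

  old_kind <- RNGkind("L'Ecuyer-CMRG")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    RNGkind(old_kind[1])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed %% .Machine$integer.max)
  stream <- get(".Random.seed", .GlobalEnv)

  mosaics <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, .GlobalEnv)
    g <- plan$group[i]; tp <- plan$timepoint[i]
    id <- sprintf("%s_d%03d_r%02d", g, round(tp), plan$rep[i])
    base <- generate_healthy(healthy, seed = NULL, retina_id = id,
                             group = g, timepoint_days = 0)
    mosaics[[i]] <- if (g == "naive" || tp == 0) {
      base$timepoint_days <- tp
      base
    } else {
      apply_injury(base, injury, tp, seed = NULL,
                   cn_ratio_true = healthy$cn_ratio_true)
    }
  }
  cohort(mosaics)
}

#' Preset generator configurations
#'
#' Named presets bundling healthy parameters, injury parameters and a study
#' design emulating the rodent models: `"naive-rat"`, `"naive-mouse"`,
#' `"rat-oht"` (ocular hypertension; mild chronic loss, days 0/7/21/56/84),
#' `"rat-pont"` (partial optic nerve transection; severe, superior-biased,
#' days 0/3/7/21/56), `"mouse-onc"` (optic nerve crush, days 0/4/7).
#'
#' Injury hazards decrease with size bin (smaller RGCs are lost faster) and
#' the pONT preset carries a superior hazard multiplier tuned so about two
#' thirds of losses fall in the superior quadrant.
#'
#' @param name preset name.
#' @param n_replicates animals per (group, timepoint).
#' @return List with elements `healthy`, `injury`, `design`.
#' @export
mosaic_preset <- function(name = c("naive-rat", "naive-mouse", "rat-oht",
                                   "rat-pont", "mouse-onc"),
                          n_replicates = 3) {
  name <- match.arg(name)
  rat <- healthy_params()
  mouse <- healthy_params(retina_radius_mm = 2.1, onh_radius_mm = 0.25,
                          target_density = 3200, inhibition_radius_um = 8,
                          cn_ratio_true = 2.00)
  scheme <- binning_scheme()
  # hazard falls off with size: bin-1 half-life ~5 d, terminal ~70 d
  k_decr <- log(2) / seq(5, 70, length.out = scheme$n_bins)
  switch(name,
    "naive-rat" = list(healthy = rat, injury = NULL,
                       design = list(naive = rep(0, n_replicates))),
    "naive-mouse" = list(healthy = mouse, injury = NULL,
                         design = list(naive = rep(0, n_replicates))),
    "rat-oht" = list(
      healthy = rat,
      injury = injury_params(scheme, hazard_per_day = k_decr / 3,
                             plateau_fraction = 0.35,
                             swell_fraction = 0.08, swell_onset_day = 3,
                             swell_resolution_day = 21,
                             shrink_multiplier = 0.7, shrink_lead_days = 2),
      design = list(naive = rep(0, n_replicates),
                    OHT = rep(c(7, 21, 56, 84), each = n_replicates))),
    "rat-pont" = list(
      healthy = rat,
      injury = injury_params(scheme, hazard_per_day = k_decr,
                             plateau_fraction = 0.15,
                             swell_fraction = 0.15, swell_multiplier = 1.3,
                             swell_onset_day = 1, swell_resolution_day = 7,
                             shrink_multiplier = 0.7, shrink_lead_days = 2,
                             superior_hazard_multiplier = 2),
      design = list(naive = rep(0, n_replicates),
                    pONT = rep(c(3, 7, 21, 56), each = n_replicates))),
    "mouse-onc" = list(
      healthy = mouse,
      injury = injury_params(scheme, hazard_per_day = k_decr * 2,
                             plateau_fraction = 0.1),
      design = list(naive = rep(0, n_replicates),
                    ONC = rep(c(4, 7), each = n_replicates))))
}
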