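#' Default pipeline configuration
#'
#' Builds the configuration consumed by [run_pipeline()]. Stages run in
#' dependency order: `simulate` (synthetic cohort), then `cn_ratio`,
#' `distributions` and `stratify` on the simulated (or supplied) cohort,
#' then `decay` and `bootstrap`. Each stage's parameter block mirrors the
#' corresponding constructor's arguments. A single global seed deterministically
#' derives a per-stage seed (stage-name salted), so adding or removing one
#' stage never perturbs another stage's randomness.
#'
#' @param stages character vector of stages to run.
#' @param preset generator preset name for the `simulate` stage (see
#'   [mosaic_preset()]) or a list with elements `healthy`, `injury`,
#'   `design`.
#' @param n_replicates animals per (group, timepoint) in the simulation.
#' @param seed global seed.
#' @param scheme [binning_scheme()] shared by the size-based stages.
#' @param bootstrap a [bootstrap_config()] (its seed is overridden by the
#'   stage seed).
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("simulate", "cn_ratio", "distributions",
                                  "stratify", "decay", "bootstrap"),
                       preset = "rat-pont", n_replicates = 3, seed = 1,
                       scheme = binning_scheme(),
                       bootstrap = bootstrap_config(n_draws = 2000)) {
  known <- c("simulate", "cn_ratio", "distributions", "stratify", "decay",
             "bootstrap")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, preset = preset,
                 n_replicates = n_replicates, seed = seed, scheme = scheme,
                 bootstrap = bootstrap),
            class = "run_config")
}

stage_seed <- function(seed, stage) {
  # deterministic stage-salted 31-bit seed
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 7919 + h * 104729) %% 2147483647
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages on a synthetic cohort (or a user-supplied
#' one), writing CSV/JSON outputs under `out_dir` and returning a manifest
#' listing every output file with its MD5 content hash, the per-stage seeds
#' and wall-clock times. Re-running with the same configuration reproduces
#' identical hashes.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param chrt optional `rgc_cohort` to analyse instead of simulating one
#'   (the `simulate` stage is then skipped).
#' @return The manifest, invisibly also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("rgcrun"),
                         chrt = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(package_version = as.character(utils::packageVersion("rgcmosaic")),
                   seed = config$seed, stages = list(), files = list())
  scheme <- config$scheme

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    s <- stage_seed(config$seed, name)
    tic <- Sys.time()
    fun(s)
    manifest$stages[[name]] <<- list(
      seed = s, seconds = as.numeric(difftime(Sys.time(), tic, units = "secs")))
  }

  run_stage("simulate", function(s) {
    if (is.null(chrt)) {
      pre <- if (is.list(config$preset)) config$preset
      else mosaic_preset(config$preset, n_replicates = config$n_replicates)
      chrt <<- generate_cohort(pre$healthy, pre$injury, pre$design, seed = s)
    }
    write.csv(chrt$design, file.path(out_dir, "cohort_design.csv"),
              row.names = FALSE)
  })
  if (is.null(chrt)) stop("no cohort: include the 'simulate' stage or pass one")
  groups <- vapply(chrt$mosaics, function(m) m$group, character(1))
  injury <- setdiff(unique(groups), "naive")

  run_stage("cn_ratio", function(s) {
    rows <- lapply(chrt$mosaics, function(m) {
      r <- cn_ratio_for_mosaic(m)
      data.frame(retina_id = m$retina_id, group = m$group,
                 timepoint_days = m$timepoint_days,
                 mean_ratio = r$mean_ratio, mean_ratio_se = r$mean_ratio_se,
                 regression_slope = r$regression_slope,
                 spearman_rho = r$spearman$rho,
                 spearman_lo = r$spearman$ci[1],
                 spearman_hi = r$spearman$ci[2],
                 exclusion_fraction = r$exclusion_fraction)
    })
    write.csv(do.call(rbind, rows), file.path(out_dir, "cn_ratio.csv"),
              row.names = FALSE)
  })

  run_stage("distributions", function(s) {
    hists <- lapply(chrt$mosaics, bin_density_histogram, scheme = scheme)
    per <- do.call(rbind, lapply(hists, function(h)
      data.frame(retina_id = h$retina_id, group = h$group,
                 timepoint_days = h$timepoint_days,
                 bin = seq_len(scheme$n_bins),
                 bin_left = scheme$edges[-(scheme$n_bins + 1)],
                 bin_right = scheme$edges[-1], density = h$density)))
    write.csv(per, file.path(out_dir, "histograms.csv"), row.names = FALSE)

    naive_pdfs <- lapply(cohort_mosaics(chrt, group = "naive"),
                         pdf_from_mosaic, scheme = scheme)
    if (length(naive_pdfs) >= 2) {
      ref <- group_mean(naive_pdfs)
      diffs <- list()
      for (g in injury) {
        for (tp in setdiff(unique(vapply(
          cohort_mosaics(chrt, group = g), function(m) m$timepoint_days,
          numeric(1))), 0)) {
          ms <- cohort_mosaics(chrt, group = g, timepoint_days = tp)
          if (length(ms) < 2) next
          d <- pdf_difference(group_mean(
            lapply(ms, pdf_from_mosaic, scheme = scheme)), ref)
          diffs[[length(diffs) + 1]] <- data.frame(
            group = g, timepoint_days = tp, bin = seq_len(scheme$n_bins),
            difference = d$difference, se = d$se)
        }
      }
      if (length(diffs))
        write.csv(do.call(rbind, diffs),
                  file.path(out_dir, "pdf_differences.csv"),
                  row.names = FALSE)
    }
  })

  run_stage("stratify", function(s) {
    rows <- do.call(rbind, lapply(chrt$mosaics, function(m) {
      rings <- assign_rings(m)
      qs <- quadrant_split(m)
      sec <- data.frame(
        retina_id = m$retina_id,
        stratum = c("superior", "inferior"),
        n_cells = c(
          if (is.null(qs$superior)) 0L else
            sum(qs$superior$cells$channel == "brn3a"),
          if (is.null(qs$inferior)) 0L else
            sum(qs$inferior$cells$channel == "brn3a")))
      ring_tab <- table(rings[m$cells$channel == "brn3a"])
      rbind(sec, data.frame(retina_id = m$retina_id,
                            stratum = paste0("ring_", names(ring_tab)),
                            n_cells = as.integer(ring_tab)))
    }))
    write.csv(rows, file.path(out_dir, "strata_counts.csv"),
              row.names = FALSE)
    ecc <- do.call(rbind, lapply(chrt$mosaics, function(m) {
      r <- size_eccentricity_correlation(m)
      data.frame(retina_id = m$retina_id, group = m$group,
                 timepoint_days = m$timepoint_days, rho = r$rho,
                 ci_lo = r$ci[1], ci_hi = r$ci[2])
    }))
    write.csv(ecc, file.path(out_dir, "size_eccentricity.csv"),
              row.names = FALSE)
  })

  run_stage("decay", function(s) {
    if (length(injury)) {
      fits <- half_life_by_size_bin(chrt, scheme)
      write.csv(fits, file.path(out_dir, "decay_fits.csv"),
                row.names = FALSE)
    }
  })

  run_stage("bootstrap", function(s) {
    ref <- cohort_mosaics(chrt, group = "naive")
    for (g in injury) {
      cfg <- config$bootstrap
      cfg$seed <- s
      dis <- cohort_mosaics(chrt, group = g)
      dis <- dis[vapply(dis, function(m) m$timepoint_days, numeric(1)) > 0]
      if (!length(dis) || !length(ref)) next
      br <- run_bootstrap(ref, dis, cfg)
      base <- file.path(out_dir, paste0("bootstrap_", g))
      write.csv(br$differences, paste0(base, "_differences.csv"),
                row.names = FALSE)
      roc_pts <- do.call(rbind, lapply(names(br$roc), function(st)
        data.frame(statistic = st, fpr = br$roc[[st]]$fpr,
                   tpr = br$roc[[st]]$tpr)))
      write.csv(roc_pts, paste0(base, "_roc.csv"), row.names = FALSE)
      jsonlite::write_json(as.list(br$auc), paste0(base, "_auc.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest$files <- lapply(files, function(f)
    list(path = f,
         md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  names(manifest$files) <- files
  manifest$seconds_total <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
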