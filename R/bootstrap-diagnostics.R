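#' Spatial bootstrap configuration
#'
#' @param window_area_mm2 area of the square observation window (default
#'   0.5 mm^2, about an adaptive-optics ophthalmoscope field of view).
#' @param min_cells minimum analysis-channel cells a window must contain
#'   (default 100; rejects windows that fall mostly on background without
#'   biasing against severely depleted tissue).
#' @param n_draws windows per group (the reference study design uses
#'   100,000; smaller values are adequate for calibration work).
#' @param max_attempts_per_draw placement attempts before a draw fails.
#' @param min_retina_fraction optional lower bound on the mask coverage of a
#'   window (0 disables the filter; coverage is always recorded).
#' @param seed integer seed for [run_bootstrap()].
#' @return A `bootstrap_config`.
#' @export
bootstrap_config <- function(window_area_mm2 = 0.5, min_cells = 100,
                             n_draws = 100000, max_attempts_per_draw = 1000,
                             min_retina_fraction = 0, seed = NULL) {
  stopifnot(window_area_mm2 > 0, min_cells >= 1, n_draws >= 1,
            max_attempts_per_draw >= 1,
            min_retina_fraction >= 0, min_retina_fraction <= 1)
  structure(list(window_area_mm2 = window_area_mm2,
                 min_cells = as.integer(min_cells),
                 n_draws = as.integer(n_draws),
                 max_attempts_per_draw = as.integer(max_attempts_per_draw),
                 min_retina_fraction = min_retina_fraction, seed = seed),
            class = "bootstrap_config")
}

# Precomputed per-mosaic index for fast window queries: analysis-channel
# cells sorted by x.
window_index <- function(mosaic, channel = "brn3a") {
  cells <- mosaic$cells[mosaic$cells$channel == channel, , drop = FALSE]
  ord <- order(cells$x)
  s <- mosaic$um_per_px / UM_PER_MM
  list(x = cells$x[ord], y = cells$y[ord],
       area = cells$nucleus_area[ord],
       mask = mosaic$mask, s = s,
       W = ncol(mosaic$mask) * s, H = nrow(mosaic$mask) * s,
       retina_id = mosaic$retina_id)
}

#' Draw one observation window from a mosaic
#'
#' A square window of side `sqrt(window_area_mm2)` is placed uniformly at
#' random over the image (limits: image size minus window size) and redrawn
#' until it contains at least `min_cells` analysis-channel cells, up to
#' `max_attempts_per_draw` placements.
#'
#' @param mosaic a [retinal_mosaic()] (or a prebuilt internal index).
#' @param config a [bootstrap_config()].
#' @param channel analysis channel.
#' @return A `window_sample`: `x0`, `y0`, `side_mm`, `cells_x`, `cells_y`,
#'   `areas` (um^2), `n_cells`, `retina_fraction`, `retina_id`.
#' @export
sample_window <- function(mosaic, config = bootstrap_config(),
                          channel = "brn3a") {
  idx <- if (inherits(mosaic, "retinal_mosaic"))
    window_index(mosaic, channel) else mosaic
  side <- sqrt(config$window_area_mm2)
  if (side > idx$W || side > idx$H)
    stop("window does not fit inside the image bounds")
  for (att in seq_len(config$max_attempts_per_draw)) {
    x0 <- runif(1, 0, idx$W - side)
    y0 <- runif(1, 0, idx$H - side)
    lo <- findInterval(x0, idx$x) + 1L
    hi <- findInterval(x0 + side, idx$x)
    if (hi < lo + config$min_cells - 1L) next
    sel <- lo:hi
    keep <- idx$y[sel] >= y0 & idx$y[sel] < y0 + side
    n <- sum(keep)
    if (n < config$min_cells) next
    frac <- mask_fraction(idx, x0, y0, side)
    if (frac < config$min_retina_fraction) next
    sel <- sel[keep]
    return(structure(list(x0 = x0, y0 = y0, side_mm = side,
                          cells_x = idx$x[sel], cells_y = idx$y[sel],
                          areas = idx$area[sel], n_cells = n,
                          retina_fraction = frac,
                          retina_id = idx$retina_id),
                     class = "window_sample"))
  }
  stop(sprintf("no admissible window for retina '%s' after %d attempts",
               idx$retina_id, config$max_attempts_per_draw))
}

# fraction of the window's pixels lying inside the retina mask
mask_fraction <- function(idx, x0, y0, side) {
  s <- idx$s
  cols <- max(1L, floor(x0 / s) + 1L):min(ncol(idx$mask),
                                          ceiling((x0 + side) / s))
  # analysis frame y -> raster rows (flip)
  rows <- max(1L, floor((idx$H - y0 - side) / s) + 1L):
    min(nrow(idx$mask), ceiling((idx$H - y0) / s))
  mean(idx$mask[rows, cols])
}

#' Window statistics
#'
#' The four per-window measures: mean nearest-neighbour distance (NND, um;
#' neighbours are sought strictly within the window, with no edge
#' correction — the window emulates a bounded imaging field), regularity
#' index (RI = mean NND / sample SD of NND; about 1.91 for complete spatial
#' randomness, higher for regular mosaics), mean nucleus area (um^2) and the
#' mean absolute deviation (MAD) of nucleus area about its mean (um^2).
#'
#' @param sample a [sample_window()] result.
#' @return A `window_stats` list: `nnd_um`, `ri` (`NA` when the NND set has
#'   zero variance), `mean_area_um2`, `mad_area_um2`, `n_cells`,
#'   `retina_fraction`.
#' @export
window_statistics <- function(sample) {
  if (sample$n_cells < 2) stop("need at least 2 cells in the window")
  nn_mm <- nnd_cpp(sample$cells_x, sample$cells_y)
  nnd <- mean(nn_mm) * UM_PER_MM
  s <- sd(nn_mm) * UM_PER_MM
  ri <- if (s == 0) NA_real_ else nnd / s
  ma <- mean(sample$areas)
  structure(list(nnd_um = nnd, ri = ri, mean_area_um2 = ma,
                 mad_area_um2 = mean(abs(sample$areas - ma)),
                 n_cells = sample$n_cells,
                 retina_fraction = sample$retina_fraction),
            class = "window_stats")
}

bootstrap_statistics <- c("nnd_um", "ri", "mean_area_um2", "mad_area_um2")

draw_group <- function(mosaics, config, channel) {
  idxs <- lapply(mosaics, window_index, channel = channel)
  n <- config$n_draws
  out <- data.frame(draw = seq_len(n), retina_id = character(n),
                    nnd_um = numeric(n), ri = numeric(n),
                    mean_area_um2 = numeric(n), mad_area_um2 = numeric(n),
                    n_cells = integer(n), retina_fraction = numeric(n),
                    stringsAsFactors = FALSE)
  pick <- sample.int(length(idxs), n, replace = TRUE)
  for (i in seq_len(n)) {
    w <- sample_window(idxs[[pick[i]]], config, channel)
    st <- window_statistics(w)
    out$retina_id[i] <- w$retina_id
    out$nnd_um[i] <- st$nnd_um
    out$ri[i] <- st$ri
    out$mean_area_um2[i] <- st$mean_area_um2
    out$mad_area_um2[i] <- st$mad_area_um2
    out$n_cells[i] <- st$n_cells
    out$retina_fraction[i] <- st$retina_fraction
  }
  out
}

#' Run the spatial bootstrap diagnostic
#'
#' Per draw: a retina is sampled with replacement from the group, a window
#' is sampled from it, and the four window statistics are recorded;
#' `n_draws` draws are made for each group. Difference samples pair draw i
#' of the disease group with draw i of the reference group. For each
#' statistic a ROC curve treats disease draws as positives scored by the
#' statistic's value, and the AUC is the tie-corrected Mann-Whitney
#' probability `P(pos > neg) + P(pos = neg)/2`; because some statistics
#' decrease under disease, the reflection `max(AUC, 1 - AUC)` is reported
#' alongside as `discrimination`.
#'
#' @param reference_group,disease_group lists of [retinal_mosaic()] objects
#'   (e.g. from [cohort_mosaics()]).
#' @param config a [bootstrap_config()].
#' @param channel analysis channel.
#' @return A `bootstrap_result`: `reference`, `disease` (per-draw data
#'   frames), `differences` (disease - reference, index-paired), `roc`
#'   (per-statistic list with `fpr`, `tpr`, `auc`, `discrimination`) and
#'   `auc` (named vector).
#' @export
run_bootstrap <- function(reference_group, disease_group,
                          config = bootstrap_config(), channel = "brn3a") {
  if (length(reference_group) == 0 || length(disease_group) == 0)
    stop("both groups must contain at least one mosaic")
  if (!is.null(config$seed)) set.seed(config$seed)
  ref <- draw_group(reference_group, config, channel)
  dis <- draw_group(disease_group, config, channel)

  diffs <- as.data.frame(lapply(bootstrap_statistics, function(s)
    dis[[s]] - ref[[s]]))
  names(diffs) <- bootstrap_statistics

  roc <- lapply(bootstrap_statistics, function(s)
    roc_auc(dis[[s]], ref[[s]]))
  names(roc) <- bootstrap_statistics

  structure(list(reference = ref, disease = dis, differences = diffs,
                 roc = roc,
                 auc = vapply(roc, function(r) r$auc, numeric(1)),
                 config = config),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d draws per group\n", nrow(x$reference)))
  for (s in names(x$roc))
    cat(sprintf("  %-14s AUC = %.4f (discrimination %.4f)\n", s,
                x$roc[[s]]$auc, x$roc[[s]]$discrimination))
  invisible(x)
}

#' ROC curve and AUC from two score samples
#'
#' AUC is computed by midranks (`P(pos > neg) + P(pos = neg)/2`, the
#' Mann-Whitney U statistic normalised by `n_pos * n_neg`); the curve sweeps
#' thresholds over all observed score values, predicting positive for scores
#' at or above the threshold, and is anchored at (0,0) and (1,1). Since a
#' statistic may shift downwards under disease, `discrimination =
#' max(AUC, 1 - AUC)` is reported as the orientation-free separability.
#'
#' @param pos_scores,neg_scores numeric score vectors (`NA`s dropped).
#' @return List `fpr`, `tpr`, `auc`, `discrimination`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  pos <- pos_scores[!is.na(pos_scores)]
  neg <- neg_scores[!is.na(neg_scores)]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both score sets must be non-empty")
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg))  # midranks
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  sc <- c(pos, neg)
  lab <- rep(c(1L, 0L), c(np, nn))
  ord <- order(sc, decreasing = TRUE)
  sc <- sc[ord]; lab <- lab[ord]
  # one ROC vertex per distinct threshold: last index of each tied run
  cut <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tpr <- c(0, cumsum(lab)[cut] / np)
  fpr <- c(0, cumsum(1L - lab)[cut] / nn)
  list(fpr = fpr, tpr = tpr, auc = auc,
       discrimination = max(auc, 1 - auc), n_pos = np, n_neg = nn)
}
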