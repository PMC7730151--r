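#' Fit a one-phase exponential decay with plateau
#'
#' Fits `Y = (Y0 - P) * exp(-k * x) + P` to density observations by
#' constrained Levenberg-Marquardt least squares, where `Y0` is the density
#' at day 0, `P >= 0` the plateau the density decays to, and `k >= 0` the
#' rate constant; the half-life is `ln(2) / k`. The fit is parameterised as
#' `P = f * Y0` with `f` in \[0, 1\] so the constraint `0 <= P <= Y0` is a
#' box, and is restarted from three rate initialisations (the log-linear
#' slope of `Y - min(Y)` and that slope scaled by 1/3 and 3) keeping the
#' lowest residual sum of squares.
#'
#' @param x times, days (>= 0; must include day 0 observations and >= 3
#'   distinct timepoints).
#' @param y densities, cells/mm^2, same length.
#' @return A `decay_fit`: `Y0`, `P`, `k`, `half_life_days` (`NA` when
#'   `k = 0`), `rss`, `converged` (optimizer convergence), `identifiable`
#'   (`FALSE` when the data are non-decreasing and `k` is pinned at 0).
#' @export
fit_one_phase_decay <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (length(unique(x)) < 3) stop("need at least 3 distinct timepoints")
  if (!any(x == 0)) stop("missing baseline (day 0) observations")

  ybar <- tapply(y, x, mean)
  xs <- as.numeric(names(ybar))
  y0_init <- unname(ybar[which.min(xs)])
  p_init <- max(min(ybar), 0)

  # non-decreasing mean time-course: decay rate not identifiable
  if (ybar[which.min(xs)] <= min(ybar) + 1e-12 * max(ybar, 1) &&
      which.min(ybar) == which.min(xs)) {
    ybar_all <- mean(y)
    return(decay_fit_obj(Y0 = y0_init, P = ybar_all, k = 0,
                         rss = sum((y - ybar_all)^2),
                         converged = TRUE, identifiable = FALSE))
  }

  # log-linear slope of the excess over the plateau estimate
  excess <- pmax(ybar - 0.95 * p_init, 1e-9 * max(ybar))
  pos <- excess > 0
  k_init <- if (sum(pos) >= 2)
    max(1e-4, -unname(coef(lm(log(excess[pos]) ~ xs[pos]))[2])) else 0.05

  f_init <- if (y0_init > 0) min(0.999, p_init / y0_init) else 0.5
  resid_fn <- function(par)
    y - par[1] * ((1 - par[2]) * exp(-par[3] * x) + par[2])
  best <- NULL
  for (k0 in unique(c(k_init, k_init / 3, k_init * 3))) {
    fit <- try(minpack.lm::nls.lm(
      par = c(Y0 = max(y0_init, 1e-9), f = f_init, k = k0),
      lower = c(0, 0, 0), upper = c(Inf, 1, Inf), fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = .Machine$double.eps,
        ptol = .Machine$double.eps)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(decay_fit_obj(Y0 = y0_init, P = p_init, k = NA_real_,
                         rss = NA_real_, converged = FALSE,
                         identifiable = FALSE))
  cf <- best$par
  k <- unname(cf["k"])
  decay_fit_obj(Y0 = unname(cf["Y0"]), P = unname(cf["Y0"] * cf["f"]),
                k = k, rss = best$deviance,
                converged = best$info %in% 1:4,
                identifiable = k > 1e-8)
}

decay_fit_obj <- function(Y0, P, k, rss, converged, identifiable) {
  structure(list(Y0 = Y0, P = P, k = k,
                 half_life_days = if (!is.na(k) && k > 0) log(2) / k
                 else NA_real_,
                 rss = rss, converged = converged,
                 identifiable = identifiable),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "one-phase decay: Y0 = %.4g, P = %.4g, k = %.4g /day, t1/2 = %.4g d%s\n",
    x$Y0, x$P, x$k, x$half_life_days,
    if (!x$identifiable) " [non-identifiable]" else ""))
  invisible(x)
}

#' Half-life of each size bin's density time-course
#'
#' For each injury group in the cohort and each nucleus-area bin, collects
#' the per-retina bin density at every timepoint (pooled as independent
#' observations, with any naive mosaics contributing at day 0) and fits
#' [fit_one_phase_decay()]. Bins with no cells at any timepoint are skipped.
#'
#' @param chrt an `rgc_cohort`.
#' @param scheme a [binning_scheme()].
#' @param groups injury groups to fit (default: all non-naive groups
#'   present).
#' @return data.frame with one row per (group, bin): `group`, `bin`,
#'   `bin_left`, `bin_right`, `Y0`, `P`, `k`, `half_life_days`, `converged`,
#'   `identifiable`, `skipped`, `skip_reason`.
#' @export
half_life_by_size_bin <- function(chrt, scheme = binning_scheme(),
                                  groups = NULL) {
  all_groups <- vapply(chrt$mosaics, function(m) m$group, character(1))
  if (is.null(groups)) groups <- setdiff(unique(all_groups), "naive")
  out <- list()
  for (g in groups) {
    sel <- chrt$mosaics[all_groups %in% c(g, "naive")]
    # naive animals are baseline (day 0) observations for every group
    tp <- vapply(sel, function(m) m$timepoint_days, numeric(1))
    if (length(unique(tp)) < 3)
      stop("group '", g, "' has fewer than 3 distinct timepoints")
    if (!any(tp == 0)) stop("group '", g, "' lacks a baseline timepoint")
    hists <- lapply(sel, bin_density_histogram, scheme = scheme)
    dens <- vapply(hists, function(h) h$density, numeric(scheme$n_bins))
    for (b in seq_len(scheme$n_bins)) {
      row <- data.frame(group = g, bin = b,
                        bin_left = scheme$edges[b],
                        bin_right = scheme$edges[b + 1])
      if (all(dens[b, ] == 0)) {
        row <- cbind(row, Y0 = NA, P = NA, k = NA, half_life_days = NA,
                     converged = NA, identifiable = NA, skipped = TRUE,
                     skip_reason = "no cells")
      } else {
        f <- fit_one_phase_decay(tp, dens[b, ])
        row <- cbind(row, Y0 = f$Y0, P = f$P, k = f$k,
                     half_life_days = f$half_life_days,
                     converged = f$converged, identifiable = f$identifiable,
                     skipped = FALSE, skip_reason = "")
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
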