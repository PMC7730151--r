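#' Nucleus-area binning scheme
#'
#' Equal-width bins over nucleus area. The default is 25 bins of 9.52 um^2
#' starting at 0, spanning 0-238 um^2; its edges land (after rounding to
#' integers) on the band boundaries 57, 105, 133 and 143 um^2 used when
#' describing size-selective loss.
#'
#' @param n_bins number of bins.
#' @param bin_width_um2 bin width, um^2.
#' @param origin_um2 left edge of the first bin, um^2.
#' @return A `binning_scheme` with an `edges` vector of length `n_bins + 1`.
#' @export
binning_scheme <- function(n_bins = 25, bin_width_um2 = 9.52,
                           origin_um2 = 0) {
  stopifnot(n_bins >= 1, bin_width_um2 > 0)
  structure(list(n_bins = as.integer(n_bins), bin_width_um2 = bin_width_um2,
                 origin_um2 = origin_um2,
                 edges = origin_um2 + (0:n_bins) * bin_width_um2),
            class = "binning_scheme")
}

# bin index for areas: 1..n_bins in range, n_bins+1 overflow (including
# below-origin values, which cannot occur for positive areas with origin 0),
# NA for NA input
bin_index <- function(area, scheme) {
  i <- floor((area - scheme$origin_um2) / scheme$bin_width_um2) + 1
  i[!is.na(i) & (i < 1 | i > scheme$n_bins)] <- scheme$n_bins + 1
  as.integer(i)
}

same_scheme <- function(a, b) {
  isTRUE(all.equal(a$edges, b$edges, tolerance = 1e-12))
}

#' Size-binned density histogram of a mosaic
#'
#' Per-bin cell density: count of analysis-channel cells with nucleus area in
#' `[edge_b, edge_{b+1})` divided by the mask area. Cells at or above the
#' last edge are tallied separately as overflow and excluded from the bins.
#'
#' @param mosaic a [retinal_mosaic()].
#' @param scheme a [binning_scheme()].
#' @param channel analysis channel (default `"brn3a"`).
#' @return A `size_histogram`: `scheme`, `density` (cells/mm^2 per bin),
#'   `counts`, `overflow_count`, `mask_area_mm2`, plus the mosaic metadata.
#' @export
bin_density_histogram <- function(mosaic, scheme = binning_scheme(),
                                  channel = "brn3a") {
  area_mm2 <- mask_area(mosaic)
  a <- mosaic$cells$nucleus_area[mosaic$cells$channel == channel]
  idx <- bin_index(a, scheme)
  counts <- tabulate(idx, nbins = scheme$n_bins + 1L)
  structure(list(scheme = scheme,
                 density = counts[seq_len(scheme$n_bins)] / area_mm2,
                 counts = counts[seq_len(scheme$n_bins)],
                 overflow_count = counts[scheme$n_bins + 1L],
                 mask_area_mm2 = area_mm2,
                 retina_id = mosaic$retina_id, group = mosaic$group,
                 timepoint_days = mosaic$timepoint_days),
            class = "size_histogram")
}

#' Nucleus-area probability distribution function (PDF) of a mosaic
#'
#' The normalised size histogram: probability of observing a cell in each
#' nucleus-area bin, over in-range cells (overflow excluded).
#'
#' @inheritParams bin_density_histogram
#' @return A `size_pdf`: `scheme`, `probability` (sums to 1), `n_cells`,
#'   plus mosaic metadata.
#' @export
pdf_from_mosaic <- function(mosaic, scheme = binning_scheme(),
                            channel = "brn3a") {
  h <- bin_density_histogram(mosaic, scheme, channel)
  n <- sum(h$counts)
  if (n == 0) stop("no in-range cells: cannot form a PDF")
  structure(list(scheme = scheme, probability = h$counts / n, n_cells = n,
                 retina_id = h$retina_id, group = h$group,
                 timepoint_days = h$timepoint_days),
            class = "size_pdf")
}

values_of <- function(x) {
  if (inherits(x, "size_histogram")) x$density
  else if (inherits(x, "size_pdf")) x$probability
  else stop("expected size_histogram or size_pdf objects")
}

#' Per-bin group mean and standard error
#'
#' Averages size histograms or PDFs across retinas (the animal is the unit of
#' replication): per-bin arithmetic mean and standard error `sd / sqrt(n)`.
#'
#' @param xs list of `size_histogram` or `size_pdf` objects sharing one
#'   binning scheme.
#' @return A `group_mean`: `scheme`, `mean`, `se`, `n`.
#' @export
group_mean <- function(xs) {
  if (length(xs) < 2) stop("need at least 2 retinas to average")
  for (x in xs[-1])
    if (!same_scheme(x$scheme, xs[[1]]$scheme))
      stop("mixed binning schemes")
  m <- vapply(xs, values_of, numeric(xs[[1]]$scheme$n_bins))
  structure(list(scheme = xs[[1]]$scheme,
                 mean = rowMeans(m),
                 se = apply(m, 1, sd) / sqrt(length(xs)),
                 n = length(xs)),
            class = "group_mean")
}

#' Difference between two mean PDFs
#'
#' Per-bin `test - reference` with standard errors propagated in quadrature.
#' Because both inputs are normalised, the differences sum to zero.
#'
#' @param test,reference [group_mean()] objects (of PDFs) on one scheme.
#' @return A `pdf_difference`: `scheme`, `difference`, `se`.
#' @export
pdf_difference <- function(test, reference) {
  if (!same_scheme(test$scheme, reference$scheme))
    stop("mixed binning schemes")
  structure(list(scheme = test$scheme,
                 difference = test$mean - reference$mean,
                 se = sqrt(test$se^2 + reference$se^2)),
            class = "pdf_difference")
}

#' Per-bin two-group comparison with Bonferroni correction
#'
#' Welch two-sample t test per size bin of per-retina densities (or
#' probabilities), flagged significant where `p < alpha / n_bins`. This is a
#' per-bin stand-in for an omnibus two-way ANOVA with Bonferroni post hoc
#' tests; with one bin-wise contrast per bin the Bonferroni thresholds
#' coincide.
#'
#' @param group_a,group_b lists of `size_histogram` (or `size_pdf`) objects,
#'   >= 2 per group, one shared scheme.
#' @param alpha family-wise error rate.
#' @return data.frame with `bin`, `bin_left`, `bin_right`, `mean_a`,
#'   `mean_b`, `p_value` (`NA` where both groups are degenerate in a bin) and
#'   `significant`.
#' @export
per_bin_comparison <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 retinas per group")
  for (x in c(group_a, group_b))
    if (!same_scheme(x$scheme, group_a[[1]]$scheme))
      stop("mixed binning schemes")
  scheme <- group_a[[1]]$scheme
  a <- vapply(group_a, values_of, numeric(scheme$n_bins))
  b <- vapply(group_b, values_of, numeric(scheme$n_bins))
  thresh <- alpha / scheme$n_bins
  p <- vapply(seq_len(scheme$n_bins), function(i) {
    if (sd(a[i, ]) == 0 && sd(b[i, ]) == 0) return(NA_real_)
    t.test(a[i, ], b[i, ])$p.value
  }, numeric(1))
  data.frame(bin = seq_len(scheme$n_bins),
             bin_left = scheme$edges[-(scheme$n_bins + 1)],
             bin_right = scheme$edges[-1],
             mean_a = rowMeans(a), mean_b = rowMeans(b),
             p_value = p,
             significant = !is.na(p) & p < thresh)
}
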