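#' Construct a retinal mosaic
#'
#' A retinal mosaic is a marked point pattern of segmented cells together with
#' the binary wholemount mask, the optic nerve head (ONH) position and cohort
#' metadata. Coordinates are in mm in the analysis frame in which superior is
#' towards +y (rasters store rows top-down; [read_mosaic()] flips the y axis
#' at load so that all analyses share the superior = +y convention).
#'
#' @param cells data.frame with columns `cell_id`, `channel` (one of
#'   `"brn3a"`, `"rbpms"`, `"gfp"`), `x`, `y` (mm, analysis frame),
#'   `nucleus_area` (um^2; may be `NA` for rbpms-channel detections, whose
#'   measured area is cytoplasmic), `cytoplasm_area` (um^2 or `NA`).
#' @param mask logical matrix, `TRUE` = retina; rows are raster rows
#'   (top-down).
#' @param um_per_px raster scale, micrometres per pixel.
#' @param onh numeric length-2, ONH (x, y) in mm, analysis frame.
#' @param retina_id character scalar.
#' @param group one of `"naive"`, `"OHT"`, `"pONT"`, `"ONC"`.
#' @param timepoint_days days post induction (0 = baseline).
#' @param mask_policy what to do with cells on masked-out pixels:
#'   `"reject"` (drop with a warning, the default) or `"keep"`.
#'
#' @return An object of class `retinal_mosaic`.
#' @export
retinal_mosaic <- function(cells, mask, um_per_px, onh, retina_id = "retina",
                           group = c("naive", "OHT", "pONT", "ONC"),
                           timepoint_days = 0,
                           mask_policy = c("reject", "keep")) {
  group <- match.arg(group)
  mask_policy <- match.arg(mask_policy)
  stopifnot(is.matrix(mask), um_per_px > 0, length(onh) == 2,
            timepoint_days >= 0)
  cells <- validate_cells(cells)
  mask <- mask != 0
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask has no retina pixels (mask area would be 0)")

  inside <- cells_in_mask(cells, mask, um_per_px)
  if (mask_policy == "reject" && any(!inside)) {
    warning(sprintf("%d cell(s) on masked-out pixels rejected", sum(!inside)))
    cells <- cells[inside, , drop = FALSE]
    rownames(cells) <- NULL
  }
  if (nrow(cells) == 0L) stop("no cell lies inside the mask")

  structure(
    list(cells = cells, mask = mask, um_per_px = um_per_px,
         onh = as.numeric(onh), retina_id = as.character(retina_id),
         group = group, timepoint_days = as.numeric(timepoint_days)),
    class = "retinal_mosaic")
}

validate_cells <- function(cells) {
  req <- c("cell_id", "channel", "x", "y", "nucleus_area", "cytoplasm_area")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols))
    stop("cell table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!all(cells$channel %in% c("brn3a", "rbpms", "gfp")))
    stop("unknown channel value(s) in cell table")
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y)))
    stop("non-finite cell coordinates")
  nuc <- cells$channel != "rbpms"
  if (any(is.na(cells$nucleus_area[nuc])) ||
      any(cells$nucleus_area[nuc] <= 0, na.rm = TRUE))
    stop("validation error: nucleus_area must be positive for nuclear channels")
  if (any(cells$cytoplasm_area <= 0, na.rm = TRUE))
    stop("validation error: cytoplasm_area, when present, must be positive")
  as.data.frame(cells)
}

# Pixel containment test in the analysis (superior = +y) frame.
cells_in_mask <- function(cells, mask, um_per_px) {
  s <- um_per_px / UM_PER_MM
  H <- nrow(mask) * s
  col <- floor(cells$x / s) + 1L
  row <- floor((H - cells$y) / s) + 1L
  ok <- col >= 1L & col <= ncol(mask) & row >= 1L & row <= nrow(mask)
  inside <- ok
  inside[ok] <- mask[cbind(row[ok], col[ok])]
  inside
}

#' @export
print.retinal_mosaic <- function(x, ...) {
  cat(sprintf(
    "retinal_mosaic '%s' (%s, day %g): %d cells, mask %.2f mm^2, %.0f um/px\n",
    x$retina_id, x$group, x$timepoint_days, nrow(x$cells), mask_area(x),
    x$um_per_px))
  tab <- table(x$cells$channel)
  cat("  channels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Wholemount mask area
#'
#' Area of the binary retina mask: true-pixel count times the squared pixel
#' size.
#'
#' @param mosaic a [retinal_mosaic()].
#' @return Area in mm^2.
#' @export
mask_area <- function(mosaic) {
  n <- sum(mosaic$mask)
  if (n == 0L) stop("empty mask")
  n * (mosaic$um_per_px / UM_PER_MM)^2
}

#' Overall RGC density of a mosaic
#'
#' Count of cells of the analysis channel divided by the mask area.
#'
#' @param mosaic a [retinal_mosaic()].
#' @param channel marker channel to count (default `"brn3a"`, the nuclear
#'   pan-RGC label).
#' @return Density in cells/mm^2.
#' @export
overall_density <- function(mosaic, channel = "brn3a") {
  sum(mosaic$cells$channel == channel) / mask_area(mosaic)
}

# ---- I/O ---------------------------------------------------------------

#' Read a retinal mosaic from a cell table, mask raster and sidecar metadata
#'
#' The cell table is a CSV with header
#' `cell_id,channel,x_mm,y_mm,nucleus_area_um2,cytoplasm_area_um2` with
#' coordinates in the image frame (origin top-left, y downward); the y axis is
#' flipped at load so the returned mosaic uses superior = +y. The mask is a
#' single-channel PNG or PGM raster (nonzero = retina). Metadata is a YAML
#' sidecar with keys `um_per_px`, `onh_x_mm`, `onh_y_mm` (image frame),
#' `retina_id`, `group`, `timepoint_days`.
#'
#' @param cell_table_path path to the cell CSV.
#' @param mask_path path to the mask raster (`.png` or `.pgm`).
#' @param metadata_path path to the YAML sidecar.
#' @param mask_policy see [retinal_mosaic()].
#' @return A [retinal_mosaic()].
#' @export
read_mosaic <- function(cell_table_path, mask_path, metadata_path,
                        mask_policy = c("reject", "keep")) {
  meta <- yaml::read_yaml(metadata_path)
  for (k in c("um_per_px", "onh_x_mm", "onh_y_mm", "retina_id", "group",
              "timepoint_days"))
    if (is.null(meta[[k]])) stop("metadata missing key: ", k)
  if (meta$um_per_px <= 0) stop("um_per_px must be positive")

  mask <- read_mask(mask_path)
  H <- nrow(mask) * meta$um_per_px / UM_PER_MM

  tab <- read.csv(cell_table_path, stringsAsFactors = FALSE)
  req <- c("cell_id", "channel", "x_mm", "y_mm", "nucleus_area_um2",
           "cytoplasm_area_um2")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("cell table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  cells <- data.frame(
    cell_id = as.integer(tab$cell_id),
    channel = as.character(tab$channel),
    x = as.numeric(tab$x_mm),
    y = H - as.numeric(tab$y_mm),  # image frame -> superior = +y
    nucleus_area = as.numeric(tab$nucleus_area_um2),
    cytoplasm_area = as.numeric(tab$cytoplasm_area_um2),
    stringsAsFactors = FALSE)

  retinal_mosaic(cells, mask, meta$um_per_px,
                 onh = c(meta$onh_x_mm, H - meta$onh_y_mm),
                 retina_id = meta$retina_id, group = meta$group,
                 timepoint_days = meta$timepoint_days,
                 mask_policy = match.arg(mask_policy))
}

#' Write a retinal mosaic to a cell table, mask raster and metadata sidecar
#'
#' Inverse of [read_mosaic()]: coordinates are flipped back to the image frame
#' (y downward) on disk.
#'
#' @param mosaic a [retinal_mosaic()].
#' @param cell_table_path,mask_path,metadata_path output paths; the mask
#'   format follows the `mask_path` extension (`.png` or `.pgm`).
#' @return Invisibly, the three paths.
#' @export
write_mosaic <- function(mosaic, cell_table_path, mask_path, metadata_path) {
  H <- nrow(mosaic$mask) * mosaic$um_per_px / UM_PER_MM
  tab <- data.frame(
    cell_id = mosaic$cells$cell_id,
    channel = mosaic$cells$channel,
    x_mm = mosaic$cells$x,
    y_mm = H - mosaic$cells$y,
    nucleus_area_um2 = mosaic$cells$nucleus_area,
    cytoplasm_area_um2 = mosaic$cells$cytoplasm_area)
  write.csv(tab, cell_table_path, row.names = FALSE, na = "")
  write_mask(mosaic$mask, mask_path)
  meta <- list(um_per_px = mosaic$um_per_px,
               onh_x_mm = mosaic$onh[1], onh_y_mm = H - mosaic$onh[2],
               retina_id = mosaic$retina_id, group = mosaic$group,
               timepoint_days = mosaic$timepoint_days)
  yaml::write_yaml(meta, metadata_path, precision = 15)
  invisible(c(cell_table_path, mask_path, metadata_path))
}

read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    return(img > 0)
  }
  if (ext == "pgm") return(read_pgm(path) > 0)
  stop("unsupported mask format: .", ext)
}

write_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(mask * 1.0, path)
  } else if (ext == "pgm") {
    write_pgm(mask * 255L, path)
  } else stop("unsupported mask format: .", ext)
  invisible(path)
}

# Plain (P2) PGM: text-only raster, convenient for version-controlled
# fixtures.
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only plain (P2) PGM supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

# ---- cohorts -----------------------------------------------------------

#' Bundle mosaics into a cohort
#'
#' @param mosaics list of [retinal_mosaic()] objects with unique `retina_id`s.
#' @return An object of class `rgc_cohort` with a `design` table
#'   (group x timepoint x n).
#' @export
cohort <- function(mosaics) {
  stopifnot(length(mosaics) >= 1)
  ids <- vapply(mosaics, function(m) m$retina_id, character(1))
  if (anyDuplicated(ids)) stop("retina_id values must be unique")
  design <- as.data.frame(table(
    group = vapply(mosaics, function(m) m$group, character(1)),
    timepoint_days = vapply(mosaics, function(m) m$timepoint_days, numeric(1))),
    responseName = "n")
  design <- design[design$n > 0, , drop = FALSE]
  design$timepoint_days <- as.numeric(as.character(design$timepoint_days))
  rownames(design) <- NULL
  structure(list(mosaics = mosaics, design = design), class = "rgc_cohort")
}

#' @export
print.rgc_cohort <- function(x, ...) {
  cat(sprintf("rgc_cohort: %d mosaics\n", length(x$mosaics)))
  print(x$design)
  invisible(x)
}

#' Subset a cohort by group and/or timepoint
#'
#' @param x an `rgc_cohort`.
#' @param group,timepoint_days optional filters.
#' @return List of matching mosaics.
#' @export
cohort_mosaics <- function(x, group = NULL, timepoint_days = NULL) {
  keep <- rep(TRUE, length(x$mosaics))
  if (!is.null(group))
    keep <- keep & vapply(x$mosaics, function(m) m$group, character(1)) %in% group
  if (!is.null(timepoint_days))
    keep <- keep & vapply(x$mosaics, function(m) m$timepoint_days,
                          numeric(1)) %in% timepoint_days
  x$mosaics[keep]
}
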