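# Cell and nucleus segmentation producing the geometry the ring analysis
# needs. Coordinates are 0-based (row, col) with pixel centers at integer
# positions; areas are pixel counts (and um^2 when pixel size is known).

#' Construct a CellGeometry
#'
#' Bundles the cell mask, nucleus mask and nucleus centroid for one
#' segmented cell, enforcing the geometric invariants the ring partition
#' relies on: the nucleus lies inside the cell, the centroid lies inside
#' the cell mask, and the cell mask is a single connected component.
#'
#' @param cell_mask logical matrix.
#' @param nucleus_mask logical matrix, same shape.
#' @param pixel_size micrometres per pixel (`NA` = unknown).
#' @return object of class `CellGeometry` with fields `cell_mask`,
#'   `nucleus_mask`, `centroid` (0-based `(row, col)`), `cell_area` (px^2)
#'   and `pixel_size`.
#' @export
cell_geometry <- function(cell_mask, nucleus_mask, pixel_size = NA_real_) {
  cell_mask <- cell_mask != 0
  nucleus_mask <- nucleus_mask != 0
  if (!identical(dim(cell_mask), dim(nucleus_mask)))
    stop("cell and nucleus masks must have identical shapes", call. = FALSE)
  if (!any(cell_mask)) stop("cell mask is empty", call. = FALSE)
  if (!any(nucleus_mask)) stop("nucleus mask is empty", call. = FALSE)
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus mask extends outside the cell mask", call. = FALSE)
  lab <- label_components(cell_mask, 8)
  if (max(lab) > 1)
    stop("cell mask must be a single connected component (found ",
         max(lab), ")", call. = FALSE)
  centroid <- mask_centroid(nucleus_mask)
  ci <- round(centroid) + 1
  if (!cell_mask[ci[1], ci[2]])
    stop("nucleus centroid does not lie inside the cell mask", call. = FALSE)
  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 centroid = centroid, cell_area = sum(cell_mask),
                 pixel_size = as.numeric(pixel_size)),
            class = "CellGeometry")
}

#' @export
print.CellGeometry <- function(x, ...) {
  cat(sprintf(paste0("CellGeometry: cell %d px^2, nucleus %d px^2, ",
                     "centroid (%.1f, %.1f)\n"),
              x$cell_area, sum(x$nucleus_mask), x$centroid[1], x$centroid[2]))
  invisible(x)
}

# intensity-unweighted center of mass, 0-based (row, col)
mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
}

largest_component <- function(mask) {
  lab <- label_components(mask, 8)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0], max(lab))
  lab == which.max(sizes)
}

#' Segment the nucleus from a DNA-stain channel
#'
#' Otsu threshold on a 3x3 median-filtered image, hole filling, one
#' morphological closing (disk, radius 2 px), then the largest connected
#' component. The centroid is the unweighted center of mass of the mask.
#'
#' @param dapi numeric matrix, the nuclear-stain channel.
#' @return list with `mask` (logical matrix) and `centroid`
#'   (0-based `(row, col)`).
#' @export
segment_nucleus <- function(dapi) {
  dapi <- as_image_matrix(dapi)
  sm <- median_filter3(dapi)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask))
    stop("nucleus segmentation found no foreground pixels", call. = FALSE)
  mask <- binary_close(fill_holes(mask), se_disk(2))
  mask <- largest_component(mask)
  if (!any(mask))
    stop("nucleus segmentation found no foreground pixels", call. = FALSE)
  list(mask = mask, centroid = mask_centroid(mask))
}

#' Segment the cell from a tracer channel
#'
#' Otsu threshold on a 3x3 median-filtered tracer image; keeps the
#' above-threshold connected component containing the nucleus, fills holes
#' and unions the nucleus in, so `nucleus_mask` is always contained in the
#' returned mask. An automatic stand-in for manual cell outlining,
#' validated on synthetic scenes.
#'
#' @param tracer numeric matrix, cell-fill channel.
#' @param nucleus_mask logical matrix from [segment_nucleus()].
#' @return logical cell mask.
#' @export
segment_cell <- function(tracer, nucleus_mask) {
  tracer <- as_image_matrix(tracer)
  nucleus_mask <- nucleus_mask != 0
  if (!identical(dim(tracer), dim(nucleus_mask)))
    stop("tracer image and nucleus mask shapes differ", call. = FALSE)
  sm <- median_filter3(tracer)
  thr <- otsu_threshold(sm)
  fg <- binary_close(fill_holes(sm > thr), se_disk(2))
  lab <- label_components(fg, 8)
  overlap <- lab[nucleus_mask]
  overlap <- overlap[overlap > 0]
  if (length(overlap) == 0)
    stop("no foreground component contains the nucleus", call. = FALSE)
  keep <- as.integer(names(which.max(table(overlap))))
  fill_holes(lab == keep | nucleus_mask)
}

#' Build a CellGeometry from manually drawn masks
#'
#' Mask images use the 0 = background / nonzero = foreground convention.
#' A nucleus that slightly overhangs the cell (<= 10% of its area) is
#' clipped with a warning; larger overhangs are an error.
#'
#' @param cell_mask logical/numeric matrix or path to a mask TIFF.
#' @param nucleus_mask same, identical shape.
#' @param pixel_size micrometres per pixel.
#' @return a `CellGeometry`.
#' @export
load_manual_masks <- function(cell_mask, nucleus_mask, pixel_size = NA_real_) {
  cell_mask <- as_mask(cell_mask)
  nucleus_mask <- as_mask(nucleus_mask)
  if (!identical(dim(cell_mask), dim(nucleus_mask)))
    stop("cell and nucleus masks must have identical shapes", call. = FALSE)
  if (!any(cell_mask)) stop("cell mask is empty", call. = FALSE)
  if (!any(nucleus_mask)) stop("nucleus mask is empty", call. = FALSE)
  n_total <- sum(nucleus_mask)
  clipped <- nucleus_mask & cell_mask
  n_out <- n_total - sum(clipped)
  if (sum(clipped) == 0)
    stop("nucleus mask lies entirely outside the cell mask", call. = FALSE)
  if (n_out > 0.10 * n_total)
    stop(sprintf("nucleus extends %.0f%% outside the cell (max 10%%)",
                 100 * n_out / n_total), call. = FALSE)
  if (n_out > 0)
    aq_log("load_manual_masks",
           "clipped %d/%d nucleus pixels outside the cell", n_out, n_total,
           level = "WARN")
  cell_geometry(cell_mask, clipped, pixel_size)
}

as_mask <- function(x) {
  if (is.character(x)) {
    st <- read_stack(x)
    x <- get_channel(st, 1)
  }
  as_image_matrix(x) != 0
}

#' Write a binary mask as an 8-bit TIFF (0 background, 255 foreground)
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_tiff((mask != 0) * 255, path, bits = 8)
}
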