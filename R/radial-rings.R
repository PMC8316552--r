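# Equal-area concentric-ring partition of a segmented cell and the
# per-ring normalized intensity-density profile. This is the package's
# core computation: each cell is divided into K (default 4) concentric
# rings of equal area whose boundaries are uniform scalings of the cell
# boundary about the nucleus centroid; the marker intensity density per
# ring is then normalized to the whole-cell intensity density.

#' Partition a cell into concentric equal-area rings
#'
#' Ring boundaries are uniformly scaled copies of the cell boundary about
#' the nucleus centroid. Because a scaled copy of a non-convex cell about
#' an off-center point need not nest inside the cell, each scaled region is
#' intersected with the cell mask and the scale factors are solved
#' numerically (bisection on the scale, areas measured by pixel counting)
#' so that every ring holds `1/K` of the cell area to within `area_tol`.
#' Ring 1 is the outermost (peripheral) ring, ring `K` the innermost
#' (perinuclear); pixels on a boundary go to the innermost ring whose
#' scaled region contains them.
#'
#' @param geometry a [cell_geometry()].
#' @param n_rings number of rings K (default 4).
#' @param area_tol relative tolerance on each ring's area (default 0.02).
#' @param max_iter bisection iterations per boundary (default 100).
#' @return object of class `RingPartition`: `labels` (integer matrix, 0 =
#'   outside cell, 1..K rings), `n_rings`, `scales` (K-1 boundary scale
#'   factors, decreasing), `areas` (px^2 per ring), `cell_area`,
#'   `centroid`, `pixel_size`.
#' @export
compute_ring_partition <- function(geometry, n_rings = 4, area_tol = 0.02,
                                   max_iter = 100) {
  stopifnot(inherits(geometry, "CellGeometry"))
  K <- as.integer(n_rings)
  if (K < 2) stop("`n_rings` must be >= 2", call. = FALSE)
  mask <- geometry$cell_mask
  p <- geometry$centroid
  A <- geometry$cell_area
  idx <- which(mask, arr.ind = TRUE)
  r0 <- idx[, 1] - 1  # 0-based coordinates of cell pixels
  c0 <- idx[, 2] - 1
  nr <- nrow(mask); nc <- ncol(mask)

  # pixels of the cell whose preimage under scaling by s about p is in the
  # cell mask, i.e. membership in the s-scaled copy of the cell boundary
  scaled_member <- function(s) {
    pr <- round(p[1] + (r0 - p[1]) / s) + 1
    pc <- round(p[2] + (c0 - p[2]) / s) + 1
    ok <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
    member <- logical(length(r0))
    member[ok] <- mask[cbind(pr[ok], pc[ok])]
    member
  }

  # solve area(region(s)) = target by bisection; area is monotone in s up
  # to pixel-rounding jitter, which the area tolerance absorbs
  tol_px <- area_tol * A / K / 2
  solve_scale <- function(target) {
    lo <- 1e-3; hi <- 1
    s <- NA_real_
    for (i in seq_len(max_iter)) {
      s <- (lo + hi) / 2
      a <- sum(scaled_member(s))
      if (abs(a - target) <= tol_px) return(s)
      if (a > target) hi <- s else lo <- s
    }
    s
  }

  scales <- numeric(K - 1)
  inner <- matrix(0L, length(r0), K - 1)
  for (k in seq_len(K - 1)) {
    target <- (K - k) / K * A
    scales[k] <- solve_scale(target)
    inner[, k] <- scaled_member(scales[k])
  }
  # label = 1 + number of boundary regions containing the pixel
  # (innermost-containing-region rule; ring 1 touches the cell boundary)
  lab_vec <- 1L + as.integer(rowSums(inner))
  labels <- matrix(0L, nr, nc)
  labels[idx] <- lab_vec

  areas <- tabulate(lab_vec, K)
  rel_err <- abs(areas - A / K) / (A / K)
  if (max(rel_err) > area_tol)
    stop(sprintf(paste0("equal-area solver did not converge: ring areas ",
                        "(%s) px^2 vs target %.1f px^2 (tolerance %.1f%%)"),
                 paste(areas, collapse = ", "), A / K, 100 * area_tol),
         call. = FALSE)

  structure(list(labels = labels, n_rings = K, scales = scales,
                 areas = as.numeric(areas), cell_area = A,
                 centroid = p, pixel_size = geometry$pixel_size),
            class = "RingPartition")
}

#' @export
print.RingPartition <- function(x, ...) {
  cat(sprintf("RingPartition: %d rings, cell %d px^2\n  scales: %s\n  areas: %s\n",
              x$n_rings, x$cell_area,
              paste(sprintf("%.4f", x$scales), collapse = ", "),
              paste(x$areas, collapse = ", ")))
  invisible(x)
}

#' Per-ring intensity-density profile of one cell
#'
#' For each ring k of the partition: integrated intensity `I`, area `A`
#' (px^2), density `d = I / A`, normalized density `n = d / d_cell` where
#' `d_cell` is the whole-cell intensity density (uniform staining gives
#' `n = 1` in every ring), and intensity fraction `f = I / sum(I)`.
#'
#' @param image numeric matrix, a (background-subtracted) marker channel.
#' @param partition a [compute_ring_partition()] result.
#' @param cell_id identifier recorded in the output.
#' @param condition condition label recorded in the output.
#' @return a `RadialProfile` data frame with one row per ring and columns
#'   `cell`, `condition`, `ring`, `I`, `A`, `d`, `n`, `f`.
#' @export
ring_intensity_profile <- function(image, partition, cell_id = "cell1",
                                   condition = "none") {
  stopifnot(inherits(partition, "RingPartition"))
  image <- as_image_matrix(image)
  if (!identical(dim(image), dim(partition$labels)))
    stop("image and partition shapes differ", call. = FALSE)
  if (any(image < 0))
    stop("image has negative intensities; subtract background first",
         call. = FALSE)
  K <- partition$n_rings
  I <- vapply(seq_len(K), function(k) sum(image[partition$labels == k]),
              numeric(1))
  if (sum(I) <= 0)
    stop("cell has zero total intensity", call. = FALSE)
  A <- partition$areas
  d <- I / A
  d_cell <- sum(I) / sum(A)
  out <- data.frame(cell = cell_id, condition = condition, ring = seq_len(K),
                    I = I, A = A, d = d, n = d / d_cell, f = I / sum(I),
                    stringsAsFactors = FALSE)
  class(out) <- c("RadialProfile", "data.frame")
  out
}

#' Aggregate radial profiles per condition
#'
#' Per condition and ring: mean, SEM (`sd/sqrt(n)`) and n of the
#' normalized density and of the intensity fraction. Logs a warning when a
#' condition holds fewer than 30 cells (the recommended minimum for this
#' assay).
#'
#' @param profiles a list of `RadialProfile` data frames, or one data
#'   frame with the same columns.
#' @return data frame with columns `condition`, `ring`, `n_mean`, `n_sem`,
#'   `f_mean`, `f_sem`, `n_cells`.
#' @export
aggregate_profiles <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  if (length(profiles) == 0) stop("no profiles to aggregate", call. = FALSE)
  all <- do.call(rbind, lapply(profiles, as.data.frame))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- do.call(rbind, lapply(split(all, list(all$condition, all$ring),
                                     drop = TRUE), function(g) {
    data.frame(condition = g$condition[1], ring = g$ring[1],
               n_mean = mean(g$n), n_sem = sem(g$n),
               f_mean = mean(g$f), f_sem = sem(g$f),
               n_cells = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$condition, out$ring), ]
  rownames(out) <- NULL
  for (cond in unique(out$condition)) {
    n <- out$n_cells[out$condition == cond][1]
    if (n < 30)
      aq_log("aggregate_profiles",
             "condition '%s' has only %d cells (fewer than the recommended 30)",
             cond, n, level = "WARN")
  }
  out
}

#' Full ring analysis of one multi-channel cell image
#'
#' Convenience wrapper: maximum-intensity projection, nucleus and cell
#' segmentation (or supplied manual masks), rolling-ball background
#' subtraction of the marker channel, equal-area ring partition and the
#' radial profile.
#'
#' @param stack an `ImageStack` with `dapi`, `marker` and `tracer`
#'   channels (names configurable).
#' @param config run configuration, see [default_config()].
#' @param geometry optional pre-computed [cell_geometry()] (manual masks);
#'   when given, segmentation is skipped.
#' @param channels named character vector mapping roles to channel names.
#' @param cell_id,condition labels for the output rows.
#' @return list with `profile` (a `RadialProfile`), `partition`,
#'   `geometry`.
#' @export
analyze_cell_rings <- function(stack, config = default_config(),
                               geometry = NULL,
                               channels = c(dapi = "dapi", marker = "marker",
                                            tracer = "tracer"),
                               cell_id = "cell1", condition = "none") {
  stopifnot(inherits(stack, "ImageStack"))
  if (dim(stack$data)[2] > 1) stack <- max_intensity_projection(stack)
  if (is.null(geometry)) {
    nuc <- segment_nucleus(get_channel(stack, channels[["dapi"]]))
    cell <- segment_cell(get_channel(stack, channels[["tracer"]]), nuc$mask)
    geometry <- cell_geometry(cell, nuc$mask, stack$pixel_size)
  }
  marker <- get_channel(stack, channels[["marker"]])
  if (isTRUE(config$rings$subtract_background))
    marker <- rolling_ball_subtract(marker, config$rings$rolling_ball_radius)
  part <- compute_ring_partition(geometry, config$rings$n_rings,
                                 config$rings$area_tol)
  prof <- ring_intensity_profile(marker, part, cell_id, condition)
  aq_log("rings", "cell %s: areas = %s px^2, n = %s", cell_id,
         paste(part$areas, collapse = "/"),
         paste(sprintf("%.3f", prof$n), collapse = "/"))
  list(profile = prof, partition = part, geometry = geometry)
}
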