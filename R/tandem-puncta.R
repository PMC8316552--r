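# Punctum detection (Laplacian-of-Gaussian) and tandem-reporter scoring.
# mCherry-positive puncta = total autophagic vacuoles (AV); puncta
# positive for both GFP and mCherry = autophagosomes (APG); mCherry-only
# puncta = autolysosomes (AL), the flux readout, since the acidic
# autolysosome lumen quenches GFP.

#' Detect fluorescent puncta
#'
#' Local maxima of the scale-normalized Laplacian-of-Gaussian response at
#' scale `sigma` that exceed `threshold` times the maximum response, with
#' a minimum separation of `2 * sigma` between detections (the strongest
#' of a close pair is kept; exact ties go to the smallest `(row, col)`).
#' Centers are refined to sub-pixel precision by a parabolic fit to the
#' response.
#'
#' @param image numeric matrix.
#' @param sigma detection scale in px (approximately the spot Gaussian
#'   width).
#' @param threshold relative threshold in (0, 1].
#' @return data frame with columns `row`, `col` (0-based, sub-pixel),
#'   `scale`, `response`, `peak` (image value at the detection).
#' @export
detect_puncta <- function(image, sigma = 2, threshold = 0.1) {
  image <- as_image_matrix(image)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be > 0", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  resp <- log_response(image, sigma)
  mx <- max(resp)
  empty <- data.frame(row = numeric(), col = numeric(), scale = numeric(),
                      response = numeric(), peak = numeric())
  if (!is.finite(mx) || mx <= 0) return(empty)
  peaks <- cpp_local_maxima(resp, as.integer(ceiling(2 * sigma)),
                            threshold * mx)
  if (nrow(peaks) == 0) return(empty)
  refine <- function(r, c) {
    # 1-D parabolic interpolation in each axis on the response
    out <- c(r, c)
    if (r > 0 && r < nrow(resp) - 1) {
      v <- resp[r:(r + 2), c + 1]
      den <- v[1] - 2 * v[2] + v[3]
      if (den < 0) out[1] <- r + 0.5 * (v[1] - v[3]) / den
    }
    if (c > 0 && c < ncol(resp) - 1) {
      v <- resp[r + 1, c:(c + 2)]
      den <- v[1] - 2 * v[2] + v[3]
      if (den < 0) out[2] <- c + 0.5 * (v[1] - v[3]) / den
    }
    out
  }
  centers <- t(apply(peaks, 1, function(rc) refine(rc[1], rc[2])))
  out <- data.frame(row = centers[, 1], col = centers[, 2], scale = sigma,
                    response = resp[peaks + 1L],
                    peak = image[peaks + 1L])
  out[order(out$row, out$col), , drop = FALSE]
}

#' Classify tandem-reporter puncta into autophagosomes and autolysosomes
#'
#' Greedy nearest-pair matching of red (mCherry) to green (GFP) puncta
#' within `match_radius`, each green punctum used at most once. Matched
#' red puncta are scored as autophagosomes (APG), unmatched red puncta as
#' autolysosomes (AL); the total AV count is the number of red puncta.
#' Green-only puncta are not counted (their number is logged). Inputs are
#' sorted by `(row, col)` first so the greedy order is deterministic.
#'
#' @param red data frame of red-channel detections (`row`, `col`).
#' @param green data frame of green-channel detections.
#' @param match_radius maximum center distance in px for a red-green pair.
#' @param cell_id identifier recorded in the output.
#' @return one-row data frame of class `PunctaSummary`: `cell`, `AV`,
#'   `APG`, `AL`, `match_radius`.
#' @export
classify_tandem <- function(red, green, match_radius = 4, cell_id = "cell1") {
  if (!is.numeric(match_radius) || match_radius <= 0)
    stop("`match_radius` must be > 0", call. = FALSE)
  n_red <- NROW(red); n_green <- NROW(green)
  apg <- 0L
  if (n_red > 0 && n_green > 0) {
    red <- red[order(red$row, red$col), , drop = FALSE]
    green <- green[order(green$row, green$col), , drop = FALSE]
    d <- outer(red$row, green$row, `-`)^2 + outer(red$col, green$col, `-`)^2
    d <- sqrt(d)
    d[d > match_radius] <- Inf
    # greedy globally-nearest pairs: repeatedly take the smallest distance
    while (any(is.finite(d))) {
      k <- which.min(d)  # ties: first in column-major order (deterministic)
      i <- (k - 1) %% n_red + 1
      j <- (k - 1) %/% n_red + 1
      apg <- apg + 1L
      d[i, ] <- Inf
      d[, j] <- Inf
    }
  }
  green_only <- n_green - apg
  if (green_only > 0)
    aq_log("classify_tandem", "%d green-only puncta ignored (cell %s)",
           green_only, cell_id, level = "DEBUG")
  out <- data.frame(cell = cell_id, AV = n_red, APG = apg,
                    AL = n_red - apg, match_radius = match_radius,
                    stringsAsFactors = FALSE)
  class(out) <- c("PunctaSummary", "data.frame")
  out
}

#' Analyze one tandem-reporter scene
#'
#' Detects puncta in the red and green channels (after rolling-ball
#' background subtraction) and classifies them. With `green_mode =
#' "intensity"`, GFP-positivity is instead decided by the green intensity
#' at each red punctum exceeding `green_thresh` times the brightest green
#' reading among red puncta.
#'
#' @param stack two-channel `ImageStack` (`red`, `green`).
#' @param config run configuration (see [default_config()]).
#' @param cell_id identifier for the output.
#' @return list with `summary` (a `PunctaSummary`), `red`, `green`
#'   (detection tables).
#' @export
analyze_tandem_scene <- function(stack, config = default_config(),
                                 cell_id = "cell1") {
  stopifnot(inherits(stack, "ImageStack"))
  if (dim(stack$data)[2] > 1) stack <- max_intensity_projection(stack)
  pc <- config$puncta
  r <- if (isTRUE(config$rings$subtract_background))
    config$rings$rolling_ball_radius else NA
  prep <- function(img) if (is.na(r)) img else rolling_ball_subtract(img, r)
  red_img <- prep(get_channel(stack, "red"))
  green_img <- prep(get_channel(stack, "green"))
  red <- detect_puncta(red_img, pc$sigma, pc$threshold)
  radius <- if (is.na(pc$match_radius)) 2 * pc$sigma else pc$match_radius
  if (identical(pc$green_mode, "intensity")) {
    n_red <- nrow(red)
    apg <- 0L
    if (n_red > 0) {
      vals <- green_img[cbind(pmin(nrow(green_img), round(red$row) + 1),
                              pmin(ncol(green_img), round(red$col) + 1))]
      apg <- sum(vals > pc$green_thresh * max(vals))
    }
    summary <- data.frame(cell = cell_id, AV = n_red, APG = as.integer(apg),
                          AL = n_red - as.integer(apg),
                          match_radius = NA_real_, stringsAsFactors = FALSE)
    class(summary) <- c("PunctaSummary", "data.frame")
    green <- NULL
  } else {
    green <- detect_puncta(green_img, pc$sigma, pc$threshold)
    summary <- classify_tandem(red, green, radius, cell_id)
  }
  list(summary = summary, red = red, green = green)
}

#' Summarize autophagic flux across cells
#'
#' Per condition: mean, SEM and n of the AV, APG and AL counts, plus the
#' flux readout (mean autolysosomes per cell) and the mean APG/AV
#' fraction.
#'
#' @param summaries list of `PunctaSummary` rows (or one combined data
#'   frame) with a `condition` column, or a single condition label via
#'   `condition`.
#' @param condition fallback condition label if the tables carry none.
#' @return data frame with one row per condition.
#' @export
summarize_flux <- function(summaries, condition = "none") {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  if (length(summaries) == 0) stop("no puncta summaries given", call. = FALSE)
  all <- do.call(rbind, lapply(summaries, as.data.frame))
  if (is.null(all$condition)) all$condition <- condition
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  out <- do.call(rbind, lapply(split(all, all$condition), function(g) {
    data.frame(condition = g$condition[1], n_cells = nrow(g),
               AV_mean = mean(g$AV), AV_sem = sem(g$AV),
               APG_mean = mean(g$APG), APG_sem = sem(g$APG),
               AL_mean = mean(g$AL), AL_sem = sem(g$AL),
               flux = mean(g$AL),
               apg_fraction = mean(ifelse(g$AV > 0, g$APG / g$AV, NA),
                                   na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
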