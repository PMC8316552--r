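#' @useDynLib autoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Structuring elements -------------------------------------------------

# Offsets and heights of a structuring element. Flat disk: h = 0 inside
# radius. Ball: hemisphere heights sqrt(r^2 - d^2), the classic rolling-ball
# (paraboloid-equivalent) element for background estimation.
se_disk <- function(radius, flat = TRUE) {
  stopifnot(radius >= 1)
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- g$dr^2 + g$dc^2
  keep <- d2 <= radius^2
  h <- if (flat) rep(0, sum(keep)) else sqrt(radius^2 - d2[keep])
  list(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]), h = h)
}

gray_erode <- function(img, se) cpp_gray_erode(img, se$dr, se$dc, se$h)
gray_dilate <- function(img, se) cpp_gray_dilate(img, se$dr, se$dc, se$h)

gray_open <- function(img, se) gray_dilate(gray_erode(img, se), se)

## Rolling-ball background subtraction ----------------------------------

#' Rolling-ball background subtraction
#'
#' Estimates the image background as the grayscale morphological opening of
#' the image by a ball-shaped (hemispherical) structuring element of the
#' given radius, and subtracts it. This flattens slow illumination
#' gradients while leaving features smaller than the ball (such as
#' fluorescent puncta) intact. Output is clipped at zero.
#'
#' @param img numeric matrix, a single-channel 2-D image.
#' @param radius ball radius in pixels (default 30).
#' @return numeric matrix of the same shape, `img - background`, clipped
#'   at 0.
#' @export
rolling_ball_subtract <- function(img, radius = 30) {
  img <- as_image_matrix(img)
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1)
    stop("`radius` must be a single number >= 1", call. = FALSE)
  if (radius >= min(dim(img)))
    stop("rolling-ball radius (", radius, ") must be smaller than the ",
         "smallest image dimension (", min(dim(img)), ")", call. = FALSE)
  bg <- gray_open(img, se_disk(radius, flat = FALSE))
  out <- img - bg
  out[out < 0] <- 0
  out
}

## Binary morphology ----------------------------------------------------

binary_erode <- function(mask, se) {
  gray_erode(mask * 1, se) >= 1
}

binary_dilate <- function(mask, se) {
  gray_dilate(mask * 1, se) >= 1
}

binary_close <- function(mask, se) {
  # pad so that closing cannot be truncated by the image border
  r <- max(abs(c(se$dr, se$dc)))
  p <- pad_matrix(mask * 1, r, 0)
  out <- binary_erode(binary_dilate(p >= 1, se), se)
  unpad_matrix(out, r)
}

pad_matrix <- function(m, r, value = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(value, nr + 2 * r, nc + 2 * r)
  out[(r + 1):(r + nr), (r + 1):(r + nc)] <- m
  out
}

unpad_matrix <- function(m, r) {
  m[(r + 1):(nrow(m) - r), (r + 1):(ncol(m) - r)]
}

#' Fill holes in a binary mask
#'
#' A hole is any background component not connected (4-connectivity) to the
#' image border.
#' @param mask logical matrix.
#' @return logical matrix with holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  mask <- mask != 0
  bg <- cpp_label_components(!mask, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels != 0]
  mask | (bg != 0 & !(bg %in% border_labels))
}

#' Label connected components of a binary mask
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  cpp_label_components(mask != 0, as.integer(connectivity))
}

## Filters --------------------------------------------------------------

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(img, sigma) {
  k <- gaussian_kernel_1d(sigma)
  cpp_convolve_sep(cpp_convolve_sep(img, k, TRUE), k, FALSE)
}

median_filter3 <- function(img) cpp_median3(as_image_matrix(img))

# Scale-normalized negated Laplacian of Gaussian; bright blobs of width
# ~sigma give positive peaks of amplitude independent of sigma.
log_response <- function(img, sigma) {
  g <- gaussian_blur(img, sigma)
  lap <- cpp_convolve_sep(g, c(1, -2, 1), TRUE) +
    cpp_convolve_sep(g, c(1, -2, 1), FALSE)
  -sigma^2 * lap
}

## Thresholding ---------------------------------------------------------

#' Otsu threshold of a grayscale image
#'
#' Exhaustive maximisation of the between-class variance over a 256-bin
#' histogram of the image range.
#' @param img numeric matrix.
#' @return scalar threshold on the intensity scale of `img`; pixels
#'   strictly above it are foreground.
#' @export
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("image has no finite pixels", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nbins <- 256L
  h <- tabulate(pmin(nbins, 1L + floor((v - lo) / (hi - lo) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + k / nbins * (hi - lo)
}

as_image_matrix <- function(img) {
  if (is.matrix(img)) return(img)
  a <- drop(img)
  if (is.matrix(a)) return(a)
  stop("expected a 2-D image matrix", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
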