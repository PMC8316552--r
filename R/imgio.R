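# Image-stack container, TIFF stack I/O, run configuration and logging.

#' Construct an ImageStack
#'
#' The package's in-memory image container: a 4-D numeric array indexed
#' `(channel, z, row, col)` plus channel names and physical pixel metadata.
#'
#' @param data 2-D matrix (promoted to one channel, one plane), 3-D array
#'   `(channel, row, col)`, or 4-D array `(channel, z, row, col)`.
#' @param channels character vector of unique channel names.
#' @param pixel_size pixel size in micrometres per pixel (`NA` = unknown,
#'   treated as 1.0 pixel units).
#' @param z_step z spacing in micrometres (optional).
#' @param provenance free-text origin string.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, channels = NULL, pixel_size = NA_real_,
                        z_step = NA_real_, provenance = "in-memory") {
  if (is.matrix(data)) {
    data <- array(data, c(1, 1, nrow(data), ncol(data)))
  } else if (length(dim(data)) == 3) {
    d <- dim(data)
    data <- array(data, c(d[1], 1, d[2], d[3]))
  } else if (length(dim(data)) != 4) {
    stop("`data` must be a matrix or a 3-/4-D array", call. = FALSE)
  }
  nchan <- dim(data)[1]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nchan))
  if (length(channels) != nchan || anyDuplicated(channels))
    stop("`channels` must be ", nchan, " unique names", call. = FALSE)
  if (!is.na(pixel_size) && pixel_size <= 0)
    stop("`pixel_size` must be positive", call. = FALSE)
  structure(list(data = data, channels = as.character(channels),
                 pixel_size = as.numeric(pixel_size),
                 z_step = as.numeric(z_step),
                 provenance = as.character(provenance)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d channel(s) [%s], %d z-plane(s), %d x %d px\n",
              d[1], paste(x$channels, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  pixel size: %s, z step: %s, provenance: %s\n",
              if (is.na(x$pixel_size)) "unknown" else
                paste0(x$pixel_size, " um/px"),
              if (is.na(x$z_step)) "-" else paste0(x$z_step, " um"),
              x$provenance))
  invisible(x)
}

#' Extract one channel (and optionally one plane) as a matrix
#' @param stack an `ImageStack`.
#' @param channel channel name or index.
#' @param z plane index (default 1).
#' @return numeric matrix `(row, col)`.
#' @export
get_channel <- function(stack, channel, z = 1) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channels)
    if (is.na(idx)) stop("no channel named '", channel, "'", call. = FALSE)
  } else idx <- as.integer(channel)
  d <- dim(stack$data)
  matrix(stack$data[idx, z, , ], d[3], d[4])
}

#' Write an ImageStack as multi-page TIFF
#'
#' Pages are ordered channel-major (all z planes of channel 1, then
#' channel 2, ...). Channel names, plane count and pixel metadata go into
#' a JSON ImageDescription so the stack round-trips losslessly.
#' @param stack an `ImageStack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  pages <- list()
  for (ci in seq_len(d[1]))
    for (zi in seq_len(d[2]))
      pages[[length(pages) + 1]] <- matrix(stack$data[ci, zi, , ], d[3], d[4])
  meta <- list(channels = stack$channels, nz = d[2],
               pixel_size_um = stack$pixel_size, z_step_um = stack$z_step)
  desc <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, na = "null")
  write_tiff(pages, path, description = as.character(desc), bits = 64)
}

#' Read a TIFF file into an ImageStack
#'
#' Axes are normalised to `(channel, z, row, col)`. If the file carries the
#' JSON metadata written by [write_stack()] it is honoured; otherwise each
#' page becomes one channel with a single z-plane, pixel size defaults to
#' 1.0 pixel units, and a warning is logged. Negative intensities (possible
#' in third-party float TIFFs) are clipped to zero.
#'
#' @param path TIFF path.
#' @return an `ImageStack`.
#' @export
read_stack <- function(path) {
  tf <- tryCatch(read_tiff(path), error = function(e)
    stop("cannot read image '", path, "': ", conditionMessage(e), call. = FALSE))
  meta <- NULL
  if (!is.null(tf$description) && grepl("^\\s*\\{", tf$description))
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)

  n_pages <- length(tf$pages)
  nr <- nrow(tf$pages[[1]]); nc <- ncol(tf$pages[[1]])
  if (!is.null(meta) && !is.null(meta$channels) && !is.null(meta$nz)) {
    channels <- as.character(meta$channels)
    nz <- as.integer(meta$nz)
    if (length(channels) * nz != n_pages)
      stop("metadata of '", path, "' announces ", length(channels), " x ",
           nz, " pages but file has ", n_pages, call. = FALSE)
    pixel_size <- as.numeric(meta$pixel_size_um %||% NA_real_)
    z_step <- as.numeric(meta$z_step_um %||% NA_real_)
  } else {
    channels <- paste0("ch", seq_len(n_pages))
    nz <- 1L
    pixel_size <- NA_real_
    z_step <- NA_real_
    aq_log("read_stack", "no pixel-size metadata in '%s'; using 1.0 px units",
           path, level = "WARN")
  }
  if (length(pixel_size) == 0 || is.null(pixel_size)) pixel_size <- NA_real_
  if (length(z_step) == 0 || is.null(z_step)) z_step <- NA_real_

  data <- array(0, c(length(channels), nz, nr, nc))
  k <- 1
  for (ci in seq_along(channels))
    for (zi in seq_len(nz)) {
      data[ci, zi, , ] <- tf$pages[[k]]
      k <- k + 1
    }
  data[data < 0] <- 0
  image_stack(data, channels = channels, pixel_size = pixel_size,
              z_step = z_step, provenance = path)
}

#' Maximum intensity projection over z
#'
#' Collapses the z axis by taking, per channel and pixel, the maximum
#' across planes — the standard preprocessing step before single-cell ring
#' analysis of confocal stacks.
#' @param stack an `ImageStack` with at least one z-plane.
#' @return an `ImageStack` with a single z-plane; metadata preserved.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  if (any(d == 0)) stop("empty stack", call. = FALSE)
  out <- array(0, c(d[1], 1, d[3], d[4]))
  for (ci in seq_len(d[1]))
    out[ci, 1, , ] <- apply(stack$data[ci, , , , drop = FALSE], c(3, 4), max)
  image_stack(out, channels = stack$channels, pixel_size = stack$pixel_size,
              z_step = NA_real_,
              provenance = paste0(stack$provenance, " | MIP"))
}

## Run configuration ----------------------------------------------------

#' Default run configuration
#'
#' Every pipeline stage parameter with its default. Ring analysis defaults
#' follow the published procedure (4 equal-area rings, rolling-ball radius
#' 30 px); detection and simulation defaults are package choices validated
#' on synthetic ground truth.
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    rings = list(
      n_rings = 4L,            # concentric equal-area rings per cell
      area_tol = 0.02,         # relative per-ring area tolerance
      rolling_ball_radius = 30, # px
      subtract_background = TRUE
    ),
    puncta = list(
      sigma = 2.0,             # detection scale, px
      threshold = 0.1,         # relative to max LoG response
      match_radius = NA_real_, # px; NA = 2 * sigma
      green_mode = "match",    # "match" or "intensity"
      green_thresh = 0.5
    ),
    morpho = list(
      size_gate_um = 0.5       # minimum vacuole diameter
    ),
    stats = list(
      test = "t",              # "t" or "anova"
      var_equal = TRUE,
      adjust = "sidak",
      alpha = 0.05
    ),
    sim = list(
      kind = "lysosome",
      shape = c(256L, 256L),
      pixel_size = 0.05,       # um/px (50 nm)
      cell_shape = "star",
      cell_radius_frac = 0.42,
      nucleus_radius_frac = 0.25,
      n_puncta = 120L,
      spot_sigma = 2.0,
      spot_amplitude = 100,
      ring_weights = c(0.25, 0.25, 0.25, 0.25),
      apg_fraction = 0.5,
      background = 5,
      gradient_amplitude = 2,
      poisson_noise = TRUE,
      read_noise_sd = 1,
      n_scenes = 1L,
      # vacuole / band table generators
      n_vacuoles = 40L,
      class_mix = c(APG = 0.5, AUT = 0.5),
      sub_threshold_fraction = 0.1,
      n_lanes = 6L,
      fold_changes = c(control = 1, treated = 2),
      band_noise_sd = 0.1
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key '", key, "' must be a mapping", call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      val <- user[[nm]]
      if (is.list(val)) val <- unlist(val)
      defaults[[nm]] <- val
    }
  }
  defaults
}

#' Load a YAML run configuration
#'
#' Reads a YAML file, checks every key against the schema implied by
#' [default_config()] (unknown keys are errors, catching typos) and merges
#' it over the defaults.
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested named list as [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}

#' Save a run configuration as YAML
#' @param config nested list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  # named atomic vectors must become YAML maps, not bare sequences,
  # or their names are lost on reload
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(prep(config), path)
  invisible(path)
}

## Logging --------------------------------------------------------------

aq_log <- function(stage, fmt, ..., level = "INFO") {
  levels <- c(DEBUG = 0, INFO = 1, WARN = 2, ERROR = 3)
  min_level <- getOption("autoquant.log_level", "INFO")
  if (levels[[level]] < levels[[min_level]]) return(invisible(NULL))
  message(sprintf("%s [%s] %s", level, stage, sprintf(fmt, ...)))
  invisible(NULL)
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
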