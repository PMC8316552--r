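# Minimal baseline TIFF codec: uncompressed, single-sample grayscale,
# multi-page, little-endian on write; little- or big-endian, 8/16/32-bit
# unsigned or 32-bit float, strip-organised on read.  Covers exactly what
# the pipeline's image interchange needs (no compression, no tiles); the
# test suite cross-checks it against an independent TIFF implementation.

.tiff_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.tiff_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.tiff_tag <- function(id, type, count, value4) {
  stopifnot(length(value4) == 4)
  c(.tiff_u16(id), .tiff_u16(type), .tiff_u32(count), value4)
}

.tiff_inline <- function(bytes) c(bytes, raw(4 - length(bytes)))

#' Write a multi-page grayscale TIFF
#'
#' Pages are written uncompressed, one strip per page, little-endian.
#' `bits = 64`/`bits = 32` store IEEE float samples; `bits = 8` stores
#' unsigned bytes (used for masks). Stacks are written at 64 bits so
#' arrays round-trip exactly.
#'
#' @param pages a numeric matrix or a list of numeric matrices (one per
#'   page, all the same shape).
#' @param path output file path.
#' @param description optional character scalar stored in the first page's
#'   ImageDescription tag (the stack writer puts JSON metadata here).
#' @param bits 64 or 32 (IEEE float) or 8 (unsigned byte).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, description = NULL, bits = 32) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, bits %in% c(8, 32, 64))
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  for (p in pages)
    if (nrow(p) != nr || ncol(p) != nc)
      stop("all pages must have identical dimensions", call. = FALSE)

  desc_raw <- raw(0)
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(as.character(description)), as.raw(0))
    if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  }

  bytes_per_px <- bits / 8
  strip_len <- nr * nc * bytes_per_px
  n_pages <- length(pages)

  # layout: header(8) | description | strips | IFDs
  desc_off <- 8L
  strip0 <- desc_off + length(desc_raw)
  strip_offsets <- strip0 + (seq_len(n_pages) - 1L) * strip_len
  ifd0 <- strip0 + n_pages * strip_len
  n_entries <- rep(10L, n_pages)
  if (length(desc_raw) > 0) n_entries[1] <- 11L
  ifd_sizes <- 2L + 12L * n_entries + 4L
  ifd_offsets <- ifd0 + cumsum(c(0L, ifd_sizes[-n_pages]))

  sample_format <- if (bits >= 32) 3L else 1L
  buf <- c(charToRaw("II"), .tiff_u16(42), .tiff_u32(ifd_offsets[1]), desc_raw)

  for (i in seq_len(n_pages)) {
    m <- t(pages[[i]])  # TIFF strips are row-major
    buf <- c(buf, if (bits >= 32) {
      writeBin(as.numeric(m), raw(), size = bits / 8, endian = "little")
    } else {
      v <- pmax(0, pmin(255, round(as.numeric(m))))
      as.raw(v)
    })
  }

  for (i in seq_len(n_pages)) {
    tags <- list(
      .tiff_tag(256, 4, 1, .tiff_u32(nc)),
      .tiff_tag(257, 4, 1, .tiff_u32(nr)),
      .tiff_tag(258, 3, 1, .tiff_inline(.tiff_u16(bits))),
      .tiff_tag(259, 3, 1, .tiff_inline(.tiff_u16(1))),
      .tiff_tag(262, 3, 1, .tiff_inline(.tiff_u16(1))))
    if (i == 1 && length(desc_raw) > 0)
      tags <- c(tags, list(.tiff_tag(270, 2, length(desc_raw), .tiff_u32(desc_off))))
    tags <- c(tags, list(
      .tiff_tag(273, 4, 1, .tiff_u32(strip_offsets[i])),
      .tiff_tag(277, 3, 1, .tiff_inline(.tiff_u16(1))),
      .tiff_tag(278, 4, 1, .tiff_u32(nr)),
      .tiff_tag(279, 4, 1, .tiff_u32(strip_len)),
      .tiff_tag(339, 3, 1, .tiff_inline(.tiff_u16(sample_format)))))
    next_off <- if (i < n_pages) ifd_offsets[i + 1] else 0L
    buf <- c(buf, .tiff_u16(length(tags)), do.call(c, tags), .tiff_u32(next_off))
  }

  writeBin(buf, path)
  invisible(path)
}

.tiff_read_val <- function(con, type, count, endian) {
  # reads `count` values of the given TIFF type at the current position
  switch(as.character(type),
    "1" = as.integer(readBin(con, "raw", count)),
    "2" = {
      r <- readBin(con, "raw", count)
      rawToChar(r[r != as.raw(0)])
    },
    "3" = readBin(con, "integer", count, size = 2, signed = FALSE, endian = endian),
    "4" = readBin(con, "integer", count, size = 4, endian = endian),
    "5" = {
      v <- readBin(con, "integer", 2 * count, size = 4, endian = endian)
      v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
    },
    stop("unsupported TIFF field type ", type, call. = FALSE))
}

#' Read a TIFF file
#'
#' Supports the subset this package writes plus common variants:
#' uncompressed strips, grayscale, 8/16/32-bit unsigned or 32-bit float,
#' either byte order, any number of pages.
#'
#' @param path TIFF file path.
#' @return list with `pages` (list of numeric matrices) and `description`
#'   (character or `NULL`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, charToRaw("II"))) "little"
            else if (identical(magic, charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path, call. = FALSE)
  if (readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian) != 42)
    stop("not a TIFF file: ", path, call. = FALSE)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)

  pages <- list()
  description <- NULL
  while (ifd_off > 0) {
    seek(con, ifd_off)
    n <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(n)) {
      id <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
      type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
      count <- readBin(con, "integer", 1, size = 4, endian = endian)
      type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8)[as.character(type)]
      if (is.na(type_size)) { readBin(con, "raw", 4); next }
      nbytes <- type_size * count
      if (nbytes <= 4) {
        here <- seek(con, NA)
        val <- .tiff_read_val(con, type, count, endian)
        seek(con, here + 4)
      } else {
        off <- readBin(con, "integer", 1, size = 4, endian = endian)
        here <- seek(con, NA)
        seek(con, off)
        val <- .tiff_read_val(con, type, count, endian)
        seek(con, here)
      }
      tags[[as.character(id)]] <- val
    }
    next_off <- readBin(con, "integer", 1, size = 4, endian = endian)

    need <- function(id) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) stop("TIFF page missing required tag ", id,
                           " in ", path, call. = FALSE)
      v
    }
    width <- need(256); height <- need(257)
    bits <- tags[["258"]] %||% 1L
    if (length(bits) > 1) bits <- bits[1]
    compression <- tags[["259"]] %||% 1L
    if (compression != 1)
      stop("compressed TIFF (scheme ", compression, ") not supported: ",
           path, call. = FALSE)
    spp <- tags[["277"]] %||% 1L
    if (spp != 1)
      stop("multi-sample TIFF pixels not supported (SamplesPerPixel = ",
           spp, "): ", path, call. = FALSE)
    fmt <- tags[["339"]] %||% 1L
    if (length(fmt) > 1) fmt <- fmt[1]
    offsets <- need(273)
    counts <- need(279)
    if (is.null(description) && !is.null(tags[["270"]]))
      description <- tags[["270"]]

    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      npx <- counts[s] / (bits / 8)
      v <- if (fmt == 3 && bits %in% c(32, 64)) {
        readBin(con, "double", npx, size = bits / 8, endian = endian)
      } else if (bits == 8) {
        as.numeric(readBin(con, "raw", npx))
      } else if (bits == 16) {
        readBin(con, "integer", npx, size = 2, signed = FALSE, endian = endian)
      } else if (bits == 32) {
        readBin(con, "integer", npx, size = 4, endian = endian)
      } else stop("unsupported TIFF sample depth: ", bits, " bits in ",
                  path, call. = FALSE)
      vals <- c(vals, as.numeric(v))
    }
    if (length(vals) != width * height)
      stop("TIFF strip data truncated in ", path, call. = FALSE)
    pages[[length(pages) + 1]] <- t(matrix(vals, nrow = width, ncol = height))
    ifd_off <- next_off
  }
  if (length(pages) == 0) stop("TIFF has no pages: ", path, call. = FALSE)
  list(pages = pages, description = description)
}
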