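# Minimal baseline TIFF codec: uncompressed grayscale, 8/16-bit, multi-page.
# Covers the subset of TIFF 6.0 the package reads and writes; no compression,
# no tiles, no palettes. Sufficient for Spectralis-like B-scan stacks exported
# as raster stacks. (No TIFF package ships with this R installation.)

.tiff_tag <- function(con, order) {
  tag  <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = order)
  type <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = order)
  count <- readBin(con, "integer", 1L, size = 4L, endian = order)
  raw4 <- readBin(con, "raw", 4L)
  list(tag = tag, type = type, count = count, raw = raw4)
}

.tiff_type_size <- function(type) {
  # BYTE, ASCII, SHORT, LONG, RATIONAL, ...
  sizes <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)
  if (type < 1L || type > length(sizes)) 1L else sizes[type]
}

.tiff_tag_values <- function(con, entry, order) {
  size <- .tiff_type_size(entry$type) * entry$count
  get_vals <- function(raw) {
    rcon <- rawConnection(raw)
    on.exit(close(rcon))
    if (entry$type == 3L) {
      readBin(rcon, "integer", entry$count, size = 2L, signed = FALSE, endian = order)
    } else if (entry$type == 4L) {
      readBin(rcon, "integer", entry$count, size = 4L, endian = order)
    } else if (entry$type == 1L) {
      as.integer(readBin(rcon, "raw", entry$count))
    } else {
      NULL
    }
  }
  if (size <= 4L) {
    get_vals(entry$raw)
  } else {
    offset <- readBin(entry$raw, "integer", 1L, size = 4L, endian = order)
    cur <- seek(con)
    seek(con, offset)
    raw <- readBin(con, "raw", size)
    seek(con, cur)
    get_vals(raw)
  }
}

#' Read a grayscale (multi-page) TIFF
#'
#' Reads an uncompressed, single-sample-per-pixel baseline TIFF and returns
#' one integer matrix per page (rows = image rows). Values are raw container
#' values (0..255 or 0..65535); no rescaling is applied.
#'
#' @param path path to a TIFF file.
#' @return list with elements `pages` (list of integer matrices) and
#'   `bits` (8 or 16).
#' @keywords internal
read_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  order <- switch(magic, II = "little", MM = "big",
                  stop("not a TIFF file (bad byte-order mark): ", path))
  fortytwo <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = order)
  if (fortytwo != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_offset <- readBin(con, "integer", 1L, size = 4L, endian = order)

  pages <- list()
  bits_all <- integer(0)
  page <- 0L
  while (ifd_offset != 0L) {
    page <- page + 1L
    seek(con, ifd_offset)
    n_entries <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = order)
    entries <- vector("list", n_entries)
    for (i in seq_len(n_entries)) entries[[i]] <- .tiff_tag(con, order)
    ifd_offset <- readBin(con, "integer", 1L, size = 4L, endian = order)

    tagval <- function(tag, default = NULL) {
      for (e in entries) if (e$tag == tag) return(.tiff_tag_values(con, e, order))
      default
    }
    width  <- tagval(256L)
    height <- tagval(257L)
    bits   <- tagval(258L, 8L)[1]
    compression <- tagval(259L, 1L)[1]
    photometric <- tagval(262L, 1L)[1]
    strip_offsets <- tagval(273L)
    samples <- tagval(277L, 1L)[1]
    rows_per_strip <- tagval(278L, height)[1]
    strip_counts <- tagval(279L)

    if (is.null(width) || is.null(height) || is.null(strip_offsets))
      stop("TIFF page ", page, " is missing required tags")
    if (compression != 1L)
      stop("TIFF page ", page, ": unsupported compression (", compression,
           "); only uncompressed baseline TIFF is readable")
    if (samples != 1L)
      stop("TIFF page ", page, ": unsupported samples per pixel (", samples,
           "); grayscale only")
    if (!(bits %in% c(8L, 16L)))
      stop("TIFF page ", page, ": unsupported bit depth (", bits,
           "); 8 and 16 bit supported")
    if (is.null(strip_counts))
      strip_counts <- rep(rows_per_strip * width * (bits %/% 8L),
                          length(strip_offsets))

    npx <- width * height
    buf <- raw(npx * (bits %/% 8L))
    pos <- 1L
    for (s in seq_along(strip_offsets)) {
      seek(con, strip_offsets[s])
      chunk <- readBin(con, "raw", strip_counts[s])
      buf[pos:(pos + length(chunk) - 1L)] <- chunk
      pos <- pos + length(chunk)
    }
    vals <- if (bits == 8L) {
      as.integer(buf)
    } else {
      readBin(buf, "integer", npx, size = 2L, signed = FALSE, endian = order)
    }
    if (photometric == 0L) vals <- (2L^bits - 1L) - vals  # WhiteIsZero
    pages[[page]] <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    bits_all[page] <- bits
  }
  if (length(pages) == 0L) stop("TIFF file has no pages: ", path)
  if (length(unique(bits_all)) > 1L)
    stop("TIFF pages have mixed bit depths in ", path)
  list(pages = pages, bits = bits_all[1])
}

#' Write a grayscale (multi-page) TIFF
#'
#' Writes a list of numeric/integer matrices as an uncompressed little-endian
#' baseline TIFF, one strip per page. Values must already be integers in
#' `[0, 2^bits - 1]`.
#'
#' @param pages a matrix or list of equally-sized matrices of integer values.
#' @param path output path.
#' @param bits container bit depth, 8 or 16.
#' @keywords internal
write_tiff <- function(pages, path, bits = 8L) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, bits %in% c(8L, 16L))
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all pages must have identical dimensions")
  h <- dims[1, 1]; w <- dims[2, 1]
  maxv <- 2^bits - 1
  bytes_pp <- bits %/% 8L
  page_bytes <- h * w * bytes_pp

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2L, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  n <- length(pages)
  data_start <- 8L
  ifd_start <- data_start + n * page_bytes
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  writeBin(as.integer(ifd_start), con, size = 4L, endian = "little")

  for (p in seq_len(n)) {
    m <- pages[[p]]
    v <- as.integer(round(m))
    if (any(v < 0L | v > maxv))
      stop("page ", p, ": values outside [0, ", maxv, "] for ", bits, "-bit container")
    v <- as.vector(t(m))  # row-major
    writeBin(as.integer(round(v)), con, size = bytes_pp, endian = "little")
  }

  write_tag <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (p in seq_len(n)) {
    writeBin(n_tags, con, size = 2L, endian = "little")
    write_tag(256L, 4L, 1L, w)
    write_tag(257L, 4L, 1L, h)
    write_tag(258L, 3L, 1L, bits)
    write_tag(259L, 3L, 1L, 1L)              # no compression
    write_tag(262L, 3L, 1L, 1L)              # BlackIsZero
    write_tag(273L, 4L, 1L, data_start + (p - 1L) * page_bytes)
    write_tag(277L, 3L, 1L, 1L)
    write_tag(278L, 4L, 1L, h)
    write_tag(279L, 4L, 1L, page_bytes)
    next_ifd <- if (p < n) ifd_start + p * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
  }
  invisible(path)
}
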