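#' Scan geometry description
#'
#' Physical spacing and grid size of a volumetric OCT acquisition. Defaults
#' follow the Spectralis-like protocol used throughout the package: 49 B-scans
#' of 496 (depth) x 512 (A-scans) pixels covering about 6 x 6 mm en face.
#'
#' @param n_bscans number of B-scans (slow axis).
#' @param n_depth axial (depth) pixels per A-scan.
#' @param n_ascans A-scans per B-scan (fast axis).
#' @param fov_mm en-face field of view in mm, length 2 `(fast, slow)`.
#' @param dz_um axial pixel pitch in micrometres. The default of 1 means
#'   thickness values are reported in pixels; supply a device calibration to
#'   obtain micrometres.
#' @return an `oct_geometry` list with the grid sizes and `dx_mm`, `dy_mm`,
#'   `dz_um` spacings.
#' @export
oct_geometry <- function(n_bscans = 49L, n_depth = 496L, n_ascans = 512L,
                         fov_mm = c(6, 6), dz_um = 1) {
  stopifnot(n_bscans >= 1L, n_depth >= 1L, n_ascans >= 1L,
            all(fov_mm > 0), dz_um > 0)
  structure(list(n_bscans = as.integer(n_bscans),
                 n_depth = as.integer(n_depth),
                 n_ascans = as.integer(n_ascans),
                 dx_mm = fov_mm[1] / n_ascans,
                 dy_mm = fov_mm[2] / n_bscans,
                 dz_um = dz_um),
            class = "oct_geometry")
}

#' Construct an OCT volume
#'
#' Wraps a 3-D intensity array indexed `[b-scan, depth row, a-scan]` together
#' with its physical spacings. Intensities must be finite and lie in `[0, 1]`.
#'
#' @param voxels 3-D numeric array, dims `(n_bscans, n_depth, n_ascans)`.
#' @param dx_mm,dy_mm en-face A-scan / B-scan spacing (mm).
#' @param dz_um axial pixel size (micrometres; 1 = report in pixels).
#' @return an `oct_volume` object.
#' @export
oct_volume <- function(voxels, dx_mm = 6 / 512, dy_mm = 6 / 49, dz_um = 1) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            dx_mm > 0, dy_mm > 0, dz_um > 0)
  if (!all(is.finite(voxels)))
    stop("volume contains non-finite voxels")
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 1)
    stop("voxel intensities must lie in [0, 1]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  structure(list(voxels = voxels,
                 n_bscans = dim(voxels)[1], n_depth = dim(voxels)[2],
                 n_ascans = dim(voxels)[3],
                 dx_mm = dx_mm, dy_mm = dy_mm, dz_um = dz_um),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("oct_volume: %d B-scans x %d depth px x %d A-scans\n",
              x$n_bscans, x$n_depth, x$n_ascans))
  cat(sprintf("  spacing: dx = %.4f mm, dy = %.4f mm, dz = %g um\n",
              x$dx_mm, x$dy_mm, x$dz_um))
  cat(sprintf("  intensity range: [%.3f, %.3f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$voxels)

.read_raster_page <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tf <- read_tiff(path)
    if (length(tf$pages) != 1L)
      stop("expected a single-page raster, got ", length(tf$pages),
           " pages in ", path)
    tf$pages[[1]] / (2^tf$bits - 1)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] > 1L)
        stop("unsupported PNG (", dim(img)[3], " channels); grayscale only: ",
             path)
      img <- img[, , 1]
    }
    img
  } else {
    stop("unsupported raster format '.", ext, "': ", path)
  }
}

#' Load an OCT volume from a TIFF stack or an image directory
#'
#' Reads either a multi-page grayscale TIFF (pages ordered as B-scan index
#' 0..n-1) or a directory of equally sized PNG/TIFF B-scans sorted by
#' filename. Intensities are rescaled to `[0, 1]` by the container's dtype
#' maximum.
#'
#' @param path TIFF file or directory of per-B-scan images.
#' @param geometry an [oct_geometry()] supplying physical spacings. Grid
#'   sizes are taken from the images themselves.
#' @return an [oct_volume()].
#' @export
load_volume <- function(path, geometry = oct_geometry()) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L)
      stop("directory contains no PNG/TIFF B-scans: ", path)
    files <- files[order(basename(files))]
    pages <- lapply(files, .read_raster_page)
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
      stop("B-scan size mismatch at ", basename(files[bad]),
           " (", dims[1, bad], "x", dims[2, bad], " vs ",
           dims[1, 1], "x", dims[2, 1], ")")
    }
  } else {
    tf <- read_tiff(path)
    pages <- lapply(tf$pages, function(p) p / (2^tf$bits - 1))
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
      stop("TIFF page size mismatch at page ", bad)
    }
  }
  vox <- aperm(abind::abind(pages, along = 3), c(3, 1, 2))
  oct_volume(vox, dx_mm = geometry$dx_mm, dy_mm = geometry$dy_mm,
             dz_um = geometry$dz_um)
}

#' Save an OCT volume (or congruent mask/score stack) as multi-page TIFF
#'
#' @param x an [oct_volume()] or a 3-D array with values in `[0, 1]`.
#' @param path output TIFF path.
#' @param bits 8 or 16-bit container.
#' @export
save_volume <- function(x, path, bits = 8L) {
  vox <- if (inherits(x, "oct_volume")) x$voxels else x
  stopifnot(length(dim(vox)) == 3L)
  if (!all(is.finite(vox)) || min(vox) < 0 || max(vox) > 1)
    stop("values must be finite and in [0, 1]")
  maxv <- 2^bits - 1
  pages <- lapply(seq_len(dim(vox)[1]), function(b)
    round(vox[b, , , drop = TRUE] * maxv))
  write_tiff(pages, path, bits = bits)
}

#' Write an en-face map as CSV
#'
#' One row per B-scan, one column per A-scan; values round-trip through
#' [load_enface_csv()] exactly at 6 decimals.
#'
#' @param map an [enface_map()] or a numeric matrix.
#' @param path output CSV path.
#' @export
save_enface_csv <- function(map, path) {
  grid <- if (inherits(map, "enface_map")) map$grid else map
  if (!is.matrix(grid) || length(grid) == 0L)
    stop("en-face map is empty")
  if (!all(is.finite(grid)))
    stop("en-face map contains non-finite values")
  utils::write.table(format(grid, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an en-face CSV written by [save_enface_csv()]
#'
#' @param path CSV path.
#' @return numeric matrix, rows = B-scans.
#' @export
load_enface_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Save an en-face map as a raster image
#'
#' Min-max normalizes the grid (see [normalize_for_display()]) and writes a
#' 16-bit TIFF or an 8-bit PNG preview depending on the file extension.
#'
#' @param map an [enface_map()] or numeric matrix.
#' @param path output path ending in `.tif`/`.tiff` (16-bit) or `.png` (8-bit).
#' @export
save_enface_raster <- function(map, path) {
  grid <- if (inherits(map, "enface_map")) map$grid else map
  norm <- normalize_for_display(grid)$values
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff(round(norm * 65535), path, bits = 16L)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    stop("unsupported extension '.", ext, "' (use .tiff or .png)")
  }
  invisible(path)
}
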