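# En-face reconstruction: per-B-scan interface extraction with cubic
# smoothing-spline fitting, per-A-scan thickness, and projection of the
# ensemble disagreement (std) map along the layer's medial axis.

#' Construct an en-face map
#'
#' A `(n_bscans x n_ascans)` grid of thickness or disagreement values: row `b`
#' derives solely from B-scan `b`, column `x` from A-scan `x`.
#'
#' @param grid numeric matrix, rows = B-scans.
#' @param kind `"thickness"` or `"std"`.
#' @param units `"px"`, `"um"` or `"score-std"`.
#' @param dx_mm,dy_mm en-face spacings (mm).
#' @return an `enface_map`.
#' @export
enface_map <- function(grid, kind = c("thickness", "std"), units = "px",
                       dx_mm = 6 / 512, dy_mm = 6 / 49) {
  kind <- match.arg(kind)
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  if (kind == "thickness" && any(grid < 0, na.rm = TRUE))
    stop("thickness map has negative entries")
  structure(list(grid = grid, kind = kind, units = units,
                 dx_mm = dx_mm, dy_mm = dy_mm),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  cat(sprintf("enface_map (%s, %s): %d B-scans x %d A-scans, range [%g, %g]\n",
              x$kind, x$units, nrow(x$grid), ncol(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.enface_map <- function(x) dim(x$grid)

# Cubic smoothing spline through (x, y) support points, evaluated on
# `at`. Degrees of freedom grow with the number of support columns so the fit
# tracks low-frequency layer geometry while smoothing binarization jitter.
# Falls back to linear interpolation (constant extrapolation) when there are
# too few support points for a cubic fit.
.fit_interface <- function(x, y, at, df_factor = 1 / 6) {
  ux <- unique(x)
  if (length(ux) == 1L || diff(range(y)) == 0)
    return(rep(y[1], length(at)))
  if (length(ux) < 5L) {
    return(stats::approx(x, y, xout = at, rule = 2, ties = mean)$y)
  }
  df <- max(4, min(length(ux) - 1, round(length(ux) * df_factor)))
  fit <- tryCatch(
    stats::smooth.spline(x, y, df = df, cv = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    return(stats::approx(x, y, xout = at, rule = 2, ties = mean)$y)
  stats::predict(fit, at)$y
}

#' Extract layer interfaces from a binary B-scan mask
#'
#' Per A-scan column, the raw upper/lower interface is the topmost/bottommost
#' foreground row (undefined on empty columns). Cubic smoothing splines are
#' fit to the defined points and evaluated at every column, deliberately
#' bridging disruptions and holes so the layer has a continuous
#' representation. Disruption flags come from the raw mask, not the spline.
#'
#' @param binary 2-D 0/1 matrix (depth rows x A-scan columns).
#' @param df_factor smoothing-spline degrees of freedom as a fraction of the
#'   number of support columns.
#' @return an `interface_set`: `upper`, `lower` (raw, NA on empty columns),
#'   `upper_fit`, `lower_fit`, `medial` (continuous, per column), `disrupted`
#'   (logical), `empty` (TRUE if the whole mask was empty).
#' @export
extract_interfaces <- function(binary, df_factor = 1 / 6) {
  stopifnot(is.matrix(binary))
  nx <- ncol(binary)
  fg <- binary != 0
  any_fg <- colSums(fg) > 0
  upper <- rep(NA_real_, nx)
  lower <- rep(NA_real_, nx)
  idx <- which(any_fg)
  if (length(idx)) {
    upper[idx] <- apply(fg[, idx, drop = FALSE], 2,
                        function(col) which(col)[1]) - 1
    lower[idx] <- apply(fg[, idx, drop = FALSE], 2,
                        function(col) max(which(col))) - 1
  }
  disrupted <- !any_fg
  if (!length(idx)) {
    return(structure(list(upper = upper, lower = lower,
                          upper_fit = rep(NA_real_, nx),
                          lower_fit = rep(NA_real_, nx),
                          medial = rep(NA_real_, nx),
                          disrupted = disrupted, empty = TRUE),
                     class = "interface_set"))
  }
  at <- seq_len(nx) - 1
  upper_fit <- .fit_interface(idx - 1, upper[idx], at, df_factor)
  lower_fit <- .fit_interface(idx - 1, lower[idx], at, df_factor)
  # the fitted lower edge may cross the upper on wild extrapolation; clamp
  lower_fit <- pmax(lower_fit, upper_fit)
  structure(list(upper = upper, lower = lower,
                 upper_fit = upper_fit, lower_fit = lower_fit,
                 medial = (upper_fit + lower_fit) / 2,
                 disrupted = disrupted, empty = FALSE),
            class = "interface_set")
}

#' Per-A-scan layer thickness from fitted interfaces
#'
#' Thickness on a non-disrupted column is the inclusive pixel extent between
#' the fitted edges, `lower_fit - upper_fit + 1` (a one-pixel band has
#' thickness 1); on disrupted columns it is exactly 0.
#'
#' @param ifs an `interface_set` from [extract_interfaces()].
#' @return numeric vector of per-column thickness in pixels.
#' @export
thickness_profile <- function(ifs) {
  stopifnot(inherits(ifs, "interface_set"))
  if (ifs$empty) return(rep(0, length(ifs$disrupted)))
  th <- pmax(ifs$lower_fit - ifs$upper_fit + 1, 0)
  th[ifs$disrupted] <- 0
  th
}

.result_binary <- function(r) {
  if (is.list(r) && !is.null(r$binary)) r$binary else r
}

#' En-face thickness map from per-B-scan segmentations
#'
#' Row `b` of the map is the [thickness_profile()] of B-scan `b`, scaled by
#' the axial pixel pitch.
#'
#' @param results list ordered by B-scan index; each element an
#'   [ensemble_result] or a binary B-scan matrix.
#' @param dz_um axial pixel size; 1 keeps thickness in pixels.
#' @param dx_mm,dy_mm en-face spacings recorded in the output map.
#' @param df_factor passed to [extract_interfaces()].
#' @return an [enface_map()] of kind `"thickness"`.
#' @export
enface_thickness <- function(results, dz_um = 1, dx_mm = 6 / 512,
                             dy_mm = 6 / 49, df_factor = 1 / 6) {
  stopifnot(length(results) >= 1)
  rows <- lapply(results, function(r) {
    thickness_profile(extract_interfaces(.result_binary(r), df_factor))
  })
  grid <- do.call(rbind, rows) * dz_um
  enface_map(grid, kind = "thickness",
             units = if (dz_um == 1) "px" else "um",
             dx_mm = dx_mm, dy_mm = dy_mm)
}

#' En-face disagreement map sampled along the medial axis
#'
#' For each B-scan, the ensemble's pixel-wise standard-deviation map is
#' sampled at the nearest-integer row of the layer's medial axis
#' `(upper_fit + lower_fit)/2` in every column, and the values become row `b`
#' of the en-face map. B-scans with an entirely empty segmentation contribute
#' zeros and are flagged in the `coverage` attribute.
#'
#' @param results list of [ensemble_result] objects ordered by B-scan, or a
#'   list of `list(std_map =, binary =)` pairs.
#' @param dx_mm,dy_mm en-face spacings.
#' @param df_factor passed to [extract_interfaces()].
#' @return an [enface_map()] of kind `"std"` with attribute `coverage`
#'   (logical vector: TRUE where the B-scan had any foreground).
#' @export
enface_std <- function(results, dx_mm = 6 / 512, dy_mm = 6 / 49,
                       df_factor = 1 / 6) {
  stopifnot(length(results) >= 1)
  coverage <- logical(length(results))
  rows <- vector("list", length(results))
  for (b in seq_along(results)) {
    r <- results[[b]]
    std <- r$std_map
    ifs <- extract_interfaces(.result_binary(r), df_factor)
    if (ifs$empty) {
      rows[[b]] <- rep(0, ncol(std))
      coverage[b] <- FALSE
    } else {
      rr <- pmin(pmax(round(ifs$medial), 0), nrow(std) - 1)
      rows[[b]] <- std[cbind(rr + 1, seq_len(ncol(std)))]
      coverage[b] <- TRUE
    }
  }
  out <- enface_map(do.call(rbind, rows), kind = "std", units = "score-std",
                    dx_mm = dx_mm, dy_mm = dy_mm)
  attr(out, "coverage") <- coverage
  out
}

#' Min-max normalize a map for display
#'
#' Maps values to `[0, 1]` by `(v - min) / (max - min)`. A constant map
#' normalizes to all zeros and is flagged degenerate.
#'
#' @param map an [enface_map()] or numeric matrix/array of finite values.
#' @return list with `values` (same shape, in `[0, 1]`) and `degenerate`
#'   (TRUE if the input was constant).
#' @export
normalize_for_display <- function(map) {
  v <- if (inherits(map, "enface_map")) map$grid else map
  if (!all(is.finite(v))) stop("map contains non-finite values")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    return(list(values = array(0, dim(v) %||% length(v)), degenerate = TRUE))
  }
  list(values = (v - lo) / (hi - lo), degenerate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
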