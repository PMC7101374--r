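# Pixel-level evaluation: precision / recall / Dice from confusion counts,
# precision-recall curves with trapezoidal AUC, ETDRS-grid region masks, and
# the distance-stratified B-scan sampling protocol.

# Expand an en-face column selection to pixel space. `region` may be NULL
# (everything), a logical vector over A-scan columns (2-D masks) or a logical
# (n_bscans x n_ascans) matrix (3-D masks): en-face membership applies to the
# whole depth column.
.region_select <- function(x, region) {
  if (is.null(region)) return(rep(TRUE, length(x)))
  d <- dim(x)
  if (length(d) == 2L) {
    stopifnot(is.logical(region), length(region) == d[2])
    rep(region, each = d[1])
  } else if (length(d) == 3L) {
    stopifnot(is.matrix(region), nrow(region) == d[1], ncol(region) == d[3])
    # x is (b, z, x): vary b fastest, then z, then x
    sel <- array(FALSE, d)
    for (b in seq_len(d[1])) sel[b, , ] <- matrix(region[b, ], d[2], d[3],
                                                  byrow = TRUE)
    as.vector(sel)
  } else stop("masks must be 2-D or 3-D")
}

#' Confusion counts over a region
#'
#' Counts true/false positives/negatives of a predicted binary mask against a
#' ground-truth mask, restricted to the pixels of the selected A-scan columns.
#'
#' @param pred,truth congruent 0/1 masks (2-D B-scan or 3-D volume).
#' @param region optional en-face region: a logical vector over columns
#'   (2-D input) or a logical `(n_bscans x n_ascans)` matrix (3-D input).
#'   Membership applies to entire A-scan columns.
#' @return named integer-ish list `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth, region = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must be congruent")
  sel <- .region_select(pred, region)
  p <- as.vector(pred != 0)[sel]
  t <- as.vector(truth != 0)[sel]
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' Precision, recall and Dice from confusion counts
#'
#' `dice = 2*tp / (2*tp + fp + fn)`, identical to twice the product of
#' precision and recall over their sum. Undefined ratios (empty truth and
#' empty prediction) are reported as `NaN` and flagged, not coerced to 1.
#'
#' @param counts output of [confusion_counts()], or a mask pair via `...`.
#' @param region label stored alongside the scores.
#' @return a `segmentation_scores` list: counts plus `precision`, `recall`,
#'   `dice`, `defined` flag and `region`.
#' @export
segmentation_scores <- function(counts, region = "full") {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  recall <- if (tp + fn > 0) tp / (tp + fn) else NaN
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NaN
  structure(c(counts,
              list(precision = precision, recall = recall, dice = dice,
                   defined = is.finite(dice), region = region)),
            class = "segmentation_scores")
}

#' Precision-recall curve and area under it
#'
#' Thresholds a score map over a fixed descending grid; at each threshold the
#' prediction is `score >= t`. Points are ordered by recall and integrated by
#' the trapezoidal rule over recall, anchored at `(recall = 0, precision at
#' the highest threshold with at least one prediction)`. Thresholds with no
#' predicted pixels contribute no point.
#'
#' @param scores numeric array of scores in `[0, 1]` (matrix or 3-D stack).
#' @param truth congruent 0/1 mask with at least one positive in the region.
#' @param region optional en-face region (see [confusion_counts()]).
#' @param n_thresholds size of the even threshold grid on `[0, 1]`.
#' @return list with `recall`, `precision`, `thresholds` (aligned vectors,
#'   recall ascending) and `auc`.
#' @export
pr_curve <- function(scores, truth, region = NULL, n_thresholds = 101L) {
  if (!identical(dim(scores), dim(truth)))
    stop("scores and truth must be congruent")
  if (!all(is.finite(scores)) || min(scores) < 0 || max(scores) > 1)
    stop("scores must be finite and in [0, 1]")
  sel <- .region_select(scores, region)
  s <- as.vector(scores)[sel]
  t <- as.vector(truth != 0)[sel]
  npos <- sum(t)
  if (npos == 0L)
    stop("region contains no positive truth pixels; PR curve undefined")
  thr <- seq(1, 0, length.out = n_thresholds)   # descending
  precision <- recall <- numeric(0)
  kept_thr <- numeric(0)
  for (tt in thr) {
    pred <- s >= tt
    np <- sum(pred)
    if (np == 0L) next
    tp <- sum(pred & t)
    precision <- c(precision, tp / np)
    recall <- c(recall, tp / npos)
    kept_thr <- c(kept_thr, tt)
  }
  if (length(recall) == 0L) {           # no threshold predicted anything
    return(list(recall = 0, precision = 1, thresholds = numeric(0), auc = 0))
  }
  # anchor at recall 0 with the precision of the strictest non-empty threshold
  r <- c(0, recall)
  p <- c(precision[1], precision)
  o <- order(r)
  r <- r[o]; p <- p[o]
  auc <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(recall = recall, precision = precision, thresholds = kept_thr,
       auc = auc)
}

#' ETDRS grid region masks on the en-face plane
#'
#' Builds boolean en-face grids for the central subfield (disk of 1 mm
#' diameter), the 3 central-millimetre area (disk of 3 mm diameter) and the
#' 3-1 ring (their difference), by the Euclidean distance of each cell centre
#' `(b * dy_mm, x * dx_mm)` from the fovea centre.
#'
#' @param n_bscans,n_ascans en-face grid size.
#' @param dx_mm,dy_mm en-face spacings.
#' @param fovea_center `(b, x)` index pair (may be fractional); defaults to
#'   the geometric centre of the grid, matching fovea-centred acquisitions.
#' @return an `etdrs_regions` list: `csf`, `cmm3`, `ring31`, `full` logical
#'   matrices plus `fovea_center`.
#' @export
etdrs_regions <- function(n_bscans, n_ascans, dx_mm = 6 / 512, dy_mm = 6 / 49,
                          fovea_center = c((n_bscans - 1) / 2,
                                           (n_ascans - 1) / 2)) {
  stopifnot(dx_mm > 0, dy_mm > 0, length(fovea_center) == 2L)
  db <- (seq_len(n_bscans) - 1 - fovea_center[1]) * dy_mm
  dx <- (seq_len(n_ascans) - 1 - fovea_center[2]) * dx_mm
  dist <- sqrt(outer(db^2, dx^2, "+"))
  csf <- dist <= 0.5
  cmm3 <- dist <= 1.5
  structure(list(csf = csf, cmm3 = cmm3, ring31 = cmm3 & !csf,
                 full = matrix(TRUE, n_bscans, n_ascans),
                 fovea_center = fovea_center),
            class = "etdrs_regions")
}

#' Mean thickness per ETDRS region
#'
#' Arithmetic mean of an en-face thickness map over each region's cells;
#' zero-thickness cells from disruptions are included, matching the
#' definition of average layer thickness over an area.
#'
#' @param map an [enface_map()] (kind thickness) or numeric matrix.
#' @param regions an [etdrs_regions()] congruent with the map.
#' @return named numeric vector: `csf`, `cmm3`, `ring31`, `full`.
#' @export
region_mean_thickness <- function(map, regions) {
  grid <- if (inherits(map, "enface_map")) map$grid else map
  stopifnot(inherits(regions, "etdrs_regions"),
            identical(dim(grid), dim(regions$full)))
  vapply(c("csf", "cmm3", "ring31", "full"),
         function(r) mean(grid[regions[[r]]]), numeric(1))
}

#' Distance-stratified random B-scan sampling
#'
#' Draws three samples of 2 distinct B-scans each, one sample per ETDRS
#' distance band from the fovea along the slow axis: 0-1 mm, 1-3 mm and
#' 3-6 mm (`lo < |b - fovea_b| * dy_mm <= hi`, with the first band closed at
#' 0). Reproducible under the seed.
#'
#' @param n_bscans number of B-scans.
#' @param dy_mm B-scan spacing (mm).
#' @param fovea_b fovea B-scan index (may be fractional).
#' @param seed RNG seed.
#' @return list of three integer vectors (0-based B-scan indices) named
#'   `band_0_1`, `band_1_3`, `band_3_6`.
#' @export
sample_bscans <- function(n_bscans, dy_mm = 6 / 49,
                          fovea_b = (n_bscans - 1) / 2, seed = 0L) {
  stopifnot(n_bscans >= 1, dy_mm > 0)
  dist <- abs(seq_len(n_bscans) - 1 - fovea_b) * dy_mm
  bands <- list(band_0_1 = c(0, 1), band_1_3 = c(1, 3), band_3_6 = c(3, 6))
  .with_seed(seed, {
    out <- lapply(names(bands), function(nm) {
      lim <- bands[[nm]]
      eligible <- which(if (lim[1] == 0) dist <= lim[2]
                        else dist > lim[1] & dist <= lim[2]) - 1L
      if (length(eligible) < 2L)
        stop("band ", nm, " (", lim[1], "-", lim[2], " mm) has ",
             length(eligible), " eligible B-scans; need 2")
      sort(sample(eligible, 2L))
    })
    names(out) <- names(bands)
    out
  })
}
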