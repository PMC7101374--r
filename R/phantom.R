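# Synthetic Spectralis-like OCT phantom with exact photoreceptor ground truth.
# The phantom states the world the rest of the package is validated in: a thin
# bright band (~2% of B-scan pixels) with smooth thickness variation, focal
# disruptions carved to zero thickness, columnar vessel shadows, dark cyst
# blobs above the band, and multiplicative speckle.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Specification of a synthetic OCT phantom
#'
#' Defaults emulate the acquisition protocol the package targets: 49 B-scans
#' of 496 x 512 px over ~6 x 6 mm, a photoreceptor band of baseline thickness
#' 10 px (so the band holds about 2% of each B-scan's pixels), smooth
#' low-frequency thickness and curvature modulation, two focal disruptions,
#' two vessel shadows, two cysts and moderate speckle.
#'
#' @param geometry an [oct_geometry()].
#' @param band_center_row mean depth (pixel row) of the band's medial axis.
#' @param band_thickness_px baseline band thickness in pixels.
#' @param thickness_amplitude peak amplitude (px) of the smooth thickness
#'   modulation field (low-frequency cosine mixture).
#' @param center_amplitude peak amplitude (px) of the smooth curvature of the
#'   band's medial axis.
#' @param disruptions list of en-face ellipses `list(b, x, rb, rx)` (centre
#'   and radii in B-scan / A-scan index units) where the layer is absent
#'   (thickness carved to exactly 0).
#' @param shadows list of `list(x0, x1, factor)` A-scan column ranges whose
#'   image intensity is multiplied by `factor` (mask untouched).
#' @param cysts list of dark ellipsoids `list(b, z, x, rb, rz, rx)` rendered
#'   above the band (image only).
#' @param speckle_sigma scale of the multiplicative log-normal speckle;
#'   0 disables noise.
#' @param seed RNG seed; the phantom is bit-reproducible given the seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(geometry = oct_geometry(),
                         band_center_row = round(geometry$n_depth * 0.62),
                         band_thickness_px = 10,
                         thickness_amplitude = 2.5,
                         center_amplitude = 18,
                         disruptions = list(
                           list(b = 15, x = 140, rb = 2.5, rx = 25),
                           list(b = 33, x = 360, rb = 3.5, rx = 35)),
                         shadows = list(
                           list(x0 = 90, x1 = 102, factor = 0.45),
                           list(x0 = 400, x1 = 408, factor = 0.55)),
                         cysts = list(
                           list(b = 20, z = round(geometry$n_depth * 0.45),
                                x = 250, rb = 5, rz = 25, rx = 40),
                           list(b = 35, z = round(geometry$n_depth * 0.5),
                                x = 150, rb = 4, rz = 18, rx = 30)),
                         speckle_sigma = 0.15,
                         seed = 0L) {
  stopifnot(inherits(geometry, "oct_geometry"),
            band_thickness_px >= 1,
            thickness_amplitude >= 0, thickness_amplitude < band_thickness_px,
            center_amplitude >= 0, speckle_sigma >= 0)
  structure(list(geometry = geometry,
                 band_center_row = band_center_row,
                 band_thickness_px = band_thickness_px,
                 thickness_amplitude = thickness_amplitude,
                 center_amplitude = center_amplitude,
                 disruptions = disruptions,
                 shadows = shadows,
                 cysts = cysts,
                 speckle_sigma = speckle_sigma,
                 seed = seed),
            class = "phantom_spec")
}

# Smooth zero-mean field in [-1, 1] over the (b, x) en-face grid: a mixture of
# low-frequency separable cosines with seeded random phases.
.cosine_field <- function(nb, nx, n_terms = 3L) {
  bb <- (seq_len(nb) - 1) / max(nb - 1, 1)
  xx <- (seq_len(nx) - 1) / max(nx - 1, 1)
  f <- matrix(0, nb, nx)
  for (k in seq_len(n_terms)) {
    fb <- stats::runif(1, 0.4, 1.6)
    fx <- stats::runif(1, 0.4, 1.6)
    pb <- stats::runif(1, 0, 2 * pi)
    px <- stats::runif(1, 0, 2 * pi)
    f <- f + outer(cos(2 * pi * fb * bb + pb), cos(2 * pi * fx * xx + px)) / k
  }
  m <- max(abs(f))
  if (m > 0) f / m else f
}

.ellipse_mask <- function(nb, nx, ellipses) {
  m <- matrix(FALSE, nb, nx)
  for (e in ellipses) {
    d <- outer(((seq_len(nb) - 1 - e$b) / e$rb)^2,
               ((seq_len(nx) - 1 - e$x) / e$rx)^2, "+")
    m <- m | (d <= 1)
  }
  m
}

#' Generate a synthetic OCT volume with exact ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: a bright band at a
#' smoothly varying depth and thickness over a darker layered background,
#' with disruptions (band absent), columnar shadows, cyst blobs and
#' multiplicative speckle. The returned truth contains the binary layer mask
#' (exactly the band support after disruption carving), the per-column
#' thickness (the foreground run length, 0 on disrupted columns) and the
#' sub-pixel interface grids.
#'
#' Shadows, cysts and speckle alter the image only, never the mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([oct_volume()]) and `truth` (list
#'   with `mask` (3-D 0/1 array), `thickness_true` ([enface_map()], px),
#'   `upper_true`, `lower_true` (matrices, NA on disrupted columns) and
#'   `disrupted` (logical matrix)).
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  nb <- g$n_bscans; nz <- g$n_depth; nx <- g$n_ascans
  .with_seed(spec$seed, {
    thick <- spec$band_thickness_px +
      spec$thickness_amplitude * .cosine_field(nb, nx)
    centre <- spec$band_center_row +
      spec$center_amplitude * .cosine_field(nb, nx)
    thick <- pmax(thick, 0)
    disrupted <- .ellipse_mask(nb, nx, spec$disruptions)

    upper <- centre - (thick - 1) / 2
    lower <- upper + thick - 1
    # round half-up (not half-to-even): both edges shift together, so an
    # integer thickness rasterizes to exactly that run length
    z0 <- floor(upper + 0.5); z1 <- floor(lower + 0.5)
    bad <- which(z0 < 0 | z1 > nz - 1)
    if (length(bad)) {
      b_bad <- (bad[1] - 1) %% nb + 1
      x_bad <- (bad[1] - 1) %/% nb + 1
      stop("band escapes image bounds at (b = ", b_bad - 1,
           ", x = ", x_bad - 1, "); adjust band_center_row / amplitudes")
    }
    upper[disrupted] <- NA_real_
    lower[disrupted] <- NA_real_

    mask <- array(0L, c(nb, nz, nx))
    vox <- array(0, c(nb, nz, nx))
    zrow <- matrix(seq_len(nz) - 1L, nz, nx)
    bg <- 0.06 + 0.10 * (seq_len(nz) - 1) / (nz - 1)   # axial gradient

    for (b in seq_len(nb)) {
      u <- matrix(z0[b, ], nz, nx, byrow = TRUE)
      l <- matrix(z1[b, ], nz, nx, byrow = TRUE)
      cen <- matrix(centre[b, ], nz, nx, byrow = TRUE)
      th <- matrix(thick[b, ], nz, nx, byrow = TRUE)
      dis <- matrix(disrupted[b, ], nz, nx, byrow = TRUE)

      band <- !dis & zrow >= u & zrow <= l
      img <- matrix(bg, nz, nx)
      # hyporeflective outer nuclear layer above the band
      onl <- zrow >= cen - th / 2 - 26 & zrow < cen - th / 2 - 2
      img[onl] <- 0.045
      # RPE-like band beneath (persists under disruptions)
      rpe <- zrow >= cen + th / 2 + 3 & zrow <= cen + th / 2 + 9
      img[rpe] <- 0.5
      img[band] <- 0.8

      for (cy in spec$cysts) {
        db <- ((b - 1 - cy$b) / cy$rb)^2
        if (db <= 1) {
          d <- db + ((zrow - cy$z) / cy$rz)^2 +
            (matrix(seq_len(nx) - 1, nz, nx, byrow = TRUE) - cy$x)^2 / cy$rx^2
          img[d <= 1] <- img[d <= 1] * 0.2
        }
      }
      for (sh in spec$shadows) {
        cols <- (sh$x0:sh$x1) + 1L
        cols <- cols[cols >= 1 & cols <= nx]
        img[, cols] <- img[, cols] * sh$factor
      }
      mask[b, , ][band] <- 1L
      vox[b, , ] <- img
    }

    if (spec$speckle_sigma > 0) {
      s <- spec$speckle_sigma
      noise <- exp(stats::rnorm(length(vox), -s^2 / 2, s))
      vox <- vox * array(noise, dim(vox))
    }
    vox <- pmin(pmax(vox, 0), 1)

    run_len <- ifelse(disrupted, 0L, z1 - z0 + 1L)
    list(volume = oct_volume(vox, dx_mm = g$dx_mm, dy_mm = g$dy_mm,
                             dz_um = g$dz_um),
         truth = list(mask = mask,
                      thickness_true = enface_map(run_len, kind = "thickness",
                                                  units = "px",
                                                  dx_mm = g$dx_mm,
                                                  dy_mm = g$dy_mm),
                      upper_true = upper, lower_true = lower,
                      disrupted = disrupted))
  })
}

#' Split items into train / validation / test sets
#'
#' Reproducible, disjoint, exhaustive split with optional stratification
#' (each stratum contributes proportionally to each fold, largest-remainder
#' rounding). The default fractions mirror the 25/3/12 organisation of a
#' 40-volume study.
#'
#' @param items list or vector to split.
#' @param fractions length-3 numeric `(train, val, test)` summing to 1.
#' @param seed RNG seed.
#' @param strata optional vector of stratum labels, same length as `items`
#'   (e.g. phantom pathology class), preserved proportionally across folds.
#' @return list with elements `train`, `val`, `test` (subsets of `items`),
#'   plus an `indices` attribute holding the fold index vectors.
#' @export
split_dataset <- function(items, fractions = c(25, 3, 12) / 40, seed = 0L,
                          strata = NULL) {
  n <- length(items)
  if (n < 3L) stop("need at least 3 items to split, got ", n)
  if (length(fractions) != 3L || any(fractions < 0))
    stop("fractions must be 3 non-negative numbers")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  if (is.null(strata)) strata <- rep(1L, n)
  stopifnot(length(strata) == n)

  .alloc <- function(m, frac) {
    # largest-remainder apportionment of m items across 3 folds
    raw <- frac * m
    base <- floor(raw)
    rem <- m - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    as.integer(base)
  }

  idx <- list(integer(0), integer(0), integer(0))
  .with_seed(seed, {
    for (s in unique(strata)) {
      pool <- sample(which(strata == s))
      k <- .alloc(length(pool), fractions)
      idx[[1]] <- c(idx[[1]], pool[seq_len(k[1])])
      idx[[2]] <- c(idx[[2]], pool[k[1] + seq_len(k[2])])
      idx[[3]] <- c(idx[[3]], pool[k[1] + k[2] + seq_len(k[3])])
    }
  })
  out <- list(train = items[sort(idx[[1]])],
              val = items[sort(idx[[2]])],
              test = items[sort(idx[[3]])])
  attr(out, "indices") <- lapply(idx, sort)
  out
}
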