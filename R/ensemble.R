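# Ensemble fusion: pixel-wise mean + population standard deviation of member
# score maps, then Otsu binarization of the mean score map (per B-scan).

#' Fuse member score maps into mean and disagreement maps
#'
#' Computes, independently per pixel, the arithmetic mean and the population
#' (divide-by-n) standard deviation of the member score maps. The population
#' form bounds the std of `[0, 1]` scores by 0.5.
#'
#' @param score_maps list of >= 2 congruent numeric matrices with values in
#'   `[0, 1]`.
#' @return list with `mean_score` and `std_map` (matrices congruent with the
#'   inputs).
#' @export
fuse_scores <- function(score_maps) {
  if (!is.list(score_maps) || length(score_maps) < 2L)
    stop("need at least 2 score maps to fuse")
  d <- dim(score_maps[[1]])
  for (i in seq_along(score_maps)) {
    m <- score_maps[[i]]
    if (!identical(dim(m), d))
      stop("score map ", i, " has mismatched shape")
    if (!all(is.finite(m)) || min(m) < 0 || max(m) > 1)
      stop("score map ", i, " has values outside [0, 1]")
  }
  n <- length(score_maps)
  s <- Reduce(`+`, score_maps)
  mean_score <- s / n
  ss <- Reduce(`+`, lapply(score_maps, function(m) (m - mean_score)^2))
  list(mean_score = mean_score, std_map = sqrt(ss / n))
}

#' Otsu threshold of a score map
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' `[0, 1]` scores; ties break toward the lowest maximizing threshold. The
#' returned threshold is the lower edge of the first foreground bin, and the
#' binary mask is `scores >= threshold`. A constant map is degenerate: the
#' threshold is the map value and the mask is empty.
#'
#' @param mean_score numeric matrix of scores in `[0, 1]`.
#' @param n_bins histogram resolution (default 256).
#' @return list with `binary` (0/1 integer matrix), `threshold`, and
#'   `degenerate` flag.
#' @export
otsu_binarize <- function(mean_score, n_bins = 256L) {
  if (!all(is.finite(mean_score)) ||
      min(mean_score) < 0 || max(mean_score) > 1)
    stop("scores must be finite and in [0, 1]")
  if (min(mean_score) == max(mean_score)) {
    return(list(binary = array(0L, dim(mean_score)),
                threshold = mean_score[1], degenerate = TRUE))
  }
  bin <- pmin(floor(mean_score * n_bins), n_bins - 1L)  # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = n_bins)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[n_bins]; mu <- m[n_bins]
  # split after bin k: background bins 1..k, foreground k+1..256
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) {
    # all mass in one bin: no split separates the classes
    return(list(binary = array(0L, dim(mean_score)),
                threshold = mean(mean_score), degenerate = TRUE))
  }
  sigma_b <- rep(-Inf, n_bins - 1L)
  mu0 <- m[k] / w0
  mu1 <- (mu - m[k]) / w1
  sigma_b[valid] <- (w0 * w1)[valid] * (mu0 - mu1)[valid]^2
  k_best <- which.max(sigma_b)            # which.max takes the lowest tie
  threshold <- k_best / n_bins            # lower edge of first foreground bin
  binary <- array(0L, dim(mean_score))
  binary[mean_score >= threshold] <- 1L
  list(binary = binary, threshold = threshold, degenerate = FALSE)
}

#' Segment every B-scan of a volume with a model ensemble
#'
#' For each B-scan: predict a score map with every member model, fuse the
#' maps ([fuse_scores()]), and binarize the mean score map with Otsu's method
#' ([otsu_binarize()], computed per B-scan).
#'
#' @param models list of trained models (see [train_model()]); typically the
#'   four U-shaped architectures.
#' @param volume an [oct_volume()].
#' @return list of `ensemble_result` objects ordered by B-scan index, each
#'   with `mean_score`, `std_map`, `binary`, `threshold`, `degenerate`.
#' @export
segment_volume <- function(models, volume) {
  stopifnot(inherits(volume, "oct_volume"), length(models) >= 2L)
  lapply(seq_len(volume$n_bscans), function(b) {
    img <- volume$voxels[b, , , drop = TRUE]
    maps <- lapply(models, predict_bscan, image = img)
    fused <- fuse_scores(maps)
    ots <- otsu_binarize(fused$mean_score)
    structure(list(mean_score = fused$mean_score, std_map = fused$std_map,
                   binary = ots$binary, threshold = ots$threshold,
                   degenerate = ots$degenerate),
              class = "ensemble_result")
  })
}
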