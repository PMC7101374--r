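# Shared fixtures: small phantom specs and hand-built masks, all generated
# in code at test time.

tiny_geometry <- function(n_bscans = 6L, n_depth = 96L, n_ascans = 64L)
  oct_geometry(n_bscans, n_depth, n_ascans, fov_mm = c(6, 6))

# small, quiet phantom: no pathology unless asked for
tiny_spec <- function(geometry = tiny_geometry(), seed = 1L,
                      disruptions = list(), shadows = list(), cysts = list(),
                      speckle_sigma = 0, thickness_amplitude = 2,
                      center_amplitude = 6, band_thickness_px = 10,
                      band_center_row = round(geometry$n_depth * 0.6)) {
  phantom_spec(geometry = geometry, band_center_row = band_center_row,
               band_thickness_px = band_thickness_px,
               thickness_amplitude = thickness_amplitude,
               center_amplitude = center_amplitude,
               disruptions = disruptions, shadows = shadows, cysts = cysts,
               speckle_sigma = speckle_sigma, seed = seed)
}

# B-scan mask with a solid horizontal band on rows r0..r1 (0-based, inclusive)
band_mask <- function(n_depth, n_ascans, r0, r1) {
  m <- matrix(0L, n_depth, n_ascans)
  m[(r0:r1) + 1L, ] <- 1L
  m
}

# per-column foreground run length (brute-force thickness oracle)
column_run_length <- function(mask) {
  apply(mask != 0, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) 0 else max(w) - min(w) + 1
  })
}

# exhaustive 256-bin Otsu oracle: explicit between-class variance at every
# split, means computed from the per-class pixel sets
otsu_oracle <- function(scores, n_bins = 256L) {
  bin <- pmin(floor(scores * n_bins), n_bins - 1L)
  mids <- (bin + 0.5) / n_bins
  best <- -Inf; best_k <- NA
  for (k in 0:(n_bins - 2L)) {
    lo <- mids[bin <= k]; hi <- mids[bin > k]
    if (length(lo) == 0 || length(hi) == 0) next
    s <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; best_k <- k }
  }
  if (is.na(best_k)) NA_real_ else (best_k + 1) / n_bins
}

# exact Wilcoxon signed-rank p by full 2^n sign enumeration (oracle)
wilcoxon_enum_oracle <- function(d, tail = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  p_le <- mean(v_all <= v_obs + 1e-9)
  switch(tail, greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
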