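test_that("same seed gives bit-identical phantom; geometry matches spec", {
  sp <- tiny_spec(seed = 7, speckle_sigma = 0.15,
                  disruptions = list(list(b = 2, x = 20, rb = 1.2, rx = 6)))
  a <- generate_volume(sp)
  b <- generate_volume(sp)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$mask, b$truth$mask)
  expect_equal(dim(a$volume$voxels), c(6L, 96L, 64L))
})

test_that("mask is invariant to speckle and shadow settings", {
  base <- tiny_spec(seed = 3)
  noisy <- tiny_spec(seed = 3, speckle_sigma = 0.4,
                     shadows = list(list(x0 = 10, x1 = 20, factor = 0.3)))
  a <- generate_volume(base)
  b <- generate_volume(noisy)
  expect_identical(a$truth$mask, b$truth$mask)
  # but the image does change
  expect_false(identical(a$volume$voxels, b$volume$voxels))
  # shadows attenuate: shadowed columns are darker on average
  expect_lt(mean(b$volume$voxels[, , 11:21]), mean(a$volume$voxels[, , 11:21]))
})

test_that("thickness_true equals per-column run length of the mask", {
  for (seed in 1:4) {
    sp <- tiny_spec(seed = seed, thickness_amplitude = 3,
                    disruptions = list(list(b = 3, x = 30, rb = 1.5, rx = 8)),
                    speckle_sigma = 0.2)
    v <- generate_volume(sp)
    for (b in seq_len(v$volume$n_bscans)) {
      expect_equal(v$truth$thickness_true$grid[b, ],
                   column_run_length(v$truth$mask[b, , ]))
    }
  }
})

test_that("flat noiseless band has exactly constant thickness", {
  sp <- tiny_spec(thickness_amplitude = 0, center_amplitude = 0,
                  band_thickness_px = 10)
  v <- generate_volume(sp)
  expect_true(all(v$truth$thickness_true$grid == 10))
})

test_that("disruption ellipse zeroes thickness exactly on its footprint", {
  sp <- tiny_spec(disruptions = list(list(b = 5, x = 40, rb = 0.5, rx = 10.4)))
  v <- generate_volume(sp)
  # b = 5 (0-based) is the only affected B-scan; columns within |x-40|<=10
  expect_true(all(v$truth$thickness_true$grid[6, (30:50) + 1] == 0))
  expect_true(all(v$truth$thickness_true$grid[6, -((30:50) + 1)] > 0))
  expect_true(all(v$truth$thickness_true$grid[-6, ] > 0))
  expect_true(all(v$truth$mask[6, , (30:50) + 1] == 0))
})

test_that("band escaping the depth range fails with coordinates", {
  sp <- tiny_spec(band_center_row = 4, band_thickness_px = 12)
  expect_error(generate_volume(sp), "escapes image bounds at \\(b = ")
})

test_that("default spec foreground fraction is ~2% of B-scan pixels", {
  v <- generate_volume(phantom_spec(seed = 0L))
  frac <- mean(vapply(seq_len(dim(v$truth$mask)[1]),
                      function(b) mean(v$truth$mask[b, , ]), numeric(1)))
  expect_gte(frac, 0.015)
  expect_lte(frac, 0.025)
})

test_that("split_dataset reproduces the 25/3/12 organisation", {
  s <- split_dataset(seq_len(40), c(25, 3, 12) / 40, seed = 7)
  expect_equal(lengths(s), c(train = 25L, val = 3L, test = 12L))
  expect_setequal(unlist(s), 1:40)
  s2 <- split_dataset(seq_len(40), c(25, 3, 12) / 40, seed = 7)
  expect_identical(s, s2)
})

test_that("split_dataset handles minimal and stratified cases", {
  s <- split_dataset(1:3, c(1, 1, 1) / 3, seed = 1)
  expect_equal(lengths(s), c(train = 1L, val = 1L, test = 1L))

  strata <- rep(c("RVO", "DME"), each = 20)
  s <- split_dataset(seq_len(40), c(0.5, 0.2, 0.3), seed = 3, strata = strata)
  for (cls in c("RVO", "DME")) {
    in_cls <- which(strata == cls)
    n_test <- length(intersect(s$test, in_cls))
    expect_gte(n_test, 5L)
    expect_lte(n_test, 7L)
  }
  expect_error(split_dataset(1:2, c(1, 1, 1) / 3), "at least 3")
})
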