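test_that("constant band gives exact interfaces, medial axis and thickness", {
  m <- band_mask(200, 40, 100, 110)
  ifs <- extract_interfaces(m)
  expect_equal(ifs$upper, rep(100, 40))
  expect_equal(ifs$lower, rep(110, 40))
  expect_equal(ifs$upper_fit, rep(100, 40))
  expect_equal(ifs$medial, rep(105, 40))
  expect_false(any(ifs$disrupted))
  expect_equal(thickness_profile(ifs), rep(11, 40))
})

test_that("single-pixel band has thickness 1", {
  m <- band_mask(80, 30, 50, 50)
  ifs <- extract_interfaces(m)
  expect_equal(ifs$upper, ifs$lower)
  expect_equal(ifs$medial, rep(50, 30))
  expect_equal(thickness_profile(ifs), rep(1, 30))
})

test_that("disruptions are flagged from the raw mask and bridged by the fit", {
  m <- band_mask(200, 300, 100, 110)
  m[, (200:210) + 1] <- 0L
  ifs <- extract_interfaces(m)
  expect_equal(which(ifs$disrupted) - 1, 200:210)
  # spline bridges the gap within the band's row range
  expect_true(all(ifs$upper_fit[(200:210) + 1] >= 99 &
                  ifs$upper_fit[(200:210) + 1] <= 111))
  expect_true(all(is.finite(ifs$upper_fit)))
  th <- thickness_profile(ifs)
  expect_true(all(th[(200:210) + 1] == 0))
  expect_true(all(abs(th[-((200:210) + 1)] - 11) < 1))
})

test_that("empty mask yields all-disrupted interface set, zero thickness", {
  ifs <- extract_interfaces(matrix(0L, 30, 20))
  expect_true(ifs$empty)
  expect_true(all(ifs$disrupted))
  expect_equal(thickness_profile(ifs), rep(0, 20))
})

test_that("thickness recovery matches run-length oracle on random phantoms", {
  for (seed in 1:3) {
    sp <- tiny_spec(seed = seed, thickness_amplitude = 3,
                    disruptions = list(list(b = 2, x = 25, rb = 1.2, rx = 7)))
    v <- generate_volume(sp)
    for (b in c(1, 3, 6)) {
      mask <- v$truth$mask[b, , ]
      th <- thickness_profile(extract_interfaces(mask))
      rl <- column_run_length(mask)
      expect_true(all(th[rl == 0] == 0))
      expect_lt(max(abs(th - rl)[rl > 0]), 1)
    }
  }
})

test_that("enface_thickness assembles rows from B-scans and scales by dz", {
  masks <- lapply(1:3, function(b) band_mask(60, 20, 20, 29))
  m1 <- enface_thickness(masks, dz_um = 1)
  expect_equal(dim(m1$grid), c(3L, 20L))
  expect_true(all(m1$grid == 10))
  expect_equal(m1$units, "px")
  m35 <- enface_thickness(masks, dz_um = 3.5)
  expect_true(all(m35$grid == 35))
  expect_equal(m35$units, "um")
})

test_that("en-face maps are equivariant to B-scan reordering", {
  set.seed(9)
  masks <- lapply(1:4, function(b) {
    r0 <- sample(10:30, 1)
    band_mask(60, 25, r0, r0 + sample(3:8, 1))
  })
  perm <- c(3, 1, 4, 2)
  a <- enface_thickness(masks)$grid
  b <- enface_thickness(masks[perm])$grid
  expect_equal(b, a[perm, ])
})

test_that("enface_std samples the std map at the medial axis", {
  std <- matrix(0, 60, 20)
  binary <- band_mask(60, 20, 20, 30)   # medial = 25
  std[25 + 1, 7 + 1] <- 0.4             # hot pixel on the medial axis at x=7
  res <- list(list(std_map = matrix(0, 60, 20), binary = binary),
              list(std_map = matrix(0, 60, 20), binary = binary),
              list(std_map = matrix(0, 60, 20), binary = binary),
              list(std_map = std, binary = binary))
  res <- res[c(4, 1, 2, 3)]             # hot B-scan is b = 0
  m <- enface_std(res)
  expect_equal(m$grid[1, 7 + 1], 0.4)
  expect_equal(sum(m$grid != 0), 1L)
  expect_true(all(attr(m, "coverage")))
})

test_that("empty B-scan contributes zeros and is flagged in coverage", {
  binary <- band_mask(40, 10, 10, 15)
  res <- list(list(std_map = matrix(0.2, 40, 10), binary = binary),
              list(std_map = matrix(0.2, 40, 10),
                   binary = matrix(0L, 40, 10)))
  m <- enface_std(res)
  expect_true(all(m$grid[2, ] == 0))
  expect_equal(attr(m, "coverage"), c(TRUE, FALSE))
})

test_that("normalize_for_display follows the min-max rule", {
  out <- normalize_for_display(matrix(c(1, 5, 3, 9), 2))
  expect_equal(out$values, matrix(c(0, 0.5, 0.25, 1), 2))
  expect_false(out$degenerate)

  idm <- matrix(c(0, 0.25, 0.5, 1), 2)
  expect_equal(normalize_for_display(idm)$values, idm)

  cst <- normalize_for_display(matrix(4, 3, 3))
  expect_true(cst$degenerate)
  expect_true(all(cst$values == 0))
})
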