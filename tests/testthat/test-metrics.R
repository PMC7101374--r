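test_that("confusion counts and derived scores match direct arithmetic", {
  # fixture with tp=50, fp=10, fn=30 (tn fills the rest)
  pred <- matrix(0L, 10, 10); truth <- matrix(0L, 10, 10)
  pred[1:60] <- 1L
  truth[11:90] <- 1L   # overlap 11..60 = 50
  cc <- confusion_counts(pred, truth)
  expect_equal(cc[c("tp", "fp", "fn")], list(tp = 50, fp = 10, fn = 30))
  s <- segmentation_scores(cc)
  expect_equal(s$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(s$recall, 0.625)
  expect_equal(round(c(s$precision, s$recall, s$dice), 4),
               c(0.8333, 0.6250, 0.7143))
})

test_that("identity prediction has no errors; empty/empty is flagged NaN", {
  set.seed(12)
  m <- matrix(rbinom(100, 1, 0.3), 10)
  cc <- confusion_counts(m, m)
  expect_equal(cc$fp + cc$fn, 0)
  expect_equal(segmentation_scores(cc)$dice, 1)

  z <- matrix(0L, 5, 5)
  s0 <- segmentation_scores(confusion_counts(z, z))
  expect_true(is.nan(s0$dice))
  expect_false(s0$defined)
})

test_that("dice == 2PR/(P+R) == 2tp/(2tp+fp+fn) on random fixtures", {
  set.seed(13)
  for (i in 1:100) {
    pred <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8)
    truth <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8)
    s <- segmentation_scores(confusion_counts(pred, truth))
    if (!s$defined) next
    expect_equal(s$dice, 2 * s$tp / (2 * s$tp + s$fp + s$fn),
                 tolerance = 1e-14)
    if (is.finite(s$precision) && is.finite(s$recall) &&
        s$precision + s$recall > 0) {
      expect_equal(s$dice,
                   2 * s$precision * s$recall / (s$precision + s$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("region argument restricts counting to whole A-scan columns", {
  pred <- matrix(1L, 4, 6)
  truth <- matrix(0L, 4, 6); truth[, 1:3] <- 1L
  region <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  cc <- confusion_counts(pred, truth, region)
  expect_equal(cc$tp, 8); expect_equal(cc$fp, 0)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 8)

  # 3-D volume with an en-face region matrix
  pv <- array(1L, c(2, 4, 6)); tv <- array(0L, c(2, 4, 6))
  tv[1, , 1:3] <- 1L
  reg <- matrix(FALSE, 2, 6); reg[1, 1:3] <- TRUE
  cc3 <- confusion_counts(pv, tv, reg)
  expect_equal(cc3$tp, 12); expect_equal(cc3$fp, 0); expect_equal(cc3$tn, 0)
})

test_that("pr_curve: perfect, constant and random scorers", {
  truth <- matrix(0L, 20, 25)
  truth[3:6, ] <- 1L   # prevalence 0.2
  perfect <- pr_curve(truth + 0, truth)
  expect_equal(perfect$auc, 1)

  const <- pr_curve(matrix(0.5, 20, 25), truth)
  expect_equal(const$auc, 0.2, tolerance = 1e-12)
  expect_true(all(const$recall == 1))
  expect_true(all(const$precision == 0.2))

  set.seed(14)
  n <- 100 * 100
  truth_r <- matrix(rbinom(n, 1, 0.2), 100)
  rand <- pr_curve(matrix(runif(n), 100), truth_r)
  expect_equal(rand$auc, mean(truth_r), tolerance = 0.03)
})

test_that("pr_curve AUC is invariant to monotone score transforms", {
  set.seed(15)
  truth <- matrix(rbinom(2500, 1, 0.1), 50)
  s <- matrix(runif(2500), 50)^2 * 0.6 + truth * runif(2500, 0, 0.4)
  s <- s / max(s)
  a1 <- pr_curve(s, truth, n_thresholds = 1001L)$auc
  a2 <- pr_curve(s^2, truth, n_thresholds = 1001L)$auc
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("pr_curve rejects regions without positives", {
  expect_error(pr_curve(matrix(0.5, 3, 3), matrix(0L, 3, 3)), "no positive")
})

test_that("ETDRS regions match a brute-force distance scan", {
  nb <- 49L; nx <- 512L
  dx <- 6 / 512; dy <- 6 / 49
  reg <- etdrs_regions(nb, nx, dx, dy, fovea_center = c(24, 255.5))
  # brute force over all cells
  brute_csf <- 0L; brute_ring <- 0L
  for (b in 0:(nb - 1)) for (x in 0:(nx - 1)) {
    d <- sqrt(((b - 24) * dy)^2 + ((x - 255.5) * dx)^2)
    if (d <= 0.5) brute_csf <- brute_csf + 1L
    if (d > 0.5 && d <= 1.5) brute_ring <- brute_ring + 1L
  }
  expect_equal(sum(reg$csf), brute_csf)
  expect_equal(sum(reg$ring31), brute_ring)
  # area sanity: ~ pi * r^2 / cell area, within discretization
  expect_equal(sum(reg$csf), pi * 0.25 / (dx * dy), tolerance = 0.06)
  # partition properties
  expect_equal(sum(reg$csf & reg$ring31), 0L)
  expect_identical(reg$cmm3, reg$csf | reg$ring31)
})

test_that("corner fovea yields about a quarter-disk CSF", {
  nb <- 49L; nx <- 512L
  dx <- 6 / 512; dy <- 6 / 49
  centred <- sum(etdrs_regions(nb, nx, dx, dy,
                               fovea_center = c(24, 255.5))$csf)
  corner_reg <- etdrs_regions(nb, nx, dx, dy, fovea_center = c(0, 0))
  corner <- sum(corner_reg$csf)
  # exact brute-force oracle at the corner
  brute <- 0L
  for (b in 0:(nb - 1)) for (x in 0:(nx - 1)) {
    if (sqrt((b * dy)^2 + (x * dx)^2) <= 0.5) brute <- brute + 1L
  }
  expect_equal(corner, brute)
  # ~ quarter of the centred disk, up to the half-row/half-column of cells
  # that sit exactly on the axes at a corner fovea
  expect_equal(corner, centred / 4, tolerance = 0.2)
})

test_that("region_mean_thickness averages with zeros included", {
  reg <- etdrs_regions(9L, 9L, dx_mm = 0.25, dy_mm = 0.25)
  uni <- matrix(10, 9, 9)
  expect_equal(unname(region_mean_thickness(uni, reg)),
               rep(10, 4))
  inside <- matrix(0, 9, 9); inside[reg$csf] <- 10
  got <- region_mean_thickness(inside, reg)
  expect_equal(unname(got["full"]), 10 * sum(reg$csf) / 81)
  expect_equal(unname(got["csf"]), 10)
})

test_that("sample_bscans eligibility matches brute-force bands", {
  nb <- 49L; dy <- 6 / 49
  s <- sample_bscans(nb, dy, fovea_b = 0, seed = 21)
  dist <- abs(0:(nb - 1) - 0) * dy
  expect_true(all(dist[s$band_0_1 + 1] <= 1))
  expect_true(all(dist[s$band_1_3 + 1] > 1 & dist[s$band_1_3 + 1] <= 3))
  expect_true(all(dist[s$band_3_6 + 1] > 3 & dist[s$band_3_6 + 1] <= 6))
  expect_true(all(lengths(s) == 2))
  # determinism
  expect_identical(s, sample_bscans(nb, dy, fovea_b = 0, seed = 21))
  # different seed, different draw (with very high probability)
  expect_false(identical(s, sample_bscans(nb, dy, fovea_b = 0, seed = 22)))
})

test_that("centred fovea on a 6 mm scan leaves the 3-6 mm band empty", {
  expect_error(sample_bscans(49L, 6 / 49, fovea_b = 24, seed = 1),
               "band_3_6.*eligible")
})
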