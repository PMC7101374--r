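test_that("all four architectures satisfy the shape and range contract", {
  set.seed(41)
  img <- matrix(runif(64 * 64), 64)
  for (arch in c("unet", "all_dropout", "bru_net", "u2net")) {
    m <- build_model(model_config(arch, depth = 3L, base_channels = 8L,
                                  seed = 42))
    s <- predict_bscan(m, img)
    expect_equal(dim(s), c(64L, 64L), label = arch)
    expect_true(all(is.finite(s) & s >= 0 & s <= 1), label = arch)
    # determinism: same image twice -> bit-identical maps
    expect_identical(s, predict_bscan(m, img), label = arch)
  }
})

test_that("non-multiple-of-2^depth sizes are padded and cropped back", {
  m <- build_model(model_config("unet", depth = 3L, base_channels = 4L,
                                seed = 1))
  img <- matrix(runif(61 * 37), 61)
  s <- predict_bscan(m, img)
  expect_equal(dim(s), c(61L, 37L))
  # full B-scan geometry (496 x 512) maps to a congruent score map
  big <- matrix(runif(496 * 64), 496, 64)  # narrow slice keeps it fast
  expect_equal(dim(predict_bscan(m, big)), c(496L, 64L))
})

test_that("dropout at rate 0 makes train and eval passes identical", {
  m <- build_model(model_config("all_dropout", depth = 2L, base_channels = 4L,
                                dropout_rate = 0, seed = 2))
  x <- matrix(runif(16 * 16), 16)
  f1 <- prlquant:::.forward_logits(m, x, training = TRUE)
  f2 <- prlquant:::.forward_logits(m, x, training = FALSE)
  expect_identical(f1$tape$vals[[f1$out]], f2$tape$vals[[f2$out]])
})

test_that("dropout at positive rate perturbs the training pass only", {
  m <- build_model(model_config("all_dropout", depth = 2L, base_channels = 4L,
                                dropout_rate = 0.5, seed = 2))
  x <- matrix(runif(16 * 16), 16)
  set.seed(1)
  f1 <- prlquant:::.forward_logits(m, x, training = TRUE)
  e1 <- prlquant:::.forward_logits(m, x, training = FALSE)
  e2 <- prlquant:::.forward_logits(m, x, training = FALSE)
  expect_false(identical(f1$tape$vals[[f1$out]], e1$tape$vals[[e1$out]]))
  expect_identical(e1$tape$vals[[e1$out]], e2$tape$vals[[e2$out]])
})

test_that("u2net has strictly more parameters than unet at equal size", {
  n_u <- n_params(build_model(model_config("unet", depth = 3L,
                                           base_channels = 8L)))
  n_u2 <- n_params(build_model(model_config("u2net", depth = 3L,
                                            base_channels = 8L)))
  expect_gt(n_u2, n_u)
})

test_that("unknown architecture is rejected", {
  expect_error(model_config("resnet"), "unknown arch_name")
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(43)
  for (arch in c("unet", "bru_net", "u2net")) {
    cfg <- model_config(arch, depth = 2L, base_channels = 4L,
                        dropout_rate = 0, seed = 3)
    m <- build_model(cfg)
    x <- matrix(runif(64), 8)
    y <- matrix(rbinom(64, 1, 0.3), 8)
    loss_of <- function() {
      fwd <- prlquant:::.forward_logits(m, x, training = FALSE)
      logits <- fwd$tape$vals[[fwd$out]]
      prlquant:::.dice_bce_loss(logits, array(y, dim(logits)))
    }
    l <- local({
      fwd <- prlquant:::.forward_logits(m, x, training = FALSE)
      logits <- fwd$tape$vals[[fwd$out]]
      ll <- prlquant:::.dice_bce_loss(logits, array(y, dim(logits)))
      list(g = prlquant:::tape_backward(fwd$tape, fwd$out, ll$grad))
    })
    nm <- names(l$g)[1]
    for (i in unique(pmin(c(1L, 5L), length(m$params[[nm]]$w)))) {
      eps <- 1e-6
      w0 <- m$params[[nm]]$w[i]
      m$params[[nm]]$w[i] <- w0 + eps; lp <- loss_of()$loss
      m$params[[nm]]$w[i] <- w0 - eps; lm <- loss_of()$loss
      m$params[[nm]]$w[i] <- w0
      num <- (lp - lm) / (2 * eps)
      expect_equal(l$g[[nm]]$w[i], num, tolerance = 1e-4, label = arch)
    }
  }
})

test_that("training is seeded-reproducible and memorizes a single image", {
  img <- band_mask(32, 32, 12, 18) * 0.7 + 0.05
  msk <- band_mask(32, 32, 12, 18)
  pair <- list(list(image = img, mask = msk))
  cfg <- model_config("unet", depth = 2L, base_channels = 4L,
                      max_epochs = 12L, patience = 12L, crop_size = 32L,
                      crops_per_epoch = 20L, seed = 7)
  m1 <- build_model(cfg); train_model(m1, pair, pair, cfg)
  m2 <- build_model(cfg); train_model(m2, pair, pair, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # memorization: best validation dice is high and the best is tracked
  expect_gte(max(m1$history$val_dice), 0.95)
  expect_equal(m1$best_score, max(m1$history$val_dice))
})

test_that("early stopping respects patience with a frozen learning rate", {
  img <- band_mask(16, 16, 6, 9) * 0.8
  pair <- list(list(image = img, mask = band_mask(16, 16, 6, 9)))
  cfg <- model_config("unet", depth = 2L, base_channels = 4L,
                      max_epochs = 10L, patience = 1L, crop_size = 16L,
                      crops_per_epoch = 2L, learning_rate = 0, seed = 8)
  m <- build_model(cfg)
  train_model(m, pair, pair, cfg)
  expect_lte(nrow(m$history), 2L)
})

test_that("empty training set and non-finite images are rejected", {
  m <- build_model(model_config("unet", depth = 2L, base_channels = 4L))
  expect_error(train_model(m, list()), "empty training set")
  expect_error(predict_bscan(m, matrix(NaN, 8, 8)), "non-finite")
})

test_that("models round-trip through save_model / load_model", {
  m <- build_model(model_config("bru_net", depth = 2L, base_channels = 4L,
                                seed = 9))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  img <- matrix(runif(32 * 32), 32)
  expect_identical(predict_bscan(m, img), predict_bscan(m2, img))
})

test_that("a tiny unet learns noiseless phantom B-scans to dice >= 0.9", {
  sp <- tiny_spec(geometry = tiny_geometry(4L, 96L, 64L), seed = 44,
                  speckle_sigma = 0, thickness_amplitude = 2)
  v <- generate_volume(sp)
  pairs <- lapply(seq_len(4), function(b)
    list(image = v$volume$voxels[b, , ], mask = v$truth$mask[b, , ]))
  cfg <- model_config("unet", depth = 3L, base_channels = 8L,
                      max_epochs = 8L, patience = 8L, crop_size = 64L,
                      crops_per_epoch = 30L, seed = 10)
  m <- build_model(cfg)
  train_model(m, pairs[1:3], pairs[4], cfg)
  expect_gte(max(m$history$val_dice), 0.9)
})
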