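# Training (Adam on soft-Dice + binary cross-entropy) and inference for the
# segmentation networks. Everything is seeded and single-threaded, so runs
# are reproducible on a fixed machine configuration.

# reflect-pad a matrix so both sides are multiples of m; returns the padded
# matrix and the original size
.pad_to_multiple <- function(img, m) {
  h <- nrow(img); w <- ncol(img)
  ph <- (m - h %% m) %% m
  pw <- (m - w %% m) %% m
  if (ph > 0) img <- rbind(img, img[h - seq_len(ph) + 1, , drop = FALSE])
  if (pw > 0) img <- cbind(img, img[, w - seq_len(pw) + 1, drop = FALSE])
  list(img = img, h = h, w = w)
}

# loss and gradient w.r.t. logits for a sigmoid score map:
# BCE (mean) + (1 - soft Dice)
.dice_bce_loss <- function(logits, y, eps = 1) {
  p <- 1 / (1 + exp(-logits))
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  dice_soft <- (2 * spy + eps) / (sp + sy + eps)
  loss <- bce + (1 - dice_soft)
  ddice_dp <- (2 * y * (sp + sy + eps) - (2 * spy + eps)) / (sp + sy + eps)^2
  dloss_dp_bce <- (p - y) / (pc * (1 - pc)) / n
  dz <- dloss_dp_bce * p * (1 - p) - ddice_dp * p * (1 - p)
  list(loss = loss, grad = dz, dice_soft = dice_soft)
}

.dice_binary <- function(pred, truth) {
  tp <- sum(pred & truth)
  den <- 2 * tp + sum(pred & !truth) + sum(!pred & truth)
  if (den == 0) NaN else 2 * tp / den
}

# sample a training crop, biased toward windows containing foreground
.sample_crop <- function(img, mask, size, fg_bias) {
  h <- nrow(img); w <- ncol(img)
  if (h <= size && w <= size) return(list(img = img, mask = mask))
  ch <- min(size, h); cw <- min(size, w)
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) > 0 && stats::runif(1) < fg_bias) {
    ctr <- fg[sample.int(nrow(fg), 1L), ] +
      round(stats::runif(2, -size / 8, size / 8))
    r0 <- min(max(ctr[1] - ch %/% 2, 1), h - ch + 1)
    c0 <- min(max(ctr[2] - cw %/% 2, 1), w - cw + 1)
  } else {
    r0 <- sample.int(h - ch + 1L, 1L)
    c0 <- sample.int(w - cw + 1L, 1L)
  }
  list(img = img[r0:(r0 + ch - 1), c0:(c0 + cw - 1)],
       mask = mask[r0:(r0 + ch - 1), c0:(c0 + cw - 1)])
}

.adam_update <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (part in c("w", "b")) {
      g <- grads[[nm]][[part]]
      key <- paste0(nm, ".", part)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      step <- lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
      model$params[[nm]][[part]] <- model$params[[nm]][[part]] - step
    }
  }
  invisible(state)
}

#' Train a segmentation model
#'
#' Optimizes soft-Dice + binary cross-entropy with Adam over randomly sampled
#' (foreground-biased) square crops. After each epoch the model is scored on
#' the validation pairs by binary Dice at threshold 0.5; the parameters of
#' the best validation epoch are restored at the end, and training stops
#' early after `config$patience` epochs without improvement.
#'
#' @param model a `prl_model` from [build_model()].
#' @param train_pairs list of `list(image =, mask =)` with congruent 2-D
#'   matrices, image in `[0, 1]`, mask 0/1.
#' @param val_pairs like `train_pairs`; used for model selection. If `NULL`,
#'   the (negative) training loss is used instead.
#' @param config a [model_config()]; defaults to the model's own.
#' @return the model (invisibly modified in place), with `history`
#'   (data.frame epoch / loss / val_dice) and `trained = TRUE`.
#' @export
train_model <- function(model, train_pairs, val_pairs = NULL,
                        config = model$config) {
  stopifnot(inherits(model, "prl_model"))
  if (length(train_pairs) == 0L) stop("empty training set")
  for (p in train_pairs)
    stopifnot(is.matrix(p$image), identical(dim(p$image), dim(p$mask)))
  m <- 2^(config$depth - 1)
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()

  best_score <- -Inf
  best_params <- NULL
  since_best <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_dice = numeric(0))

  .with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      loss_sum <- 0
      for (step in seq_len(config$crops_per_epoch)) {
        pair <- train_pairs[[sample.int(length(train_pairs), 1L)]]
        crop <- .sample_crop(pair$image, pair$mask, config$crop_size,
                             config$fg_bias)
        pi <- .pad_to_multiple(crop$img, m)
        pm <- .pad_to_multiple(crop$mask, m)
        fwd <- .forward_logits(model, pi$img, training = TRUE)
        logits <- fwd$tape$vals[[fwd$out]]
        l <- .dice_bce_loss(logits, array(pm$img, dim(logits)))
        if (!is.finite(l$loss))
          stop("NaN/Inf loss at epoch ", epoch, ", step ", step,
               " (arch ", config$arch_name, "); lower the learning rate")
        loss_sum <- loss_sum + l$loss
        grads <- tape_backward(fwd$tape, fwd$out, l$grad)
        .adam_update(model, grads, state, config$learning_rate)
      }
      mean_loss <- loss_sum / config$crops_per_epoch

      score <- if (!is.null(val_pairs) && length(val_pairs) > 0) {
        dices <- vapply(val_pairs, function(vp) {
          pr <- predict_bscan(model, vp$image)
          .dice_binary(pr >= 0.5, vp$mask != 0)
        }, numeric(1))
        mean(dices, na.rm = TRUE)
      } else -mean_loss
      val_dice <- if (!is.null(val_pairs) && length(val_pairs) > 0)
        score else NA_real_
      history <- rbind(history, data.frame(epoch = epoch, loss = mean_loss,
                                           val_dice = val_dice))
      if (score > best_score) {
        best_score <- score
        best_params <- model$params
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  })
  if (!is.null(best_params)) model$params <- best_params
  model$history <- history
  model$best_score <- best_score
  model$trained <- TRUE
  invisible(model)
}

#' Predict a score map for one B-scan
#'
#' Pure function of the model parameters and the image: reflect-pads the
#' input to a multiple of `2^(depth-1)`, runs the network in evaluation mode
#' (dropout off) and crops back, returning a `[0, 1]` score map congruent
#' with the input.
#'
#' @param model a `prl_model`.
#' @param image 2-D matrix with values in `[0, 1]`.
#' @return numeric matrix of pseudo-probabilities, same size as `image`.
#' @export
predict_bscan <- function(model, image) {
  stopifnot(inherits(model, "prl_model"), is.matrix(image))
  if (!all(is.finite(image)))
    stop("image contains non-finite pixels")
  m <- 2^(model$config$depth - 1)
  pd <- .pad_to_multiple(image, m)
  fwd <- .forward_logits(model, pd$img, training = FALSE)
  logits <- fwd$tape$vals[[fwd$out]][, , 1]
  score <- 1 / (1 + exp(-logits))
  score[seq_len(pd$h), seq_len(pd$w), drop = FALSE]
}

#' Save / load a trained model
#'
#' Serializes parameters, configuration and training history into a single
#' file (RDS container with the configuration embedded as JSON for
#' inspection with external tools).
#'
#' @param model a `prl_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config_json = jsonlite::toJSON(unclass(model$config),
                                              auto_unbox = TRUE),
               config = model$config, params = model$params,
               history = model$history, trained = model$trained),
          path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model`: the restored `prl_model`.
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$config <- x$config
  model$params <- x$params
  model$history <- x$history
  model$trained <- isTRUE(x$trained)
  class(model) <- "prl_model"
  model
}
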