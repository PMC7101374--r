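# The four U-shaped fully-convolutional architectures of the ensemble:
# a standard U-Net; an "all-dropout" variant with dropout after every
# convolution block; a residual-bottleneck variant ("BRU-style"); and a
# cascaded two-stage U ("U2-style") in which a second U refines the first
# stage's score map. All share one I/O contract: a [0,1] grayscale B-scan in,
# a congruent score map out, so they are interchangeable inside the ensemble.

.ARCHS <- c("unet", "all_dropout", "bru_net", "u2net")

#' Model configuration
#'
#' @param arch_name one of `"unet"`, `"all_dropout"`, `"bru_net"`, `"u2net"`.
#' @param depth number of resolution levels (>= 2).
#' @param base_channels filters at the first level (>= 4); doubled per level.
#' @param dropout_rate dropout probability; defaults to 0.2 for
#'   `all_dropout`, 0 otherwise.
#' @param loss_name training loss; `"dice_bce"` (soft-Dice + binary
#'   cross-entropy) is the only built-in.
#' @param learning_rate Adam step size.
#' @param max_epochs,patience training length and early-stopping patience
#'   (epochs without validation improvement).
#' @param crop_size square training crop side (padded to a multiple of
#'   `2^(depth-1)`).
#' @param crops_per_epoch optimizer steps per epoch.
#' @param fg_bias fraction of crops centred on a foreground pixel.
#' @param seed RNG seed for initialization, cropping and dropout.
#' @return a `model_config` list.
#' @export
model_config <- function(arch_name = "unet", depth = 3L, base_channels = 8L,
                         dropout_rate = NULL, loss_name = "dice_bce",
                         learning_rate = 1e-3, max_epochs = 30L,
                         patience = 5L, crop_size = 64L,
                         crops_per_epoch = 100L, fg_bias = 0.7, seed = 0L) {
  if (!arch_name %in% .ARCHS)
    stop("unknown arch_name '", arch_name, "'; choose one of: ",
         paste(.ARCHS, collapse = ", "))
  if (is.null(dropout_rate))
    dropout_rate <- if (arch_name == "all_dropout") 0.2 else 0
  stopifnot(depth >= 2L, base_channels >= 4L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(arch_name = arch_name, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dropout_rate = dropout_rate, loss_name = loss_name,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 crop_size = as.integer(crop_size),
                 crops_per_epoch = as.integer(crops_per_epoch),
                 fg_bias = fg_bias, seed = as.integer(seed)),
            class = "model_config")
}

# double conv block, optionally with dropout after each conv-relu
.cblock <- function(tape, id, name, ch, rate) {
  id <- t_relu(tape, t_conv(tape, id, paste0(name, "a"), ch))
  if (rate > 0 || tape$model$config$arch_name == "all_dropout")
    id <- t_dropout(tape, id, rate)
  id <- t_relu(tape, t_conv(tape, id, paste0(name, "b"), ch))
  if (rate > 0 || tape$model$config$arch_name == "all_dropout")
    id <- t_dropout(tape, id, rate)
  id
}

# residual bottleneck block: 1x1 reduce -> 3x3 -> 1x1 expand + skip
.rblock <- function(tape, id, name, ch) {
  r <- t_relu(tape, t_conv(tape, id, paste0(name, "r1"), max(ch %/% 2, 1),
                           k = 1L))
  r <- t_relu(tape, t_conv(tape, r, paste0(name, "r2"), max(ch %/% 2, 1)))
  r <- t_conv(tape, r, paste0(name, "r3"), ch, k = 1L)
  t_relu(tape, t_add(tape, id, r))
}

# one U pass (encoder-decoder with skip connections); `block` renders a
# level's feature block, `prefix` namespaces the parameters
.u_pass <- function(tape, id, prefix, block, depth, base, rate) {
  skips <- integer(depth - 1)
  for (l in seq_len(depth - 1)) {
    id <- block(tape, id, paste0(prefix, "enc", l), base * 2^(l - 1), rate)
    skips[l] <- id
    id <- t_pool2(tape, id)
  }
  id <- block(tape, id, paste0(prefix, "bot"), base * 2^(depth - 1), rate)
  for (l in rev(seq_len(depth - 1))) {
    ch <- base * 2^(l - 1)
    id <- t_up2(tape, id)
    id <- t_relu(tape, t_conv(tape, id, paste0(prefix, "up", l), ch))
    id <- t_concat(tape, id, skips[l])
    id <- block(tape, id, paste0(prefix, "dec", l), ch, rate)
  }
  t_conv(tape, id, paste0(prefix, "head"), 1L, k = 1L)   # logits
}

# forward pass to logits; input H, W must be multiples of 2^(depth-1)
.forward_logits <- function(model, x, training = FALSE) {
  cfg <- model$config
  tape <- nn_tape(model, training)
  id <- t_input(tape, x)
  rate <- cfg$dropout_rate
  out <- switch(cfg$arch_name,
    unet = .u_pass(tape, id, "", .cblock, cfg$depth, cfg$base_channels, 0),
    all_dropout = .u_pass(tape, id, "", .cblock, cfg$depth,
                          cfg$base_channels, rate),
    bru_net = {
      blk <- function(tape, id, name, ch, r) {
        id <- t_relu(tape, t_conv(tape, id, paste0(name, "in"), ch))
        .rblock(tape, id, name, ch)
      }
      .u_pass(tape, id, "", blk, cfg$depth, cfg$base_channels, 0)
    },
    u2net = {
      s1 <- .u_pass(tape, id, "s1_", .cblock, cfg$depth, cfg$base_channels, 0)
      s1s <- t_sigmoid(tape, s1)
      id2 <- t_concat(tape, id, s1s)
      .u_pass(tape, id2, "s2_", .cblock, cfg$depth, cfg$base_channels, 0)
    })
  list(tape = tape, out = out)
}

#' Build an untrained segmentation model
#'
#' Instantiates the architecture and initializes all parameters (He normal,
#' seeded by `config$seed`) by tracing one dummy forward pass, so parameter
#' creation order — and hence initialization — is deterministic.
#'
#' @param config a [model_config()].
#' @return a `prl_model` (environment with `config`, `params`, `history`).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- list()
  model$history <- NULL
  model$trained <- FALSE
  class(model) <- "prl_model"
  m <- 2^(config$depth - 1)
  .with_seed(config$seed, {
    dummy <- array(0, c(2 * m, 2 * m, 1))
    invisible(.forward_logits(model, dummy, training = FALSE))
  })
  model
}

#' Number of learnable parameters of a model
#' @param model a `prl_model`.
#' @return integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params,
             function(p) length(p$w) + length(p$b), numeric(1)))
}

#' @export
print.prl_model <- function(x, ...) {
  cat(sprintf("prl_model '%s': depth %d, base %d, %s, %d parameters\n",
              x$config$arch_name, x$config$depth, x$config$base_channels,
              if (x$trained) "trained" else "untrained",
              n_params(x)))
  invisible(x)
}
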