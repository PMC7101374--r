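# A small reverse-mode tape for the segmentation networks. Forward calls
# record one node per primitive (conv / relu / sigmoid / maxpool / upsample /
# concat / add / dropout); tape_backward() walks the record in reverse and
# accumulates gradients for inputs and parameters. Parameters live in the
# model's environment and are created lazily (He initialization) the first
# time a conv layer is traversed, so each architecture definition exists in
# exactly one place.

nn_tape <- function(model, training = FALSE) {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- list()
  tape$vals <- list()
  tape$model <- model
  tape$training <- training
  tape
}

.tape_push <- function(tape, op, value, inputs = integer(0), extra = NULL) {
  id <- length(tape$nodes) + 1L
  tape$nodes[[id]] <- list(op = op, inputs = inputs, extra = extra)
  tape$vals[[id]] <- value
  id
}

.as_cube <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}

t_input <- function(tape, x) .tape_push(tape, "input", .as_cube(x))

# lazily-initialized convolution parameters; w stored as (k*k*cin, cout)
.conv_params <- function(model, name, cin, cout, k) {
  if (is.null(model$params[[name]])) {
    fan_in <- k * k * cin
    w <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                fan_in, cout)
    model$params[[name]] <- list(w = w, b = numeric(cout),
                                 cin = cin, cout = cout, k = k)
  }
  p <- model$params[[name]]
  if (p$cin != cin || p$cout != cout || p$k != k)
    stop("parameter '", name, "' reused with incompatible shape")
  p
}

t_conv <- function(tape, id, name, cout, k = 3L) {
  force(id)
  x <- tape$vals[[id]]
  p <- .conv_params(tape$model, name, dim(x)[3], cout, k)
  y <- nn_conv_fwd(x, p$w, p$b, k)
  .tape_push(tape, "conv", y, id, list(name = name, k = k))
}

t_relu <- function(tape, id) {
  force(id)
  x <- tape$vals[[id]]
  .tape_push(tape, "relu", pmax(x, 0), id)
}

t_sigmoid <- function(tape, id) {
  force(id)
  x <- tape$vals[[id]]
  .tape_push(tape, "sigmoid", 1 / (1 + exp(-x)), id)
}

t_pool2 <- function(tape, id) {
  force(id)
  x <- tape$vals[[id]]
  r <- nn_pool2_fwd(x)
  .tape_push(tape, "pool2", r$y, id,
             list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}

t_up2 <- function(tape, id) {
  force(id)
  .tape_push(tape, "up2", nn_up2_fwd(tape$vals[[id]]), id)
}

t_concat <- function(tape, id1, id2) {
  force(id1); force(id2)
  x1 <- tape$vals[[id1]]; x2 <- tape$vals[[id2]]
  stopifnot(dim(x1)[1] == dim(x2)[1], dim(x1)[2] == dim(x2)[2])
  .tape_push(tape, "concat", abind::abind(x1, x2, along = 3),
             c(id1, id2), list(c1 = dim(x1)[3]))
}

t_add <- function(tape, id1, id2) {
  force(id1); force(id2)
  .tape_push(tape, "add", tape$vals[[id1]] + tape$vals[[id2]], c(id1, id2))
}

# inverted dropout; identity (and no RNG consumption) when rate is 0 or in
# evaluation mode
t_dropout <- function(tape, id, rate) {
  force(id)
  x <- tape$vals[[id]]
  if (!tape$training || rate <= 0)
    return(.tape_push(tape, "identity", x, id))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  .tape_push(tape, "dropout", x * mask, id, list(mask = mask))
}

# Backward pass from node `out_id` seeded with gradient `gout`; returns a
# named list of parameter gradients (matching model$params element names,
# each a list(w, b)).
tape_backward <- function(tape, out_id, gout) {
  n <- length(tape$nodes)
  grads <- vector("list", n)
  grads[[out_id]] <- .as_cube(gout)
  pg <- list()
  acc <- function(slot, g) {
    if (is.null(grads[[slot]])) g else grads[[slot]] + g
  }
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    ins <- node$inputs
    switch(node$op,
      input = NULL,
      identity = {
        grads[[ins]] <- acc(ins, g)
      },
      conv = {
        x <- tape$vals[[ins]]
        p <- tape$model$params[[node$extra$name]]
        r <- nn_conv_bwd(x, p$w, g, node$extra$k)
        grads[[ins]] <- acc(ins, r$gx)
        nm <- node$extra$name
        if (is.null(pg[[nm]])) {
          pg[[nm]] <- list(w = r$gw, b = as.numeric(r$gb))
        } else {
          pg[[nm]]$w <- pg[[nm]]$w + r$gw
          pg[[nm]]$b <- pg[[nm]]$b + as.numeric(r$gb)
        }
      },
      relu = {
        x <- tape$vals[[ins]]
        grads[[ins]] <- acc(ins, g * (x > 0))
      },
      sigmoid = {
        y <- tape$vals[[id]]
        grads[[ins]] <- acc(ins, g * y * (1 - y))
      },
      pool2 = {
        e <- node$extra
        grads[[ins]] <- acc(ins, nn_pool2_bwd(e$idx, g, e$H, e$W))
      },
      up2 = {
        grads[[ins]] <- acc(ins, nn_up2_bwd(g))
      },
      concat = {
        c1 <- node$extra$c1
        g1 <- g[, , seq_len(c1), drop = FALSE]
        g2 <- g[, , -seq_len(c1), drop = FALSE]
        grads[[ins[1]]] <- acc(ins[1], g1)
        grads[[ins[2]]] <- acc(ins[2], g2)
      },
      add = {
        grads[[ins[1]]] <- acc(ins[1], g)
        grads[[ins[2]]] <- acc(ins[2], g)
      },
      dropout = {
        grads[[ins]] <- acc(ins, g * node$extra$mask)
      },
      stop("unknown op in tape: ", node$op))
    grads[id] <- list(NULL)   # free as we go
  }
  pg
}
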