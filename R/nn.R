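# Minimal feed-forward network engine used by both classifier families.
#
# Conventions: convolutional tensors are column-major arrays (H, W, C, N);
# dense activations are matrices (N x D).  A network is a list of layer
# lists; each layer carries its parameters, an optional `frozen` flag, and
# a forward cache used by the backward pass.

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' @rdname nn_layers
#' @export
layer_conv <- function(filters, kernel = 3L, l2 = 0) {
  structure(list(type = "conv", filters = as.integer(filters),
                 kernel = as.integer(kernel), l2 = l2, frozen = FALSE),
            class = "mvskel_layer")
}

#' Network layer constructors
#'
#' Building blocks for [nn_net()]: 'same'-padded stride-1 convolution, ReLU
#' and sigmoid activations, 2x2 max pooling, 2x2 nearest upsampling, global
#' average pooling, flatten, reshape, dropout and dense (fully connected)
#' layers.  Parameters are lazily initialized on the first forward pass from
#' the actual input shape.
#'
#' @param filters,units Output channel / unit counts.
#' @param kernel Odd kernel size for convolutions.
#' @param l2 L2 weight-penalty coefficient for this layer's weights.
#' @param rate Dropout rate in `[0, 1)`.
#' @param shape Target `(h, w, c)` for [layer_reshape()].
#' @name nn_layers
#' @export
layer_dense <- function(units, l2 = 0) {
  structure(list(type = "dense", units = as.integer(units), l2 = l2,
                 frozen = FALSE), class = "mvskel_layer")
}

#' @rdname nn_layers
#' @export
layer_relu <- function() structure(list(type = "relu", frozen = FALSE), class = "mvskel_layer")

#' @rdname nn_layers
#' @export
layer_sigmoid <- function() structure(list(type = "sigmoid", frozen = FALSE), class = "mvskel_layer")

#' @rdname nn_layers
#' @export
layer_maxpool <- function() structure(list(type = "maxpool", frozen = FALSE), class = "mvskel_layer")

#' @rdname nn_layers
#' @export
layer_upsample <- function() structure(list(type = "upsample", frozen = FALSE), class = "mvskel_layer")

#' @rdname nn_layers
#' @export
layer_gap <- function() structure(list(type = "gap", frozen = FALSE), class = "mvskel_layer")

#' @rdname nn_layers
#' @export
layer_flatten <- function() structure(list(type = "flatten", frozen = FALSE), class = "mvskel_layer")

#' @rdname nn_layers
#' @export
layer_reshape <- function(shape) {
  structure(list(type = "reshape", shape = as.integer(shape), frozen = FALSE),
            class = "mvskel_layer")
}

#' @rdname nn_layers
#' @export
layer_dropout <- function(rate = 0.3) {
  structure(list(type = "dropout", rate = rate, frozen = FALSE), class = "mvskel_layer")
}

#' @rdname nn_layers
#' @param mu,sd Fixed per-feature location and scale of
#'   [layer_standardize()] (not trained; typically estimated from training
#'   features).
#' @export
layer_standardize <- function(mu, sd) {
  structure(list(type = "standardize", mu = mu, sd = pmax(sd, 1e-8),
                 frozen = TRUE), class = "mvskel_layer")
}

#' Assemble a network
#'
#' @param ... Layers from the [nn_layers] constructors.
#' @param input_shape Input shape, either `(h, w, c)` for convolutional input
#'   or a single integer for dense input.
#' @return An object of class `mvskel_net`.
#' @export
nn_net <- function(..., input_shape) {
  net <- structure(list(layers = list(...), input_shape = as.integer(input_shape),
                        initialized = FALSE),
                   class = "mvskel_net")
  nn_init(net)
}

# Shape propagation + parameter initialization.  Weights are drawn from the
# current RNG stream so training seeds control initialization; with
# `redraw = TRUE` the parameters of non-frozen layers are re-sampled (frozen
# layers, e.g. a pretrained trunk, are always kept).
nn_init <- function(net, redraw = FALSE) {
  shape <- net$input_shape  # length 3 (h,w,c) or 1 (d)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    draw <- function() is.null(l$W) || (redraw && !isTRUE(l$frozen))
    switch(l$type,
      conv = {
        if (length(shape) != 3) stop("conv layer needs spatial input")
        K <- l$kernel
        if (draw()) {
          l$W <- glorot(K * K * shape[3], K * K * l$filters,
                        c(K, K, shape[3], l$filters))
          l$b <- numeric(l$filters)
        }
        shape <- c(shape[1], shape[2], l$filters)
      },
      dense = {
        if (length(shape) != 1) stop("dense layer needs flat input")
        if (draw()) {
          l$W <- matrix(glorot(shape, l$units, c(shape, l$units)), shape, l$units)
          l$b <- numeric(l$units)
        }
        shape <- l$units
      },
      maxpool = {
        if (any(shape[1:2] %% 2 != 0)) {
          stop("spatial dims ", shape[1], "x", shape[2],
               " not divisible by 2 for pooling")
        }
        shape <- c(shape[1:2] %/% 2L, shape[3])
      },
      upsample = shape <- c(shape[1:2] * 2L, shape[3]),
      gap = shape <- shape[3],
      flatten = shape <- prod(shape),
      reshape = {
        if (prod(shape) != prod(l$shape)) {
          stop("cannot reshape ", prod(shape), " values to ",
               paste(l$shape, collapse = "x"))
        }
        shape <- l$shape
      },
      standardize = {
        if (length(shape) != 1 || shape != length(l$mu)) {
          stop("standardize layer statistics do not match input width")
        }
      },
      relu = NULL, sigmoid = NULL, dropout = NULL,
      stop("unknown layer type: ", l$type)
    )
    l$out_shape <- shape
    net$layers[[i]] <- l
  }
  net$output_shape <- shape
  net$initialized <- TRUE
  net
}

n_samples <- function(x) if (is.matrix(x)) nrow(x) else dim(x)[length(dim(x))]

batch_select <- function(x, idx) {
  if (is.matrix(x)) {
    x[idx, , drop = FALSE]
  } else {
    d <- dim(x)
    y <- x[, , , idx, drop = FALSE]
    dim(y) <- c(d[1:3], length(idx))
    y
  }
}

# Forward pass.  Returns list(net, out); caches live in net$layers[[i]]$cache.
nn_forward <- function(net, x, training = FALSE) {
  if (!is.matrix(x) && length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    switch(l$type,
      conv = {
        l$cache <- list(x = x)
        x <- conv2d_fwd(x, l$W, l$b)
      },
      dense = {
        l$cache <- list(x = x)
        x <- sweep(x %*% l$W, 2, l$b, "+")
      },
      relu = {
        x <- pmax(x, 0)
        l$cache <- list(y = x)
      },
      sigmoid = {
        x <- 1 / (1 + exp(-x))
        l$cache <- list(y = x)
      },
      maxpool = {
        p <- maxpool2_fwd(x)
        l$cache <- list(argmax = p$argmax, in_dim = dim(x))
        x <- p$y
      },
      upsample = x <- upsample2_fwd(x),
      gap = {
        d <- dim(x)
        l$cache <- list(in_dim = d)
        m <- matrix(x, d[1] * d[2], d[3] * d[4])
        x <- t(matrix(colMeans(m), d[3], d[4]))
      },
      flatten = {
        d <- dim(x)
        l$cache <- list(in_dim = d)
        x <- t(matrix(x, prod(d[1:3]), d[4]))
      },
      reshape = {
        l$cache <- list(n = nrow(x))
        x <- array(t(x), c(l$shape, nrow(x)))
      },
      standardize = {
        x <- sweep(sweep(x, 2, l$mu, "-"), 2, l$sd, "/")
      },
      dropout = {
        if (training && l$rate > 0) {
          mask <- array(stats::rbinom(length(x), 1, 1 - l$rate) / (1 - l$rate),
                        dim(x) %||% length(x))
          if (is.matrix(x)) mask <- matrix(mask, nrow(x), ncol(x))
          x <- x * mask
          l$cache <- list(mask = mask)
        } else {
          l$cache <- list(mask = NULL)
        }
      }
    )
    net$layers[[i]] <- l
  }
  list(net = net, out = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward pass from the gradient of the loss w.r.t. the network output.
# Returns list(grads, dx); grads[[i]] holds dW/db for parameterized layers.
nn_backward <- function(net, dout) {
  grads <- vector("list", length(net$layers))
  dx <- dout
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    switch(l$type,
      conv = {
        g <- conv2d_bwd(l$cache$x, l$W, dx)
        if (l$l2 > 0) g$dw <- g$dw + 2 * l$l2 * l$W
        grads[[i]] <- list(dW = g$dw, db = g$db)
        dx <- g$dx
      },
      dense = {
        dW <- crossprod(l$cache$x, dx)
        if (l$l2 > 0) dW <- dW + 2 * l$l2 * l$W
        grads[[i]] <- list(dW = dW, db = colSums(dx))
        dx <- tcrossprod(dx, l$W)
      },
      relu = dx <- dx * (l$cache$y > 0),
      sigmoid = dx <- dx * l$cache$y * (1 - l$cache$y),
      maxpool = dx <- maxpool2_bwd(dx, l$cache$argmax,
                                   l$cache$in_dim[1], l$cache$in_dim[2]),
      upsample = dx <- upsample2_bwd(dx),
      gap = {
        d <- l$cache$in_dim
        per <- t(dx) / (d[1] * d[2])            # C x N
        dx <- array(rep(per, each = d[1] * d[2]), d)
      },
      flatten = dx <- array(t(dx), l$cache$in_dim),
      reshape = dx <- t(matrix(dx, prod(l$shape), l$cache$n)),
      standardize = dx <- sweep(dx, 2, l$sd, "/"),
      dropout = if (!is.null(l$cache$mask)) dx <- dx * l$cache$mask
    )
  }
  list(grads = grads, dx = dx)
}

adam_init <- function(net) {
  st <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (!is.null(l$W)) {
      st[[i]] <- list(mW = array(0, dim(l$W) %||% length(l$W)),
                      vW = array(0, dim(l$W) %||% length(l$W)),
                      mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    }
  }
  list(t = 0L, state = st, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(net, grads, opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (is.null(l$W) || isTRUE(l$frozen) || is.null(grads[[i]])) next
    s <- opt$state[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * grads[[i]]$dW
    s$vW <- b2 * s$vW + (1 - b2) * grads[[i]]$dW^2
    s$mb <- b1 * s$mb + (1 - b1) * grads[[i]]$db
    s$vb <- b2 * s$vb + (1 - b2) * grads[[i]]$db^2
    l$W <- l$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + opt$eps)
    l$b <- l$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + opt$eps)
    opt$state[[i]] <- s
    net$layers[[i]] <- l
  }
  list(net = net, opt = opt)
}

loss_value <- function(loss, pred, target) {
  if (loss == "mse") {
    mean((pred - target)^2)
  } else {  # binary cross-entropy on sigmoid outputs
    p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
    -mean(target * log(p) + (1 - target) * log(1 - p))
  }
}

loss_grad <- function(loss, pred, target) {
  n <- length(pred)
  if (loss == "mse") {
    2 * (pred - target) / n
  } else {
    p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
    g <- (p - target) / (p * (1 - p)) / n
    if (!is.null(dim(pred))) dim(g) <- dim(pred) else g
    g
  }
}

#' Training configuration
#'
#' Mirrors the standard hyperparameter sheet of the two classifier families:
#' Adam optimizer, binary cross-entropy loss (mean squared error for
#' autoencoder reconstruction), at most 100 epochs, batch size 32, and early
#' stopping on validation loss with patience 3.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement before training halts and the best weights are restored).
#' @param val_fraction Fraction of the training data carved off for
#'   validation when no explicit validation set is supplied.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A list of class `mvskel_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 100L, batch_size = 32L,
                         patience = 3L, val_fraction = 0.2, seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 1, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "mvskel_train_config")
}

#' Train a network
#'
#' Minibatch Adam with early stopping on validation loss.  When `xval` is
#' `NULL` a validation split is carved from the tail of a seeded shuffle of
#' the training data.
#'
#' @param net An `mvskel_net`.
#' @param x,y Training inputs and targets (arrays `(h,w,c,n)` or matrices
#'   `(n,d)`).
#' @param loss `"bce"` or `"mse"`.
#' @param config An [train_config()] object.
#' @param xval,yval Optional explicit validation set.
#' @param verbose Print per-epoch losses.
#' @return List with the trained `net` and a `history` data frame
#'   (epoch, train_loss, val_loss).
#' @export
nn_train <- function(net, x, y, loss = c("bce", "mse"), config = train_config(),
                     xval = NULL, yval = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  n <- n_samples(x)
  if (n < 1) stop("empty training set")
  set.seed(config$seed)
  # re-draw non-frozen parameters under the training seed so runs reproduce
  net <- nn_init(net, redraw = TRUE)
  if (is.null(xval)) {
    ord <- sample.int(n)
    nval <- max(1L, floor(config$val_fraction * n))
    if (n - nval < 1) stop("training set too small for a validation split")
    vid <- ord[seq_len(nval)]; tid <- ord[-seq_len(nval)]
    xval <- batch_select(x, vid); yval <- batch_select(y, vid)
    x <- batch_select(x, tid); y <- batch_select(y, tid)
    n <- length(tid)
  }
  opt <- adam_init(net)
  best <- list(loss = Inf, layers = NULL, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tl <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- batch_select(x, idx); yb <- batch_select(y, idx)
      fw <- nn_forward(net, xb, training = TRUE)
      net <- fw$net
      if (!all(is.finite(fw$out))) stop("non-finite activations at epoch ", epoch)
      lv <- loss_value(loss, fw$out, yb)
      if (!is.finite(lv)) stop("non-finite training loss at epoch ", epoch)
      bw <- nn_backward(net, loss_grad(loss, fw$out, yb))
      upd <- adam_step(net, bw$grads, opt, config$learning_rate)
      net <- upd$net; opt <- upd$opt
      tl <- tl + lv; nb <- nb + 1L
    }
    vout <- nn_forward(net, xval, training = FALSE)$out
    vl <- loss_value(loss, vout, yval)
    if (!is.finite(vl)) stop("non-finite validation loss at epoch ", epoch)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb, val_loss = vl))
    if (verbose) message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tl / nb, vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, layers = net$layers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  if (!is.null(best$layers)) net$layers <- best$layers
  list(net = net, history = hist, best_epoch = best$epoch)
}

#' Network prediction
#'
#' @param net A trained `mvskel_net`.
#' @param x Input batch.
#' @return Network output (matrix or array).
#' @export
nn_predict <- function(net, x) nn_forward(net, x, training = FALSE)$out

# Deep-copy guard for freeze contracts: snapshot of all layer weights.
nn_weights <- function(net) lapply(net$layers, function(l) list(W = l$W, b = l$b))

nn_freeze <- function(net) {
  for (i in seq_along(net$layers)) net$layers[[i]]$frozen <- TRUE
  net
}
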