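# Hierarchical classifier families.
#
# Both families share one structure: a trunk turns the input image into
# features (a small trainable CNN trained with the level-1 head, or a
# convolutional autoencoder's encoder trained by reconstruction), a level-1
# head performs normal/abnormal classification, and level-2/level-3 heads are
# chained on the penultimate representation of the preceding level, with all
# upstream layers frozen while a head trains.

#' Build a convolutional autoencoder
#'
#' Encoder: two (convolution + ReLU + 2x2 max-pool) stages; decoder mirrors
#' them with nearest upsampling and a linear convolutional output layer
#' (reconstructions are clipped to `[0, 1]` when extracted; a linear output
#' avoids the saturation a sigmoid suffers on predominantly dark
#' radiographs).  At full scale a `224x224x3` input with
#' `filters = c(64, 128)` yields a `56x56x128` latent map; the same topology
#' rules apply at reduced scale (e.g. `64x64x3` with `filters = c(16, 32)`
#' yields `16x16x32`).
#'
#' @param input_shape `(rows, cols, channels)`.
#' @param filters Channel counts of the two encoder stages.
#' @return An object of class `mvskel_cae`.
#' @export
build_cae <- function(input_shape = c(64L, 64L, 3L), filters = c(16L, 32L)) {
  if (any(input_shape[1:2] %% 4 != 0)) {
    stop("input spatial dims must be divisible by 4 (two 2x2 poolings)")
  }
  net <- nn_net(
    layer_conv(filters[1]), layer_relu(), layer_maxpool(),
    layer_conv(filters[2]), layer_relu(), layer_maxpool(),
    layer_conv(filters[2]), layer_relu(), layer_upsample(),
    layer_conv(filters[1]), layer_relu(), layer_upsample(),
    layer_conv(input_shape[3]),
    input_shape = input_shape
  )
  structure(list(net = net, input_shape = as.integer(input_shape),
                 latent_index = 6L,
                 latent_shape = net$layers[[6]]$out_shape,
                 trained = FALSE, history = NULL),
            class = "mvskel_cae")
}

#' Train a convolutional autoencoder by reconstruction
#'
#' Minimizes the mean squared error between input and reconstruction (mean
#' over all pixels), with early stopping on validation loss.
#'
#' @param cae An [build_cae()] object.
#' @param x Training images, array `(rows, cols, channels, n)`.
#' @param config An [train_config()]; the loss is fixed to MSE.
#' @param xval Optional validation images.
#' @return The trained `mvskel_cae` with a `history` data frame.
#' @export
train_cae <- function(cae, x, config = train_config(learning_rate = 1e-3),
                      xval = NULL) {
  if (n_samples(x) < 1) stop("train_cae needs at least one image")
  fit <- nn_train(cae$net, x, x, loss = "mse", config = config,
                  xval = xval, yval = xval)
  cae$net <- fit$net
  cae$history <- fit$history
  cae$trained <- TRUE
  cae
}

#' Encode images to the latent feature map
#'
#' @param cae A trained `mvskel_cae`.
#' @param x Images `(rows, cols, channels, n)`.
#' @return Latent array `(rows/4, cols/4, filters2, n)`.
#' @export
cae_encode <- function(cae, x) nn_forward_upto(cae$net, x, cae$latent_index)

#' Reconstruct images through the autoencoder
#'
#' @inheritParams cae_encode
#' @return Array shaped like `x`, clipped to `[0, 1]`.
#' @export
cae_reconstruct <- function(cae, x) pmin(pmax(nn_predict(cae$net, x), 0), 1)

# forward through the first k layers only
nn_forward_upto <- function(net, x, k) {
  sub <- structure(list(layers = net$layers[seq_len(k)],
                        input_shape = net$input_shape, initialized = TRUE),
                   class = "mvskel_net")
  nn_forward(sub, x, training = FALSE)$out
}

#' Build a small trainable convolutional backbone
#'
#' Two (convolution + ReLU + max-pool) stages producing a spatial feature
#' map; the desk-scale stand-in for a large pretrained backbone behind the
#' same interface (any `mvskel_net` whose output is a spatial map can serve
#' as a trunk).
#'
#' @param input_shape `(rows, cols, channels)`.
#' @param filters Channel counts of the two stages.
#' @return An `mvskel_net` whose output shape is `(rows/4, cols/4, filters[2])`.
#' @export
build_backbone <- function(input_shape, filters = c(8L, 16L)) {
  if (any(input_shape[1:2] %% 4 != 0)) {
    stop("input spatial dims must be divisible by 4")
  }
  nn_net(
    layer_conv(filters[1]), layer_relu(), layer_maxpool(),
    layer_conv(filters[2]), layer_relu(), layer_maxpool(),
    input_shape = input_shape
  )
}

#' Per-view features combined channel-wise
#'
#' Runs each single-view image through the backbone and concatenates the two
#' feature maps along the channel axis (DV block first), giving the combined
#' multiview feature map fed to level-1 classification.
#'
#' @param dv_image,lat_image Arrays `(rows, cols, c, n)` (or matrices).
#' @param backbone An `mvskel_net` trunk.
#' @return Array `(rows', cols', 2 * channels, n)`.
#' @export
extract_combined_features <- function(dv_image, lat_image, backbone) {
  as4 <- function(m) {
    if (is.matrix(m)) array(m, c(dim(m), 1L, 1L)) else m
  }
  fd <- nn_predict(backbone, as4(dv_image))
  fl <- nn_predict(backbone, as4(lat_image))
  if (!identical(dim(fd), dim(fl))) stop("per-view feature map shapes differ")
  d <- dim(fd)
  out <- array(0, c(d[1], d[2], 2L * d[3], d[4]))
  out[, , seq_len(d[3]), ] <- fd
  out[, , d[3] + seq_len(d[3]), ] <- fl
  out
}

#' Level-1 classifier on a backbone trunk
#'
#' Global average pooling over the trunk's feature map, a 32-unit ReLU dense
#' layer, and a single sigmoid output unit; trained end to end with binary
#' cross-entropy.
#'
#' @param backbone An `mvskel_net` trunk (its layers are copied in).
#' @return List with the full `net` and `penultimate` (index of the layer
#'   whose output is the 32-vector handed to level 2).
#' @export
build_l1_backbone_classifier <- function(backbone) {
  layers <- c(backbone$layers,
              list(layer_gap(), layer_dense(32L), layer_relu(),
                   layer_dense(1L), layer_sigmoid()))
  net <- structure(list(layers = layers, input_shape = backbone$input_shape,
                        initialized = FALSE), class = "mvskel_net")
  net <- nn_init(net)
  list(net = net, penultimate = length(layers) - 2L)
}

# smallest square-ish (h, w, c) factorization of d with even h = w
reshape_dims <- function(d) {
  for (ch in seq_len(d)) {
    if (d %% ch == 0) {
      s <- sqrt(d / ch)
      if (s == floor(s) && s %% 2 == 0) return(c(as.integer(s), as.integer(s), as.integer(ch)))
    }
  }
  stop("cannot reshape a length-", d, " vector into an even square tensor")
}

#' Level-2 head
#'
#' Backbone family: the level-1 penultimate vector is reshaped into a small
#' 3-D tensor, passed through a convolution + max-pool + flatten block, then
#' three L2-regularized ReLU dense layers and a 3-unit sigmoid output.  CAE
#' family: no convolutions (the encoder already convolved); two ReLU dense
#' layers with dropout, then the 3-unit sigmoid output.
#'
#' @param input_width Width of the incoming feature vector.
#' @param family `"backbone"` or `"cae"`.
#' @param n_out Output width (number of retained level-2 classes).
#' @param hp Hyperparameters, see [head_hp()].
#' @return List with `net` and `penultimate` layer index.
#' @export
build_l2_head <- function(input_width, family = c("backbone", "cae"),
                          n_out = 3L, hp = head_hp()) {
  family <- match.arg(family)
  if (family == "backbone") {
    net <- nn_net(
      layer_reshape(reshape_dims(input_width)),
      layer_conv(hp$conv_filters), layer_relu(), layer_maxpool(), layer_flatten(),
      layer_dense(hp$dense_widths[1], l2 = hp$l2_penalty), layer_relu(),
      layer_dense(hp$dense_widths[2], l2 = hp$l2_penalty), layer_relu(),
      layer_dense(hp$dense_widths[3], l2 = hp$l2_penalty), layer_relu(),
      layer_dense(n_out), layer_sigmoid(),
      input_shape = input_width
    )
    list(net = net, penultimate = length(net$layers) - 2L)
  } else {
    net <- nn_net(
      layer_dense(hp$dense_widths[1]), layer_relu(), layer_dropout(hp$dropout),
      layer_dense(hp$dense_widths[2]), layer_relu(), layer_dropout(hp$dropout),
      layer_dense(n_out), layer_sigmoid(),
      input_shape = input_width
    )
    # hand-off to level 3: the post-ReLU output of the first hidden layer
    # (the level-2 feature representation closest to the latent; the deeper
    # 3-class-specific layers discard within-subclass location information
    # the level-3 head needs)
    list(net = net, penultimate = 2L)
  }
}

#' Level-3 head
#'
#' Same topology family-wise as [build_l2_head()] but with a 10-unit sigmoid
#' output; trained with all upstream (level-2 and trunk) layers frozen.
#'
#' @inheritParams build_l2_head
#' @export
build_l3_head <- function(input_width, family = c("backbone", "cae"),
                          n_out = 10L, hp = head_hp()) {
  family <- match.arg(family)
  if (family == "backbone") {
    build_l2_head(input_width, "backbone", n_out = n_out, hp = hp)
  } else {
    net <- nn_net(
      layer_dense(hp$dense_widths[2]), layer_relu(), layer_dropout(hp$dropout),
      layer_dense(hp$dense_widths[3]), layer_relu(), layer_dropout(hp$dropout),
      layer_dense(n_out), layer_sigmoid(),
      input_shape = input_width
    )
    list(net = net, penultimate = 5L)
  }
}

#' Head hyperparameters
#'
#' @param conv_filters,dense_widths,l2_penalty,dropout Convolution filter
#'   count, dense layer widths, L2 weight-penalty coefficient and dropout
#'   rate used by the level heads.
#' @export
head_hp <- function(conv_filters = 32L, dense_widths = c(128L, 64L, 32L),
                    l2_penalty = 1e-4, dropout = 0.3) {
  list(conv_filters = as.integer(conv_filters),
       dense_widths = as.integer(dense_widths),
       l2_penalty = l2_penalty, dropout = dropout)
}

#' Per-level training control
#'
#' Bundles the training configurations of the trunk and the three level
#' heads.  The defaults mirror the published hyperparameter sheet: Adam,
#' binary cross-entropy, 100 epochs maximum, batch size 32, validation-loss
#' early stopping with patience 3; learning rates 0.001 / 0.0001 / 0.00011
#' for the backbone family's levels and 0.00001 for the CAE family's heads.
#' The autoencoder reconstruction itself uses 0.001.
#'
#' @param family `"cae"` or `"backbone"`.
#' @param cae,l1,l2,l3 [train_config()] overrides.
#' @param cae_filters,backbone_filters Trunk channel counts.
#' @param hp Head hyperparameters ([head_hp()]).
#' @export
fit_control <- function(family = c("cae", "backbone"),
                        cae = NULL, l1 = NULL, l2 = NULL, l3 = NULL,
                        cae_filters = c(16L, 32L),
                        backbone_filters = c(8L, 16L),
                        hp = head_hp()) {
  family <- match.arg(family)
  if (family == "backbone") {
    l1 <- l1 %||% train_config(learning_rate = 0.001)
    l2 <- l2 %||% train_config(learning_rate = 0.0001)
    l3 <- l3 %||% train_config(learning_rate = 0.00011)
  } else {
    l1 <- l1 %||% train_config(learning_rate = 0.00001)
    l2 <- l2 %||% train_config(learning_rate = 0.00001)
    l3 <- l3 %||% train_config(learning_rate = 0.00001)
  }
  cae <- cae %||% train_config(learning_rate = 0.001)
  structure(list(family = family, cae = cae, l1 = l1, l2 = l2, l3 = l3,
                 cae_filters = as.integer(cae_filters),
                 backbone_filters = as.integer(backbone_filters), hp = hp),
            class = "mvskel_control")
}

# select the channels a view mode sees: MV = all three composite channels,
# DV / LAT = that view's mean-image channel only
select_view <- function(x, view) {
  switch(view,
    MV = x,
    DV = x[, , 1L, , drop = FALSE],
    LAT = x[, , 2L, , drop = FALSE],
    stop("unknown view mode: ", view)
  )
}

label_matrix <- function(labels, taxonomy) {
  v <- t(vapply(labels, function(l) encode_label_vector(l, taxonomy),
                integer(length(taxonomy$retained_l2) + length(taxonomy$retained_l3))))
  y1 <- vapply(labels, function(l) as.numeric(l$l1 == "abnormal"), numeric(1))
  n2 <- length(taxonomy$retained_l2)
  list(y1 = matrix(y1, ncol = 1),
       y2 = v[, seq_len(n2), drop = FALSE],
       y3 = v[, -seq_len(n2), drop = FALSE])
}

#' Fit a hierarchical abnormality classifier
#'
#' Fits the three-level hierarchy on specimen composites: level 1 separates
#' abnormal from normal specimens, level 2 assigns abnormal specimens to
#' anatomical subclasses, level 3 refines them into specific abnormality
#' classes.  Levels are trained in order; each level's head consumes the
#' penultimate representation of the previous level, whose layers are frozen.
#' Level-2 and level-3 heads train (and are meant to be evaluated) on
#' abnormal specimens only.
#'
#' @param x Composite array `(rows, cols, 3, n)` from [curate_dataset()].
#' @param labels List of `mvskel_label`, aligned with `x`.
#' @param taxonomy An `mvskel_taxonomy`.
#' @param family `"cae"` (autoencoder trunk) or `"backbone"` (small CNN
#'   trunk trained with level 1).
#' @param view `"MV"` (all three channels), `"DV"` or `"LAT"` (that view's
#'   mean-image channel only).
#' @param control An [fit_control()] bundle.
#' @param seed Integer seed; per-stage seeds are derived from it.
#' @param xval,labels_val Optional validation specimens for early stopping;
#'   without them a validation split is carved from `x`.
#' @param verbose Print stage progress.
#' @return An object of class `mvskel_hier` with `print`, `summary`,
#'   [predict.mvskel_hier()] and `plot` methods.
#' @export
mvskel_fit <- function(x, labels, taxonomy, family = c("cae", "backbone"),
                       view = c("MV", "DV", "LAT"),
                       control = fit_control(match.arg(family)),
                       seed = 1L, xval = NULL, labels_val = NULL,
                       verbose = FALSE) {
  family <- match.arg(family)
  view <- match.arg(view)
  if (n_samples(x) != length(labels)) stop("x and labels lengths differ")
  xv <- select_view(x, view)
  xval_v <- if (!is.null(xval)) select_view(xval, view)
  ym <- label_matrix(labels, taxonomy)
  yv <- if (!is.null(labels_val)) label_matrix(labels_val, taxonomy)
  say <- function(...) if (verbose) message(...)
  seeds <- seed + 0:3
  input_shape <- dim(xv)[1:3]
  n2 <- length(taxonomy$retained_l2); n3 <- length(taxonomy$retained_l3)

  abn <- which(ym$y1[, 1] == 1)
  if (!length(abn)) stop("empty training split: no abnormal specimens for levels 2/3")
  abn_val <- if (!is.null(yv)) which(yv$y1[, 1] == 1)

  histories <- list()
  if (family == "cae") {
    say("training autoencoder trunk (reconstruction)")
    cae <- build_cae(input_shape, control$cae_filters)
    cfg <- control$cae; cfg$seed <- seeds[1]
    cae <- train_cae(cae, xv, cfg, xval = xval_v)
    histories$cae <- cae$history
    trunk_layers <- lapply(cae$net$layers[seq_len(cae$latent_index)],
                           function(l) { l$frozen <- TRUE; l })
    feat_raw <- function(z) {
      f <- nn_forward_upto(cae$net, z, cae$latent_index)
      d <- dim(f); t(matrix(f, prod(d[1:3]), d[4]))
    }
    F0 <- feat_raw(xv)
    # standardize latent features on training statistics before the heads;
    # the scale is floored at a twentieth of the mean feature scale so that
    # near-constant latent units are not amplified into pure noise
    sc_mu <- colMeans(F0)
    sc_sd <- apply(F0, 2, stats::sd)
    floor_sd <- 0.05 * mean(sc_sd[sc_sd > 0])
    sc_sd <- pmax(sc_sd, if (is.finite(floor_sd) && floor_sd > 0) floor_sd else 1e-8)
    std <- layer_standardize(sc_mu, sc_sd)
    feat <- function(z) {
      sweep(sweep(feat_raw(z), 2, sc_mu, "-"), 2, sc_sd, "/")
    }
    Ftr <- sweep(sweep(F0, 2, sc_mu, "-"), 2, sc_sd, "/")
    Fva <- if (!is.null(xval_v)) feat(xval_v)
    D <- ncol(Ftr)

    say("level 1: latent probe")
    probe <- nn_net(layer_dense(1L), layer_sigmoid(), input_shape = D)
    cfg <- control$l1; cfg$seed <- seeds[2]
    f1 <- nn_train(probe, Ftr, ym$y1, "bce", cfg, xval = Fva, yval = yv$y1)
    histories$l1 <- f1$history

    say("level 2 head (abnormal specimens)")
    h2 <- build_l2_head(D, "cae", n_out = n2, hp = control$hp)
    cfg <- control$l2; cfg$seed <- seeds[3]
    f2 <- nn_train(h2$net, Ftr[abn, , drop = FALSE], ym$y2[abn, , drop = FALSE],
                   "bce", cfg,
                   xval = if (length(abn_val)) Fva[abn_val, , drop = FALSE],
                   yval = if (length(abn_val)) yv$y2[abn_val, , drop = FALSE])
    histories$l2 <- f2$history
    l2_frozen <- nn_freeze(f2$net)

    say("level 3 head (abnormal specimens)")
    P2tr <- nn_forward_upto(l2_frozen, Ftr[abn, , drop = FALSE], h2$penultimate)
    P2va <- if (length(abn_val)) nn_forward_upto(l2_frozen, Fva[abn_val, , drop = FALSE], h2$penultimate)
    h3 <- build_l3_head(ncol(P2tr), "cae", n_out = n3, hp = control$hp)
    cfg <- control$l3; cfg$seed <- seeds[4]
    f3 <- nn_train(h3$net, P2tr, ym$y3[abn, , drop = FALSE], "bce", cfg,
                   xval = P2va,
                   yval = if (length(abn_val)) yv$y3[abn_val, , drop = FALSE])
    histories$l3 <- f3$history

    pre <- c(trunk_layers, list(layer_flatten(), std))
    chains <- list(
      l1 = chain_net(c(pre, f1$net$layers), input_shape),
      l2 = chain_net(c(pre, l2_frozen$layers), input_shape),
      l3 = chain_net(c(pre, l2_frozen$layers[seq_len(h2$penultimate)], f3$net$layers),
                     input_shape)
    )
    trunk <- cae
  } else {
    say("level 1: backbone classifier (end to end)")
    bb <- build_backbone(input_shape, control$backbone_filters)
    l1c <- build_l1_backbone_classifier(bb)
    cfg <- control$l1; cfg$seed <- seeds[2]
    f1 <- nn_train(l1c$net, xv, ym$y1, "bce", cfg, xval = xval_v, yval = yv$y1)
    histories$l1 <- f1$history
    l1_frozen <- nn_freeze(f1$net)
    H1tr <- nn_forward_upto(l1_frozen, xv, l1c$penultimate)
    H1va <- if (!is.null(xval_v)) nn_forward_upto(l1_frozen, xval_v, l1c$penultimate)

    say("level 2 head (abnormal specimens)")
    h2 <- build_l2_head(ncol(H1tr), "backbone", n_out = n2, hp = control$hp)
    cfg <- control$l2; cfg$seed <- seeds[3]
    f2 <- nn_train(h2$net, H1tr[abn, , drop = FALSE], ym$y2[abn, , drop = FALSE],
                   "bce", cfg,
                   xval = if (length(abn_val)) H1va[abn_val, , drop = FALSE],
                   yval = if (length(abn_val)) yv$y2[abn_val, , drop = FALSE])
    histories$l2 <- f2$history
    l2_frozen <- nn_freeze(f2$net)

    say("level 3 head (abnormal specimens)")
    P2tr <- nn_forward_upto(l2_frozen, H1tr[abn, , drop = FALSE], h2$penultimate)
    P2va <- if (length(abn_val)) nn_forward_upto(l2_frozen, H1va[abn_val, , drop = FALSE], h2$penultimate)
    h3 <- build_l3_head(ncol(P2tr), "backbone", n_out = n3, hp = control$hp)
    cfg <- control$l3; cfg$seed <- seeds[4]
    f3 <- nn_train(h3$net, P2tr, ym$y3[abn, , drop = FALSE], "bce", cfg,
                   xval = P2va,
                   yval = if (length(abn_val)) yv$y3[abn_val, , drop = FALSE])
    histories$l3 <- f3$history

    pre <- l1_frozen$layers[seq_len(l1c$penultimate)]
    chains <- list(
      l1 = chain_net(l1_frozen$layers, input_shape),
      l2 = chain_net(c(pre, l2_frozen$layers), input_shape),
      l3 = chain_net(c(pre, l2_frozen$layers[seq_len(h2$penultimate)], f3$net$layers),
                     input_shape)
    )
    trunk <- l1_frozen
  }

  structure(list(family = family, view = view, taxonomy = taxonomy,
                 chains = chains, trunk = trunk, histories = histories,
                 input_shape = input_shape, control = control, seed = seed,
                 n_train = n_samples(x)),
            class = "mvskel_hier")
}

chain_net <- function(layers, input_shape) {
  net <- structure(list(layers = layers, input_shape = as.integer(input_shape),
                        initialized = FALSE), class = "mvskel_net")
  nn_init(net)
}

#' Predict hierarchical abnormality probabilities
#'
#' Returns threshold-free sigmoid probabilities at all three levels; the
#' concatenated level-2 and level-3 probabilities form the 13-slot prediction
#' aligned with the taxonomy's label-vector ordering.
#'
#' @param object A fitted `mvskel_hier`.
#' @param x Composite array `(rows, cols, 3, n)` (full composites; the
#'   object's view mode selects its channels).
#' @param ... Unused.
#' @return List with `p_l1` (length-n vector), `p_l2` (n x 3), `p_l3`
#'   (n x 10) and `vector` (n x 13 matrix).
#' @export
predict.mvskel_hier <- function(object, x, ...) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] == 3L) x <- select_view(x, object$view)
  p1 <- nn_predict(object$chains$l1, x)
  p2 <- nn_predict(object$chains$l2, x)
  p3 <- nn_predict(object$chains$l3, x)
  colnames(p2) <- object$taxonomy$retained_l2
  colnames(p3) <- object$taxonomy$retained_l3
  list(p_l1 = as.numeric(p1), p_l2 = p2, p_l3 = p3, vector = cbind(p2, p3))
}

#' @export
print.mvskel_hier <- function(x, ...) {
  cat("<mvskel_hier> ", x$family, "-family hierarchical classifier (view: ",
      x$view, ")\n", sep = "")
  cat("  input ", paste(x$input_shape, collapse = "x"),
      "; trained on ", x$n_train, " specimens (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$histories)) {
    h <- x$histories[[nm]]
    cat(sprintf("  %-4s %3d epochs, final val loss %.5f\n",
                nm, nrow(h), h$val_loss[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.mvskel_hier <- function(object, ...) {
  print(object)
  cat("  level-2 classes: ", paste(object$taxonomy$retained_l2, collapse = ", "), "\n", sep = "")
  cat("  level-3 classes: ", paste(object$taxonomy$retained_l3, collapse = ", "), "\n", sep = "")
  invisible(object)
}

#' Plot training histories of a fitted hierarchy
#'
#' @param x A fitted `mvskel_hier`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mvskel_hier <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$histories)))
  on.exit(graphics::par(op))
  for (nm in names(x$histories)) {
    h <- x$histories[[nm]]
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                      lty = 1:2, col = c("black", "red"), xlab = "epoch",
                      ylab = "loss", main = nm, ...)
  }
  invisible(x)
}
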