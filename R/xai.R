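# Decision interpretation via class activation maps.
#
# The map for a class is the rectified weighted sum of the feature maps of a
# convolutional layer, with per-channel weights taken as the spatial mean of
# the class score's gradient at that layer (this reduces to the classic
# dense-weight construction when the path from the layer to the class unit
# is global-average-pooling followed by a single dense layer).  The raw map
# is upsampled bilinearly to the input size and min-max normalized to [0, 1].

# activations of every layer of a net for a single input
nn_activations <- function(net, x) {
  if (!is.matrix(x) && length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  acts <- vector("list", length(net$layers))
  cur <- x
  for (i in seq_along(net$layers)) {
    sub <- structure(list(layers = net$layers[i], input_shape = NULL,
                          initialized = TRUE), class = "mvskel_net")
    cur <- nn_forward(sub, cur, training = FALSE)$out
    acts[[i]] <- cur
  }
  acts
}

# gradient of out[class_index] w.r.t. the output of layer `layer`
nn_class_grad <- function(net, x, class_index, layer) {
  fw <- nn_forward(net, x, training = FALSE)
  out <- fw$out
  if (class_index < 1 || class_index > ncol(out)) stop("invalid class index")
  dout <- matrix(0, nrow(out), ncol(out))
  dout[, class_index] <- 1
  sub <- structure(list(layers = fw$net$layers[(layer + 1):length(net$layers)],
                        initialized = TRUE), class = "mvskel_net")
  nn_backward(sub, dout)$dx
}

last_conv_index <- function(net) {
  idx <- which(vapply(net$layers, function(l) l$type == "conv", logical(1)))
  if (!length(idx)) stop("model has no convolutional layer on this path")
  max(idx)
}

#' Class activation map
#'
#' @param object A fitted `mvskel_hier`.
#' @param x A single composite `(rows, cols, 3)` or `(rows, cols, 3, 1)`.
#' @param level Hierarchy level of the class (1, 2 or 3).
#' @param class_index Output unit within that level's head.
#' @param layer Index of the convolutional layer whose feature maps are
#'   weighted; defaults to the last convolutional layer on the level's path.
#' @return Object of class `mvskel_cam`: a `(rows, cols)` matrix in `[0, 1]`
#'   with attributes `level`, `class_index`, `layer`.
#' @export
compute_cam <- function(object, x, level = 1L, class_index = 1L, layer = NULL) {
  chain <- object$chains[[paste0("l", level)]]
  if (is.null(chain)) stop("no trained head for level ", level)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] == 3L && object$input_shape[3] != 3L) x <- select_view(x, object$view)
  layer <- layer %||% last_conv_index(chain)
  if (chain$layers[[layer]]$type != "conv") stop("layer ", layer, " is not convolutional")
  acts <- nn_activations(chain, x)
  feat <- acts[[layer]]                       # (h, w, C, 1)
  grad <- nn_class_grad(chain, x, class_index, layer)
  d <- dim(feat)
  w <- apply(array(grad, d)[, , , 1, drop = FALSE], 3, mean)  # channel weights
  raw <- matrix(0, d[1], d[2])
  for (ch in seq_len(d[3])) raw <- raw + w[ch] * feat[, , ch, 1]
  raw <- pmax(raw, 0)
  up <- as.matrix(EBImage::resize(raw, w = dim(x)[1], h = dim(x)[2]))
  up <- pmax(up, 0)
  mx <- max(up)
  out <- if (mx > 0) up / mx else up * 0
  structure(out, level = level, class_index = class_index, layer = layer,
            class = "mvskel_cam")
}

#' Overlay an activation map on a grayscale image
#'
#' Color-maps the activation with a perceptually uniform palette and
#' alpha-blends it over the image; `alpha = 0` reproduces the input
#' (replicated to three channels), `alpha = 1` shows the pure color-mapped
#' activation.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param activation_map Matrix in `[0, 1]`, same shape.
#' @param alpha Blend weight of the activation in `[0, 1]`.
#' @return Array `(rows, cols, 3)` in `[0, 1]`, suitable for PNG export.
#' @export
overlay <- function(image, activation_map, alpha = 0.4) {
  if (!identical(dim(image), dim(activation_map)[1:2])) stop("shapes differ")
  stopifnot(alpha >= 0, alpha <= 1)
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- pmin(pmax(floor(as.vector(activation_map) * 255) + 1L, 1L), 256L)
  cm <- grDevices::col2rgb(pal[idx]) / 255
  out <- array(0, c(dim(image), 3L))
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * image + alpha * matrix(cm[ch, ], nrow(image))
  }
  pmin(pmax(out, 0), 1)
}
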