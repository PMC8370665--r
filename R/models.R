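#' Declarative CNN model specifications
#'
#' A `cnn_spec` is an ordered list of layer descriptors with resolved output
#' shapes and per-layer trainable flags. [build_proposed_cnn()] constructs
#' the compact five-convolution-layer classifier; [build_transfer_model()]
#' constructs the VGG16, Xception and DenseNet-121 topologies (randomly
#' initialized; parameter accounting matches the published 1000-class
#' ImageNet heads exactly) with feature-extraction or fine-tuning trainable
#' flags.
#'
#' @name models
NULL

layer_spec <- function(kind, ..., trainable = TRUE) {
  l <- list(kind = kind, trainable = trainable, ...)
  if (!is.null(l$rate) && (l$rate < 0 || l$rate >= 1))
    stop("dropout rate must be in [0, 1)")
  l
}

new_cnn_spec <- function(layers, input_size, n_classes, name) {
  structure(list(layers = layers, input_size = input_size,
                 n_classes = n_classes, name = name), class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec '%s'> input %s, %d layers, %s parameters\n",
              x$name, paste(x$input_size, collapse = "x"), length(x$layers),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Build the proposed five-convolution-layer CNN
#'
#' Layer sequence: five blocks of same-padded 5x5 convolution (stride 1)
#' followed by 2x2/stride-2 max pooling and ReLU, then flatten, dropout 0.5,
#' a 64-unit fully connected layer with ReLU, and the classification head
#' (one sigmoid unit for binary problems, a softmax layer otherwise). With
#' the default 224 px input the spatial chain is 224 -> 112 -> 56 -> 28 ->
#' 14 -> 7 and the flattened width is 25,088. `filters_scale` shrinks every
#' filter bank proportionally for reduced variants (the 64 px variant used
#' for desk-scale experiments).
#'
#' @param input_side square input side in pixels; must be divisible by 32.
#' @param n_classes number of classes (2 gives a single sigmoid unit).
#' @param channels input channels.
#' @param filters_scale multiplier on the filter counts
#'   `(64, 128, 256, 512, 512)`; must keep them integral.
#' @param dense_units width of the fully connected layer (64).
#' @param dropout_rate dropout rate before the dense layer.
#' @return a `cnn_spec`.
#' @export
build_proposed_cnn <- function(input_side = 224L, n_classes = 2L,
                               channels = 3L, filters_scale = 1,
                               dense_units = 64L, dropout_rate = 0.5) {
  if (input_side %% 32 != 0)
    stop("non-integral shape chain: input_side must be divisible by 32")
  filters <- c(64, 128, 256, 512, 512) * filters_scale
  if (any(filters != round(filters)))
    stop("filters_scale must keep filter counts integral")
  side <- input_side
  in_ch <- channels
  layers <- list()
  for (f in filters) {
    layers <- c(layers, list(
      layer_spec("conv", kernel = c(5L, 5L, in_ch), filters = f,
                 stride = c(1L, 1L), padding = "same",
                 out_shape = c(side, side, f))))
    side <- side / 2L
    layers <- c(layers, list(
      layer_spec("maxpool", pool = c(2L, 2L), stride = c(2L, 2L),
                 out_shape = c(side, side, f)),
      layer_spec("relu", out_shape = c(side, side, f))))
    in_ch <- f
  }
  flat <- side * side * in_ch
  out_units <- if (n_classes == 2) 1L else n_classes
  layers <- c(layers, list(
    layer_spec("flatten", out_shape = flat),
    layer_spec("dropout", rate = dropout_rate, out_shape = flat),
    layer_spec("dense", units = dense_units, in_features = flat,
               activation = "relu", out_shape = dense_units),
    layer_spec("output", units = out_units, in_features = dense_units,
               activation = if (out_units == 1) "sigmoid" else "softmax",
               out_shape = out_units)))
  new_cnn_spec(layers, c(input_side, input_side, channels), n_classes,
               sprintf("proposed_cnn_%d", input_side))
}

#' Count parameters of a model specification
#'
#' Sums weight and bias element counts over all layers: convolutions
#' contribute `kh * kw * in * out (+ out if biased)`, separable convolutions
#' `kh * kw * in + in * out`, batch normalization `4 * channels` (scale,
#' shift and the two moving moments), dense layers `in * out + out`.
#'
#' @param spec a `cnn_spec`.
#' @param trainable_only count only layers flagged trainable.
#' @return numeric parameter count.
#' @export
count_parameters <- function(spec, trainable_only = FALSE) {
  stopifnot(inherits(spec, "cnn_spec"))
  total <- 0
  for (l in spec$layers) {
    if (trainable_only && !isTRUE(l$trainable)) next
    n <- switch(l$kind,
      conv = prod(l$kernel) * l$filters +
        (if (isFALSE(l$bias)) 0 else l$filters),
      sepconv = l$kernel[1] * l$kernel[2] * l$kernel[3] +
        l$kernel[3] * l$filters + (if (isTRUE(l$bias)) l$filters else 0),
      batchnorm = 4 * l$channels,
      dense = l$in_features * l$units + l$units,
      output = l$in_features * l$units + l$units,
      0)
    total <- total + n
  }
  total
}

# ---- transfer-learning base topologies -------------------------------------

conv_l <- function(k, in_ch, out_ch, bias = TRUE)
  layer_spec("conv", kernel = c(k, k, in_ch), filters = out_ch, bias = bias,
             stride = c(1L, 1L), padding = "same")
bn_l <- function(ch) layer_spec("batchnorm", channels = ch)
sep_l <- function(k, in_ch, out_ch)
  layer_spec("sepconv", kernel = c(k, k, in_ch), filters = out_ch, bias = FALSE)
pool_l <- function() layer_spec("maxpool", pool = c(2L, 2L))
dense_l <- function(in_f, units, act = "relu")
  layer_spec("dense", units = units, in_features = in_f, activation = act)

build_vgg16 <- function(n_classes = 1000L) {
  widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  layers <- list()
  in_ch <- 3L
  for (blk in widths) {
    for (w in blk) {
      layers <- c(layers, list(conv_l(3L, in_ch, w), layer_spec("relu")))
      in_ch <- w
    }
    layers <- c(layers, list(pool_l()))
  }
  layers <- c(layers, list(
    layer_spec("flatten"),
    dense_l(7L * 7L * 512L, 4096L), dense_l(4096L, 4096L),
    layer_spec("output", units = n_classes, in_features = 4096L,
               activation = "softmax")))
  new_cnn_spec(layers, c(224L, 224L, 3L), n_classes, "vgg16")
}

xception_block <- function(in_ch, mid_ch, out_ch) {
  c(list(sep_l(3L, in_ch, mid_ch), bn_l(mid_ch),
         sep_l(3L, mid_ch, out_ch), bn_l(out_ch), pool_l(),
         # residual projection
         conv_l(1L, in_ch, out_ch, bias = FALSE), bn_l(out_ch)))
}

build_xception <- function(n_classes = 1000L) {
  layers <- list(
    conv_l(3L, 3L, 32L, bias = FALSE), bn_l(32L), layer_spec("relu"),
    conv_l(3L, 32L, 64L, bias = FALSE), bn_l(64L), layer_spec("relu"))
  layers <- c(layers, xception_block(64L, 128L, 128L),
              xception_block(128L, 256L, 256L),
              xception_block(256L, 728L, 728L))
  for (b in 1:8)
    layers <- c(layers, list(sep_l(3L, 728L, 728L), bn_l(728L),
                             sep_l(3L, 728L, 728L), bn_l(728L),
                             sep_l(3L, 728L, 728L), bn_l(728L)))
  layers <- c(layers, xception_block(728L, 728L, 1024L))
  layers <- c(layers, list(
    sep_l(3L, 1024L, 1536L), bn_l(1536L),
    sep_l(3L, 1536L, 2048L), bn_l(2048L),
    layer_spec("gap"),
    layer_spec("output", units = n_classes, in_features = 2048L,
               activation = "softmax")))
  new_cnn_spec(layers, c(299L, 299L, 3L), n_classes, "xception")
}

build_densenet121 <- function(n_classes = 1000L) {
  growth <- 32L
  layers <- list(conv_l(7L, 3L, 64L, bias = FALSE), bn_l(64L),
                 layer_spec("relu"), pool_l())
  ch <- 64L
  blocks <- c(6L, 12L, 24L, 16L)
  for (bi in seq_along(blocks)) {
    for (i in seq_len(blocks[bi])) {
      layers <- c(layers, list(
        bn_l(ch), layer_spec("relu"), conv_l(1L, ch, 4L * growth, bias = FALSE),
        bn_l(4L * growth), layer_spec("relu"),
        conv_l(3L, 4L * growth, growth, bias = FALSE)))
      ch <- ch + growth
    }
    if (bi < length(blocks)) {
      layers <- c(layers, list(bn_l(ch), layer_spec("relu"),
                               conv_l(1L, ch, ch %/% 2L, bias = FALSE),
                               layer_spec("avgpool")))
      ch <- ch %/% 2L
    }
  }
  layers <- c(layers, list(bn_l(ch), layer_spec("relu"), layer_spec("gap"),
                           layer_spec("output", units = n_classes,
                                      in_features = ch,
                                      activation = "softmax")))
  new_cnn_spec(layers, c(224L, 224L, 3L), n_classes, "densenet121")
}

#' Transfer-model specification
#'
#' @param base one of `"vgg16"`, `"xception"`, `"densenet121"`.
#' @param mode `"feature_extraction"` (all base layers frozen) or
#'   `"fine_tune"` (the last `n_unfrozen` parameterized base layers
#'   trainable).
#' @param n_unfrozen number of trailing base layers to unfreeze in
#'   `fine_tune` mode.
#' @return object of class `transfer_spec`.
#' @export
transfer_spec <- function(base = c("vgg16", "xception", "densenet121"),
                          mode = c("feature_extraction", "fine_tune"),
                          n_unfrozen = 0L) {
  base <- match.arg(base)
  mode <- match.arg(mode)
  if (n_unfrozen < 0) stop("n_unfrozen must be >= 0")
  structure(list(base = base, mode = mode, n_unfrozen = as.integer(n_unfrozen)),
            class = "transfer_spec")
}

#' Build a transfer-learning model
#'
#' Constructs the base topology and appends a classification head. With
#' `n_classes = 1000` and `head = NULL` the standard published ImageNet top
#' is kept, so [count_parameters()] reproduces the published totals. For
#' other class counts the top is replaced by a global-average-pooling (or
#' flatten, for VGG16) head with a single dense classifier. Trainable flags
#' follow the mode: `feature_extraction` freezes every base layer;
#' `fine_tune` unfreezes the last `n_unfrozen` parameterized base layers.
#' `fine_tune` with `n_unfrozen = 0` therefore equals `feature_extraction`.
#'
#' @param spec a [transfer_spec()].
#' @param n_classes classes for the head (2 gives one sigmoid unit).
#' @return a `cnn_spec` with trainable flags set.
#' @export
build_transfer_model <- function(spec, n_classes = 1000L) {
  stopifnot(inherits(spec, "transfer_spec"))
  builder <- switch(spec$base, vgg16 = build_vgg16,
                    xception = build_xception, densenet121 = build_densenet121)
  full <- builder(n_classes = 1000L)
  layers <- full$layers
  # split off the published top (output layer; for vgg16 also the FC stack)
  head_start <- if (spec$base == "vgg16")
    which(vapply(layers, function(l) l$kind == "flatten", TRUE))[1]
  else length(layers)  # the output layer
  base_layers <- layers[seq_len(head_start - 1L)]
  param_idx <- which(vapply(base_layers, function(l)
    l$kind %in% c("conv", "sepconv", "dense", "batchnorm"), TRUE))
  if (spec$n_unfrozen > length(param_idx))
    stop("n_unfrozen exceeds base depth (", length(param_idx), " layers)")
  frozen <- param_idx
  if (spec$mode == "fine_tune" && spec$n_unfrozen > 0)
    frozen <- utils::head(param_idx, length(param_idx) - spec$n_unfrozen)
  for (i in frozen) base_layers[[i]]$trainable <- FALSE

  if (n_classes == 1000L) {
    head_layers <- layers[head_start:length(layers)]
  } else {
    feat <- switch(spec$base, vgg16 = 512L, xception = 2048L,
                   densenet121 = 1024L)
    out_units <- if (n_classes == 2) 1L else n_classes
    head_layers <- list(
      layer_spec("gap"),
      layer_spec("output", units = out_units, in_features = feat,
                 activation = if (out_units == 1) "sigmoid" else "softmax"))
  }
  new_cnn_spec(c(base_layers, head_layers), full$input_size, n_classes,
               paste0(spec$base, "_", spec$mode))
}
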