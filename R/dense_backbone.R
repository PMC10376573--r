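#' Feature-map count at a dense layer
#'
#' In a dense block every layer receives the concatenation of the block
#' input and all previous layers' outputs, so the number of input feature
#' maps at the l-th layer is `k0 + k * (l - 1)`, where `k0` is the number of
#' channels entering the block and `k` the growth rate.
#'
#' @param k0 channels entering the block (>= 1).
#' @param k growth rate (>= 0).
#' @param l 1-based layer index within the block (>= 1); may be a vector.
#' @return integer count(s) of input feature maps.
#' @examples
#' feature_map_count(64, 32, 7)  # 256
#' @export
feature_map_count <- function(k0, k, l) {
  if (any(l < 1)) stop("layer index `l` must be >= 1")
  if (k0 < 1 || k < 0) stop("require k0 >= 1 and k >= 0")
  as.integer(k0 + k * (l - 1))
}

#' Dense backbone configuration
#'
#' Describes a densely connected convolutional feature extractor: a stem
#' (7x7 conv stride 2, then 3x3 max pool stride 2), alternating dense blocks
#' and transition layers, a final batch norm + rectifier, and global average
#' pooling. The default is the DenseNet201 topology (growth rate 32, stem 64
#' channels, blocks 6/12/48/32, compression 0.5), whose terminal feature
#' vector has length 1920.
#'
#' @param growth_rate `k`, feature maps added by each dense layer.
#' @param stem_channels `k0` of the stem output.
#' @param block_layers layers per dense block.
#' @param compression transition-layer channel multiplier in `(0, 1]`
#'   (floored, minimum 1 channel).
#' @param bottleneck_factor width of the 1x1 bottleneck conv as a multiple
#'   of the growth rate (the conventional dense-bottleneck value is 4).
#' @param input_shape nominal `(H, W, 3)` input; forwarding accepts any
#'   spatial size large enough for the stem and transitions.
#' @param seed seeds the random parameter initialization.
#' @param pretrained_path optional checkpoint to load with
#'   [load_pretrained()] after building.
#' @return an object of class `oct_backbone_config`.
#' @export
backbone_config <- function(growth_rate = 32L, stem_channels = 64L,
                            block_layers = c(6L, 12L, 48L, 32L),
                            compression = 0.5, bottleneck_factor = 4L,
                            input_shape = c(224L, 224L, 3L), seed = 1L,
                            pretrained_path = NULL) {
  if (growth_rate < 1) stop("growth_rate must be >= 1")
  if (length(block_layers) == 0L || any(block_layers < 1))
    stop("block_layers must be a non-empty vector of positive integers")
  if (compression <= 0 || compression > 1) stop("compression must be in (0, 1]")
  if (bottleneck_factor < 1) stop("bottleneck_factor must be >= 1")
  structure(list(growth_rate = as.integer(growth_rate),
                 stem_channels = as.integer(stem_channels),
                 block_layers = as.integer(block_layers),
                 compression = compression,
                 bottleneck_factor = as.integer(bottleneck_factor),
                 input_shape = as.integer(input_shape), seed = as.integer(seed),
                 pretrained_path = pretrained_path),
            class = "oct_backbone_config")
}

#' Per-layer channel ledger of a backbone configuration
#'
#' Recomputes, by pure arithmetic, the number of input channels of every
#' dense layer (via [feature_map_count()]) and the channel count after each
#' block and transition — the reference against which the runtime forward
#' pass is audited.
#'
#' @param config an [backbone_config()].
#' @return list with `stem` (channels after the stem), `block_inputs` (list
#'   of per-layer input-channel vectors), `block_out`, `transition_out`, and
#'   `terminal` (the feature-vector length after global pooling).
#' @export
channel_ledger <- function(config) {
  k <- config$growth_rate
  ch <- config$stem_channels
  block_inputs <- list(); block_out <- integer(0); trans_out <- integer(0)
  nb <- length(config$block_layers)
  for (b in seq_len(nb)) {
    L <- config$block_layers[b]
    block_inputs[[b]] <- feature_map_count(ch, k, seq_len(L))
    ch <- feature_map_count(ch, k, L + 1L)   # block output = k0 + k*L
    block_out <- c(block_out, ch)
    if (b < nb) {
      ch <- max(1L, as.integer(floor(ch * config$compression)))
      trans_out <- c(trans_out, ch)
    }
  }
  list(stem = config$stem_channels, block_inputs = block_inputs,
       block_out = block_out, transition_out = trans_out, terminal = ch)
}

# ---- parameter blocks ------------------------------------------------------

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c),
                            mean = numeric(c), var = rep(1, c))

bn_apply <- function(x, bn, eps = 1e-5) {
  d <- dim(x)
  scale <- bn$gamma / sqrt(bn$var + eps)
  shift <- bn$beta - bn$mean * scale
  sweep(sweep(x, 3L, scale, "*"), 3L, shift, "+")
}

conv_nb <- function(x, w, stride = 1L, pad = 0L)
  cpp_conv2d(x, w, numeric(dim(w)[4]), as.integer(stride), as.integer(pad))

#' Create and apply a single dense layer
#'
#' A dense layer maps the running concatenation of all previous feature maps
#' to `k` new channels via BN -> rectifier -> 1x1 bottleneck conv
#' (`bottleneck_factor * k` channels) -> BN -> rectifier -> 3x3 conv
#' (`k` channels, padding 1). Spatial size is unchanged.
#'
#' @param cin input channel count (must equal [feature_map_count()] at this
#'   layer's position).
#' @param k growth rate.
#' @param bottleneck_factor bottleneck width multiple.
#' @return `make_dense_layer`: a parameter block; `dense_layer`: the layer's
#'   output with exactly `k` channels.
#' @export
make_dense_layer <- function(cin, k, bottleneck_factor = 4L) {
  bw <- bottleneck_factor * k
  list(cin = as.integer(cin), k = as.integer(k),
       bn1 = init_bn(cin),
       w1 = array(rnorm(cin * bw, sd = sqrt(2 / cin)), dim = c(1L, 1L, cin, bw)),
       bn2 = init_bn(bw),
       w2 = array(rnorm(9 * bw * k, sd = sqrt(2 / (9 * bw))),
                  dim = c(3L, 3L, bw, k)))
}

#' @rdname make_dense_layer
#' @param x input tensor `(H, W, cin)`.
#' @param layer a parameter block from `make_dense_layer`.
#' @export
dense_layer <- function(x, layer) {
  if (dim(x)[3] != layer$cin)
    stop("dense layer expects ", layer$cin, " input channels, got ", dim(x)[3])
  h <- relu(bn_apply(x, layer$bn1))
  h <- conv_nb(h, layer$w1)
  h <- relu(bn_apply(h, layer$bn2))
  conv_nb(h, layer$w2, pad = 1L)
}

#' Create and apply a transition layer
#'
#' BN -> rectifier -> 1x1 conv compressing channels to
#' `max(1, floor(cin * compression))` -> 2x2 average pooling (stride 2,
#' trailing odd row/column dropped).
#'
#' @param cin input channel count.
#' @param compression channel multiplier in `(0, 1]`.
#' @return `make_transition`: a parameter block; `transition`: the
#'   downsampled tensor.
#' @export
make_transition <- function(cin, compression = 0.5) {
  cout <- max(1L, as.integer(floor(cin * compression)))
  list(cin = as.integer(cin), cout = cout,
       bn = init_bn(cin),
       w = array(rnorm(cin * cout, sd = sqrt(2 / cin)),
                 dim = c(1L, 1L, cin, cout)))
}

#' @rdname make_transition
#' @param x input tensor `(H, W, cin)` with spatial size >= 2.
#' @param layer a parameter block from `make_transition`.
#' @export
transition <- function(x, layer) {
  if (dim(x)[1] < 2 || dim(x)[2] < 2)
    stop("transition layer needs spatial size >= 2, got ",
         dim(x)[1], "x", dim(x)[2])
  h <- relu(bn_apply(x, layer$bn))
  h <- conv_nb(h, layer$w)
  cpp_avgpool(h, 2L, 2L)
}

#' Build a dense backbone
#'
#' Initializes all parameters from `config$seed` (He-normal convolutions,
#' identity batch-norm statistics) and precomputes the channel ledger. If
#' `config$pretrained_path` is set, the checkpoint is loaded after building.
#'
#' @param config an [backbone_config()].
#' @return an object of class `oct_backbone`.
#' @export
build_backbone <- function(config = backbone_config()) {
  stopifnot(inherits(config, "oct_backbone_config"))
  ledger <- channel_ledger(config)
  k <- config$growth_rate
  bb <- with_seed(config$seed, {
    k0 <- config$stem_channels
    params <- list(
      stem_conv = array(rnorm(7 * 7 * 3 * k0, sd = sqrt(2 / (49 * 3))),
                        dim = c(7L, 7L, 3L, k0)),
      stem_bn = init_bn(k0),
      blocks = list(), transitions = list())
    nb <- length(config$block_layers)
    for (b in seq_len(nb)) {
      params$blocks[[b]] <- lapply(ledger$block_inputs[[b]], function(cin)
        make_dense_layer(cin, k, config$bottleneck_factor))
      if (b < nb)
        params$transitions[[b]] <- make_transition(ledger$block_out[b],
                                                   config$compression)
    }
    params$final_bn <- init_bn(ledger$terminal)
    structure(list(config = config, params = params, ledger = ledger),
              class = "oct_backbone")
  })
  if (!is.null(config$pretrained_path))
    bb <- load_pretrained(bb, config$pretrained_path)
  bb
}

# Forward pass to the terminal feature map, auditing runtime channel counts
# against the arithmetic ledger at every dense layer.
backbone_forward <- function(backbone, x, audit = TRUE) {
  p <- backbone$params; led <- backbone$ledger
  if (dim(x)[1] < 8 || dim(x)[2] < 8)
    stop("input too small for the stem (minimum 8x8)")
  h <- conv_nb(x, p$stem_conv, stride = 2L, pad = 3L)
  h <- relu(bn_apply(h, p$stem_bn))
  h <- cpp_maxpool(h, 3L, 2L, 1L)$out
  nb <- length(p$blocks)
  for (b in seq_len(nb)) {
    for (l in seq_along(p$blocks[[b]])) {
      if (audit && dim(h)[3] != led$block_inputs[[b]][l])
        stop(sprintf("channel audit failed at block %d layer %d: %d != %d",
                     b, l, dim(h)[3], led$block_inputs[[b]][l]))
      y <- dense_layer(h, p$blocks[[b]][[l]])
      h <- array(c(h, y), dim = c(dim(h)[1:2], dim(h)[3] + dim(y)[3]))
    }
    if (audit && dim(h)[3] != led$block_out[b])
      stop("channel audit failed after block ", b)
    if (b < nb) {
      h <- transition(h, p$transitions[[b]])
      if (audit && dim(h)[3] != led$transition_out[b])
        stop("channel audit failed after transition ", b)
    }
  }
  relu(bn_apply(h, p$final_bn))
}

#' Extract a fixed-length feature vector from an image
#'
#' Runs the backbone and applies global average pooling over all spatial
#' locations of the terminal feature map. The vector length equals the
#' backbone's terminal channel count and is independent of the input's
#' spatial size (1920 for the reference DenseNet201 topology).
#'
#' @param backbone an `oct_backbone`.
#' @param image H x W matrix (replicated to 3 channels) or H x W x 3 array.
#' @param scale_tag optional label recording which pyramid scale produced
#'   the image; defaults to the input height.
#' @return an `oct_feature`: list with `values`, `scale_tag`, `length`.
#' @export
extract_features <- function(backbone, image, scale_tag = NULL) {
  stopifnot(inherits(backbone, "oct_backbone"))
  x <- to_rgb(image)
  if (dim(x)[3] != 3L) stop("backbone expects a 3-channel image")
  h <- backbone_forward(backbone, x)
  v <- apply(h, 3L, mean)
  structure(list(values = as.numeric(v),
                 scale_tag = scale_tag %||% as.character(dim(x)[1]),
                 length = length(v)),
            class = "oct_feature")
}

#' Save / load backbone parameters
#'
#' The checkpoint is a self-describing list of the config and all named
#' parameter arrays. `load_pretrained` validates the topology parameter by
#' parameter and reports the first mismatching layer by name.
#'
#' @param backbone an `oct_backbone`.
#' @param path checkpoint file path.
#' @return `save_backbone`: `path`, invisibly. `load_pretrained`: the
#'   backbone with parameters replaced.
#' @export
save_backbone <- function(backbone, path) {
  stopifnot(inherits(backbone, "oct_backbone"))
  saveRDS(list(config = backbone$config, params = backbone$params), path)
  invisible(path)
}

check_param_tree <- function(a, b, path = "") {
  if (is.list(a)) {
    if (!is.list(b) || !identical(names(a), names(b)))
      stop("topology mismatch at '", path, "': parameter names differ")
    for (nm in if (is.null(names(a))) seq_along(a) else names(a))
      check_param_tree(a[[nm]], b[[nm]], paste0(path, "/", nm))
  } else {
    da <- dim(a) %||% length(a); db <- dim(b) %||% length(b)
    if (!identical(as.integer(da), as.integer(db)))
      stop("topology mismatch at '", path, "': expected shape (",
           paste(da, collapse = ", "), "), checkpoint has (",
           paste(db, collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' @rdname save_backbone
#' @param weights path to a checkpoint written by [save_backbone()].
#' @export
load_pretrained <- function(backbone, weights) {
  stopifnot(inherits(backbone, "oct_backbone"))
  if (!file.exists(weights)) stop("weights file not found: ", weights)
  obj <- readRDS(weights)
  check_param_tree(backbone$params, obj$params)
  backbone$params <- obj$params
  backbone
}
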