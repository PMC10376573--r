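#' Configuration of the autoencoder scale-adaptation module
#'
#' The module accepts OCT images of any size and emits the three calibrated
#' pyramid scales consumed by the feature-extraction backbones. Its encoder
#' is a stack of conv(3x3) + maxpool(2x2) stages; a linear projection to 3
#' channels followed by a bilinear resize yields the latent feature map
#' `F_AE` at the first pyramid scale (224 x 224 x 3 by default); `F_AE` is
#' further processed by a conv, a stride-1 transposed conv and a
#' channel-expanding conv to a 12-channel map; the concatenation of `F_AE`
#' and the processed map feeds a high-resolution head (the pyramid input)
#' and a low-resolution head that reconstructs the image at its original
#' size for training.
#'
#' @param target_scales ordered list of `(height, width, channels)` triples,
#'   strictly decreasing in spatial size. Default `224/112/56` with 3
#'   channels each.
#' @param encoder_stages number of conv + pool stages in the encoder.
#' @param base_channels channels of the first encoder stage (doubled at each
#'   subsequent stage).
#' @param delta pseudo-Huber transition scale (see [pseudo_huber()]).
#' @param loss_weights length-2 nonnegative weights `(w_hi, w_lo)` for the
#'   high-resolution (two pseudo-Huber terms) and low-resolution (log-cosh)
#'   parts of the training loss.
#' @param epochs,batch_size,learning_rate training hyperparameters (Adam).
#' @param seed integer; seeds parameter initialization and batch shuffling.
#' @return an object of class `oct_ae_config`.
#' @export
ae_config <- function(target_scales = list(c(224L, 224L, 3L),
                                           c(112L, 112L, 3L),
                                           c(56L, 56L, 3L)),
                      encoder_stages = 3L, base_channels = 8L,
                      delta = 1, loss_weights = c(1, 1),
                      epochs = 5L, batch_size = 8L, learning_rate = 1e-3,
                      seed = 1L) {
  sizes <- vapply(target_scales, function(s) s[1] * s[2], numeric(1))
  if (length(target_scales) < 1L || any(diff(sizes) >= 0))
    stop("`target_scales` must be strictly decreasing in spatial size")
  if (delta <= 0) stop("`delta` must be positive")
  if (length(loss_weights) != 2L || any(loss_weights < 0) || sum(loss_weights) == 0)
    stop("`loss_weights` must be two nonnegative values, not both zero")
  if (target_scales[[1]][1] > 2048 || target_scales[[1]][2] > 2048)
    stop("first target scale exceeds the practical encoder output bound (2048)")
  structure(list(target_scales = lapply(target_scales, as.integer),
                 encoder_stages = as.integer(encoder_stages),
                 base_channels = as.integer(base_channels),
                 delta = delta, loss_weights = loss_weights,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "oct_ae_config")
}

# He-normal conv parameter block
init_conv <- function(kh, kw, cin, cout) {
  list(w = array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

#' Build the scale-adaptation autoencoder
#'
#' Parameters are initialized from `config$seed`, so two builds with the
#' same config are identical.
#'
#' @param config an [ae_config()].
#' @return an object of class `oct_ae` exposing [ae_forward()],
#'   [train_ae()] and [emit_pyramid()].
#' @export
build_ae <- function(config = ae_config()) {
  stopifnot(inherits(config, "oct_ae_config"))
  S <- config$encoder_stages
  b <- config$base_channels
  m <- 2L * b   # width of the post-latent processing convs
  with_seed(config$seed, {
    params <- list()
    cin <- 3L
    for (s in seq_len(S)) {
      cout <- b * 2L^(s - 1L)
      params[[paste0("enc", s)]] <- init_conv(3L, 3L, cin, cout)
      cin <- cout
    }
    params$proj <- init_conv(3L, 3L, cin, 3L)
    params$cl <- init_conv(3L, 3L, 3L, m)
    # stride-1 transposed conv: algebraically a convolution with a flipped
    # kernel, so it is parameterized directly as a conv layer
    params$tconv <- init_conv(3L, 3L, m, m)
    params$expand <- init_conv(1L, 1L, m, 12L)
    params$high <- init_conv(3L, 3L, 15L, 3L)
    params$low <- init_conv(3L, 3L, 15L, 3L)
    structure(list(config = config, params = params), class = "oct_ae")
  })
}

relu <- function(x) { x[x < 0] <- 0; x }

#' Forward pass of the scale-adaptation module
#'
#' @param ae an `oct_ae` handle.
#' @param image an H x W matrix (grayscale, replicated to 3 channels) or an
#'   H x W x 3 array; any spatial size at least `2^encoder_stages`.
#' @param cache keep intermediate activations (needed for training)?
#' @return an `oct_ae_outputs` list: `f_ae` (latent map at the first pyramid
#'   scale, 3 channels), `processed` (12-channel processed map), `high_res`
#'   (first-scale image fed to the pyramid), `low_res_reconstruction`
#'   (reconstruction at the original input size), and `cache` when requested.
#' @export
ae_forward <- function(ae, image, cache = FALSE) {
  stopifnot(inherits(ae, "oct_ae"))
  x <- to_rgb(image)
  cfg <- ae$config
  S <- cfg$encoder_stages
  if (dim(x)[1] < 2^S || dim(x)[2] < 2^S)
    stop("input smaller than the encoder's ", 2^S, "-pixel minimum")
  s1 <- cfg$target_scales[[1L]]
  p <- ae$params
  cc <- list(input = x)

  h <- x
  for (s in seq_len(S)) {
    lay <- p[[paste0("enc", s)]]
    a <- cpp_conv2d(h, lay$w, lay$b, 1L, 1L)
    r <- relu(a)
    mp <- cpp_maxpool(r, 2L, 2L, 0L)
    if (cache) {
      cc[[paste0("enc_in", s)]] <- h
      cc[[paste0("enc_pre", s)]] <- a
      cc[[paste0("enc_idx", s)]] <- mp$idx
      cc[[paste0("enc_dim", s)]] <- dim(r)
    }
    h <- mp$out
  }
  aproj <- cpp_conv2d(h, p$proj$w, p$proj$b, 1L, 1L)
  f_ae <- cpp_resize(aproj, s1[1], s1[2], 0L)

  c1 <- cpp_conv2d(f_ae, p$cl$w, p$cl$b, 1L, 1L)
  c1r <- relu(c1)
  t1 <- cpp_conv2d(c1r, p$tconv$w, p$tconv$b, 1L, 1L)
  t1r <- relu(t1)
  proc <- cpp_conv2d(t1r, p$expand$w, p$expand$b, 1L, 0L)

  cat15 <- array(c(f_ae, proc), dim = c(s1[1], s1[2], 15L))
  high <- cpp_conv2d(cat15, p$high$w, p$high$b, 1L, 1L)
  lowin <- cpp_resize(cat15, dim(x)[1], dim(x)[2], 0L)
  low <- cpp_conv2d(lowin, p$low$w, p$low$b, 1L, 1L)

  out <- structure(list(f_ae = f_ae, processed = proc, high_res = high,
                        low_res_reconstruction = low),
                   class = "oct_ae_outputs")
  if (cache) {
    cc$enc_out <- h; cc$aproj_dim <- dim(aproj)
    cc$c1 <- c1; cc$c1r <- c1r; cc$t1 <- t1; cc$t1r <- t1r
    cc$cat15 <- cat15; cc$lowin <- lowin
    out$cache <- cc
  }
  out
}

# Parameter gradients of ae_loss for one image; returns a params-shaped list.
ae_backward <- function(ae, out, target_hi, original) {
  cfg <- ae$config; p <- ae$params; cc <- out$cache
  w <- cfg$loss_weights
  g <- lapply(p, function(lay) list(w = array(0, dim(lay$w)), b = numeric(length(lay$b))))

  n_hi <- length(out$high_res); n_fae <- length(out$f_ae)
  n_lo <- length(out$low_res_reconstruction)
  g_high <- w[1] * pseudo_huber_grad(out$high_res - target_hi, cfg$delta) / n_hi
  g_fae_direct <- w[1] * pseudo_huber_grad(out$f_ae - target_hi, cfg$delta) / n_fae
  g_low <- w[2] * tanh(out$low_res_reconstruction - original) / n_lo
  dim(g_high) <- dim(out$high_res); dim(g_fae_direct) <- dim(out$f_ae)
  dim(g_low) <- dim(out$low_res_reconstruction)

  s1 <- cfg$target_scales[[1L]]

  gr <- cpp_conv2d_grad(cc$lowin, p$low$w, g_low, 1L, 1L)
  g$low$w <- gr$dw; g$low$b <- gr$db
  d_cat <- cpp_resize_grad(gr$dx, s1[1], s1[2], 0L)

  gr <- cpp_conv2d_grad(cc$cat15, p$high$w, g_high, 1L, 1L)
  g$high$w <- gr$dw; g$high$b <- gr$db
  d_cat <- d_cat + gr$dx

  d_fae <- g_fae_direct + d_cat[, , 1:3, drop = FALSE]
  d_proc <- d_cat[, , 4:15, drop = FALSE]

  gr <- cpp_conv2d_grad(cc$t1r, p$expand$w, d_proc, 1L, 0L)
  g$expand$w <- gr$dw; g$expand$b <- gr$db
  d_t1 <- gr$dx * (cc$t1 > 0)

  gr <- cpp_conv2d_grad(cc$c1r, p$tconv$w, d_t1, 1L, 1L)
  g$tconv$w <- gr$dw; g$tconv$b <- gr$db
  d_c1 <- gr$dx * (cc$c1 > 0)

  gr <- cpp_conv2d_grad(out$f_ae, p$cl$w, d_c1, 1L, 1L)
  g$cl$w <- gr$dw; g$cl$b <- gr$db
  d_fae <- d_fae + gr$dx

  d_aproj <- cpp_resize_grad(d_fae, cc$aproj_dim[1], cc$aproj_dim[2], 0L)
  gr <- cpp_conv2d_grad(cc$enc_out, p$proj$w, d_aproj, 1L, 1L)
  g$proj$w <- gr$dw; g$proj$b <- gr$db
  d_h <- gr$dx

  for (s in rev(seq_len(cfg$encoder_stages))) {
    dims <- cc[[paste0("enc_dim", s)]]
    d_r <- cpp_maxpool_grad(cc[[paste0("enc_idx", s)]], d_h,
                            dims[1], dims[2], dims[3])
    d_a <- d_r * (cc[[paste0("enc_pre", s)]] > 0)
    lay <- p[[paste0("enc", s)]]
    gr <- cpp_conv2d_grad(cc[[paste0("enc_in", s)]], lay$w, d_a, 1L, 1L)
    key <- paste0("enc", s)
    g[[key]]$w <- gr$dw; g[[key]]$b <- gr$db
    d_h <- gr$dx
  }
  g
}

# High-resolution reconstruction target: antialiased (area) downsample of
# the original image to the first pyramid scale.
ae_target_hi <- function(image3, s1) cpp_resize(image3, s1[1], s1[2], 1L)

ae_dataset_loss <- function(ae, imgs3, targets) {
  mean(vapply(seq_along(imgs3), function(i) {
    out <- ae_forward(ae, imgs3[[i]])
    ae_loss(out, imgs3[[i]], targets[[i]], ae$config)
  }, numeric(1)))
}

#' Train the scale-adaptation autoencoder
#'
#' Unsupervised training (labels, if any, are ignored) with Adam on the
#' combined pseudo-Huber + log-cosh reconstruction loss. The per-image
#' high-resolution target is an antialiased downsample of the image to the
#' first pyramid scale; the low-resolution branch is compared against the
#' original image at its native size. The returned model carries the
#' parameters of the best epoch (full-dataset mean loss), so the final loss
#' never exceeds the initial one.
#'
#' @param ae an `oct_ae` from [build_ae()].
#' @param images an `oct_image_set`, or a list of matrices / H x W x 3 arrays.
#' @param config optional [ae_config()] overriding `ae$config` training
#'   fields (epochs, batch size, learning rate, seed).
#' @return a list: `ae` (trained handle) and `history` (mean training-set
#'   loss; element 1 is the pre-training loss, then one value per epoch).
#' @export
train_ae <- function(ae, images, config = NULL) {
  stopifnot(inherits(ae, "oct_ae"))
  cfg <- config %||% ae$config
  imgs <- if (inherits(images, "oct_image_set")) images$images else images
  if (length(imgs) < 2L) stop("training requires at least 2 images")
  imgs3 <- lapply(imgs, to_rgb)
  s1 <- ae$config$target_scales[[1L]]
  targets <- lapply(imgs3, ae_target_hi, s1 = s1)

  adam <- list(t = 0)
  mstate <- lapply(ae$params, function(l) list(w = array(0, dim(l$w)),
                                               b = numeric(length(l$b))))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate

  history <- ae_dataset_loss(ae, imgs3, targets)
  best <- list(loss = history[1], params = ae$params)

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(imgs3))
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        acc <- NULL
        for (i in idx) {
          out <- ae_forward(ae, imgs3[[i]], cache = TRUE)
          g <- ae_backward(ae, out, targets[[i]], imgs3[[i]])
          acc <- if (is.null(acc)) g else mapply(function(a, b)
            list(w = a$w + b$w, b = a$b + b$b), acc, g, SIMPLIFY = FALSE)
        }
        nb <- length(idx)
        adam$t <- adam$t + 1
        corr <- sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
        for (nm in names(ae$params)) {
          gw <- acc[[nm]]$w / nb; gb <- acc[[nm]]$b / nb
          mstate[[nm]]$w <- b1 * mstate[[nm]]$w + (1 - b1) * gw
          mstate[[nm]]$b <- b1 * mstate[[nm]]$b + (1 - b1) * gb
          vstate[[nm]]$w <- b2 * vstate[[nm]]$w + (1 - b2) * gw^2
          vstate[[nm]]$b <- b2 * vstate[[nm]]$b + (1 - b2) * gb^2
          ae$params[[nm]]$w <- ae$params[[nm]]$w -
            lr * corr * mstate[[nm]]$w / (sqrt(vstate[[nm]]$w) + eps)
          ae$params[[nm]]$b <- ae$params[[nm]]$b -
            lr * corr * mstate[[nm]]$b / (sqrt(vstate[[nm]]$b) + eps)
        }
      }
      l <- ae_dataset_loss(ae, imgs3, targets)
      history <- c(history, l)
      if (l < best$loss) best <- list(loss = l, params = ae$params)
    }
  })
  ae$params <- best$params
  list(ae = ae, history = history)
}

#' Emit the three-scale image pyramid for one image
#'
#' Runs the scale-adaptation forward pass; the first (largest) scale is the
#' module's high-resolution output, and the smaller scales are derived from
#' it by average pooling at the integer scale ratio (bilinear resampling
#' when the ratio is not integer) — a parameter-free reduction that
#' preserves the module's learned content at every scale.
#'
#' @param ae an `oct_ae` handle (trained or freshly initialized).
#' @param image matrix or H x W x 3 array of any size.
#' @return an `oct_multiscale`: list of arrays, one per configured scale,
#'   named by spatial size (e.g. `"224"`, `"112"`, `"56"`).
#' @export
emit_pyramid <- function(ae, image) {
  out <- ae_forward(ae, image)
  scales <- ae$config$target_scales
  s1 <- scales[[1L]]
  pyr <- list(out$high_res)
  for (k in seq_along(scales)[-1L]) {
    s <- scales[[k]]
    ratio <- s1[1] / s[1]
    pyr[[k]] <- if (ratio == round(ratio) && s1[2] / s[2] == ratio) {
      cpp_avgpool(out$high_res, as.integer(ratio), as.integer(ratio))
    } else {
      cpp_resize(out$high_res, s[1], s[2], 1L)
    }
  }
  names(pyr) <- vapply(scales, function(s) as.character(s[1]), character(1))
  structure(pyr, class = "oct_multiscale")
}

#' Save / load a scale-adaptation checkpoint
#'
#' The checkpoint is a self-describing list holding the config and all
#' parameter arrays.
#'
#' @param ae an `oct_ae`.
#' @param path file path.
#' @return `save_ae` returns `path` invisibly; `load_ae` returns the handle.
#' @export
save_ae <- function(ae, path) {
  stopifnot(inherits(ae, "oct_ae"))
  saveRDS(list(config = ae$config, params = ae$params), path)
  invisible(path)
}

#' @rdname save_ae
#' @export
load_ae <- function(path) {
  obj <- readRDS(path)
  structure(list(config = obj$config, params = obj$params), class = "oct_ae")
}
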