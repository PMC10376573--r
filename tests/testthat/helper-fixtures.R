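# Shared desk-scale fixtures: every configuration here is deliberately tiny
# so the full pipeline stays inside interactive runtimes.

tiny_ae_config <- function(seed = 3L, epochs = 2L, ...) {
  ae_config(target_scales = list(c(16L, 16L, 3L), c(8L, 8L, 3L), c(4L, 4L, 3L)),
            encoder_stages = 2L, base_channels = 2L, epochs = epochs,
            batch_size = 4L, seed = seed, ...)
}

tiny_backbone_config <- function(seed = 5L, ...) {
  backbone_config(growth_rate = 8L, stem_channels = 16L,
                  block_layers = c(2L, 2L), compression = 0.5,
                  input_shape = c(16L, 16L, 3L), seed = seed, ...)
}

tiny_image_set <- function(n_per_class = 3L, h = 32L, w = 40L, seed = 7L)
  generate_dataset(synthetic_spec(n_per_class, image_height = h,
                                  image_width = w, seed = seed))

# Gaussian class blobs: linearly separable in 4 dimensions, one mean per
# class along distinct axes so every pair is separable.
separable_features <- function(n_per_class = 20L, sd = 0.3, seed = 11L,
                               classes = c("NORMAL", "CNV", "DME", "DRUSEN")) {
  means <- diag(4)[seq_along(classes), , drop = FALSE] * 4
  X <- NULL; y <- character(0)
  set.seed(seed)
  for (i in seq_along(classes)) {
    X <- rbind(X, matrix(rnorm(n_per_class * 4, sd = sd), n_per_class, 4) +
                 matrix(means[i, ], n_per_class, 4, byrow = TRUE))
    y <- c(y, rep(classes[i], n_per_class))
  }
  list(X = X, y = y, classes = classes)
}

# Classifier spec scaled to tiny fixtures (the printed MLP defaults target
# corpus-scale training sets).
fixture_mlp_spec <- function(seed = 13L)
  classifier_spec("MLP", seed = seed, hidden = c(32L, 16L), epochs = 150L,
                  batch_size = 16L, dropout = 0.2)

# AE whose scales are all large enough for the backbone stem (>= 8 pixels)
fusion_ae_config <- function(seed = 3L, ...)
  ae_config(target_scales = list(c(32L, 32L, 3L), c(16L, 16L, 3L),
                                 c(8L, 8L, 3L)),
            encoder_stages = 2L, base_channels = 2L, epochs = 2L,
            batch_size = 4L, seed = seed, ...)
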