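#' Specification for a synthetic OCT B-scan dataset
#'
#' Describes a balanced, seeded synthetic dataset of layered B-scan images
#' with class-specific lesions. Defaults generate 256 x 320 images —
#' deliberately different from every pyramid scale, so the scale-adaptation
#' path is always exercised on "any size" input.
#'
#' @param n_per_class number of images per class (>= 1).
#' @param image_height,image_width image size in pixels.
#' @param classes ordered, unique class labels. The generator knows the
#'   morphology of `NORMAL`, `CNV`, `DME` and `DRUSEN`.
#' @param noise_level speckle intensity: pixel values are multiplied by
#'   `1 + noise_level * u`, `u ~ Uniform(-1, 1)`, then clipped to `[0, 1]`.
#' @param seed integer RNG seed; the same spec always generates a
#'   bit-identical dataset.
#' @return an object of class `oct_synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class,
                           image_height = 256L, image_width = 320L,
                           classes = c("NORMAL", "CNV", "DME", "DRUSEN"),
                           noise_level = 0.15, seed = 1L) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L || n_per_class < 1)
    stop("invalid spec: `n_per_class` must be a positive integer")
  if (image_height < 1 || image_width < 1)
    stop("invalid spec: image dimensions must be positive")
  if (length(classes) == 0L || anyDuplicated(classes))
    stop("invalid spec: `classes` must be non-empty and unique")
  if (noise_level < 0) stop("invalid spec: `noise_level` must be nonnegative")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 classes = as.character(classes),
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "oct_synthetic_spec")
}

# One synthetic B-scan. The retina is a stack of smoothly curved horizontal
# bands of alternating reflectivity over a dark background; lesions modify
# the deep-band geometry (CNV dome, drusen bumps) or carve a dark
# intraretinal cyst (DME). All per-image randomness comes from the caller's
# RNG stream.
render_bscan <- function(class, H, W, noise_level) {
  img <- matrix(0.04, H, W)
  j <- seq_len(W)
  ri <- matrix(seq_len(H), H, W)

  # top retinal surface with gentle curvature and tilt
  y_top <- H * (0.20 + runif(1, -0.03, 0.03)) +
    H * 0.05 * sin(2 * pi * j / W + runif(1, 0, 2 * pi)) +
    H * runif(1, -0.02, 0.02) * (j - W / 2) / W
  thick <- H * (0.42 + runif(1, -0.04, 0.04))

  # band boundaries as fractions of retinal thickness; last band is the
  # bright outer complex (RPE), below it a fading choroid
  fr <- c(0, 0.14, 0.34, 0.52, 0.72, 0.86, 1)
  base_int <- c(0.62, 0.30, 0.52, 0.38, 0.28, 0.78)
  band_int <- pmin(pmax(base_int + runif(6, -0.05, 0.05), 0.05), 0.95)

  bounds <- lapply(fr, function(f) y_top + f * thick)   # each length W
  deep_idx <- length(bounds)                            # bottom of RPE band

  # deep-band displacement (toward the surface): dome for CNV, periodic
  # bumps for drusen, none otherwise
  disp <- numeric(W)
  if (class == "CNV") {
    cj <- runif(1, 0.3, 0.7) * W
    width <- runif(1, 0.10, 0.18) * W
    amp <- runif(1, 0.10, 0.16) * H
    disp <- amp * exp(-((j - cj) / width)^2)
  } else if (class == "DRUSEN") {
    period <- runif(1, 0.08, 0.14) * W
    amp <- runif(1, 0.03, 0.05) * H
    phase <- runif(1, 0, 2 * pi)
    disp <- amp * pmax(0, sin(2 * pi * j / period + phase))^2
  }

  top_rpe <- bounds[[deep_idx - 1L]] - disp   # displaced top of RPE band
  bot_rpe <- bounds[[deep_idx]]

  for (b in seq_len(deep_idx - 2L)) {
    lo <- matrix(rep(bounds[[b]], each = H), H, W)
    hi <- matrix(rep(pmin(bounds[[b + 1L]], top_rpe), each = H), H, W)
    img[ri >= lo & ri < hi] <- band_int[b]
  }
  lo <- matrix(rep(top_rpe, each = H), H, W)
  hi <- matrix(rep(bot_rpe, each = H), H, W)
  img[ri >= lo & ri < hi] <- band_int[deep_idx - 1L]

  # choroid: dim texture fading with depth below the RPE
  below <- ri - matrix(rep(bot_rpe, each = H), H, W)
  ch <- below >= 0
  img[ch] <- pmax(0.20 * exp(-below[ch] / (0.15 * H)), 0.04)

  if (class == "DME") {
    ci <- mean(y_top) + runif(1, 0.35, 0.6) * thick
    cj <- runif(1, 0.25, 0.75) * W
    a <- runif(1, 0.07, 0.11) * H
    b2 <- runif(1, 0.08, 0.14) * W
    cjm <- matrix(rep(j, each = H), H, W)
    cyst <- ((ri - ci) / a)^2 + ((cjm - cj) / b2)^2 <= 1
    img[cyst] <- 0.05
  }

  if (noise_level > 0) {
    u <- matrix(runif(H * W, -1, 1), H, W)
    img <- img * (1 + noise_level * u)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a balanced synthetic OCT dataset
#'
#' Produces `n_per_class` grayscale B-scan-like images per class. `NORMAL`
#' images are smooth stacked horizontal bands (retinal layers) under
#' multiplicative speckle; `DME` adds a dark intraretinal ellipse (cyst);
#' `CNV` adds a dome-shaped elevation of the deep bright band; `DRUSEN`
#' adds small periodic bumps on that band. The function is pure: the same
#' spec (including seed) yields bit-identical output and the caller's RNG
#' state is left untouched.
#'
#' @param spec an [synthetic_spec()] object.
#' @return an `oct_image_set`: list with `images` (list of H x W matrices
#'   with values in `[0, 1]`), `labels` (character vector aligned with
#'   `images`), `classes`, and `layout_path` (NULL until written).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "oct_synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  with_seed(spec$seed, {
    images <- list(); labels <- character(0)
    for (cl in spec$classes) {
      for (i in seq_len(spec$n_per_class)) {
        images[[length(images) + 1L]] <-
          render_bscan(cl, spec$image_height, spec$image_width, spec$noise_level)
        labels <- c(labels, cl)
      }
    }
    structure(list(images = images, labels = labels, classes = spec$classes,
                   layout_path = NULL),
              class = "oct_image_set")
  })
}

#' Write an image set as a folder-per-class PNG layout
#'
#' Creates `root/<CLASS>/<index>.png` with lossless 8-bit grayscale PNGs —
#' the conventional public-OCT folder layout.
#'
#' @param set an `oct_image_set`.
#' @param root output directory (created if missing).
#' @return `root`, invisibly usable as input to [read_folder_layout()].
#' @export
write_folder_layout <- function(set, root) {
  stopifnot(inherits(set, "oct_image_set"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create directory: ", root)
  counters <- stats::setNames(integer(length(set$classes)), set$classes)
  for (i in seq_along(set$images)) {
    cl <- set$labels[i]
    d <- file.path(root, cl)
    dir.create(d, showWarnings = FALSE)
    counters[cl] <- counters[cl] + 1L
    png::writePNG(set$images[[i]], file.path(d, sprintf("%04d.png", counters[cl])))
  }
  invisible(root)
}

read_one_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- tryCatch({
    if (ext == "png") {
      png::readPNG(f)
    } else if (ext %in% c("jpg", "jpeg")) {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG support requires the EBImage package")
      e <- EBImage::imageData(EBImage::readImage(f))
      # EBImage stores (x, y[, c]); transpose to (row, col[, c])
      if (length(dim(e)) == 2L) t(e) else aperm(e, c(2L, 1L, 3L))
    } else stop("unsupported image format: .", ext)
  }, error = function(e) stop("failed to read image '", f, "': ",
                              conditionMessage(e), call. = FALSE))
  img <- to_gray(img)
  pmin(pmax(img, 0), 1)
}

#' Read a folder-per-class image layout
#'
#' Labels are inferred from subfolder names; traversal is alphabetically
#' sorted (deterministic). PNG is read natively; JPEG via EBImage when
#' available. RGB images are collapsed to luminance, since the pipeline's
#' pixel container is grayscale (channel replication to RGB happens at the
#' backbone boundary).
#'
#' @param root directory containing one subfolder per class.
#' @return an `oct_image_set` with pixel values in `[0, 1]`.
#' @export
read_folder_layout <- function(root) {
  if (!dir.exists(root)) stop("directory does not exist: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("empty dataset: no class subfolders under ", root)
  images <- list(); labels <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- read_one_image(f)
      labels <- c(labels, cl)
    }
  }
  structure(list(images = images, labels = labels, classes = classes,
                 layout_path = root),
            class = "oct_image_set")
}

#' @export
print.oct_image_set <- function(x, ...) {
  cat("<oct_image_set> ", length(x$images), " images\n", sep = "")
  if (length(x$labels)) print(table(x$labels))
  invisible(x)
}
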