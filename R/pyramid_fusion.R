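#' Pyramid configuration
#'
#' One backbone per pyramid scale. With `share_weights = FALSE` (the
#' default) each path gets its own seeded parameter set (seed, seed + 1,
#' seed + 2, ...); with `share_weights = TRUE` a single parameter set is
#' shared by all paths.
#'
#' @param backbone_config an [backbone_config()] used for every path.
#' @param scale_list list of `(height, width, channels)` triples, matching
#'   the scale-adaptation output (default 224/112/56).
#' @param share_weights share one backbone across the paths?
#' @return an object of class `oct_pyramid_config`.
#' @export
pyramid_config <- function(backbone_config = octpyramid::backbone_config(),
                           scale_list = list(c(224L, 224L, 3L),
                                             c(112L, 112L, 3L),
                                             c(56L, 56L, 3L)),
                           share_weights = FALSE) {
  structure(list(backbone_config = backbone_config,
                 scale_list = lapply(scale_list, as.integer),
                 share_weights = isTRUE(share_weights)),
            class = "oct_pyramid_config")
}

#' Build the per-scale backbones of a pyramid
#'
#' @param config an [pyramid_config()].
#' @return an `oct_pyramid`: list of `oct_backbone` handles, one per scale,
#'   named by scale height.
#' @export
build_pyramid <- function(config) {
  stopifnot(inherits(config, "oct_pyramid_config"))
  bbs <- list()
  for (i in seq_along(config$scale_list)) {
    bc <- config$backbone_config
    if (!config$share_weights) bc$seed <- bc$seed + (i - 1L)
    bc$input_shape <- config$scale_list[[i]]
    bbs[[i]] <- build_backbone(bc)
  }
  if (config$share_weights) for (i in seq_along(bbs)) bbs[[i]] <- bbs[[1L]]
  names(bbs) <- vapply(config$scale_list, function(s) as.character(s[1]),
                       character(1))
  structure(list(backbones = bbs, config = config), class = "oct_pyramid")
}

#' Extract per-scale feature vectors from a multi-scale image
#'
#' Runs each pyramid path on its scale and returns one global-pooled feature
#' vector per scale (length 1920 each for the reference topology).
#'
#' @param multiscale an `oct_multiscale` from [emit_pyramid()], or a named
#'   list of image arrays keyed like the pyramid's scales.
#' @param pyramid an `oct_pyramid` from [build_pyramid()], or an
#'   [pyramid_config()] (backbones are then built on the fly).
#' @return list of `oct_feature`, in scale order.
#' @export
extract_pyramid <- function(multiscale, pyramid) {
  if (inherits(pyramid, "oct_pyramid_config")) pyramid <- build_pyramid(pyramid)
  stopifnot(inherits(pyramid, "oct_pyramid"))
  tags <- names(pyramid$backbones)
  missing <- setdiff(tags, names(multiscale))
  if (length(missing))
    stop("missing pyramid scale(s): ", paste(missing, collapse = ", "))
  lapply(tags, function(tag)
    extract_features(pyramid$backbones[[tag]], multiscale[[tag]],
                     scale_tag = tag))
}

#' Fuse per-scale feature vectors by concatenation
#'
#' The fused predictor is the plain concatenation of the per-scale vectors
#' in scale order (largest first); no rescaling or normalization is applied
#' at this stage. Three 1920-length vectors fuse to length 5760.
#'
#' @param vectors non-empty list of `oct_feature` objects (or bare numeric
#'   vectors) in a fixed scale order.
#' @return an `oct_fused_feature`: list with `values`, `component_lengths`,
#'   `source_scales`.
#' @export
fuse_features <- function(vectors) {
  if (length(vectors) == 0L) stop("cannot fuse an empty feature list")
  vals <- lapply(vectors, function(v) if (inherits(v, "oct_feature")) v$values else as.numeric(v))
  tags <- vapply(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    if (inherits(v, "oct_feature")) v$scale_tag else as.character(i)
  }, character(1))
  structure(list(values = unlist(vals, use.names = FALSE),
                 component_lengths = lengths(vals),
                 source_scales = tags),
            class = "oct_fused_feature")
}

#' Build a fused feature table for a set of images
#'
#' Convenience wrapper over the full front end: every image is passed
#' through the scale-adaptation module, each scale through its backbone, and
#' the per-scale vectors are concatenated. Optionally also returns the
#' per-scale feature matrices (for scale-ablation comparisons).
#'
#' @param images `oct_image_set` or list of images.
#' @param ae a (typically trained) `oct_ae`.
#' @param pyramid an `oct_pyramid` or [pyramid_config()].
#' @param per_scale also return per-scale matrices?
#' @return list with `fused` (n x D matrix) and, if requested, `per_scale`
#'   (named list of n x d matrices, one per scale).
#' @export
feature_table <- function(images, ae, pyramid, per_scale = FALSE) {
  if (inherits(pyramid, "oct_pyramid_config")) pyramid <- build_pyramid(pyramid)
  imgs <- if (inherits(images, "oct_image_set")) images$images else images
  tags <- names(pyramid$backbones)
  rows <- lapply(imgs, function(im) {
    vecs <- extract_pyramid(emit_pyramid(ae, im), pyramid)
    list(fused = fuse_features(vecs)$values,
         per = lapply(vecs, function(v) v$values))
  })
  fused <- do.call(rbind, lapply(rows, `[[`, "fused"))
  out <- list(fused = fused)
  if (per_scale) {
    out$per_scale <- stats::setNames(lapply(seq_along(tags), function(i)
      do.call(rbind, lapply(rows, function(r) r$per[[i]]))), tags)
  }
  out
}

#' Write / read a fused feature table as CSV
#'
#' One row per image: `id`, `label`, then the fused feature values
#' (`v1..vD`) — readable by the cascade trainer, the evaluator and external
#' tools.
#'
#' @param features n x D matrix of fused features.
#' @param labels length-n labels.
#' @param path CSV file path.
#' @param ids optional row identifiers (default `img1..imgn`).
#' @return `write_feature_csv`: `path` invisibly; `read_feature_csv`: list
#'   with `features` (matrix), `labels`, `ids`.
#' @export
write_feature_csv <- function(features, labels, path, ids = NULL) {
  features <- as.matrix(features)
  ids <- ids %||% paste0("img", seq_len(nrow(features)))
  df <- data.frame(id = ids, label = as.character(labels), features)
  colnames(df) <- c("id", "label", paste0("v", seq_len(ncol(features))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(features = as.matrix(df[, -(1:2), drop = FALSE]),
       labels = df$label, ids = df$id)
}
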