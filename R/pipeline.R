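#' Cross-validated end-to-end pipeline
#'
#' Runs the full architecture under stratified k-fold cross-validation with
#' every fitted component (scale-adaptation autoencoder, classifier heads,
#' feature standardizers) trained on the training folds only. Per fold it
#' trains the autoencoder unsupervised on the training images, extracts and
#' fuses the three-scale features with seeded (untrained) backbones, fits
#' the two-stage cascade, the all-at-once four-class head and — for
#' scale-ablation comparison — linear (logistic-regression) probes on the
#' fused and each single-scale feature set, then evaluates all of them on
#' the held-out fold.
#'
#' @param images an `oct_image_set` (or list of images).
#' @param labels four-class labels aligned with `images` (taken from the
#'   image set when omitted).
#' @param ae_cfg an [ae_config()].
#' @param pyramid_cfg an [pyramid_config()]; its scales must match
#'   `ae_cfg$target_scales`.
#' @param spec an [classifier_spec()] for the cascade and four-class heads.
#' @param k folds (default 5).
#' @param seed seeds the fold plan.
#' @param normal_class,abnormal_classes the cascade taxonomy.
#' @return an `oct_pipeline_report`: per-fold and aggregate metrics for the
#'   cascade (four-class), its stage-1 gate (binary, with AUC), the
#'   all-at-once head (with macro one-vs-rest AUC), and the linear probes
#'   (`linear$fused`, `linear$per_scale` per-fold accuracy columns).
#' @export
run_pipeline_cv <- function(images, labels = NULL, ae_cfg, pyramid_cfg, spec,
                            k = 5L, seed = 1L, normal_class = "NORMAL",
                            abnormal_classes = c("CNV", "DME", "DRUSEN")) {
  if (inherits(images, "oct_image_set")) {
    labels <- labels %||% images$labels
    imgs <- images$images
  } else imgs <- images
  labels <- as.character(labels)
  classes <- c(normal_class, abnormal_classes)
  plan <- make_folds(labels, k = k, seed = seed, stratified = TRUE)
  lin_spec <- classifier_spec("LR", seed = seed)

  scale_tags <- vapply(pyramid_cfg$scale_list, function(s) as.character(s[1]),
                       character(1))
  rows_cascade <- list(); rows_stage1 <- list(); rows_all4 <- list()
  rows_linear <- list()
  pooled_cascade <- NULL; pooled_all4 <- NULL

  for (f in seq_len(plan$k)) {
    te <- which(plan$assignments == f)
    tr <- setdiff(seq_along(imgs), te)

    ae <- train_ae(build_ae(ae_cfg), imgs[tr])$ae
    pyr <- build_pyramid(pyramid_cfg)
    ft_tr <- feature_table(imgs[tr], ae, pyr, per_scale = TRUE)
    ft_te <- feature_table(imgs[te], ae, pyr, per_scale = TRUE)

    cascade <- train_cascade(ft_tr$fused, labels[tr], spec, normal_class,
                             abnormal_classes)
    all4 <- train_all_at_once(ft_tr$fused, labels[tr], spec, classes)

    det <- predict_cascade(cascade, ft_te$fused, detail = TRUE)
    cm_c <- confusion_matrix(labels[te], as.character(det$labels), classes)
    pooled_cascade <- if (is.null(pooled_cascade)) cm_c$counts
                      else pooled_cascade + cm_c$counts
    rows_cascade[[f]] <- as.data.frame(as.list(multiclass_metrics(cm_c)))

    y1 <- ifelse(labels[te] == normal_class, "NORMAL", "ABNORMAL")
    cm1 <- confusion_matrix(y1, ifelse(as.character(det$labels) == normal_class,
                                       "NORMAL", "ABNORMAL"),
                            c("NORMAL", "ABNORMAL"))
    m1 <- as.list(binary_metrics(cm1, "ABNORMAL"))
    m1$auc <- roc_auc(det$stage1_score, y1 == "ABNORMAL", positive = "TRUE")
    rows_stage1[[f]] <- as.data.frame(m1)

    p4 <- predict_head(all4, ft_te$fused)
    cm4 <- confusion_matrix(labels[te], as.character(p4), classes)
    pooled_all4 <- if (is.null(pooled_all4)) cm4$counts
                   else pooled_all4 + cm4$counts
    m4 <- as.list(multiclass_metrics(cm4))
    m4$auc <- roc_auc_ovr(score_head(all4, ft_te$fused), labels[te])
    rows_all4[[f]] <- as.data.frame(m4)

    acc_of <- function(Xtr, Xte) {
      h <- train_head(Xtr, factor(labels[tr], classes), lin_spec)
      mean(as.character(predict_head(h, Xte)) == labels[te])
    }
    lin <- c(fused = acc_of(ft_tr$fused, ft_te$fused),
             vapply(scale_tags, function(tag)
               acc_of(ft_tr$per_scale[[tag]], ft_te$per_scale[[tag]]),
               numeric(1)))
    rows_linear[[f]] <- as.data.frame(as.list(lin))
  }

  agg <- function(rows, pooled = NULL, order = NULL) {
    pf <- do.call(rbind, rows)
    out <- list(per_fold = pf, mean = colMeans(pf, na.rm = TRUE),
                sd = apply(pf, 2L, stats::sd, na.rm = TRUE), k = plan$k,
                seed = plan$seed)
    if (!is.null(pooled))
      out$pooled_confusion <- structure(list(counts = pooled,
                                             class_order = order),
                                        class = "oct_confusion")
    structure(out, class = "oct_metrics_report")
  }
  structure(list(cascade = agg(rows_cascade, pooled_cascade, classes),
                 stage1 = agg(rows_stage1),
                 all_at_once = agg(rows_all4, pooled_all4, classes),
                 linear = agg(rows_linear),
                 classes = classes, plan = plan),
            class = "oct_pipeline_report")
}

#' @export
print.oct_pipeline_report <- function(x, ...) {
  cat("== cascaded (stage 1 + stage 2) four-class output ==\n")
  print(x$cascade)
  cat("== stage 1: normal vs abnormal ==\n")
  print(x$stage1)
  cat("== all-at-once four-class ==\n")
  print(x$all_at_once)
  cat("== linear probes (accuracy) ==\n")
  print(x$linear)
  invisible(x)
}
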