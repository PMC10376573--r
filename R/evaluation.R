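#' Confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors; every label must be in
#'   `class_order`.
#' @param class_order the label set defining row/column order.
#' @return an `oct_confusion`: list with `counts` (square matrix,
#'   `counts[i, j]` = number of samples with true class i predicted j) and
#'   `class_order`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_order) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(y_true, class_order), factor(y_pred, class_order))
  counts <- matrix(as.integer(counts), nrow = length(class_order),
                   dimnames = list(true = class_order, pred = class_order))
  structure(list(counts = counts, class_order = class_order),
            class = "oct_confusion")
}

#' Accuracy, sensitivity and specificity of a binary confusion matrix
#'
#' `Acc = (TN + TP) / (TN + TP + FN + FP)`, `Sen = TP / (TP + FN)`,
#' `Spc = TN / (TN + FP)`. Cells whose denominator is zero yield `NA` (an
#' explicit undefined marker), never silently 0.
#'
#' @param cm an `oct_confusion` over exactly two classes.
#' @param positive_class which class is "positive" (TP-defining).
#' @return named numeric: `acc`, `sen`, `spc` in `[0, 1]` (or `NA`).
#' @export
binary_metrics <- function(cm, positive_class) {
  stopifnot(inherits(cm, "oct_confusion"))
  if (length(cm$class_order) != 2L)
    stop("binary_metrics requires a 2x2 confusion matrix")
  pos <- positive_class
  neg <- setdiff(cm$class_order, pos)
  if (length(neg) != 1L) stop("positive_class not in class_order")
  TP <- cm$counts[pos, pos]; FN <- cm$counts[pos, neg]
  FP <- cm$counts[neg, pos]; TN <- cm$counts[neg, neg]
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  c(acc = sdiv(TN + TP, TN + TP + FN + FP),
    sen = sdiv(TP, TP + FN),
    spc = sdiv(TN, TN + FP))
}

#' Macro-averaged multiclass metrics
#'
#' Accuracy is `trace / total`; sensitivity and specificity are unweighted
#' means of the per-class one-vs-rest binary values, with undefined
#' (zero-denominator) classes excluded from the average.
#'
#' @param cm an `oct_confusion` with >= 2 classes.
#' @return named numeric: `acc`, `sen`, `spc`.
#' @export
multiclass_metrics <- function(cm) {
  stopifnot(inherits(cm, "oct_confusion"))
  C <- cm$counts
  if (nrow(C) < 2L) stop("need at least 2 classes")
  total <- sum(C)
  acc <- if (total == 0) NA_real_ else sum(diag(C)) / total
  per <- vapply(seq_len(nrow(C)), function(i) {
    TP <- C[i, i]; FN <- sum(C[i, -i]); FP <- sum(C[-i, i])
    TN <- total - TP - FN - FP
    c(sen = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
      spc = if (TN + FP == 0) NA_real_ else TN / (TN + FP))
  }, numeric(2))
  c(acc = acc, sen = mean(per["sen", ], na.rm = TRUE),
    spc = mean(per["spc", ], na.rm = TRUE))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic with midranks for ties:
#' the probability that a random positive scores above a random negative
#' (ties counted half).
#'
#' @param scores numeric scores (larger = more positive). For the
#'   multiclass variant see [roc_auc_ovr()].
#' @param labels binary labels.
#' @param positive which label is positive; default the larger of the two
#'   label values.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) < 2L) stop("both classes must be present to compute AUC")
  if (length(u) > 2L) stop("roc_auc is binary; use roc_auc_ovr for multiclass")
  pos <- positive %||% u[2L]
  is_pos <- labels == pos
  r <- rank(scores)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest macro AUC
#'
#' The unweighted mean over classes of the binary AUC of "this class vs all
#' others", using the per-class score columns.
#'
#' @param score_matrix n x K matrix with `colnames` = class labels.
#' @param labels length-n true labels.
#' @return macro-averaged AUC.
#' @export
roc_auc_ovr <- function(score_matrix, labels) {
  classes <- colnames(score_matrix)
  if (is.null(classes)) stop("score_matrix must have class colnames")
  present <- intersect(classes, unique(as.character(labels)))
  mean(vapply(present, function(cl)
    roc_auc(score_matrix[, cl], labels == cl, positive = "TRUE"),
    numeric(1)))
}

#' Stratified fold plan for k-fold cross-validation
#'
#' Each sample is assigned to exactly one of `k` folds. With
#' `stratified = TRUE` the per-class counts across folds differ by at most
#' one. Deterministic under `seed`.
#'
#' @param labels sample labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified stratify by class?
#' @return an `oct_fold_plan`: list with `assignments` (fold index per
#'   sample), `k`, `seed`, `stratified`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L, stratified = TRUE) {
  k <- as.integer(k)
  n <- length(labels)
  if (n < k) stop("need at least k samples")
  assignments <- integer(n)
  with_seed(seed, {
    if (stratified) {
      classes <- unique(as.character(labels))
      small <- classes[vapply(classes, function(cl)
        sum(labels == cl) < k, logical(1))]
      if (length(small))
        stop("class(es) smaller than k under stratification: ",
             paste(small, collapse = ", "))
      for (ci in seq_along(classes)) {
        idx <- sample(which(labels == classes[ci]))
        assignments[idx] <- as.integer(((seq_along(idx) - 1L + ci) %% k) + 1L)
      }
    } else {
      assignments <- as.integer(sample(rep_len(seq_len(k), n)))
    }
  })
  structure(list(assignments = assignments, k = as.integer(k),
                 seed = as.integer(seed), stratified = stratified),
            class = "oct_fold_plan")
}

subset_x <- function(x, idx) {
  if (is.matrix(x) || is.data.frame(x)) x[idx, , drop = FALSE]
  else if (inherits(x, "oct_image_set")) {
    x$images <- x$images[idx]; x$labels <- x$labels[idx]; x
  } else x[idx]
}

#' Cross-validate a pipeline
#'
#' For each fold, the factory's `fit` is called on the training split only
#' and its `predict` (and optional `score`) on the held-out split — no
#' test-fold sample influences any fitted component. Per-fold confusion
#' matrices and metrics are aggregated into a report.
#'
#' @param factory list with `fit(x, labels) -> model`,
#'   `predict(model, x) -> labels`, and optionally
#'   `score(model, x) -> matrix` (class-named columns, for AUC).
#' @param dataset list with `x` (matrix rows, list elements, or an
#'   `oct_image_set`) and `labels`.
#' @param plan an [make_folds()] plan covering the dataset.
#' @param class_order label order for confusion matrices (default: sorted
#'   unique labels).
#' @param positive_class positive class for binary metrics (default: second
#'   entry of `class_order`).
#' @return an `oct_metrics_report`: `per_fold` (data.frame of acc/sen/spc
#'   and auc when scores are available), `mean`, `sd`, `pooled_confusion`,
#'   `k`, `seed`.
#' @export
cross_validate <- function(factory, dataset, plan, class_order = NULL,
                           positive_class = NULL) {
  stopifnot(inherits(plan, "oct_fold_plan"))
  labels <- as.character(dataset$labels)
  n <- length(labels)
  if (length(plan$assignments) != n)
    stop("fold plan does not match the dataset size")
  class_order <- class_order %||% sort(unique(labels))
  binary <- length(class_order) == 2L
  if (binary) positive_class <- positive_class %||% class_order[2L]

  fold_rows <- list(); pooled <- NULL
  for (f in seq_len(plan$k)) {
    te <- which(plan$assignments == f)
    tr <- setdiff(seq_len(n), te)
    model <- factory$fit(subset_x(dataset$x, tr), labels[tr])
    pred <- as.character(factory$predict(model, subset_x(dataset$x, te)))
    cm <- confusion_matrix(labels[te], pred, class_order)
    pooled <- if (is.null(pooled)) cm$counts else pooled + cm$counts
    m <- if (binary) binary_metrics(cm, positive_class)
         else multiclass_metrics(cm)
    row <- as.list(m)
    if (!is.null(factory$score)) {
      S <- factory$score(model, subset_x(dataset$x, te))
      row$auc <- if (binary)
        roc_auc(S[, positive_class], labels[te] == positive_class,
                positive = "TRUE")
      else roc_auc_ovr(S, labels[te])
    }
    fold_rows[[f]] <- as.data.frame(row)
  }
  per_fold <- do.call(rbind, fold_rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold, na.rm = TRUE),
                 sd = apply(per_fold, 2L, stats::sd, na.rm = TRUE),
                 pooled_confusion = structure(
                   list(counts = pooled, class_order = class_order),
                   class = "oct_confusion"),
                 k = plan$k, seed = plan$seed),
            class = "oct_metrics_report")
}

#' @export
print.oct_metrics_report <- function(x, ...) {
  cat("<oct_metrics_report>", x$k, "folds (seed", paste0(x$seed, ")\n"))
  agg <- rbind(mean = x$mean, sd = x$sd)
  print(round(agg, 4))
  invisible(x)
}

#' Paired Student's t-test on per-fold metrics
#'
#' Two-sided test on the fold-wise differences, with `n - 1` degrees of
#' freedom. If every difference is identical (zero variance) the test is
#' degenerate and `t`/`p` are returned as `NA` with `degenerate = TRUE`.
#'
#' @param metric_a,metric_b equal-length (>= 2) per-fold metric vectors.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_ttest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 2L)
    stop("need two equal-length vectors with at least 2 folds")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                degenerate = TRUE))
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Write a metrics report as JSON
#'
#' @param report an `oct_metrics_report` (or any list of reports).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "oct_confusion"))
      return(list(counts = as.data.frame.matrix(x$counts),
                  class_order = x$class_order))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
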