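#' Classifier specification
#'
#' Describes one of the six pluggable classifier families used by the
#' cascade heads, with the conventional defaults: SVM (RBF kernel,
#' one-vs-rest decision function), decision tree (gini criterion, best
#' splitter), random forest (gini, 100 estimators), Gaussian naive Bayes
#' (priors estimated from data, variance smoothing 1e-9), logistic
#' regression (L2-regularized, liblinear-style `C = 1`), and a multilayer
#' perceptron (two rectifier hidden layers of 256 and 128 units, 40%
#' dropout, adaptive-moment optimizer with initial learning rate 0.001
#' reduced on plateau, 50 epochs, batch size 128).
#'
#' @param kind one of `"MLP"`, `"LR"`, `"SVM"`, `"DT"`, `"RF"`, `"NB"`.
#' @param seed integer; all stochastic kinds (MLP, RF, SVM probability
#'   calibration) are reproducible under it.
#' @param ... overrides of the kind's hyperparameters (see Details).
#' @details Hyperparameters by kind: MLP — `hidden` (c(256, 128)), `dropout`
#'   (0.4), `epochs` (50), `batch_size` (128), `learning_rate` (0.001),
#'   `plateau_factor` (0.1), `plateau_patience` (5); LR — `C` (1); SVM —
#'   `cost` (1), `gamma` (`"scale"`); DT — `criterion` (`"gini"`); RF —
#'   `n_estimators` (100); NB — `var_smoothing` (1e-9). Features are
#'   standardized (training-set mean/variance) for MLP, LR and SVM; DT, RF
#'   and NB see the raw features.
#' @return an object of class `oct_classifier_spec`.
#' @export
classifier_spec <- function(kind, seed = 1L, ...) {
  kind <- toupper(kind)
  defaults <- switch(kind,
    MLP = list(hidden = c(256L, 128L), dropout = 0.4, epochs = 50L,
               batch_size = 128L, learning_rate = 1e-3,
               plateau_factor = 0.1, plateau_patience = 5L),
    LR  = list(C = 1),
    SVM = list(kernel = "rbf", decision_function = "ovr", cost = 1,
               gamma = "scale"),
    DT  = list(criterion = "gini", splitter = "best"),
    RF  = list(criterion = "gini", n_estimators = 100L),
    NB  = list(priors = NULL, var_smoothing = 1e-9),
    stop("unknown classifier kind: ", kind))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "oct_classifier_spec")
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}
standardize_apply <- function(X, sc)
  sweep(sweep(X, 2L, sc$mean, "-"), 2L, sc$sd, "/")

# ---- multilayer perceptron (matrix implementation) -------------------------

mlp_init <- function(dims, seed) {
  with_seed(seed, lapply(seq_len(length(dims) - 1L), function(i)
    list(W = matrix(rnorm(dims[i] * dims[i + 1L], sd = sqrt(2 / dims[i])),
                    dims[i], dims[i + 1L]),
         b = numeric(dims[i + 1L]))))
}

mlp_forward <- function(layers, X, dropout = 0, train = FALSE) {
  acts <- list(X)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- acts[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    if (i < nl) {
      A <- pmax(Z, 0)
      if (train && dropout > 0) {
        mask <- matrix(runif(length(A)) >= dropout, nrow(A), ncol(A)) / (1 - dropout)
        A <- A * mask
      }
      acts[[i + 1L]] <- A
    } else acts[[i + 1L]] <- Z
  }
  acts
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

fit_mlp <- function(X, y, classes, hp, seed) {
  n <- nrow(X); K <- length(classes)
  binary <- K == 2L
  out_dim <- if (binary) 1L else K
  layers <- mlp_init(c(ncol(X), hp$hidden, out_dim), seed)
  Y <- if (binary) matrix(as.numeric(y == classes[2L]), ncol = 1L) else {
    M <- matrix(0, n, K); M[cbind(seq_len(n), match(y, classes))] <- 1; M
  }
  lr <- hp$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  ms <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  vs <- ms
  best_loss <- Inf; wait <- 0L
  with_seed(seed + 1L, {
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[start:min(start + hp$batch_size - 1L, n)]
        acts <- mlp_forward(layers, X[idx, , drop = FALSE], hp$dropout, TRUE)
        Z <- acts[[length(acts)]]
        if (binary) {
          P <- 1 / (1 + exp(-Z))
          ep_loss <- ep_loss - mean(Y[idx, ] * log(P + 1e-12) +
                                    (1 - Y[idx, ]) * log(1 - P + 1e-12))
          dZ <- (P - Y[idx, , drop = FALSE]) / length(idx)
        } else {
          P <- softmax_rows(Z)
          ep_loss <- ep_loss - mean(log(P[cbind(seq_along(idx),
                                                match(y[idx], classes))] + 1e-12))
          dZ <- (P - Y[idx, , drop = FALSE]) / length(idx)
        }
        nb <- nb + 1
        grads <- vector("list", length(layers))
        d <- dZ
        for (i in rev(seq_along(layers))) {
          grads[[i]] <- list(W = crossprod(acts[[i]], d), b = colSums(d))
          if (i > 1L) d <- (d %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
        }
        t <- t + 1
        corr <- sqrt(1 - b2^t) / (1 - b1^t)
        for (i in seq_along(layers)) {
          for (f in c("W", "b")) {
            ms[[i]][[f]] <- b1 * ms[[i]][[f]] + (1 - b1) * grads[[i]][[f]]
            vs[[i]][[f]] <- b2 * vs[[i]][[f]] + (1 - b2) * grads[[i]][[f]]^2
            layers[[i]][[f]] <- layers[[i]][[f]] -
              lr * corr * ms[[i]][[f]] / (sqrt(vs[[i]][[f]]) + eps)
          }
        }
      }
      ep_loss <- ep_loss / nb
      if (ep_loss < best_loss - 1e-8) { best_loss <- ep_loss; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= hp$plateau_patience) { lr <- lr * hp$plateau_factor; wait <- 0L }
      }
    }
  })
  list(layers = layers, classes = classes, binary = binary)
}

mlp_scores <- function(model, X) {
  acts <- mlp_forward(model$layers, X)
  Z <- acts[[length(acts)]]
  if (model$binary) {
    p <- 1 / (1 + exp(-Z[, 1L]))
    cbind(1 - p, p)
  } else softmax_rows(Z)
}

# ---- Gaussian naive Bayes ---------------------------------------------------

fit_gnb <- function(X, y, classes, var_smoothing, priors = NULL) {
  mu <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                 numeric(ncol(X))))
  va <- t(vapply(classes, function(cl) {
    xc <- X[y == cl, , drop = FALSE]
    colMeans(sweep(xc, 2L, colMeans(xc))^2)
  }, numeric(ncol(X))))
  global_var <- colMeans(sweep(X, 2L, colMeans(X))^2)
  va <- va + var_smoothing * max(global_var, 1e-300)
  pri <- priors %||% as.numeric(table(factor(y, classes)) / length(y))
  list(mu = mu, va = va, log_prior = log(pri), classes = classes)
}

gnb_scores <- function(model, X) {
  K <- length(model$classes)
  LL <- vapply(seq_len(K), function(k) {
    m <- model$mu[k, ]; v <- model$va[k, ]
    rowSums(sweep(-0.5 * sweep(X, 2L, m)^2, 2L, v, "/")) -
      0.5 * sum(log(2 * pi * v)) + model$log_prior[k]
  }, numeric(nrow(X)))
  LL <- LL - apply(LL, 1L, max)
  E <- exp(LL)
  E / rowSums(E)
}

# ---- generic head -----------------------------------------------------------

#' Train a classifier head
#'
#' Fits one classifier of the given spec on a feature matrix. Used
#' internally by [train_stage1()], [train_stage2()] and
#' [train_all_at_once()], and exported for direct use (e.g. single-scale
#' ablations).
#'
#' @param X numeric n x d feature matrix.
#' @param y labels (coerced to factor; its levels fix the class order).
#' @param spec an [classifier_spec()].
#' @return an `oct_head` with `predict`/`score` support via
#'   [predict_head()] and [score_head()].
#' @export
train_head <- function(X, y, spec) {
  stopifnot(inherits(spec, "oct_classifier_spec"))
  X <- as.matrix(X)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) stop("training requires at least two classes")
  cnt <- table(y)
  if (any(cnt < 2L))
    stop("need >= 2 samples per class; too few of: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  hp <- spec$hyperparameters
  scaler <- NULL
  if (spec$kind %in% c("MLP", "LR", "SVM")) {
    scaler <- standardize_fit(X)
    X <- standardize_apply(X, scaler)
  }
  fit <- switch(spec$kind,
    MLP = fit_mlp(X, y, classes, hp, spec$seed),
    LR = {
      lam <- 1 / (hp$C * length(y))
      fam <- if (length(classes) == 2L) "binomial" else "multinomial"
      with_seed(spec$seed,
        glmnet::glmnet(X, y, family = fam, alpha = 0, lambda = lam,
                       standardize = FALSE))
    },
    SVM = with_seed(spec$seed, {
      # one-vs-rest ensemble of RBF SVMs, per the OVR decision function
      lapply(classes, function(cl) {
        yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("rest", "pos"))
        e1071::svm(X, yy, kernel = "radial", cost = hp$cost,
                   gamma = if (identical(hp$gamma, "scale"))
                     1 / (ncol(X) * max(mean(apply(X, 2, stats::var)), 1e-12))
                   else hp$gamma,
                   probability = FALSE)
      })
    }),
    DT = {
      df <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(minsplit = 2, cp = 0,
                                                  xval = 0))
    },
    RF = with_seed(spec$seed,
      randomForest::randomForest(X, y, ntree = hp$n_estimators)),
    NB = fit_gnb(X, y, classes, hp$var_smoothing, hp$priors))
  structure(list(kind = spec$kind, spec = spec, classes = classes,
                 scaler = scaler, n_features = ncol(X), fit = fit),
            class = "oct_head")
}

check_feature_dim <- function(head, X) {
  if (ncol(X) != head$n_features)
    stop("feature length mismatch: head expects ", head$n_features,
         ", got ", ncol(X))
}

#' Per-class scores of a trained head
#'
#' For the probabilistic kinds (MLP, LR, RF, NB) the rows are probability
#' distributions over the head's classes (nonnegative, summing to 1). For
#' SVM the rows are softmax-normalized one-vs-rest decision values
#' (monotone in the decision function but not calibrated probabilities).
#' For DT the rows are the training-label proportions of the reached leaf.
#'
#' @param head an `oct_head`.
#' @param X feature matrix (rows = samples).
#' @return n x K matrix with `colnames = head$classes`.
#' @export
score_head <- function(head, X) {
  X <- as.matrix(X)
  if (!is.null(head$scaler)) {
    check_feature_dim(head, X)
    X <- standardize_apply(X, head$scaler)
  } else check_feature_dim(head, X)
  S <- switch(head$kind,
    MLP = mlp_scores(head$fit, X),
    LR = {
      p <- predict(head$fit, newx = X, type = "response")
      if (length(head$classes) == 2L) cbind(1 - p[, 1L], p[, 1L])
      else p[, , 1L][, head$classes, drop = FALSE]
    },
    SVM = {
      dv <- vapply(head$fit, function(m) {
        pr <- predict(m, X, decision.values = TRUE)
        d <- attr(pr, "decision.values")
        # orient so larger = more "pos"
        if (grepl("^pos/", colnames(d)[1])) d[, 1L] else -d[, 1L]
      }, numeric(nrow(X)))
      if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1L)
      softmax_rows(dv)
    },
    DT = {
      p <- predict(head$fit, data.frame(X), type = "prob")
      p[, head$classes, drop = FALSE]
    },
    RF = {
      p <- predict(head$fit, X, type = "prob")
      p[, head$classes, drop = FALSE]
    },
    NB = gnb_scores(head$fit, X))
  S <- as.matrix(S)
  colnames(S) <- head$classes
  rownames(S) <- NULL
  S
}

#' Predict class labels with a trained head
#'
#' The argmax of [score_head()]; ties break to the lowest class index
#' (the head's class order), deterministically.
#'
#' @inheritParams score_head
#' @return factor of length n with levels `head$classes`.
#' @export
predict_head <- function(head, X) {
  S <- score_head(head, X)
  factor(head$classes[max.col(S, ties.method = "first")],
         levels = head$classes)
}

# ---- cascade ----------------------------------------------------------------

#' Train the stage-1 (normal vs. abnormal) head
#'
#' Maps the four-class labels to `NORMAL` vs `ABNORMAL` (everything else)
#' and fits a binary head. The head's abnormal score drives the cascade
#' gate and the stage-1 ROC.
#'
#' @param X feature matrix.
#' @param labels four-class labels.
#' @param spec an [classifier_spec()].
#' @param normal_class label treated as normal (default `"NORMAL"`).
#' @return a binary `oct_head` with classes `(NORMAL, ABNORMAL)`.
#' @export
train_stage1 <- function(X, labels, spec, normal_class = "NORMAL") {
  y <- factor(ifelse(labels == normal_class, "NORMAL", "ABNORMAL"),
              levels = c("NORMAL", "ABNORMAL"))
  if (nlevels(droplevels(y)) < 2L)
    stop("stage 1 needs both normal and abnormal samples")
  train_head(X, y, spec)
}

#' Train the stage-2 (disease subtype) head
#'
#' Fits a three-class head on the abnormal samples only.
#'
#' @inheritParams train_stage1
#' @param classes the abnormal class set, in tie-break order
#'   (default CNV, DME, DRUSEN).
#' @return an `oct_head` over `classes`.
#' @export
train_stage2 <- function(X, labels, spec,
                         classes = c("CNV", "DME", "DRUSEN")) {
  keep <- labels %in% classes
  X <- as.matrix(X)[keep, , drop = FALSE]
  y <- factor(labels[keep], levels = classes)
  absent <- classes[!classes %in% y]
  if (length(absent))
    stop("missing abnormal class(es): ", paste(absent, collapse = ", "))
  train_head(X, y, spec)
}

#' Train the all-at-once four-class head
#'
#' @inheritParams train_stage1
#' @param classes full class order (tie-break order).
#' @return an `oct_head` over all four classes.
#' @export
train_all_at_once <- function(X, labels, spec,
                              classes = c("NORMAL", "CNV", "DME", "DRUSEN")) {
  y <- factor(labels, levels = classes)
  absent <- classes[!classes %in% y]
  if (length(absent))
    stop("missing class(es): ", paste(absent, collapse = ", "))
  train_head(X, y, spec)
}

#' Train the two-stage diagnostic cascade
#'
#' Stage 1 separates normal from abnormal; abnormal samples are passed to
#' stage 2, which differentiates the disease subtypes.
#'
#' @inheritParams train_stage1
#' @param abnormal_classes stage-2 class set in tie-break order.
#' @param threshold stage-1 decision threshold on the abnormal score.
#' @return an `oct_cascade` model.
#' @export
train_cascade <- function(X, labels, spec, normal_class = "NORMAL",
                          abnormal_classes = c("CNV", "DME", "DRUSEN"),
                          threshold = 0.5) {
  structure(list(stage1 = train_stage1(X, labels, spec, normal_class),
                 stage2 = train_stage2(X, labels, spec, abnormal_classes),
                 normal_class = normal_class,
                 abnormal_classes = abnormal_classes,
                 threshold = threshold, spec = spec),
            class = "oct_cascade")
}

#' Predict with the cascade
#'
#' A sample is labeled `NORMAL` iff its stage-1 abnormal score is below the
#' threshold; otherwise it receives stage 2's argmax class (ties break to
#' the lowest class index in `abnormal_classes`). No sample gated as normal
#' can ever receive a disease label.
#'
#' @param model an `oct_cascade`.
#' @param X feature matrix.
#' @param threshold optional override of the model's stage-1 threshold.
#' @param detail if TRUE, also return the stage-1 abnormal score and the
#'   stage-2 score matrix.
#' @return factor of predicted labels (levels: normal class then abnormal
#'   classes), or a list when `detail = TRUE`.
#' @export
predict_cascade <- function(model, X, threshold = NULL, detail = FALSE) {
  stopifnot(inherits(model, "oct_cascade"))
  thr <- threshold %||% model$threshold
  X <- as.matrix(X)
  s1 <- score_head(model$stage1, X)[, "ABNORMAL"]
  lv <- c(model$normal_class, model$abnormal_classes)
  pred <- factor(rep(model$normal_class, nrow(X)), levels = lv)
  abn <- s1 >= thr
  s2 <- NULL
  if (any(abn)) {
    s2 <- score_head(model$stage2, X[abn, , drop = FALSE])
    pred[abn] <- factor(model$abnormal_classes[
      max.col(s2, ties.method = "first")], levels = lv)
  }
  if (detail) list(labels = pred, stage1_score = s1, stage2_scores = s2)
  else pred
}
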