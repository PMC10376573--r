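test_that("confusion matrices count exactly", {
  cm <- confusion_matrix(c("N", "N", "A", "A"), c("N", "A", "A", "A"),
                         c("N", "A"))
  expect_identical(cm$counts["N", "N"], 1L)
  expect_identical(cm$counts["N", "A"], 1L)
  expect_identical(cm$counts["A", "A"], 2L)
  expect_identical(cm$counts["A", "N"], 0L)

  perfect <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"),
                              c("A", "B", "C"))
  expect_true(all(perfect$counts[upper.tri(perfect$counts)] == 0))
  expect_identical(sum(perfect$counts), 3L)

  empty <- confusion_matrix(character(0), character(0), c("A", "B"))
  expect_identical(sum(empty$counts), 0L)
  expect_error(confusion_matrix("A", "Z", c("A", "B")), "Z")
  expect_error(confusion_matrix(c("A", "A"), "A", c("A", "B")), "length")
})

test_that("binary metrics implement the Acc/Sen/Spc formulas", {
  mk <- function(TP, FN, FP, TN) {
    counts <- matrix(as.integer(c(TP, FP, FN, TN)), 2,
                     dimnames = list(true = c("pos", "neg"),
                                     pred = c("pos", "neg")))
    structure(list(counts = counts, class_order = c("pos", "neg")),
              class = "oct_confusion")
  }
  expect_equal(binary_metrics(mk(1, 0, 0, 1), "pos"),
               c(acc = 1, sen = 1, spc = 1))
  m <- binary_metrics(mk(95, 5, 10, 90), "pos")
  expect_equal(m, c(acc = 0.925, sen = 0.95, spc = 0.90))
  # zero-denominator cells are an explicit undefined marker
  m0 <- binary_metrics(mk(0, 0, 10, 90), "pos")
  expect_true(is.na(m0["sen"]))
  expect_false(is.na(m0["spc"]))
  expect_error(binary_metrics(structure(list(counts = diag(3),
                                             class_order = c("a", "b", "c")),
                                        class = "oct_confusion"), "a"),
               "2x2")

  # oracle: 300 random 2x2 matrices against the direct formulas
  set.seed(20)
  for (i in 1:300) {
    v <- rpois(4, 5)   # TP FN FP TN
    m <- binary_metrics(mk(v[1], v[2], v[3], v[4]), "pos")
    expect_identical(unname(m["acc"]), (v[1] + v[4]) / sum(v))
    if (v[1] + v[2] > 0) expect_identical(unname(m["sen"]), v[1] / (v[1] + v[2]))
    if (v[3] + v[4] > 0) expect_identical(unname(m["spc"]), v[4] / (v[3] + v[4]))
  }
})

test_that("multiclass metrics macro-average one-vs-rest expansions", {
  counts <- matrix(as.integer(c(8, 1, 1, 1, 8, 1, 1, 1, 8)), 3, byrow = TRUE,
                   dimnames = list(true = c("a", "b", "c"),
                                   pred = c("a", "b", "c")))
  cm <- structure(list(counts = counts, class_order = c("a", "b", "c")),
                  class = "oct_confusion")
  m <- multiclass_metrics(cm)
  expect_equal(m, c(acc = 0.8, sen = 0.8, spc = 0.9))

  # brute-force OVR oracle on a random matrix
  set.seed(21)
  C <- matrix(rpois(16, 6), 4)
  cm4 <- structure(list(counts = C, class_order = letters[1:4]),
                   class = "oct_confusion")
  per <- sapply(1:4, function(i) {
    TP <- C[i, i]; FN <- sum(C[i, -i]); FP <- sum(C[-i, i])
    TN <- sum(C) - TP - FN - FP
    c(TP / (TP + FN), TN / (TN + FP))
  })
  m4 <- multiclass_metrics(cm4)
  expect_equal(unname(m4["sen"]), mean(per[1, ]))
  expect_equal(unname(m4["spc"]), mean(per[2, ]))
  expect_equal(unname(m4["acc"]), sum(diag(C)) / sum(C))
})

test_that("AUC equals the pairwise-comparison statistic", {
  expect_identical(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = "1"), 1)
  expect_identical(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1),
                           positive = "1"), 0.75)
  expect_error(roc_auc(1:4, rep("a", 4)), "both classes")

  # brute force over all positive-negative pairs, ties counted half
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(22)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y, positive = "1"), brute(s, y), tolerance = 1e-12)
  }

  # null: shuffled labels give AUC near 1/2
  set.seed(23)
  s <- runif(2000); y <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(s, y, positive = "1") - 0.5), 3 * sqrt(1 / 12) / sqrt(1000))

  # one-vs-rest macro average
  S <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  yl <- sample(c("a", "b", "c"), 100, replace = TRUE)
  manual <- mean(sapply(c("a", "b", "c"), function(cl)
    roc_auc(S[, cl], yl == cl, positive = "TRUE")))
  expect_equal(roc_auc_ovr(S, yl), manual)
})

test_that("fold plans partition, stratify and reproduce", {
  y <- rep(c("a", "b", "c", "d"), c(40, 40, 10, 10))
  plan <- make_folds(y, 5, seed = 30)
  expect_identical(sort(unique(plan$assignments)), 1:5)
  expect_length(plan$assignments, 100L)
  tab <- table(y, plan$assignments)
  expect_true(all(tab[c("a", "b"), ] == 8L))
  expect_true(all(tab[c("c", "d"), ] == 2L))
  expect_identical(make_folds(y, 5, seed = 30), plan)
  expect_false(identical(make_folds(y, 5, seed = 31)$assignments,
                         plan$assignments))
  expect_error(make_folds(rep(c("a", "b"), c(20, 3)), 5, seed = 1), "b")
  # unstratified folds still partition into near-equal sizes
  pu <- make_folds(y, 5, seed = 32, stratified = FALSE)
  expect_equal(unname(table(pu$assignments)), rep(20L, 5), ignore_attr = TRUE)
})

test_that("cross-validation keeps the test folds out of fitting", {
  # leakage canary: a memorizing classifier gets perfect training recall but
  # chance-level held-out accuracy on unique random features
  set.seed(33)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3)
  y <- sample(rep(c("a", "b", "c", "d"), n / 4))
  memorizer <- list(
    fit = function(x, labels) list(x = x, labels = labels),
    predict = function(m, x) {
      apply(x, 1, function(row) {
        hit <- which(colSums(abs(t(m$x) - row)) < 1e-12)
        if (length(hit)) m$labels[hit[1]] else "a"
      })
    })
  plan <- make_folds(y, 5, seed = 34)
  rep5 <- cross_validate(memorizer, list(x = X, labels = y), plan,
                         class_order = c("a", "b", "c", "d"))
  expect_identical(nrow(rep5$per_fold), 5L)
  # training recall of the memorizer is trivially 1
  m <- memorizer$fit(X, y)
  expect_identical(mean(memorizer$predict(m, X) == y), 1)
  # held-out accuracy collapses: no memorized row ever matches
  expect_lt(mean(rep5$per_fold$acc), 0.45)
  # aggregate mean equals the arithmetic mean of folds
  expect_equal(unname(rep5$mean["acc"]), mean(rep5$per_fold$acc),
               tolerance = 1e-12)
  expect_error(cross_validate(memorizer, list(x = X, labels = y[-1]),
                              plan), "size|match")
})

test_that("paired t-tests match the closed form and flag degeneracy", {
  a <- c(0.9, 0.92, 0.88, 0.91, 0.9)
  b <- c(0.85, 0.86, 0.84, 0.88, 0.83)
  res <- paired_ttest(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 4), tolerance = 1e-12)
  expect_identical(res$df, 4)
  expect_false(res$degenerate)

  expect_true(paired_ttest(a, a)$degenerate)
  expect_true(paired_ttest(a, a - 1)$degenerate)   # constant difference
  expect_error(paired_ttest(a, b[1:3]), "equal-length")
})
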