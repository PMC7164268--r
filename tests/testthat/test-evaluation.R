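test_that("confusion counts implement the scoped set definitions", {
  # true pairs {P1,P2,P3}; estimated {P1,P2,P4}; P3 is out of scope
  true_keys <- keyset(1, 2, 3)
  est_keys <- keyset(1, 2, 4)
  sc <- fake_scores(est_keys, c(0.9, 0.4, 0.8))
  cc <- confusion_counts(true_keys, est_keys, sc, 0.5)
  expect_equal(cc, list(tp = 1L, fp = 1L, fn = 1L, tn = 0L))
  # threshold 0 calls everything positive
  cc0 <- confusion_counts(true_keys, est_keys, sc, 0)
  expect_equal(cc0$tn + cc0$fn, 0L)
  # perfect estimate, full support
  ccp <- confusion_counts(true_keys, true_keys,
                          fake_scores(true_keys, rep(1, 3)), 1)
  expect_equal(ccp, list(tp = 3L, fp = 0L, fn = 0L, tn = 0L))
  # missing scores are an error
  expect_error(confusion_counts(true_keys, keyset(1, 5), sc, 0.5),
               "missing")
})

test_that("tp+fn and fp+tn are threshold-invariant", {
  set.seed(801)
  est_keys <- keyset(1:40)
  true_keys <- keyset(sample(1:40, 18))
  sc <- fake_scores(est_keys, round(runif(40), 2))
  base <- confusion_counts(true_keys, est_keys, sc, 0)
  for (thr in c(0.2, 0.5, 0.9, 1)) {
    cc <- confusion_counts(true_keys, est_keys, sc, thr)
    expect_equal(cc$tp + cc$fn, base$tp + base$fn)
    expect_equal(cc$fp + cc$tn, base$fp + base$tn)
  }
})

test_that("curves match a brute-force threshold sweep", {
  set.seed(802)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), 1)
    labels <- runif(n) < 0.5
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[n] <- FALSE
    roc <- roc_curve(scores, labels)
    pr <- pr_curve(scores, labels)
    for (r in seq_len(nrow(roc))) {
      t <- roc$threshold[r]
      tp <- sum(labels & scores >= t); fp <- sum(!labels & scores >= t)
      expect_equal(roc$tpr[r], tp / sum(labels))
      expect_equal(roc$fpr[r], fp / sum(!labels))
      expect_equal(pr$recall[r], tp / sum(labels))
      expect_equal(pr$precision[r], if (tp + fp == 0) 1 else tp / (tp + fp))
    }
  }
})

test_that("ROC-AUC equals the Mann-Whitney statistic", {
  set.seed(803)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    labels <- runif(n) < 0.4
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[n] <- FALSE
    expect_equal(roc_auc(scores, labels), oracle_mw_auc(scores, labels))
  }
})

test_that("AUC behaves at the classifier extremes", {
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  perfect <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  expect_equal(roc_auc(perfect, labels), 1)
  expect_equal(pr_auc(perfect, labels), 1)
  roc <- roc_curve(perfect, labels)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  # all scores equal: a single informative point, AUC 1/2
  expect_equal(roc_auc(rep(0.5, 5), labels), 0.5)
  # random scores at large n hover around 1/2
  set.seed(804)
  sc <- runif(20000); lb <- runif(20000) < 0.5
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.05)
})

test_that("a hand-computed trapezoid area is reproduced", {
  # points (0,0) -> (0,0.5) -> (0.5,0.5) -> (0.5,1) -> (1,1):
  # area = 0.5*0.5 + 0.5*1 = 0.75
  scores <- c(0.9, 0.6, 0.4, 0.2)
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  roc <- roc_curve(scores, labels)
  expect_equal(auc(roc$fpr, roc$tpr, "trapezoid"), 0.75)
  expect_equal(roc_auc(scores, labels), oracle_mw_auc(scores, labels))
})

test_that("curves and AUC are invariant under monotone score transforms", {
  set.seed(805)
  scores <- runif(50); labels <- runif(50) < 0.5
  labels[1] <- TRUE; labels[2] <- FALSE
  f <- function(x) x^3 / 2
  expect_equal(roc_auc(f(scores), labels), roc_auc(scores, labels))
  expect_equal(pr_auc(f(scores), labels), pr_auc(scores, labels))
})

test_that("degenerate label sets are reported", {
  expect_error(roc_curve(c(0.5, 0.2), c(FALSE, FALSE)), "positive")
  expect_warning(roc_curve(c(0.5, 0.2), c(TRUE, TRUE)), "degenerate")
})

test_that("pooled and averaged aggregation both summarize multiple runs", {
  set.seed(806)
  runs <- lapply(1:4, function(i) {
    s <- runif(30); l <- runif(30) < 0.5
    l[1] <- TRUE; l[2] <- FALSE
    list(scores = s, labels = l)
  })
  pooled <- aggregate_auc(runs, "pooled", "roc")
  avg <- aggregate_auc(runs, "averaged", "roc")
  expect_true(pooled >= 0 && pooled <= 1)
  expect_equal(avg, mean(vapply(runs, function(r)
    roc_auc(r$scores, r$labels), numeric(1))))
})

test_that("evaluate_support ties alignments, scores and curves together", {
  truth <- make_tiny_msa(c(a = "ACGT", b = "ACGT"))
  est <- truth
  ann <- fake_scores(homology_keys(extract_homologies(est)), rep(1, 4))
  ev <- suppressWarnings(evaluate_support(truth, est, ann))
  expect_equal(ev$pr_auc, 1)
  expect_equal(ev$n_pairs, 4)
})
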