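test_that("confusion counts partition instances and match a loop oracle", {
  set.seed(101)
  scores <- rnorm(40)
  labels <- sample(c("TSS", "FSS"), 40, replace = TRUE)
  # all-positive and all-negative calls
  expect_equal(unname(confusionCounts(scores, labels, -Inf)[c("FN", "TN")]),
               c(0, 0))
  expect_equal(unname(confusionCounts(scores, labels,
                                      max(scores) + 1)[c("TP", "FP")]),
               c(0, 0))
  for (thr in c(-0.5, 0, scores[3])) {
    got <- confusionCounts(scores, labels, thr)
    expect_equal(got, loopConfusion(scores, labels, thr))
    expect_equal(sum(got), 40)
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic, ties included", {
  # perfectly separated
  r <- rocCurve(c(5, 4, 3, 1, 0, -1), rep(c("TSS", "FSS"), each = 3))
  expect_equal(aucRoc(r), 1)
  expect_equal(aucRocSe(r), 0)
  # anti-separated
  expect_equal(aucRoc(rocCurve(c(0, 1, 5, 6),
                               c("TSS", "TSS", "FSS", "FSS"))), 0)
  # 12 hand-listed scores with ties across classes
  sc <- c(3, 2, 2, 1, 0, 3, 2, 1, 1, 0, -1, -2)
  lb <- rep(c("TSS", "FSS"), each = 6)
  expect_equal(aucRoc(rocCurve(sc, lb)), mannWhitneyAuc(sc, lb))
  # arbitrary tie structures on random draws
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(10:30, 1)
    sc <- sample(-3:3, n, replace = TRUE)
    lb <- c("TSS", "FSS", sample(c("TSS", "FSS"), n - 2, replace = TRUE))
    expect_equal(aucRoc(rocCurve(sc, lb)), mannWhitneyAuc(sc, lb))
  }
  expect_error(rocCurve(1:3, rep("TSS", 3)), "both classes")
})

test_that("Hanley-McNeil SE uses Q1, Q2 and vanishes at theta = 1", {
  th <- 0.87; n1 <- 25; n2 <- 40
  q1 <- th / (2 - th); q2 <- 2 * th^2 / (1 + th)
  expect_equal(hanleyMcNeilSe(th, n1, n2),
               sqrt((th * (1 - th) + (n1 - 1) * (q1 - th^2) +
                       (n2 - 1) * (q2 - th^2)) / (n1 * n2)))
  expect_equal(hanleyMcNeilSe(1, 50, 80), 0)
  # continuity: se -> 0 as theta -> 1 at fixed n
  ses <- vapply(c(0.9, 0.99, 0.999, 0.9999),
                hanleyMcNeilSe, numeric(1), nTss = 30, nFss = 30)
  expect_true(all(diff(ses) < 0))
})

test_that("Davis-Goadrich interpolation follows the local skew", {
  mid <- prInterpolate(c(2, 0), c(5, 6), nTss = 5)
  expect_equal(mid$tp, c(3, 4))
  expect_equal(mid$fp, c(2, 4))        # skew (6-0)/(5-2) = 2
  expect_equal(mid$recall, c(3, 4) / 5)
  expect_equal(mid$precision, c(3 / 5, 4 / 8))
  # adjacent counts: no intermediates
  expect_equal(nrow(prInterpolate(c(2, 1), c(3, 4), 5)), 0)
  # zero skew: precision strictly increases along intermediates
  up <- prInterpolate(c(1, 3), c(6, 3), nTss = 6)
  expect_true(all(diff(up$precision) > 0))
  expect_error(prInterpolate(c(5, 2), c(4, 3), 6), "TP_B > TP_A")
})

test_that("PR curve handles perfect, degenerate and brute-force cases", {
  pr <- prCurve(c(5, 4, 3, 1, 0, -1), rep(c("TSS", "FSS"), each = 3))
  expect_equal(aucPr(pr), 1)
  expect_true(all(curvePoints(pr)$precision[
    curvePoints(pr)$recall < 1] == 1))
  # single positive: curve is its achievable points, no intermediates
  pr1 <- prCurve(c(2, 3, 1, 0), c("TSS", "FSS", "FSS", "FSS"))
  expect_true(all(curvePoints(pr1)$tp %in% c(0, 1)))
  # recall non-decreasing along any curve
  set.seed(11)
  sc <- rnorm(15); lb <- c(rep("TSS", 6), rep("FSS", 9))
  prR <- prCurve(sc, lb)
  expect_true(all(diff(curvePoints(prR)$recall) >= 0))
  # achievable vertices agree with a dense-threshold brute force
  dense <- unique(t(vapply(sort(unique(sc), decreasing = TRUE),
    function(c) c(tp = sum(lb == "TSS" & sc >= c),
                  fp = sum(lb == "FSS" & sc >= c)), numeric(2))))
  pts <- curvePoints(prR)
  for (r in seq_len(nrow(dense))) {
    if (dense[r, "tp"] == 0) next
    hit <- pts$tp == dense[r, "tp"] & abs(pts$fp - dense[r, "fp"]) < 1e-9
    expect_true(any(hit))
  }
})

test_that("AUC-ROC is exactly skew-invariant while precision degrades", {
  set.seed(21)
  scP <- rnorm(20, 1); scN <- rnorm(30)
  sc <- c(scP, scN); lb <- rep(c("TSS", "FSS"), c(20, 30))
  m <- 4
  scDup <- c(scP, rep(scN, m)); lbDup <- rep(c("TSS", "FSS"), c(20, 30 * m))
  expect_identical(aucRoc(rocCurve(sc, lb)), aucRoc(rocCurve(scDup, lbDup)))
  # identical ROC vertices too
  expect_equal(curvePoints(rocCurve(sc, lb))[, c("fpr", "tpr")],
               curvePoints(rocCurve(scDup, lbDup))[, c("fpr", "tpr")])
  # PR: precision strictly drops at matching recalls (imperfect scorer)
  p1 <- curvePoints(prCurve(sc, lb))
  pm <- curvePoints(prCurve(scDup, lbDup))
  shared <- intersect(p1$recall, pm$recall)
  maxP1 <- vapply(shared, function(r) max(p1$precision[p1$recall == r]),
                  numeric(1))
  maxPm <- vapply(shared, function(r) max(pm$precision[pm$recall == r]),
                  numeric(1))
  imperfect <- maxP1 < 1            # recalls already costing FPs
  expect_gt(sum(imperfect), 0)
  expect_true(all(maxPm[imperfect] < maxP1[imperfect]))
  expect_gt(aucPr(prCurve(sc, lb)), aucPr(prCurve(scDup, lbDup)))
})

test_that("cross-validation is stratified, deterministic and fold-consistent", {
  tss <- MotifSet(randomMotifs(40, 5, seed = 61,
                               prob = c(0.55, 0.2, 0.15, 0.1)), "TSS")
  fss <- MotifSet(randomMotifs(50, 5, seed = 62), "FSS")
  cv <- crossValidate(tss, fss, k = 5, seed = 3, method = "sae",
                      threshold = 0, pseudocount = 0.5)
  expect_equal(sum(cv$folds$nTss), 40)
  expect_equal(sum(cv$folds$nFss), 50)
  expect_true(all(abs(cv$folds$nTss - 8) <= 1))
  expect_true(all(abs(cv$folds$nFss - 10) <= 1))
  cv2 <- crossValidate(tss, fss, k = 5, seed = 3, method = "sae",
                       threshold = 0, pseudocount = 0.5)
  expect_identical(cv$scores, cv2$scores)
  expect_s4_class(cv$roc, "RocResult")
  expect_s4_class(cv$pr, "PrResult")
  # symmetric two-fold fixture: identical fold metrics
  tssS <- MotifSet(rep(c("AAAA", "AAAT"), 8), "TSS")
  fssS <- MotifSet(rep(c("TTTT", "TTTA"), 8), "FSS")
  cvS <- crossValidate(tssS, fssS, k = 2, seed = 1, threshold = 0,
                       pseudocount = 0.5)
  expect_equal(cvS$folds$sens[1], cvS$folds$sens[2])
  expect_equal(cvS$folds$spec[1], cvS$folds$spec[2])
  # manual two-fold re-run reproduces the pooled scores
  ids <- donorSAE:::.withSeed(7, list(
    tss = donorSAE:::.foldIds(length(tss), 2),
    fss = donorSAE:::.foldIds(length(fss), 2)))
  cvM <- crossValidate(tss, fss, k = 2, seed = 7, pseudocount = 0.5)
  manual <- unlist(lapply(1:2, function(f) {
    clf <- trainSae(MotifSet(motifs(tss)[ids$tss != f], "TSS"),
                    MotifSet(motifs(fss)[ids$fss != f], "FSS"), 0.5)
    saeScore(clf, c(motifs(tss)[ids$tss == f], motifs(fss)[ids$fss == f]))
  }))
  expect_equal(cvM$scores, manual)
})
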