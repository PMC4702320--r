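test_that("conditional tables equal count ratios and normalise", {
  m <- suppressWarnings(fitConditionals(MotifSet("AT")))
  expect_equal(conditionalProb(m, 1, 2, "A", "T"), 1)
  m2 <- suppressWarnings(fitConditionals(MotifSet(c("AT", "GT"))))
  expect_equal(conditionalProb(m2, 1, 2, "A", "T"), 0.5)

  train <- randomMotifs(50, 9, seed = 17)
  mod <- fitConditionals(MotifSet(train))
  for (i in c(1, 4, 9)) for (j in c(2, 5)) for (s in BASES) for (t in BASES)
    expect_equal(conditionalProb(mod, i, j, s, t),
                 bruteConditional(train, i, j, s, t))
  # sum_s p(s_i | t_j) == 1 for every (i, j, t), any alpha
  for (alpha in c(0, 0.7)) {
    mA <- fitConditionals(MotifSet(train), pseudocount = alpha)
    for (i in c(2, 7)) for (j in c(3, 8)) for (t in BASES)
      expect_equal(sum(vapply(BASES, function(s)
        conditionalProb(mA, i, j, s, t), numeric(1))), 1)
  }
})

test_that("undefined conditionals warn at fit and error only when scored", {
  # T never occurs at position 2
  expect_warning(mod <- fitConditionals(MotifSet(c("AA", "AG"))),
                 "pseudocount")
  expect_true(is.nan(conditionalProb(mod, 1, 2, "A", "T")))
  expect_error(saeTotal(mod, "AT"), "pseudocount")
  # p(A1|A2) = 1/1, p(A2|A1) = 1/2
  expect_equal(saeTotal(mod, "AA"), 2 * 2 * 1 - 2 * (1 + 0.5))
  # smoothing defines every cell
  modS <- fitConditionals(MotifSet(c("AA", "AG")), pseudocount = 1)
  expect_equal(conditionalProb(modS, 1, 2, "A", "T"), (0 + 1) / (0 + 4))
  expect_false(anyNA(saeTotal(modS, "AT")))
})

test_that("SAE values match term enumeration and respect bounds", {
  train <- c("ATG", "ATG", "ACG")
  mod <- fitConditionals(MotifSet(train), pseudocount = 0.5)
  expect_equal(saeTotal(mod, "ATG"), bruteSaeTotal(train, "ATG", 0.5))
  expect_equal(saePosition(mod, "ATG", 2),
               2 * sum(1 - c(bruteConditional(train, 2, 1, "T", "A", 0.5),
                             bruteConditional(train, 2, 3, "T", "G", 0.5))))
  # additivity and the two printed forms agree
  perPos <- vapply(1:3, function(i) saePosition(mod, "ATG", i), numeric(1))
  expect_equal(saeTotal(mod, "ATG"), sum(perPos))

  # all conditionals 1 -> 0; bounds on random inputs
  one <- suppressWarnings(fitConditionals(MotifSet(rep("ATG", 4))))
  expect_equal(saeTotal(one, "ATG"), 0)
  P <- 9
  tr <- randomMotifs(40, P, seed = 23)
  modR <- fitConditionals(MotifSet(tr), pseudocount = 0.1)
  vals <- saeTotal(modR, randomMotifs(25, P, seed = 24))
  expect_true(all(vals >= 0 & vals <= 2 * P * (P - 1)))
  for (s in randomMotifs(5, P, seed = 25))
    expect_equal(saeTotal(modR, s), bruteSaeTotal(tr, s, 0.1))
})

test_that("dSAE is the literal SAE difference and is anti-symmetric", {
  tssTr <- randomMotifs(30, 5, seed = 31, prob = c(0.4, 0.3, 0.2, 0.1))
  fssTr <- randomMotifs(30, 5, seed = 32)
  clf <- trainSae(MotifSet(tssTr, "TSS"), MotifSet(fssTr, "FSS"),
                  pseudocount = 0.5)
  test <- randomMotifs(10, 5, seed = 33)
  expect_equal(dsae(clf, test),
               vapply(test, function(s)
                 bruteSaeTotal(tssTr, s, 0.5) - bruteSaeTotal(fssTr, s, 0.5),
                 numeric(1), USE.NAMES = FALSE))
  # identical training sets: dSAE identically 0
  same <- trainSae(MotifSet(tssTr, "TSS"), MotifSet(tssTr, "FSS"), 0.5)
  expect_equal(dsae(same, test), rep(0, 10))
  # swapping the models negates the score exactly
  swapped <- trainSae(MotifSet(fssTr, "TSS"), MotifSet(tssTr, "FSS"), 0.5)
  expect_equal(dsae(swapped, test), -dsae(clf, test))
  expect_equal(saeScore(clf, test), -dsae(clf, test))
})

test_that("the decision rule is strict: dSAE == epsilon goes to FSS", {
  tssTr <- randomMotifs(20, 4, seed = 41, prob = c(0.5, 0.2, 0.2, 0.1))
  fssTr <- randomMotifs(20, 4, seed = 42)
  clf <- trainSae(MotifSet(tssTr, "TSS"), MotifSet(fssTr, "FSS"), 0.5)
  expect_error(predict(clf, "AAAA"), "epsilon")
  probe <- "AAAA"
  epsilon(clf) <- dsae(clf, probe)      # boundary case
  expect_equal(predict(clf, probe)$label, "FSS")
  # identical models give dSAE 0; any negative epsilon calls FSS
  same <- trainSae(MotifSet(tssTr, "TSS"), MotifSet(tssTr, "FSS"), 0.5)
  epsilon(same) <- -1
  expect_equal(predict(same, probe)$label, "FSS")
  # labels consistent with a sign test on (dSAE - epsilon)
  epsilon(clf) <- 0.5
  test <- randomMotifs(30, 4, seed = 43)
  pred <- predict(clf, test)
  expect_equal(pred$label,
               ifelse(dsae(clf, test) - 0.5 < 0, "TSS", "FSS"))
  expect_equal(pred$score, -pred$dsae)
})

test_that("threshold estimation finds the sensitivity=specificity crossing", {
  # symmetric separation: per-fold threshold is the midpoint 0
  tss <- MotifSet(rep("AAAA", 40), "TSS")
  fss <- MotifSet(rep("TTTT", 40), "FSS")
  est <- estimateThreshold(tss, fss, fraction = 1, k = 4, seed = 1,
                           pseudocount = 0.5)
  d <- dsae(trainSae(tss, fss, 0.5), c("AAAA", "TTTT"))
  expect_equal(unname(perFoldThresholds(est)), rep(mean(d), 4))
  expect_equal(epsilon(est), mean(d))

  # reproducibility from the seed
  tssR <- MotifSet(randomMotifs(60, 5, seed = 51,
                                prob = c(0.5, 0.2, 0.2, 0.1)), "TSS")
  fssR <- MotifSet(randomMotifs(60, 5, seed = 52), "FSS")
  e1 <- estimateThreshold(tssR, fssR, k = 5, seed = 9, pseudocount = 0.5)
  e2 <- estimateThreshold(tssR, fssR, k = 5, seed = 9, pseudocount = 0.5)
  expect_identical(perFoldThresholds(e1), perFoldThresholds(e2))

  # class swap negates the dSAE distribution, hence the threshold,
  # when the folds are held fixed
  folds <- list(tss = rep(1:5, length.out = 60),
                fss = rep(1:5, length.out = 60))
  eA <- estimateThreshold(tssR, fssR, k = 5, pseudocount = 0.5,
                          folds = folds)
  eB <- estimateThreshold(fssR, tssR, k = 5, pseudocount = 0.5,
                          folds = folds)
  expect_equal(epsilon(eB), -epsilon(eA), tolerance = 1e-8)
})

test_that("candidate-set sweep agrees with a dense-grid threshold search", {
  tss <- MotifSet(randomMotifs(20, 4, seed = 61,
                               prob = c(0.55, 0.15, 0.2, 0.1)), "TSS")
  fss <- MotifSet(randomMotifs(20, 4, seed = 62), "FSS")
  folds <- list(tss = rep(1:2, 10), fss = rep(1:2, 10))
  est <- estimateThreshold(tss, fss, k = 2, pseudocount = 0.5,
                           folds = folds)
  # fold 1 oracle: fine grid over the dSAE range
  clf <- trainSae(MotifSet(motifs(tss)[folds$tss != 1], "TSS"),
                  MotifSet(motifs(fss)[folds$fss != 1], "FSS"), 0.5)
  dT <- dsae(clf, motifs(tss)[folds$tss == 1])
  dF <- dsae(clf, motifs(fss)[folds$fss == 1])
  gapAt <- function(c) abs(mean(dT <= c) - mean(dF >= c))
  grid <- seq(min(dT, dF) - 1, max(dT, dF) + 1, length.out = 20001)
  gridBest <- min(vapply(grid, gapAt, numeric(1)))
  # explicit-loop re-derivation of the candidate sweep
  v <- sort(unique(c(dT, dF)))
  cand <- sort(c(v, (v[-1] + v[-length(v)]) / 2))
  gaps <- vapply(cand, gapAt, numeric(1))
  expect_equal(min(gaps), gridBest, tolerance = 1e-9)
  expect_equal(perFoldThresholds(est)[1],
               mean(cand[gaps <= min(gaps) + 1e-12]))
})

test_that("model JSON persistence round-trips scores and epsilon", {
  tss <- MotifSet(randomMotifs(25, 5, seed = 71,
                               prob = c(0.5, 0.2, 0.2, 0.1)), "TSS")
  fss <- MotifSet(randomMotifs(25, 5, seed = 72), "FSS")
  clf <- trainSae(tss, fss, pseudocount = 0.5)
  epsilon(clf) <- -2.25
  f <- withr::local_tempfile(fileext = ".json")
  saveSaeModel(clf, f)
  back <- readSaeModel(f)
  test <- randomMotifs(10, 5, seed = 73)
  expect_equal(dsae(back, test), dsae(clf, test))
  expect_equal(epsilon(back), -2.25)
  # an unset threshold survives the round trip as NA, silently
  clfU <- trainSae(tss, fss, pseudocount = 0.5)
  f2 <- withr::local_tempfile(fileext = ".json")
  saveSaeModel(clfU, f2)
  expect_no_warning(backU <- readSaeModel(f2))
  expect_true(is.na(epsilon(backU)))
})
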