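#' Confusion counts at a score threshold
#'
#' TSS is the positive class; an instance is called positive when its
#' score (higher = more TSS-like) is >= the threshold.
#'
#' @param scores numeric scores.
#' @param labels class labels, \code{"TSS"} / \code{"FSS"}.
#' @param threshold positive-call cutoff.
#' @return named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
confusionCounts <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "TSS"
  call <- scores >= threshold
  c(TP = sum(call & pos), FP = sum(call & !pos),
    TN = sum(!call & !pos), FN = sum(!call & pos))
}

## achievable (threshold, TP, FP) path: sweep distinct scores
## descending, ties grouped on a single vertex, (0, 0) prepended
.sweepPath <- function(scores, labels) {
  pos <- labels == "TSS"
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(c) sum(pos & scores >= c), integer(1L))
  fp <- vapply(thr, function(c) sum(!pos & scores >= c), integer(1L))
  data.frame(threshold = c(Inf, thr), tp = c(0L, tp), fp = c(0L, fp))
}

#' ROC curve with trapezoidal AUC and Hanley-McNeil standard error
#'
#' Sweeps every distinct score as a threshold (ties grouped on one
#' vertex), computes the (FPR, TPR) path, the trapezoidal area theta —
#' exactly the normalised Mann-Whitney pairwise statistic with ties
#' counted 1/2 — and its standard error
#' \deqn{SE = \sqrt{(\theta(1-\theta) + (N_{TSS}-1)(Q_1-\theta^2) +
#'   (N_{FSS}-1)(Q_2-\theta^2)) / (N_{TSS} N_{FSS})}}
#' with Q1 = theta/(2-theta), Q2 = 2 theta^2/(1+theta).
#'
#' @param scores numeric scores (higher = more TSS-like).
#' @param labels \code{"TSS"} / \code{"FSS"}; both must be present.
#' @return A \linkS4class{RocResult}.
#' @export
rocCurve <- function(scores, labels) {
  nP <- sum(labels == "TSS"); nN <- sum(labels == "FSS")
  if (nP == 0L || nN == 0L)
    stop("both classes must be present to build an ROC curve")
  path <- .sweepPath(scores, labels)
  pts <- data.frame(threshold = path$threshold,
                    fpr = path$fp / nN, tpr = path$tp / nP)
  theta <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1L) +
                                  utils::tail(pts$tpr, -1L)) / 2)
  new("RocResult", points = pts, theta = theta,
      se = hanleyMcNeilSe(theta, nP, nN),
      nTss = as.integer(nP), nFss = as.integer(nN))
}

#' @rdname rocCurve
#' @param theta AUC-ROC estimate.
#' @param nTss,nFss positive / negative class sizes.
#' @export
hanleyMcNeilSe <- function(theta, nTss, nFss) {
  q1 <- theta / (2 - theta)
  q2 <- 2 * theta^2 / (1 + theta)
  sqrt((theta * (1 - theta) + (nTss - 1) * (q1 - theta^2) +
          (nFss - 1) * (q2 - theta^2)) / (nTss * nFss))
}

#' Accessors for evaluation results
#' @param x a \linkS4class{RocResult} or \linkS4class{PrResult}.
#' @name eval-accessors
#' @aliases aucRoc aucRocSe aucPr curvePoints
NULL

#' @rdname eval-accessors
#' @export
aucRoc <- function(x) x@theta

#' @rdname eval-accessors
#' @export
aucRocSe <- function(x) x@se

#' @rdname eval-accessors
#' @export
aucPr <- function(x) x@aucPr

#' @rdname eval-accessors
#' @export
curvePoints <- function(x) x@points

setMethod("show", "RocResult", function(object) {
  cat(sprintf(
    "RocResult: AUC-ROC = %.4f (SE %.4f), %d TSS vs %d FSS, %d vertices\n",
    object@theta, object@se, object@nTss, object@nFss,
    nrow(object@points)))
})

setMethod("show", "PrResult", function(object) {
  cat(sprintf("PrResult: AUC-PR = %.4f, %d points\n",
              object@aucPr, nrow(object@points)))
})

#' Davis-Goadrich interpolation between two PR-space points
#'
#' Between achievable points A and B (given as TP/FP counts), creates
#' the intermediate points TP_A + 1, ..., TP_B - 1, increasing the
#' false positives linearly by the local skew
#' (FP_B - FP_A) / (TP_B - TP_A), and converts them to
#' (recall, precision) with recall = TP / nTss.
#'
#' @param A,B numeric length-2 vectors \code{c(TP, FP)} with
#'   TP_A <= TP_B (strictly, TP_B > TP_A), FP_A <= FP_B.
#' @param nTss total number of positive instances.
#' @return data.frame with columns \code{tp}, \code{fp},
#'   \code{recall}, \code{precision}; zero rows when TP_B == TP_A + 1.
#' @examples
#' prInterpolate(c(2, 0), c(5, 6), nTss = 5)
#' @export
prInterpolate <- function(A, B, nTss) {
  if (B[1L] <= A[1L] || B[2L] < A[2L])
    stop("need TP_B > TP_A and FP_B >= FP_A")
  skew <- (B[2L] - A[2L]) / (B[1L] - A[1L])
  x <- seq_len(B[1L] - A[1L] - 1L)
  tp <- A[1L] + x
  fp <- A[2L] + x * skew
  data.frame(tp = tp, fp = fp, recall = tp / nTss,
             precision = tp / (tp + fp))
}

#' Precision-recall curve with Davis-Goadrich interpolation
#'
#' Builds the achievable (TP, FP) points from the grouped threshold
#' sweep, inserts Davis-Goadrich intermediates between consecutive
#' points whenever TP increases, and integrates the interpolated curve
#' over recall by trapezoid. The recall-0 anchor takes the limiting
#' precision of the first TP-increasing segment (1/(1 + skew) when
#' that segment starts at the origin), so a perfectly separating
#' scorer attains AUC-PR = 1.
#'
#' @param scores numeric scores (higher = more TSS-like).
#' @param labels \code{"TSS"} / \code{"FSS"}.
#' @return A \linkS4class{PrResult}.
#' @export
prCurve <- function(scores, labels) {
  nP <- sum(labels == "TSS")
  if (nP == 0L || !any(labels == "FSS"))
    stop("both classes must be present to build a PR curve")
  path <- .sweepPath(scores, labels)
  pts <- list()
  for (r in seq_len(nrow(path) - 1L)) {
    A <- c(path$tp[r], path$fp[r])
    B <- c(path$tp[r + 1L], path$fp[r + 1L])
    if (B[1L] > A[1L]) {
      if (is.null(pts[["anchor"]])) {
        ## limiting precision entering this first TP-increasing segment
        skew <- (B[2L] - A[2L]) / (B[1L] - A[1L])
        p0 <- if (A[1L] == 0L && A[2L] == 0L) 1 / (1 + skew)
              else if (A[1L] > 0L) A[1L] / (A[1L] + A[2L])
              else 0
        pts[["anchor"]] <- data.frame(tp = A[1L], fp = A[2L],
                                      recall = A[1L] / nP, precision = p0)
      }
      mid <- prInterpolate(A, B, nP)
      if (nrow(mid)) pts[[length(pts) + 1L]] <- mid
    }
    if (B[1L] > 0L)
      pts[[length(pts) + 1L]] <- data.frame(
        tp = B[1L], fp = B[2L], recall = B[1L] / nP,
        precision = B[1L] / (B[1L] + B[2L]))
  }
  curve <- do.call(rbind, pts)
  rownames(curve) <- NULL
  auc <- sum(diff(curve$recall) *
               (utils::head(curve$precision, -1L) +
                  utils::tail(curve$precision, -1L)) / 2)
  new("PrResult", points = curve, aucPr = auc)
}

#' Stratified k-fold cross-validation of a splice-site scorer
#'
#' Splits each class into k folds of near-equal size, trains the
#' chosen method on k-1 folds and scores the held-out fold, then pools
#' the held-out scores across folds for one overall ROC and PR curve
#' (pooled, not fold-averaged). When a decision threshold is supplied,
#' per-fold sensitivity and specificity at that threshold are reported
#' (for \code{method = "sae"} the threshold is epsilon on the dSAE
#' scale, positives being dSAE < epsilon; for the baselines it is a
#' cutoff on the log-odds score, positives being score >= cutoff).
#'
#' @param tss,fss \linkS4class{MotifSet}s.
#' @param k number of folds (>= 2).
#' @param seed RNG seed for the stratified fold assignment.
#' @param method \code{"sae"}, \code{"wmm"} or \code{"mm1"}.
#' @param threshold optional decision threshold (see above).
#' @param pseudocount smoothing for the fitted models (default 0 for
#'   SAE, 0.5 for the baselines).
#' @return list with \code{folds} (per-fold data.frame),
#'   \code{roc} (\linkS4class{RocResult}),
#'   \code{pr} (\linkS4class{PrResult}), and the pooled
#'   \code{scores} / \code{labels}.
#' @export
crossValidate <- function(tss, fss, k = 10, seed = 1,
                          method = c("sae", "wmm", "mm1"),
                          threshold = NULL, pseudocount = NULL) {
  method <- match.arg(method)
  stopifnot(k >= 2)
  if (is.null(pseudocount))
    pseudocount <- if (method == "sae") 0 else 0.5
  mT <- motifs(tss); mF <- motifs(fss)
  ids <- .withSeed(seed, list(tss = .foldIds(length(mT), k),
                              fss = .foldIds(length(mF), k)))
  scorer <- function(trT, trF, te) {
    switch(method,
      sae = saeScore(trainSae(MotifSet(trT, "TSS"),
                              MotifSet(trF, "FSS"), pseudocount), te),
      wmm = scoreWmm(fitWmm(MotifSet(trT, "TSS"),
                            MotifSet(trF, "FSS"), pseudocount), te),
      mm1 = scoreMm1(fitMm1(MotifSet(trT, "TSS"),
                            MotifSet(trF, "FSS"), pseudocount), te))
  }
  allScores <- numeric(0); allLabels <- character(0)
  folds <- lapply(seq_len(k), function(f) {
    teT <- mT[ids$tss == f]; teF <- mF[ids$fss == f]
    if (!length(teT) || !length(teF))
      stop("fold ", f, " lacks motifs of one class; lower k or reseed")
    sc <- scorer(mT[ids$tss != f], mF[ids$fss != f], c(teT, teF))
    lb <- rep(c("TSS", "FSS"), c(length(teT), length(teF)))
    allScores <<- c(allScores, sc); allLabels <<- c(allLabels, lb)
    sens <- spec <- NA_real_
    if (!is.null(threshold)) {
      posCall <- if (method == "sae") -sc < threshold else sc >= threshold
      sens <- mean(posCall[lb == "TSS"])
      spec <- mean(!posCall[lb == "FSS"])
    }
    data.frame(fold = f, nTss = length(teT), nFss = length(teF),
               sens = sens, spec = spec)
  })
  list(folds = do.call(rbind, folds),
       roc = rocCurve(allScores, allLabels),
       pr = prCurve(allScores, allLabels),
       scores = allScores, labels = allLabels)
}

#' Write ROC / PR curve points as TSV
#'
#' @param x a \linkS4class{RocResult} or \linkS4class{PrResult}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCurve <- function(x, path) {
  utils::write.table(curvePoints(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
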