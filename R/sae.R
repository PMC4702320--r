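#' Fit a class-conditional di-nucleotide probability table
#'
#' Estimates p(s_i | t_j) — the proportion of base s at position i
#' among training motifs carrying base t at position j — for every
#' ordered position pair i != j, as
#' \deqn{p(s_i | t_j) = (n_{ij}(s,t) + \alpha) / (n_j(t) + 4\alpha).}
#' With \code{pseudocount = 0} this is the exact count ratio; cells
#' whose conditioning base was never observed (n_j(t) = 0) are then
#' undefined, stored as NaN with a warning, and raise an error if a
#' motif is later scored through them. Use \code{pseudocount > 0}
#' (Laplace-style) for small training sets.
#'
#' @param x a \linkS4class{MotifSet} (N >= 1) or
#'   \linkS4class{IndicatorCounts}.
#' @param pseudocount smoothing constant alpha >= 0.
#' @param label class label recorded on the model (defaults to the
#'   motif set's label).
#' @return A \linkS4class{ConditionalModel}.
#' @examples
#' m <- fitConditionals(MotifSet(c("AT", "GT"), label = "TSS"))
#' conditionalProb(m, 1, 2, "A", "T")   # 0.5
#' @export
fitConditionals <- function(x, pseudocount = 0, label = NULL) {
  stopifnot(pseudocount >= 0)
  counts <- if (is(x, "IndicatorCounts")) x else countIndicators(x)
  if (is.null(label))
    label <- if (is(x, "MotifSet")) classLabel(x) else "unlabeled"
  P <- counts@P
  n <- diag(counts@joint)
  cond <- t(t(counts@joint + pseudocount) / (n + 4 * pseudocount))
  ## same-position blocks are structurally excluded from SAE sums
  for (i in seq_len(P)) {
    u <- 4L * (i - 1L) + 1:4
    cond[u, u] <- 0
  }
  if (pseudocount == 0 && any(n == 0))
    warning("some conditioning bases unobserved (n_j(t) == 0): the ",
            "affected conditionals are undefined; scoring through them ",
            "errors. Consider pseudocount > 0.")
  new("ConditionalModel", P = P, cond = cond, counts = counts,
      pseudocount = as.numeric(pseudocount), label = label)
}

#' Look up a fitted conditional probability
#'
#' @param model a \linkS4class{ConditionalModel}.
#' @param i,j positions with \code{i != j}.
#' @param s,t bases: returns p(s at i | t at j).
#' @return the fitted conditional probability (NaN if undefined).
#' @export
conditionalProb <- function(model, i, j, s, t) {
  if (i == j) stop("conditionals are defined for i != j only")
  unname(model@cond[4L * (i - 1L) + .baseRank(s),
                    4L * (j - 1L) + .baseRank(t)])
}

setMethod("show", "ConditionalModel", function(object) {
  cat(sprintf(
    "ConditionalModel (%s): P = %d, N = %d, pseudocount = %g\n",
    object@label, object@P, object@counts@N, object@pseudocount))
})

.condSubmatrix <- function(model, seq) {
  u <- .motifUnits(seq)
  if (length(u) != model@P)
    stop(sprintf("motif length %d != model P = %d", length(u), model@P))
  sub <- model@cond[u, u]
  if (anyNA(sub))
    stop("undefined conditional encountered (conditioning base unseen ",
         "in training with pseudocount 0); refit with pseudocount > 0")
  sub
}

#' Position-wise and total sum of absolute errors
#'
#' For a motif with base s at position i, the observed indicator for s
#' is 1 and for every other base 0; the model's estimate of the
#' indicator is the conditional probability given the base at each
#' other position j. Summing the absolute errors over j gives
#' \deqn{SAE_i = 2 \sum_{j \ne i} (1 - p(s_i | t_j)),}
#' in [0, 2(P-1)]; \code{saeTotal} sums over all positions,
#' \deqn{SAE_{ap} = 2P(P-1) - 2 \sum_i \sum_{j \ne i} p(s_i | t_j),}
#' in [0, 2P(P-1)]. Low values mean the motif's bases are mutually
#' predictable under the model.
#'
#' @param model a \linkS4class{ConditionalModel}.
#' @param seq a motif of length P (character scalar), or for
#'   \code{saeTotal} a vector of such motifs.
#' @param i position for the per-position value.
#' @return numeric SAE value(s).
#' @export
saePosition <- function(model, seq, i) {
  stopifnot(i >= 1L, i <= model@P)
  sub <- .condSubmatrix(model, seq)
  2 * (model@P - 1L) - 2 * sum(sub[i, -i])
}

#' @rdname saePosition
#' @export
saeTotal <- function(model, seq) {
  P <- model@P
  vapply(seq, function(s)
    2 * P * (P - 1L) - 2 * sum(.condSubmatrix(model, s)),
    numeric(1L), USE.NAMES = FALSE)
}

#' Train the SAE splice-site classifier
#'
#' Fits the TSS and FSS conditional models on their training sets. The
#' decision threshold epsilon is left unset; estimate it with
#' \code{\link{estimateThreshold}} or set it directly with
#' \code{epsilon<-}.
#'
#' @param tss,fss \linkS4class{MotifSet}s of true and false splice-site
#'   motifs sharing the motif length P.
#' @param pseudocount smoothing constant for both models.
#' @return An \linkS4class{SaeClassifier}.
#' @examples
#' tss <- MotifSet(c("AAG", "AAG", "ATG"), label = "TSS")
#' fss <- MotifSet(c("CCT", "GCA", "TTT"), label = "FSS")
#' clf <- trainSae(tss, fss, pseudocount = 0.5)
#' dsae(clf, "AAG") < dsae(clf, "CCT")
#' @export
trainSae <- function(tss, fss, pseudocount = 0) {
  stopifnot(motifLength(tss) == motifLength(fss))
  new("SaeClassifier",
      tssModel = fitConditionals(tss, pseudocount, label = "TSS"),
      fssModel = fitConditionals(fss, pseudocount, label = "FSS"),
      epsilon = NA_real_)
}

#' Accessors for SaeClassifier
#' @param x,object an \linkS4class{SaeClassifier}.
#' @param value numeric threshold on the dSAE scale.
#' @name SaeClassifier-accessors
#' @aliases epsilon epsilon<- tssModel fssModel
NULL

#' @rdname SaeClassifier-accessors
#' @export
epsilon <- function(x) x@epsilon

#' @rdname SaeClassifier-accessors
#' @export
`epsilon<-` <- function(x, value) {
  x@epsilon <- as.numeric(value)
  x
}

#' @rdname SaeClassifier-accessors
#' @export
tssModel <- function(x) x@tssModel

#' @rdname SaeClassifier-accessors
#' @export
fssModel <- function(x) x@fssModel

setMethod("show", "SaeClassifier", function(object) {
  cat(sprintf("SaeClassifier: P = %d, pseudocount = %g, epsilon = %s\n",
              object@tssModel@P, object@tssModel@pseudocount,
              if (is.na(object@epsilon)) "unset"
              else format(object@epsilon)))
})

#' dSAE score difference and prediction score
#'
#' \code{dsae} computes SAE under the TSS model minus SAE under the
#' FSS model, literally from the SAE definition; a motif whose bases
#' are better mutually predicted by the TSS conditionals gets a
#' negative dSAE. \code{saeScore} is the negated value, so higher
#' scores mean stronger TSS calls (the reporting convention of the
#' prediction output).
#'
#' @param clf an \linkS4class{SaeClassifier}.
#' @param seq motif(s) of length P.
#' @return numeric value(s).
#' @export
dsae <- function(clf, seq) {
  saeTotal(clf@tssModel, seq) - saeTotal(clf@fssModel, seq)
}

#' @rdname dsae
#' @export
saeScore <- function(clf, seq) -dsae(clf, seq)

#' Predict splice-site class for motifs or genes
#'
#' Applies the strict decision rule: dSAE < epsilon predicts TSS,
#' dSAE >= epsilon predicts FSS (the boundary goes to FSS). When
#' \code{newdata} is a \code{GRanges} of candidate windows from
#' \code{\link{scanDonorCandidates}}, the cores are scored and the
#' ranges are returned with \code{score} (-dSAE; higher = stronger
#' TSS) and \code{label} columns.
#'
#' @param object an \linkS4class{SaeClassifier} with epsilon set.
#' @param newdata character vector of motifs (length-P cores), or a
#'   \code{GRanges} of candidate windows.
#' @param ... unused.
#' @return For motifs, a data.frame with columns \code{motif},
#'   \code{dsae}, \code{score}, \code{label}; for ranges, the annotated
#'   \code{GRanges}.
#' @export
setMethod("predict", "SaeClassifier", function(object, newdata, ...) {
  if (is.na(object@epsilon))
    stop("epsilon is unset; run estimateThreshold() first ",
         "or assign epsilon(clf) <- value")
  if (is(newdata, "GRanges")) {
    d <- dsae(object, S4Vectors::mcols(newdata)$core)
    S4Vectors::mcols(newdata)$score <- -d
    S4Vectors::mcols(newdata)$label <-
      ifelse(d < object@epsilon, "TSS", "FSS")
    return(newdata)
  }
  d <- dsae(object, newdata)
  data.frame(motif = as.character(newdata), dsae = d, score = -d,
             label = ifelse(d < object@epsilon, "TSS", "FSS"),
             stringsAsFactors = FALSE)
})

## run expr under a temporary RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## stratified fold ids: sizes differ by at most 1 within a class
.foldIds <- function(n, k) {
  sample(rep_len(seq_len(k), n))
}

## sensitivity = specificity crossing over candidate thresholds.
## Candidates are the observed dSAE values plus midpoints between
## consecutive sorted values. During the sweep each class counts a
## boundary instance in its own favor (sens: dTss <= c, spec:
## dFss >= c) — a symmetric convention that makes the tie-averaged
## crossing exactly equivariant under class swap and lands on the
## midpoint for symmetric separation; the final prediction rule
## remains the strict dSAE < epsilon.
.foldThreshold <- function(dTss, dFss) {
  v <- sort(unique(c(dTss, dFss)))
  cand <- v
  if (length(v) > 1L)
    cand <- sort(c(v, (v[-1L] + v[-length(v)]) / 2))
  sens <- vapply(cand, function(c) mean(dTss <= c), numeric(1L))
  spec <- vapply(cand, function(c) mean(dFss >= c), numeric(1L))
  gap <- abs(sens - spec)
  mean(cand[gap <= min(gap) + 1e-12])
}

#' Estimate the dSAE decision threshold by cross-validation
#'
#' Draws a stratified random subset of the data (default 60\% of each
#' class), divides it into k non-overlapping folds with approximately
#' equal class composition, and for each fold trains the classifier on
#' the other k-1 folds and scores the held-out fold. Within a fold the
#' threshold is the candidate value — observed held-out dSAE values
#' plus midpoints between consecutive sorted values — that minimises
#' |sensitivity - specificity| (ties are averaged). The final epsilon
#' is the mean of the k fold-level thresholds. Because sensitivity and
#' specificity are class-conditional rates, the estimate is invariant
#' to the TSS:FSS ratio once the folds are fixed.
#'
#' @param tss,fss \linkS4class{MotifSet}s.
#' @param fraction fraction of each class sampled before the fold
#'   division (ignored when \code{folds} is given).
#' @param k number of folds.
#' @param seed RNG seed; the estimate is reproducible from it.
#' @param pseudocount smoothing for the per-fold models.
#' @param folds optional pre-assigned folds, a list with integer
#'   vectors \code{tss} and \code{fss} of fold ids (1..k) per motif;
#'   overrides sampling and randomisation.
#' @return A \linkS4class{ThresholdEstimate}.
#' @export
estimateThreshold <- function(tss, fss, fraction = 0.6, k = 10,
                              seed = 1, pseudocount = 0, folds = NULL) {
  stopifnot(motifLength(tss) == motifLength(fss), k >= 2)
  if (is.null(folds)) {
    folds <- .withSeed(seed, {
      iT <- sample(length(tss), round(fraction * length(tss)))
      iF <- sample(length(fss), round(fraction * length(fss)))
      list(tss = setNames(.foldIds(length(iT), k), iT),
           fss = setNames(.foldIds(length(iF), k), iF),
           idxTss = iT, idxFss = iF)
    })
    mT <- motifs(tss)[folds$idxTss]
    mF <- motifs(fss)[folds$idxFss]
    fT <- unname(folds$tss); fF <- unname(folds$fss)
  } else {
    mT <- motifs(tss); mF <- motifs(fss)
    fT <- folds$tss; fF <- folds$fss
    stopifnot(length(fT) == length(mT), length(fF) == length(mF))
  }
  perFold <- vapply(seq_len(k), function(f) {
    if (!any(fT == f) || !any(fF == f) ||
        !any(fT != f) || !any(fF != f))
      stop("fold ", f, " lacks motifs of one class; try a different ",
           "seed or fewer folds")
    clf <- trainSae(MotifSet(mT[fT != f], "TSS"),
                    MotifSet(mF[fF != f], "FSS"), pseudocount)
    .foldThreshold(dsae(clf, mT[fT == f]), dsae(clf, mF[fF == f]))
  }, numeric(1L))
  new("ThresholdEstimate", perFold = perFold, epsilon = mean(perFold),
      seed = as.integer(seed), fraction = as.numeric(fraction))
}

#' @describeIn estimateThreshold per-fold thresholds of an estimate.
#' @param x a \linkS4class{ThresholdEstimate}.
#' @export
perFoldThresholds <- function(x) x@perFold

setMethod("show", "ThresholdEstimate", function(object) {
  cat(sprintf(
    "ThresholdEstimate: epsilon = %.4f over %d folds (seed %d)\n",
    object@epsilon, length(object@perFold), object@seed))
})

#' Save / load an SAE classifier as self-describing JSON
#'
#' The file stores the motif length, per-class indicator counts, the
#' pseudocount and epsilon; the conditional tables are refit from the
#' counts on load, so the round trip is exact.
#'
#' @param clf an \linkS4class{SaeClassifier}.
#' @param path JSON file path.
#' @return \code{saveSaeModel}: \code{path}, invisibly;
#'   \code{readSaeModel}: the restored classifier.
#' @export
saveSaeModel <- function(clf, path) {
  dumpCounts <- function(m) list(
    N = m@counts@N, P = m@counts@P,
    joint = m@counts@joint)
  obj <- list(format = "donorSAE-model", version = 1L,
              P = clf@tssModel@P,
              pseudocount = clf@tssModel@pseudocount,
              # NULL (absent) encodes an unset threshold
              epsilon = if (is.na(clf@epsilon)) NULL else clf@epsilon,
              tss = dumpCounts(clf@tssModel),
              fss = dumpCounts(clf@fssModel))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSaeModel
#' @export
readSaeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "donorSAE-model"))
    stop("not a donorSAE model file: ", path)
  rebuild <- function(cc, label) {
    joint <- as.matrix(cc$joint)
    lab <- .unitLabels(as.integer(cc$P))
    dimnames(joint) <- list(lab, lab)
    counts <- new("IndicatorCounts", N = as.integer(cc$N),
                  P = as.integer(cc$P),
                  single = matrix(diag(joint), nrow = 4L,
                                  dimnames = list(.BASES, NULL)),
                  joint = joint)
    suppressWarnings(
      fitConditionals(counts, obj$pseudocount, label = label))
  }
  new("SaeClassifier", tssModel = rebuild(obj$tss, "TSS"),
      fssModel = rebuild(obj$fss, "FSS"),
      epsilon = if (length(obj$epsilon)) as.numeric(obj$epsilon)
                else NA_real_)
}
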