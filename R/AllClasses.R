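#' @import methods
#' @importFrom stats setNames
NULL

## Base order used throughout for unit indexing: A, T, G, C.
## Unit u = 4*(position - 1) + rank(base), 1-based, so position 8 spans
## units 29-32 of an assembled association matrix.
.BASES <- c("A", "T", "G", "C")

.baseRank <- function(x) match(x, .BASES)

.unitLabels <- function(P) {
  as.vector(vapply(seq_len(P), function(i) paste0("pos", i, ":", .BASES),
                   character(4L)))
}

#' MotifSet: position-aligned fixed-length splice-site motifs
#'
#' Holds N equal-length motifs over the alphabet \{A, T, G, C\}, a class
#' label and the window geometry. The motifs are the modeled core
#' positions of a donor-site window: the conserved GT at the intron
#' start is excised, so a "9 bp" window with 3 exonic and 6 intronic
#' flanking bases corresponds to an 11 nt genomic span.
#'
#' @slot motifs character vector of equal-length ACGT motifs.
#' @slot label one of \code{"TSS"}, \code{"FSS"}, \code{"unlabeled"}.
#' @slot exonFlank integer, bases modeled 5' of the GT (NA if unknown).
#' @slot intronFlank integer, bases modeled 3' of the GT (NA if unknown).
#' @exportClass MotifSet
setClass("MotifSet",
  representation(motifs = "character", label = "character",
                 exonFlank = "integer", intronFlank = "integer"),
  prototype(motifs = character(0), label = "unlabeled",
            exonFlank = NA_integer_, intronFlank = NA_integer_))

setValidity("MotifSet", function(object) {
  msg <- character(0)
  if (length(object@label) != 1L ||
      !object@label %in% c("TSS", "FSS", "unlabeled"))
    msg <- c(msg, "label must be one of 'TSS', 'FSS', 'unlabeled'")
  if (length(object@motifs)) {
    L <- unique(nchar(object@motifs))
    if (length(L) != 1L)
      msg <- c(msg, "all motifs must have equal length")
    if (any(grepl("[^ATGC]", object@motifs)))
      msg <- c(msg, "motifs restricted to the alphabet {A,T,G,C}")
    if (length(L) == 1L && !is.na(object@exonFlank) &&
        !is.na(object@intronFlank) &&
        L != object@exonFlank + object@intronFlank)
      msg <- c(msg, sprintf(
        "motif length %d != exonFlank + intronFlank = %d",
        L, object@exonFlank + object@intronFlank))
  }
  if (length(msg)) msg else TRUE
})

#' IndicatorCounts: single and joint base-occurrence counts
#'
#' Exact integer tallies underlying the association measure and the
#' conditional probability tables: \code{single[s, i]} is the count of
#' base s at position i; \code{joint} is the 4P x 4P matrix whose
#' (u(i,s), u(j,t)) entry counts motifs carrying s at i and t at j.
#'
#' @slot N number of motifs tallied.
#' @slot P motif length.
#' @slot single 4 x P integer matrix (rows A,T,G,C).
#' @slot joint 4P x 4P matrix of co-occurrence counts.
#' @exportClass IndicatorCounts
setClass("IndicatorCounts",
  representation(N = "integer", P = "integer",
                 single = "matrix", joint = "matrix"))

setValidity("IndicatorCounts", function(object) {
  msg <- character(0)
  if (!all(colSums(object@single) == object@N))
    msg <- c(msg, "single counts at each position must sum to N")
  if (!isTRUE(all.equal(object@joint, t(object@joint))))
    msg <- c(msg, "joint count matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' AssociationMatrix: assembled 4P x 4P position-pair association values
#'
#' Off-diagonal position blocks hold the co-occurrence association
#' (range [0, 1]); same-position blocks hold the multinomial indicator
#' correlation (1 on the unit diagonal, values in [-1, 0] between
#' different bases at one position). Degenerate same-position cells
#' (a base fixed in every motif) are NA.
#'
#' @slot P window length in positions; the matrix side is 4P.
#' @slot values numeric 4P x 4P matrix with "pos<i>:<base>" dimnames.
#' @slot N number of motifs the matrix was computed from.
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
  representation(P = "integer", values = "matrix", N = "integer"))

setValidity("AssociationMatrix", function(object) {
  side <- 4L * object@P
  if (!all(dim(object@values) == c(side, side)))
    return(sprintf("values must be %d x %d", side, side))
  TRUE
})

#' ConditionalModel: class-conditional di-nucleotide probability table
#'
#' Stores p(s_i | t_j) for every ordered position pair i != j and all
#' base pairs, estimated as (n_ij(s,t) + alpha) / (n_j(t) + 4 alpha).
#' With alpha = 0 cells whose conditioning count n_j(t) is zero are
#' undefined and stored as NaN; scoring a motif through such a cell is
#' an error (use alpha > 0 for sparse training sets).
#'
#' @slot P motif length.
#' @slot cond 4P x 4P matrix; entry (u(i,s), u(j,t)) is p(s_i | t_j);
#'   same-position blocks are structurally zero (never summed).
#' @slot counts the \linkS4class{IndicatorCounts} the table came from.
#' @slot pseudocount smoothing constant alpha >= 0.
#' @slot label class the model was trained on.
#' @exportClass ConditionalModel
setClass("ConditionalModel",
  representation(P = "integer", cond = "matrix",
                 counts = "IndicatorCounts",
                 pseudocount = "numeric", label = "character"))

#' SaeClassifier: paired TSS/FSS conditional models with threshold
#'
#' The classifier scores a motif by dSAE = SAE under the TSS model
#' minus SAE under the FSS model; low dSAE means TSS-like. The decision
#' rule is dSAE < epsilon -> TSS, dSAE >= epsilon -> FSS. The reported
#' score is -dSAE so that higher scores mean stronger TSS calls.
#'
#' @slot tssModel,fssModel \linkS4class{ConditionalModel} objects
#'   sharing P and geometry.
#' @slot epsilon decision threshold on dSAE (NA until estimated).
#' @exportClass SaeClassifier
setClass("SaeClassifier",
  representation(tssModel = "ConditionalModel",
                 fssModel = "ConditionalModel",
                 epsilon = "numeric"),
  prototype(epsilon = NA_real_))

setValidity("SaeClassifier", function(object) {
  if (object@tssModel@P != object@fssModel@P)
    return("TSS and FSS models must share the motif length P")
  TRUE
})

#' ThresholdEstimate: cross-validated decision threshold
#'
#' Per-fold thresholds at the sensitivity = specificity crossing and
#' their mean, the final epsilon.
#'
#' @slot perFold fold-level thresholds.
#' @slot epsilon mean of \code{perFold}.
#' @slot seed RNG seed used for the stratified sample and fold split.
#' @slot fraction fraction of the data sampled before fold division.
#' @exportClass ThresholdEstimate
setClass("ThresholdEstimate",
  representation(perFold = "numeric", epsilon = "numeric",
                 seed = "integer", fraction = "numeric"))

setValidity("ThresholdEstimate", function(object) {
  if (length(object@perFold) &&
      !isTRUE(all.equal(object@epsilon, mean(object@perFold))))
    return("epsilon must equal the mean of the per-fold thresholds")
  TRUE
})

#' WmmModel: per-position log-odds baseline (weight matrix method)
#'
#' Independent per-position base probabilities for the TSS and FSS
#' classes, smoothed with a shared pseudocount; scores are summed
#' log2 likelihood ratios.
#'
#' @slot tssProb,fssProb 4 x P probability matrices (rows A,T,G,C,
#'   columns sum to 1).
#' @slot pseudocount smoothing constant.
#' @exportClass WmmModel
setClass("WmmModel",
  representation(tssProb = "matrix", fssProb = "matrix",
                 pseudocount = "numeric"))

#' Mm1Model: first-order Markov log-odds baseline
#'
#' Initial-base distribution plus position-specific transition rows for
#' each class; the score is the log2 ratio of the chain likelihoods.
#'
#' @slot tssInit,fssInit length-4 initial distributions.
#' @slot tssTrans,fssTrans 4 x 4 x (P-1) transition arrays;
#'   \code{trans[a, b, i]} is p(base b at position i+1 | base a at i).
#' @slot pseudocount smoothing constant.
#' @exportClass Mm1Model
setClass("Mm1Model",
  representation(tssInit = "numeric", fssInit = "numeric",
                 tssTrans = "array", fssTrans = "array",
                 pseudocount = "numeric"))

#' RocResult: ROC points with AUC and Hanley-McNeil standard error
#'
#' @slot points data.frame with columns \code{fpr}, \code{tpr} (and the
#'   threshold that produced each vertex).
#' @slot theta trapezoidal AUC-ROC.
#' @slot se Hanley-McNeil standard error of theta.
#' @slot nTss,nFss class sizes.
#' @exportClass RocResult
setClass("RocResult",
  representation(points = "data.frame", theta = "numeric",
                 se = "numeric", nTss = "integer", nFss = "integer"))

#' PrResult: Davis-Goadrich interpolated precision-recall curve
#'
#' @slot points data.frame with \code{recall}, \code{precision}
#'   (achievable plus interpolated points, recall non-decreasing).
#' @slot aucPr trapezoidal area under the interpolated curve.
#' @exportClass PrResult
setClass("PrResult",
  representation(points = "data.frame", aucPr = "numeric"))

#' SynthSpec: synthetic motif-set generating conditions
#'
#' Describes the generator for synthetic TSS/FSS motif sets: TSS
#' positions are drawn independently from per-position distributions,
#' then each coupling (i, j, base mapping, strength lambda) overwrites
#' position j by mapping(base at i) with probability lambda; FSS motifs
#' are i.i.d. draws from one background composition.
#'
#' @slot P motif length.
#' @slot tssProfile 4 x P matrix of per-position base probabilities
#'   (rows A,T,G,C, columns sum to 1).
#' @slot fssBackground length-4 background composition.
#' @slot couplings list of \code{list(i, j, map, lambda)} entries where
#'   \code{map} is a named character vector over A,T,G,C.
#' @slot nTss,nFss motif counts to draw.
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(P = "integer", tssProfile = "matrix",
                 fssBackground = "numeric", couplings = "list",
                 nTss = "integer", nFss = "integer"))

setValidity("SynthSpec", function(object) {
  msg <- character(0)
  if (!all(dim(object@tssProfile) == c(4L, object@P)))
    msg <- c(msg, "tssProfile must be a 4 x P matrix")
  else if (any(abs(colSums(object@tssProfile) - 1) > 1e-8) ||
           any(object@tssProfile < 0))
    msg <- c(msg, "tssProfile columns must be probability distributions")
  if (length(object@fssBackground) != 4L ||
      abs(sum(object@fssBackground) - 1) > 1e-8 ||
      any(object@fssBackground < 0))
    msg <- c(msg, "fssBackground must be a length-4 distribution")
  for (cp in object@couplings) {
    if (!all(c("i", "j", "map", "lambda") %in% names(cp)))
      msg <- c(msg, "each coupling needs fields i, j, map, lambda")
    else {
      if (cp$i == cp$j) msg <- c(msg, "coupling positions must differ")
      if (cp$lambda < 0 || cp$lambda > 1)
        msg <- c(msg, "coupling lambda must lie in [0, 1]")
      if (!all(.BASES %in% names(cp$map)) ||
          !all(cp$map %in% .BASES))
        msg <- c(msg, "coupling map must send {A,T,G,C} into {A,T,G,C}")
    }
  }
  if (length(msg)) msg else TRUE
})
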