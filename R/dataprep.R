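#' Remove duplicate motifs within and across classes
#'
#' Exact duplicates (100\% identical over the modeled window) are
#' removed within each class first, keeping the first occurrence;
#' then any FSS motif whose text also occurs among the unique TSS
#' motifs is removed from the FSS set. The operation is idempotent
#' and leaves the two sets disjoint.
#'
#' @param tss,fss \linkS4class{MotifSet}s sharing the motif length.
#' @return list with elements \code{tss} and \code{fss}, the deduped
#'   sets.
#' @examples
#' d <- dedupeMotifs(MotifSet(c("AAA", "AAA"), "TSS"),
#'                   MotifSet(c("AAA", "CCC"), "FSS"))
#' motifs(d$fss)   # "CCC"
#' @export
dedupeMotifs <- function(tss, fss) {
  stopifnot(motifLength(tss) == motifLength(fss))
  uT <- unique(motifs(tss))
  uF <- unique(motifs(fss))
  uF <- uF[!uF %in% uT]
  list(tss = MotifSet(uT, "TSS", tss@exonFlank, tss@intronFlank),
       fss = MotifSet(uF, "FSS", fss@exonFlank, fss@intronFlank))
}

#' Percent identity between two aligned motifs
#'
#' Position-wise score of 1 per matching base and 0 per mismatch,
#' expressed as a percentage of the (shared) length. The motifs are
#' fixed-length and position-aligned, so this Hamming identity is the
#' appropriate similarity — no alignment is performed.
#'
#' @param a,b equal-length motif strings.
#' @return percentage in [0, 100].
#' @examples
#' percentIdentity("ATTCGTCATG", "TCTAGTTACG")   # 50
#' @export
percentIdentity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("motifs must have equal length")
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  100 * sum(ca == cb) / length(ca)
}

#' All-vs-all similarity profile between two motif sets
#'
#' Compares every query motif with every target motif (excluding the
#' same index when the query set IS the target set, i.e. a self
#' comparison) and bins the percent identities. Identities of aligned
#' P-mers are discrete multiples of 100/P, which is the default
#' binning. Reports, per identity level, the pair count and the mean
#' number of partner sequences per query at that level.
#'
#' @param query,target \linkS4class{MotifSet}s of equal motif length.
#' @param self set \code{TRUE} to exclude same-index pairs; defaults
#'   to \code{TRUE} when \code{query} and \code{target} hold identical
#'   motifs in the same order.
#' @return data.frame with columns \code{identity}, \code{count},
#'   \code{meanPartners}.
#' @export
similarityProfile <- function(query, target,
                              self = identical(motifs(query),
                                               motifs(target))) {
  P <- motifLength(query)
  stopifnot(P == motifLength(target))
  Q <- .motifMatrix(query); T_ <- .motifMatrix(target)
  nq <- nrow(Q); nt <- nrow(T_)
  matches <- matrix(0L, nq, nt)
  for (i in seq_len(P)) {
    iq <- outer(Q[, i], .BASES, "==")          # nq x 4
    it <- outer(T_[, i], .BASES, "==")         # nt x 4
    matches <- matches + tcrossprod(iq * 1L, it * 1L)
  }
  if (self) diag(matches) <- NA_integer_
  ident <- 100 * matches / P
  levels <- 100 * (0:P) / P
  cnt <- vapply(levels, function(l)
    sum(abs(ident - l) < 1e-9, na.rm = TRUE), numeric(1L))
  data.frame(identity = levels, count = cnt,
             meanPartners = cnt / nq)
}

#' Draw an imbalanced FSS subsample at a given FSS:TSS ratio
#'
#' Keeps the TSS set intact and draws round(ratio * N_TSS) FSS motifs
#' uniformly at random without replacement, reproducibly from the
#' seed. Ratio 1 gives a balanced design; e.g. ratio 2.5, 5 or 7.5
#' give increasingly FSS-heavy designs.
#'
#' @param tss,fss \linkS4class{MotifSet}s.
#' @param ratio desired FSS:TSS multiple (>= 1; non-integer products
#'   are rounded to the nearest integer).
#' @param seed RNG seed.
#' @return list with \code{tss} (unchanged) and \code{fss} (the
#'   subsample).
#' @export
sampleImbalanced <- function(tss, fss, ratio, seed = 1) {
  stopifnot(ratio >= 1)
  nWant <- round(ratio * length(tss))
  if (nWant > length(fss))
    stop(sprintf("need %d FSS motifs but only %d available",
                 nWant, length(fss)))
  keep <- .withSeed(seed, sample(length(fss), nWant))
  list(tss = tss,
       fss = MotifSet(motifs(fss)[keep], "FSS",
                      fss@exonFlank, fss@intronFlank))
}
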