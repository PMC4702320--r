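#' Fit the weight-matrix (WMM) baseline
#'
#' Independent per-position base probabilities for each class,
#' smoothed as (n_i(b) + alpha) / (N + 4 alpha). Both classes are
#' trained on the same aligned window, so the score
#' \code{scoreWmm} = sum_i log2( p_i^TSS(x_i) / p_i^FSS(x_i) ) is a
#' pure positional log-odds between the two classes.
#'
#' @param tss,fss \linkS4class{MotifSet}s sharing the motif length.
#' @param pseudocount smoothing constant (default 0.5; with 0, a zero
#'   count cell is an error when fit).
#' @return A \linkS4class{WmmModel}.
#' @export
fitWmm <- function(tss, fss, pseudocount = 0.5) {
  stopifnot(motifLength(tss) == motifLength(fss), pseudocount >= 0)
  prob <- function(set) {
    cn <- countIndicators(set)
    p <- (cn@single + pseudocount) / (cn@N + 4 * pseudocount)
    if (pseudocount == 0 && any(p == 0))
      stop("zero positional frequency with pseudocount 0; ",
           "use pseudocount > 0")
    p
  }
  new("WmmModel", tssProb = prob(tss), fssProb = prob(fss),
      pseudocount = as.numeric(pseudocount))
}

#' @rdname fitWmm
#' @param m a fitted \linkS4class{WmmModel}.
#' @param seq motif(s) of length P.
#' @export
scoreWmm <- function(m, seq) {
  vapply(seq, function(s) {
    r <- .baseRank(strsplit(s, "", fixed = TRUE)[[1L]])
    idx <- cbind(r, seq_along(r))
    sum(log2(m@tssProb[idx] / m@fssProb[idx]))
  }, numeric(1L), USE.NAMES = FALSE)
}

setMethod("show", "WmmModel", function(object) {
  cat(sprintf("WmmModel: P = %d, pseudocount = %g\n",
              ncol(object@tssProb), object@pseudocount))
})

#' Fit the first-order Markov (MM1) baseline
#'
#' Position-specific first-order chains per class: an initial
#' distribution at position 1 and transition rows
#' p(b at i+1 | a at i), each row smoothed with the pseudocount. The
#' score is the log2 ratio of the chain likelihoods of the two
#' classes.
#'
#' @param tss,fss \linkS4class{MotifSet}s (P >= 2).
#' @param pseudocount smoothing constant (default 0.5).
#' @return A \linkS4class{Mm1Model}.
#' @export
fitMm1 <- function(tss, fss, pseudocount = 0.5) {
  P <- motifLength(tss)
  stopifnot(P == motifLength(fss), P >= 2L, pseudocount >= 0)
  fit <- function(set) {
    M <- .motifMatrix(set)
    N <- nrow(M)
    init <- (tabulate(.baseRank(M[, 1L]), 4L) + pseudocount) /
      (N + 4 * pseudocount)
    trans <- array(0, c(4L, 4L, P - 1L),
                   dimnames = list(.BASES, .BASES, NULL))
    for (i in seq_len(P - 1L)) {
      tab <- table(factor(M[, i], levels = .BASES),
                   factor(M[, i + 1L], levels = .BASES))
      tab <- unclass(tab) + pseudocount
      rs <- rowSums(tab)
      if (any(rs == 0))
        stop("unobserved conditioning base at position ", i,
             " with pseudocount 0; use pseudocount > 0")
      trans[, , i] <- tab / rs
    }
    list(init = init, trans = trans)
  }
  ft <- fit(tss); ff <- fit(fss)
  if (pseudocount == 0 && (any(ft$init == 0) || any(ff$init == 0)))
    stop("zero initial frequency with pseudocount 0; use pseudocount > 0")
  new("Mm1Model", tssInit = ft$init, fssInit = ff$init,
      tssTrans = ft$trans, fssTrans = ff$trans,
      pseudocount = as.numeric(pseudocount))
}

.mm1LogLik <- function(init, trans, r) {
  ll <- log2(init[r[1L]])
  for (i in seq_len(length(r) - 1L))
    ll <- ll + log2(trans[r[i], r[i + 1L], i])
  ll
}

#' @rdname fitMm1
#' @param m a fitted \linkS4class{Mm1Model}.
#' @param seq motif(s) of length P.
#' @export
scoreMm1 <- function(m, seq) {
  vapply(seq, function(s) {
    r <- .baseRank(strsplit(s, "", fixed = TRUE)[[1L]])
    .mm1LogLik(m@tssInit, m@tssTrans, r) -
      .mm1LogLik(m@fssInit, m@fssTrans, r)
  }, numeric(1L), USE.NAMES = FALSE)
}

setMethod("show", "Mm1Model", function(object) {
  cat(sprintf("Mm1Model: P = %d, pseudocount = %g\n",
              dim(object@tssTrans)[3L] + 1L, object@pseudocount))
})
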