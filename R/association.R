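#' Tally single and joint base-occurrence counts
#'
#' Computes, for an aligned motif set, the exact counts n_i(s) of base
#' s at position i and n_ij(s,t) of s at i co-occurring with t at j,
#' for all ordered position pairs. The joint counts are assembled as
#' the cross-product of the N x 4P indicator matrix, so
#' \code{joint[u(i,s), u(j,t)] == n_ij(s,t)} with unit index
#' u = 4(pos-1) + rank and base order A, T, G, C.
#'
#' @param x a \linkS4class{MotifSet} with at least one motif.
#' @return An \linkS4class{IndicatorCounts}.
#' @examples
#' countIndicators(MotifSet(c("AT", "TA")))
#' @export
countIndicators <- function(x) {
  stopifnot(is(x, "MotifSet"), length(x) >= 1L)
  M <- .motifMatrix(x)
  N <- nrow(M); P <- ncol(M)
  ind <- matrix(0L, N, 4L * P)
  r <- .baseRank(M)                      # column-major over M
  idx <- cbind(rep(seq_len(N), times = P),
               4L * rep(seq_len(P) - 1L, each = N) + r)
  ind[idx] <- 1L
  joint <- crossprod(ind)
  lab <- .unitLabels(P)
  dimnames(joint) <- list(lab, lab)
  single <- matrix(diag(joint), nrow = 4L,
                   dimnames = list(.BASES, NULL))
  new("IndicatorCounts", N = as.integer(N), P = as.integer(P),
      single = single, joint = joint)
}

#' @describeIn countIndicators number of motifs tallied.
#' @export
setMethod("length", "IndicatorCounts", function(x) as.integer(x@N))

#' Accessors for IndicatorCounts
#' @param x an \linkS4class{IndicatorCounts}.
#' @name IndicatorCounts-accessors
#' @aliases singleCounts jointCounts
NULL

#' @rdname IndicatorCounts-accessors
#' @export
singleCounts <- function(x) x@single

#' @rdname IndicatorCounts-accessors
#' @export
jointCounts <- function(x) x@joint

setMethod("show", "IndicatorCounts", function(object) {
  cat(sprintf("IndicatorCounts: N = %d motifs, P = %d positions\n",
              object@N, object@P))
})

.checkBasePos <- function(counts, i, s) {
  stopifnot(i >= 1L, i <= counts@P)
  r <- .baseRank(s)
  if (is.na(r)) stop("unknown base: ", s)
  r
}

#' Association between bases at two different positions
#'
#' The co-occurrence association
#' a_ij(s,t) = n_ij(s,t) / sqrt(n_i(s) * n_j(t)), ranging from 0 (s at
#' i and t at j never co-occur) to 1 (complete association: whenever s
#' occurs at i, t occurs at j, and conversely). When either marginal
#' count is zero the numerator is necessarily zero too; the value is
#' defined as 0 and a data-sparsity warning is raised.
#'
#' @param counts an \linkS4class{IndicatorCounts}.
#' @param i,j positions, \code{i != j}.
#' @param s,t bases in A, T, G, C (s at i, t at j).
#' @return the association value in [0, 1].
#' @examples
#' cn <- countIndicators(MotifSet(c("AT", "AT", "AG")))
#' associationOffdiag(cn, 1, 2, "A", "T")   # 2 / sqrt(3 * 2)
#' @export
associationOffdiag <- function(counts, i, j, s, t) {
  if (i == j)
    stop("i == j: use associationDiag for same-position association")
  rs <- .checkBasePos(counts, i, s)
  rt <- .checkBasePos(counts, j, t)
  ns <- counts@single[rs, i]
  nt <- counts@single[rt, j]
  if (ns == 0L || nt == 0L) {
    warning(sprintf(
      "zero marginal count for %s at position %d or %s at position %d; association defined as 0",
      s, i, t, j))
    return(0)
  }
  unname(counts@joint[4L * (i - 1L) + rs, 4L * (j - 1L) + rt] /
           sqrt(ns * nt))
}

#' Association between bases at the same position
#'
#' From the multinomial (tetranomial) model of a single aligned
#' column: 1 when s == t, and otherwise the negative indicator
#' correlation -sqrt(n_i(s) n_i(t) / ((N - n_i(s)) (N - n_i(t)))),
#' which lies in [-1, 0]. If s != t and one of the bases occupies the
#' whole column (count == N) the expression divides by zero; the value
#' is undefined and returned as NA.
#'
#' @param counts an \linkS4class{IndicatorCounts}.
#' @param i position.
#' @param s,t bases.
#' @return 1 if \code{s == t}; otherwise a value in [-1, 0], or NA for
#'   a degenerate (fixed) column.
#' @examples
#' cn <- countIndicators(MotifSet(c("A", "A", "T", "G")))
#' associationDiag(cn, 1, "A", "T")   # -sqrt(2*1 / (2*3))
#' @export
associationDiag <- function(counts, i, s, t) {
  rs <- .checkBasePos(counts, i, s)
  rt <- .checkBasePos(counts, i, t)
  if (rs == rt) return(1)
  N <- counts@N
  ns <- counts@single[rs, i]
  nt <- counts@single[rt, i]
  if (ns == N || nt == N) return(NA_real_)
  unname(-sqrt((ns * nt) / ((N - ns) * (N - nt))))
}

#' Assemble the full 4P x 4P association matrix
#'
#' Computes the association for every (position, base) unit pair:
#' off-diagonal position blocks by the co-occurrence measure and
#' same-position blocks by the multinomial indicator correlation. For
#' a 20-position window the assembled matrix is 80 x 80 units. Cells
#' that are undefined (a base fixed in every motif paired with a
#' different base at the same position) are NA and export as blanks.
#'
#' @param x a \linkS4class{MotifSet} (N >= 2) or an
#'   \linkS4class{IndicatorCounts}.
#' @return An \linkS4class{AssociationMatrix}.
#' @examples
#' am <- associationMatrix(MotifSet(c("ATG", "ATC", "TTG")))
#' dim(assocValues(am))
#' @export
associationMatrix <- function(x) {
  counts <- if (is(x, "IndicatorCounts")) x else countIndicators(x)
  if (counts@N < 2L) stop("need at least 2 motifs")
  P <- counts@P; N <- counts@N
  n <- diag(counts@joint)                # unit marginal counts
  denom <- sqrt(outer(n, n))
  vals <- counts@joint / denom
  vals[denom == 0] <- 0                  # zero-marginal guard (Eq. 1)
  ## overwrite same-position blocks with the multinomial correlation
  for (i in seq_len(P)) {
    u <- 4L * (i - 1L) + 1:4
    ni <- n[u]
    blk <- -sqrt(outer(ni, ni) / outer(N - ni, N - ni))
    blk[!is.finite(blk)] <- NA_real_     # degenerate fixed column
    diag(blk) <- 1
    vals[u, u] <- blk
  }
  if (any(n == 0))
    warning("some bases unobserved at some positions; ",
            "their associations are reported as 0")
  new("AssociationMatrix", P = P, values = vals, N = N)
}

#' Accessors for AssociationMatrix
#' @param x an \linkS4class{AssociationMatrix}.
#' @name AssociationMatrix-accessors
#' @aliases assocValues nPositions
NULL

#' @rdname AssociationMatrix-accessors
#' @export
assocValues <- function(x) x@values

#' @rdname AssociationMatrix-accessors
#' @export
nPositions <- function(x) x@P

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf(
    "AssociationMatrix: P = %d positions (%d x %d units), N = %d motifs\n",
    object@P, 4L * object@P, 4L * object@P, object@N))
})

#' Export / re-import an association matrix as TSV
#'
#' The TSV carries "pos<i>:<base>" unit labels on both axes and full
#' double precision, so a write-read round trip is lossless; NA cells
#' (degenerate columns) are written as empty fields.
#'
#' @param m an \linkS4class{AssociationMatrix}.
#' @param path output (input) file.
#' @return \code{exportAssociationMatrix}: \code{path}, invisibly;
#'   \code{readAssociationMatrix}: the re-assembled matrix object.
#' @export
exportAssociationMatrix <- function(m, path) {
  df <- as.data.frame(m@values, check.names = FALSE)
  df <- cbind(unit = rownames(m@values), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname exportAssociationMatrix
#' @param N number of motifs to record on the re-imported object
#'   (not stored in the TSV).
#' @export
readAssociationMatrix <- function(path, N = NA) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$unit
  storage.mode(vals) <- "double"
  new("AssociationMatrix", P = as.integer(nrow(vals) / 4L),
      values = vals, N = as.integer(N))
}

#' Render an association matrix as a heat map
#'
#' Optional graphical hook: draws the assembled matrix with
#' \code{stats::heatmap}-free base graphics (\code{image}), units in
#' matrix order, no dendrograms. Intended for window-size inspection;
#' the TSV export is the primary interface.
#'
#' @param m an \linkS4class{AssociationMatrix}.
#' @param ... passed to \code{graphics::image}.
#' @return invisibly, the matrix drawn.
#' @export
plotAssociationHeatmap <- function(m, ...) {
  v <- m@values
  v[is.na(v)] <- 0
  n <- nrow(v)
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, , drop = FALSE]),
                  xlab = "unit", ylab = "unit", useRaster = TRUE, ...)
  invisible(v)
}
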