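#' Construct a MotifSet
#'
#' @param motifs character vector (or \code{DNAStringSet}) of
#'   equal-length ACGT motifs — the modeled core positions with the
#'   conserved GT excised.
#' @param label class label: \code{"TSS"}, \code{"FSS"} or
#'   \code{"unlabeled"}.
#' @param exonFlank,intronFlank window geometry: bases modeled on the
#'   exon and intron side of the GT. Optional; when given their sum
#'   must equal the motif length.
#' @return A \linkS4class{MotifSet}.
#' @examples
#' MotifSet(c("AAACCCCCC", "AAGCCCCCC"), label = "TSS",
#'          exonFlank = 3, intronFlank = 6)
#' @export
MotifSet <- function(motifs, label = "unlabeled",
                     exonFlank = NA, intronFlank = NA) {
  if (is(motifs, "XStringSet")) motifs <- as.character(motifs)
  motifs <- toupper(as.character(motifs))
  names(motifs) <- NULL
  new("MotifSet", motifs = motifs, label = label,
      exonFlank = as.integer(exonFlank),
      intronFlank = as.integer(intronFlank))
}

#' @describeIn MotifSet number of motifs in the set.
#' @param x,object a \code{MotifSet}.
#' @export
setMethod("length", "MotifSet", function(x) length(x@motifs))

#' Accessors for MotifSet
#'
#' \code{motifs} returns the motif texts; \code{motifLength} the shared
#' motif length P; \code{classLabel} the class label;
#' \code{exonFlank} / \code{intronFlank} the window geometry.
#'
#' @param x a \linkS4class{MotifSet}.
#' @return see individual descriptions.
#' @name MotifSet-accessors
#' @aliases motifs motifLength classLabel exonFlank intronFlank
NULL

#' @rdname MotifSet-accessors
#' @export
motifs <- function(x) x@motifs

#' @rdname MotifSet-accessors
#' @export
motifLength <- function(x) {
  if (!length(x@motifs)) return(0L)
  nchar(x@motifs[[1L]])
}

#' @rdname MotifSet-accessors
#' @export
classLabel <- function(x) x@label

#' @rdname MotifSet-accessors
#' @export
exonFlank <- function(x) x@exonFlank

#' @rdname MotifSet-accessors
#' @export
intronFlank <- function(x) x@intronFlank

setMethod("show", "MotifSet", function(object) {
  cat(sprintf("MotifSet of %d %s motif(s), P = %d", length(object),
              object@label, motifLength(object)))
  if (!is.na(object@exonFlank))
    cat(sprintf(" (-%d ~ +%d, GT excluded)",
                object@exonFlank, object@intronFlank))
  cat("\n")
  if (length(object))
    cat("  ", paste(utils::head(object@motifs, 3L), collapse = " "),
        if (length(object) > 3L) "..." else "", "\n")
})

## N x P character matrix of motif bases; the workhorse layout for
## counting.
.motifMatrix <- function(x) {
  m <- if (is(x, "MotifSet")) x@motifs else x
  matrix(unlist(strsplit(m, "", fixed = TRUE), use.names = FALSE),
         nrow = length(m), byrow = TRUE)
}

## unit indices u = 4*(pos-1) + baseRank for one motif string
.motifUnits <- function(seq) {
  r <- .baseRank(strsplit(seq, "", fixed = TRUE)[[1L]])
  if (anyNA(r)) stop("motif contains characters outside {A,T,G,C}: ", seq)
  4L * (seq_along(r) - 1L) + r
}
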