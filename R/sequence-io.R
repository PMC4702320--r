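#' Read gene sequences from a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readBStringSet} that upper-cases
#' the sequences and preserves record order. Sequences may contain
#' ambiguity characters; candidate-window scanning skips windows that
#' include them.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of upper-cased sequences, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "acgtGTacgtacg"), fa)
#' readFastaSeqs(fa)
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) && !startsWith(trimws(lines[nonempty[1L]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected a '>' header",
                 nonempty[1L]))
  if (!length(nonempty)) return(setNames(character(0), character(0)))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Scan genes for candidate donor-site windows
#'
#' Finds every occurrence of the conserved GT di-nucleotide on the
#' forward strand and extracts the fixed-geometry window around it:
#' \code{exonFlank} bases 5' of the GT and \code{intronFlank} bases 3'
#' of it. The reported coordinates are 1-based inclusive over the FULL
#' motif (GT included), matching genome-browser conventions; the
#' modeled \code{core} excises the GT. Windows whose flanks do not fit
#' inside the gene, or that contain non-ACGT characters, are skipped
#' (the latter are counted and reported via a message).
#'
#' @param genes named character vector (or \code{DNAStringSet}) of gene
#'   sequences; a single unnamed sequence is accepted and called
#'   \code{"gene1"}.
#' @param exonFlank,intronFlank window geometry (both >= 1).
#' @return A \code{GRanges} with one range per candidate window
#'   (seqnames = gene id) and metadata columns \code{motif} (full
#'   window, GT included) and \code{core} (GT excised). The number of
#'   windows skipped for ambiguity characters is stored in
#'   \code{metadata()$skippedAmbiguous}.
#' @examples
#' scanDonorCandidates(c(g1 = "AAAGTCCCCCC"), exonFlank = 3,
#'                     intronFlank = 6)
#' @export
scanDonorCandidates <- function(genes, exonFlank, intronFlank) {
  stopifnot(exonFlank >= 1, intronFlank >= 1)
  if (is(genes, "XStringSet")) genes <- as.character(genes)
  genes <- toupper(genes)
  if (is.null(names(genes)))
    names(genes) <- paste0("gene", seq_along(genes))
  e <- as.integer(exonFlank); i <- as.integer(intronFlank)
  W <- e + 2L + i
  skipped <- 0L
  res <- lapply(names(genes), function(g) {
    seq <- genes[[g]]
    if (nchar(seq) < W) return(NULL)
    gt <- .findGT(seq)
    ## GT offset o (1-based position of G): need e bases before and
    ## i bases after the T.
    gt <- gt[gt - e >= 1L & gt + 1L + i <= nchar(seq)]
    if (!length(gt)) return(NULL)
    start <- gt - e
    motif <- substring(seq, start, start + W - 1L)
    ok <- !grepl("[^ATGC]", motif)
    skipped <<- skipped + sum(!ok)
    if (!any(ok)) return(NULL)
    data.frame(gene = g, start = start[ok], end = start[ok] + W - 1L,
               motif = motif[ok], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (skipped > 0L)
    message(skipped, " candidate window(s) skipped (non-ACGT characters)")
  if (is.null(res))
    res <- data.frame(gene = character(0), start = integer(0),
                      end = integer(0), motif = character(0))
  gr <- GenomicRanges::GRanges(
    seqnames = res$gene,
    ranges = IRanges::IRanges(start = res$start, end = res$end),
    motif = res$motif,
    core = paste0(substring(res$motif, 1L, e),
                  substring(res$motif, e + 3L, W)))
  if (!nrow(res)) S4Vectors::mcols(gr) <-
      S4Vectors::DataFrame(motif = character(0), core = character(0))
  S4Vectors::metadata(gr)$skippedAmbiguous <- skipped
  S4Vectors::metadata(gr)$geometry <- c(exonFlank = e, intronFlank = i)
  gr
}

## 1-based positions of "G" in "GT" occurrences (overlap-safe)
.findGT <- function(seq) {
  g <- gregexpr("(?=GT)", seq, perl = TRUE)[[1L]]
  if (g[1L] == -1L) integer(0) else as.integer(g)
}

#' Collect candidate cores into a MotifSet
#'
#' @param windows a \code{GRanges} from \code{\link{scanDonorCandidates}}.
#' @param label class label for the resulting set.
#' @return A \linkS4class{MotifSet} of the core motifs (GT excised).
#' @export
windowsToMotifSet <- function(windows, label = "unlabeled") {
  geom <- S4Vectors::metadata(windows)$geometry
  MotifSet(S4Vectors::mcols(windows)$core, label = label,
           exonFlank = geom[["exonFlank"]],
           intronFlank = geom[["intronFlank"]])
}

#' Load an aligned motif set from disk
#'
#' Accepts either plain text (one uppercase ACGT motif per line, LF or
#' CRLF) or FASTA; the two encodings of the same motifs load
#' identically.
#'
#' @param path input file.
#' @param expectedP required motif length; a record of any other length
#'   is an error naming it.
#' @param label class label for the set.
#' @param strict if \code{TRUE} (default) a non-ACGT character is an
#'   error; if \code{FALSE} such records are dropped with a message.
#' @param exonFlank,intronFlank optional geometry, recorded on the set.
#' @return A \linkS4class{MotifSet} with \code{P == expectedP}.
#' @export
loadMotifSet <- function(path, expectedP, label = "unlabeled",
                         strict = TRUE, exonFlank = NA, intronFlank = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (any(startsWith(trimws(lines), ">"))) {
    seqs <- unname(readFastaSeqs(path))
    ids <- names(readFastaSeqs(path))
  } else {
    seqs <- toupper(trimws(lines[nzchar(trimws(lines))]))
    ids <- paste0("line ", which(nzchar(trimws(lines))))
  }
  bad <- which(nchar(seqs) != expectedP)
  if (length(bad))
    stop(sprintf("motif %s has length %d, expected %d",
                 ids[bad[1L]], nchar(seqs[bad[1L]]), as.integer(expectedP)))
  amb <- grepl("[^ATGC]", seqs)
  if (any(amb)) {
    if (strict)
      stop(sprintf("motif %s contains non-ACGT characters", ids[which(amb)[1L]]))
    message(sum(amb), " motif(s) dropped (non-ACGT characters)")
    seqs <- seqs[!amb]
  }
  MotifSet(seqs, label = label, exonFlank = exonFlank,
           intronFlank = intronFlank)
}

#' Write a MotifSet as plain text, one motif per line
#'
#' @param x a \linkS4class{MotifSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMotifSet <- function(x, path) {
  writeLines(motifs(x), path)
  invisible(path)
}
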