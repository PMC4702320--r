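#' Default donor-like positional profile
#'
#' A 4 x 9 per-position base distribution for the 9 bp core window
#' (3 exonic, 6 intronic modeled positions; the conserved GT is
#' excised) loosely shaped after the eukaryotic donor consensus
#' MAG | gt | RAGT: a strong G just before the junction, A-rich +4
#' and G-rich +5 intronic positions decaying to background further
#' in. The numbers are an arbitrary consensus-strength choice for
#' simulation, not fitted to any dataset.
#'
#' @param strength consensus sharpness on a log-linear scale: each
#'   column is proportional to p^strength, so 0 flattens the profile
#'   to uniform, 1 keeps it as-is and values above 1 sharpen it toward
#'   the consensus bases (a "strong-consensus" site population).
#' @return 4 x 9 matrix, rows A, T, G, C, columns summing to 1.
#' @export
defaultDonorProfile <- function(strength = 1) {
  stopifnot(strength >= 0)
  ##           -3   -2   -1   +3   +4   +5   +6   +7   +8
  p <- matrix(c(
    0.33, 0.60, 0.09, 0.55, 0.71, 0.06, 0.17, 0.28, 0.25,  # A
    0.12, 0.13, 0.07, 0.08, 0.09, 0.07, 0.45, 0.26, 0.25,  # T
    0.18, 0.14, 0.81, 0.35, 0.12, 0.82, 0.19, 0.24, 0.25,  # G
    0.37, 0.13, 0.03, 0.02, 0.08, 0.05, 0.19, 0.22, 0.25), # C
    nrow = 4L, byrow = TRUE, dimnames = list(.BASES, NULL))
  p <- p^strength
  sweep(p, 2L, colSums(p), "/")
}

#' Construct a synthetic-data specification
#'
#' Defines the generating conditions for synthetic TSS/FSS motif
#' sets: TSS motifs are drawn position-independently from
#' \code{tssProfile}, then each coupling (i, j, map, lambda)
#' overwrites position j with map(base at i) with probability lambda —
#' the simplest mechanism giving tunable, analytically checkable
#' pairwise dependence. FSS motifs are i.i.d. draws from a single
#' background composition.
#'
#' @param P motif length.
#' @param tssProfile 4 x P matrix (rows A,T,G,C, columns sum to 1).
#' @param fssBackground length-4 background composition (A,T,G,C).
#' @param couplings list of \code{list(i, j, map, lambda)}; \code{map}
#'   is a named character vector over A,T,G,C. Default: two moderate
#'   identity couplings between intronic consensus positions.
#' @param nTss,nFss motif counts to draw.
#' @return A \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(P = 9,
                      tssProfile = defaultDonorProfile(),
                      fssBackground = c(A = 0.27, T = 0.27,
                                        G = 0.23, C = 0.23),
                      couplings = list(
                        list(i = 3L, j = 7L,
                             map = c(A = "A", T = "T", G = "G", C = "C"),
                             lambda = 0.3),
                        list(i = 5L, j = 6L,
                             map = c(A = "A", T = "T", G = "G", C = "C"),
                             lambda = 0.3)),
                      nTss = 500, nFss = 500) {
  new("SynthSpec", P = as.integer(P), tssProfile = tssProfile,
      fssBackground = unname(fssBackground), couplings = couplings,
      nTss = as.integer(nTss), nFss = as.integer(nFss))
}

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf(
    "SynthSpec: P = %d, %d TSS + %d FSS, %d coupling(s)\n",
    object@P, object@nTss, object@nFss, length(object@couplings)))
})

.drawProfile <- function(n, prob) {
  ## prob: 4 x P matrix; returns n x P character matrix
  P <- ncol(prob)
  M <- matrix("", n, P)
  for (i in seq_len(P))
    M[, i] <- sample(.BASES, n, replace = TRUE, prob = prob[, i])
  M
}

#' Simulate synthetic TSS and FSS motif sets
#'
#' Draws the two classes as described in \code{\link{synthSpec}},
#' reproducibly from the seed.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param seed RNG seed.
#' @return list with \code{tss} and \code{fss}
#'   \linkS4class{MotifSet}s.
#' @examples
#' sim <- simulateMotifs(synthSpec(nTss = 20, nFss = 20), seed = 7)
#' length(sim$tss)
#' @export
simulateMotifs <- function(spec, seed = 1) {
  stopifnot(is(spec, "SynthSpec"))
  validObject(spec)
  .withSeed(seed, {
    tssM <- if (spec@nTss > 0L) .drawProfile(spec@nTss, spec@tssProfile)
            else matrix("", 0L, spec@P)
    for (cp in spec@couplings) {
      if (!nrow(tssM)) break
      hit <- stats::runif(nrow(tssM)) < cp$lambda
      tssM[hit, cp$j] <- unname(cp$map[tssM[hit, cp$i]])
    }
    fssM <- if (spec@nFss > 0L)
      matrix(sample(.BASES, spec@nFss * spec@P, replace = TRUE,
                    prob = spec@fssBackground), spec@nFss, spec@P)
      else matrix("", 0L, spec@P)
    list(tss = MotifSet(apply(tssM, 1L, paste, collapse = ""),
                        "TSS"),
         fss = MotifSet(apply(fssM, 1L, paste, collapse = ""),
                        "FSS"))
  })
}

#' Re-insert the conserved GT into a core motif
#'
#' @param core modeled core motif(s) (GT excised).
#' @param exonFlank number of exonic positions at the start of the
#'   core.
#' @return full window text(s) with GT inserted after position
#'   \code{exonFlank}.
#' @export
windowFromCore <- function(core, exonFlank) {
  paste0(substring(core, 1L, exonFlank), "GT",
         substring(core, exonFlank + 1L, nchar(core)))
}

#' Simulate background genes with planted donor-site motifs
#'
#' Generates i.i.d. background-composition genes and splices full
#' donor windows (GT included) in at the requested coordinates,
#' returning the ground-truth table for end-to-end scan/predict
#' round trips. Background GT occurrences remain in place and act as
#' decoy candidates, as they would in real genes.
#'
#' @param n number of genes.
#' @param length gene length in bases.
#' @param planted data.frame with columns \code{gene} (index in
#'   1..n), \code{start} (1-based coordinate of the first motif
#'   base) and \code{motif} (full window text including GT).
#' @param exonFlank,intronFlank window geometry; each planted motif
#'   must carry GT at positions exonFlank+1, exonFlank+2.
#' @param background length-4 base composition (A,T,G,C).
#' @param seed RNG seed.
#' @return list with \code{genes} (named character vector) and
#'   \code{truth} (data.frame gene, start, end, motif, core).
#' @export
simulateGenes <- function(n, length, planted = NULL,
                          exonFlank = 3, intronFlank = 6,
                          background = c(0.25, 0.25, 0.25, 0.25),
                          seed = 1) {
  e <- as.integer(exonFlank); i <- as.integer(intronFlank)
  W <- e + 2L + i
  genes <- .withSeed(seed, vapply(seq_len(n), function(g)
    paste(sample(.BASES, length, replace = TRUE, prob = background),
          collapse = ""), character(1L)))
  names(genes) <- paste0("synthgene", seq_len(n))
  truth <- data.frame(gene = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      core = character(0))
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(all(c("gene", "start", "motif") %in% names(planted)))
    if (any(nchar(planted$motif) != W))
      stop("planted motifs must have length exonFlank + 2 + intronFlank")
    if (any(substring(planted$motif, e + 1L, e + 2L) != "GT"))
      stop("planted motifs must carry GT at the junction offset")
    if (any(planted$start < 1L | planted$start + W - 1L > length))
      stop("planted motif does not fit inside the gene")
    for (g in unique(planted$gene)) {
      p <- planted[planted$gene == g, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      if (nrow(p) > 1L &&
          any(p$start[-1L] <= p$start[-nrow(p)] + W - 1L))
        stop("planted motifs overlap in gene ", g)
      s <- genes[[g]]
      for (r in seq_len(nrow(p)))
        substr(s, p$start[r], p$start[r] + W - 1L) <- p$motif[r]
      genes[[g]] <- s
    }
    truth <- data.frame(
      gene = names(genes)[planted$gene],
      start = as.integer(planted$start),
      end = as.integer(planted$start + W - 1L),
      motif = planted$motif,
      core = paste0(substring(planted$motif, 1L, e),
                    substring(planted$motif, e + 3L, W)),
      stringsAsFactors = FALSE)
  }
  list(genes = genes, truth = truth)
}
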