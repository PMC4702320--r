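# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (explicit loops) so they stay
# independent of the vectorised implementation paths they check.

BASES <- c("A", "T", "G", "C")

randomMotifs <- function(n, P, seed, prob = rep(0.25, 4)) {
  set.seed(seed)
  vapply(seq_len(n), function(k)
    paste(sample(BASES, P, replace = TRUE, prob = prob), collapse = ""),
    character(1))
}

motifChars <- function(m) do.call(rbind, strsplit(m, "", fixed = TRUE))

# quadruple-loop joint tally n_ij(s,t)
bruteJoint <- function(m, i, j, s, t) {
  M <- motifChars(m)
  sum(M[, i] == s & M[, j] == t)
}

bruteSingle <- function(m, i, s) {
  M <- motifChars(m)
  sum(M[, i] == s)
}

# Eq.-style direct arithmetic for the two association forms
bruteAssocOff <- function(m, i, j, s, t) {
  num <- bruteJoint(m, i, j, s, t)
  den <- sqrt(bruteSingle(m, i, s) * bruteSingle(m, j, t))
  if (den == 0) 0 else num / den
}

bruteAssocDiag <- function(m, i, s, t) {
  if (s == t) return(1)
  N <- length(m)
  ns <- bruteSingle(m, i, s); nt <- bruteSingle(m, i, t)
  if (ns == N || nt == N) return(NA_real_)
  -sqrt(ns * nt / ((N - ns) * (N - nt)))
}

# count-ratio conditional and term-enumeration SAE
bruteConditional <- function(train, i, j, s, t, alpha = 0) {
  (bruteJoint(train, i, j, s, t) + alpha) /
    (bruteSingle(train, j, t) + 4 * alpha)
}

bruteSaeTotal <- function(train, seq, alpha = 0) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  P <- length(ch)
  tot <- 0
  for (i in seq_len(P)) for (j in seq_len(P)) if (i != j) {
    p <- bruteConditional(train, i, j, ch[i], ch[j], alpha)
    tot <- tot + abs(1 - p) + abs(0 - (1 - p))
  }
  tot
}

# normalised Mann-Whitney pairwise count, ties counted 1/2
mannWhitneyAuc <- function(scores, labels) {
  sp <- scores[labels == "TSS"]; sn <- scores[labels == "FSS"]
  tot <- 0
  for (p in sp) for (n in sn)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(sp) * length(sn))
}

loopConfusion <- function(scores, labels, thr) {
  tp <- fp <- tn <- fn <- 0
  for (k in seq_along(scores)) {
    call <- scores[k] >= thr
    if (labels[k] == "TSS") { if (call) tp <- tp + 1 else fn <- fn + 1 }
    else { if (call) fp <- fp + 1 else tn <- tn + 1 }
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# minimal hand-written FASTA reader used only to cross-check readFastaSeqs
secondFastaParser <- function(path) {
  lines <- readLines(path)
  ids <- character(0); seqs <- character(0); cur <- ""
  for (l in lines) {
    if (startsWith(l, ">")) {
      ids <- c(ids, sub("^>(\\S+).*$", "\\1", l))
      seqs <- c(seqs, cur <- "")
    } else seqs[length(seqs)] <- cur <- paste0(cur, toupper(trimws(l)))
  }
  stats::setNames(seqs, ids)
}
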