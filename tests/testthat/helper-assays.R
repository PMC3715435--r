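# shared fixtures and independent oracles, built in code

partialAssay <- builtinAssay("partial")
noncompAssay <- builtinAssay("noncomp")

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# independent brute force over all (left trim, right trim, insertion) string
# families reconstructing J; no knowledge of the package's completion logic
bruteForceFamilies <- function(J, assay, maxDel = 25L, maxIns = 6L) {
  L <- assay@leftEnd@duplexTop
  R <- assay@rightEnd@duplexTop
  nL <- nchar(L); nR <- nchar(R)
  out <- character(0)
  for (tLp in 0:min(maxDel, nL - nchar(assay@leftAnchor)))
    for (tRr in 0:min(maxDel, nR - nchar(assay@rightAnchor))) {
      i <- nchar(J) - (nL - tLp) - (nR - tRr)
      if (i < 0L || i > maxIns) next
      if (substr(J, 1L, nL - tLp) == substr(L, 1L, nL - tLp) &&
          substr(J, nL - tLp + i + 1L, nchar(J)) == substr(R, tRr + 1L, nR))
        out <- c(out, paste(tLp, tRr, substr(J, nL - tLp + 1L, nL - tLp + i)))
    }
  sort(unique(out))
}

familyKeys <- function(explanations, dropMmr = TRUE) {
  keys <- vapply(explanations, function(e) {
    if (dropMmr && length(e@mmrPositions)) return(NA_character_)
    paste(e@trimLeftProt, e@trimRightRec, e@insertionTop)
  }, character(1))
  sort(unique(keys[!is.na(keys)]))
}

# independent argmin under the parsimony order, written as an explicit
# pairwise comparison loop (no shared code with rankExplanations)
oracleBest <- function(explanations) {
  better <- function(x, y) {
    if (x@cost != y@cost) return(x@cost < y@cost)
    if (x@mhLen != y@mhLen) return(x@mhLen > y@mhLen)
    if (x@mismatchesInPairing != y@mismatchesInPairing)
      return(x@mismatchesInPairing < y@mismatchesInPairing)
    tx <- x@templatedTop || x@templatedBottom
    ty <- y@templatedTop || y@templatedBottom
    if (tx != ty) return(tx)
    if (x@trimLeftProt != y@trimLeftProt) return(x@trimLeftProt < y@trimLeftProt)
    if (x@trimRightRec != y@trimRightRec) return(x@trimRightRec < y@trimRightRec)
    x@insertionTop < y@insertionTop
  }
  best <- explanations[[1]]
  for (e in explanations[-1]) if (better(e, best)) best <- e
  best
}

explKey <- function(e) paste(e@trimLeftProt, e@trimLeftRec, e@trimRightProt,
                             e@trimRightRec, e@insertionTop)

# random junction generator: apply random trims/insertion to the assay ends
randomJunction <- function(assay, maxTrim = 8L, maxIns = 6L) {
  L <- assay@leftEnd@duplexTop
  R <- assay@rightEnd@duplexTop
  tLp <- sample(0:maxTrim, 1L)
  tRr <- sample(0:maxTrim, 1L)
  i <- sample(0:maxIns, 1L)
  paste0(substr(L, 1L, nchar(L) - tLp),
         if (i > 0L) randomSeq(i) else "",
         substr(R, tRr + 1L, nchar(R)))
}

# independent exact two-sided Mann-Whitney p by full enumeration of labelings
enumMW <- function(a, b) {
  nA <- length(a); pooled <- c(a, b); n <- length(pooled)
  uOf <- function(ia) sum(outer(pooled[ia], pooled[-ia], ">"))
  uObs <- uOf(seq_len(nA))
  us <- apply(utils::combn(n, nA), 2, uOf)
  muU <- nA * (n - nA) / 2
  mean(abs(us - muU) >= abs(uObs - muU))
}
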