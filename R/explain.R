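## Junction reconstruction engine.
##
## All coordinates are on the final junction top strand, 1-based.  For an
## assay with left end top strand L (length nL, overhang = last ov bases),
## right end top strand R (length nR, starting at the recessed terminus) and
## right bottom-strand overhang Rov, define the right end's full top-sense
## content rightExt = revcomp(Rov) + R (length ov + nR): indices 1..ov are the
## bottom-overhang region, ov+1..ov+nR the duplex.
##
## An explanation family is (tLp, tRr, ins): trim tLp from the left top 3'
## terminus, tRr from the right top 5' terminus, insert ins between them.
## The family reconstructs the observed junction J iff
##     J == L[1..nL-tLp]  +  ins  +  R[tRr+1..nR]
## allowing at most one substitution inside the left part (a mismatch-repair
## resolution toward the right-end allele, validated during completion).
##
## Completion assigns the bottom-strand trims (tLr on the left recessed 5'
## terminus, tRp on the right protruding 3' terminus) that make the annealed
## intermediate geometrically coherent:
##   * bottom strands of the two ends may not overlap;
##   * every retained right-bottom base lying under retained left top must
##     Watson-Crick pair with the parental left base, except at most one
##     internal mismatch (both neighbours paired) -- the mismatch-repair case;
##   * every retained right-bottom base lying under inserted bases must match
##     them (it is their synthesis template).
## The minimal coherent (tLr, tRp) is the canonical completion; larger trims
## are cost-dominated and not enumerated.

.assayContext <- function(assay) {
  L <- assay@leftEnd@duplexTop
  R <- assay@rightEnd@duplexTop
  ov <- nchar(assay@leftEnd@overhang)
  list(L = L, R = R, ov = ov,
       nL = nchar(L), nR = nchar(R),
       rightExt = paste0(.revcomp(assay@rightEnd@overhang), R),
       maxDel = assay@maxDeletion, maxIns = assay@maxInsertion,
       lAnch = nchar(assay@leftAnchor), rAnch = nchar(assay@rightAnchor))
}

## Attempt one (tLp, tRr) family for junction J; NULL if invalid.
.analyzeFamily <- function(ctx, J, tLp, tRr) {
  nJ <- nchar(J)
  a <- ctx$nL - tLp
  i <- nJ - a - (ctx$nR - tRr)
  if (i < 0L || i > ctx$maxIns) return(NULL)
  if (a < ctx$lAnch) return(NULL)
  if (ctx$nR - tRr < ctx$rAnch) return(NULL)

  ## right part must match exactly
  if (substr(J, a + i + 1L, nJ) != substr(ctx$R, tRr + 1L, ctx$nR)) return(NULL)

  ## left part: collect candidate mismatch-repair substitutions
  Lobs <- .chars(substr(J, 1L, a))
  Lexp <- .chars(substr(ctx$L, 1L, a))
  mmL <- which(Lobs != Lexp)
  if (length(mmL) > 1L) return(NULL)

  ins <- substr(J, a + 1L, a + i)
  p0 <- a + i + 1L
  extC <- .chars(ctx$rightExt)
  Jc <- .chars(J)
  Lc <- .chars(ctx$L)

  tLrMin <- max(0L, tLp - ctx$ov)   # bottom may never protrude past the top cut
  for (tLr in tLrMin:ctx$maxDel) {
    leftBotEdge <- ctx$nL - ctx$ov - tLr
    if (leftBotEdge < 0L) break
    for (tRp in 0L:min(ctx$ov + tRr, ctx$maxDel)) {
      lo <- p0 + tRp - tRr - ctx$ov        # leftmost right-bottom position
      if (lo < leftBotEdge + 1L) next      # bottom strands would overlap
      hi <- a + i                          # beyond hi the right end is duplex
      pairing <- if (lo <= min(a, hi)) lo:min(a, hi) else integer(0)
      insCov <- if (i > 0L && lo <= hi && max(lo, a + 1L) <= hi)
        max(lo, a + 1L):hi else integer(0)

      xOf <- function(q) q - p0 + ctx$ov + tRr + 1L
      ## template check under the insertion
      if (length(insCov) &&
          !all(Jc[insCov] == extC[xOf(insCov)])) next
      ## pairing check under the retained left top
      pm <- integer(0)
      ok <- TRUE
      for (q in pairing) {
        pl <- Lc[q]; pr <- extC[xOf(q)]
        if (pl != pr) pm <- c(pm, q)
        if (Jc[q] != pl && Jc[q] != pr) { ok <- FALSE; break }
      }
      if (!ok) next
      if (length(pm) > 1L) next
      if (length(pm) == 1L) {
        q <- pm
        ## tolerated mismatch must be internal to the pairing
        if (!((q - 1L) %in% pairing) || !((q + 1L) %in% pairing)) next
        if (Lc[q - 1L] != extC[xOf(q - 1L)] || Lc[q + 1L] != extC[xOf(q + 1L)]) next
      }
      ## every observed substitution must be a mismatch position resolved
      ## toward the right-end allele
      if (length(mmL)) {
        if (!all(mmL %in% pm)) next
        if (!all(Jc[mmL] == extC[xOf(mmL)])) next
      }

      bottomFill <- max(0L, min(lo - 1L, a + i) - leftBotEdge)
      templatedTop <- i > 0L && lo <= a + 1L
      templatedBottom <- bottomFill > 0L && (lo - 1L) <= a

      ## microhomology: contiguous run at the joint attributable to both
      ## parents (defined for insertion-free explanations)
      mh <- 0L
      if (i == 0L) {
        x0 <- ctx$ov + tRr
        j <- 0L
        while (a - j >= 1L && x0 - j >= 1L &&
               Jc[a - j] == extC[x0 - j]) j <- j + 1L
        k <- 0L
        while (a + 1L + k <= min(nJ, ctx$nL) &&
               Jc[a + 1L + k] == Lc[a + 1L + k]) k <- k + 1L
        mh <- j + k
      }

      return(new("JunctionExplanation",
                 trimLeftProt = as.integer(tLp), trimLeftRec = as.integer(tLr),
                 trimRightProt = as.integer(tRp), trimRightRec = as.integer(tRr),
                 insertionTop = ins,
                 mhLen = mh, pairingLen = length(pairing),
                 mismatchesInPairing = length(pm),
                 templatedTop = templatedTop, templatedBottom = templatedBottom,
                 bottomFill = as.integer(bottomFill),
                 cost = as.integer(tLp + tLr + tRp + tRr + i),
                 mmrPositions = as.integer(mmL)))
    }
  }
  NULL
}

#' Enumerate repair events consistent with a junction
#'
#' Finds every explanation family (left-end trim, right-end trim, insertion)
#' within the assay bounds whose reconstruction reproduces the observed
#' junction top strand exactly (allowing one mismatch-repair resolved base
#' inside the annealed pairing), and annotates each with its canonical
#' annealing geometry: pairing length, microhomology, templated-fill flags,
#' tolerated mismatches, bottom-strand fill.
#'
#' @param junction observed junction top strand (character), spanning the
#'   assay's left and right anchors.
#' @param assay a [TranslocationAssay-class].
#' @return list of [JunctionExplanation-class] objects, ranked best-first by
#'   [rankExplanations()]'s order; empty list if no explanation exists within
#'   bounds.
#' @examples
#' assay <- builtinAssay("partial")
#' ## templated +CA insertion after 2-nt tip pairing
#' j <- paste0(assay@leftEnd@duplexTop, "CA", assay@rightEnd@duplexTop)
#' ex <- enumerateExplanations(j, assay)[[1]]
#' ex@insertionTop; ex@templatedTop
#' @export
enumerateExplanations <- function(junction, assay) {
  stopifnot(is(assay, "TranslocationAssay"))
  junction <- .checkDna(toupper(junction), "junction")
  ctx <- .assayContext(assay)
  if (nchar(junction) < ctx$lAnch + ctx$rAnch)
    stop("malformed-input: junction shorter than the assay anchors", call. = FALSE)
  if (!startsWith(junction, assay@leftAnchor) ||
      !endsWith(junction, assay@rightAnchor))
    stop("anchor-missing: junction does not span both assay anchors", call. = FALSE)
  out <- list()
  maxTLp <- min(ctx$maxDel, ctx$nL - ctx$lAnch)
  maxTRr <- min(ctx$maxDel, ctx$nR - ctx$rAnch)
  for (tLp in 0:maxTLp)
    for (tRr in 0:maxTRr) {
      ex <- .analyzeFamily(ctx, junction, tLp, tRr)
      if (!is.null(ex)) out[[length(out) + 1L]] <- ex
    }
  if (length(out)) out[.explanationOrder(out)] else out
}

## total order used for ranking; returns ordering permutation
.explanationOrder <- function(exs) {
  cost <- vapply(exs, function(e) e@cost, integer(1))
  mh <- vapply(exs, function(e) e@mhLen, integer(1))
  mm <- vapply(exs, function(e) e@mismatchesInPairing, integer(1))
  tmpl <- vapply(exs, function(e) e@templatedTop || e@templatedBottom, logical(1))
  tlp <- vapply(exs, function(e) e@trimLeftProt, integer(1))
  trr <- vapply(exs, function(e) e@trimRightRec, integer(1))
  ins <- vapply(exs, function(e) e@insertionTop, character(1))
  order(cost, -mh, mm, !tmpl, tlp, trr, ins, method = "radix")
}

#' Select the most parsimonious explanation
#'
#' Total order: minimise total edited nucleotides (all trims plus insertion);
#' then maximise microhomology; then minimise tolerated mismatches; then
#' prefer templated over untemplated insertions; then the left-aligned
#' placement (junction-ambiguous bases attributed to the left end).  The
#' order is total, so the winner is deterministic.
#'
#' @param candidates non-empty list of [JunctionExplanation-class] objects.
#' @return the winning explanation, with attribute \code{"coOptimal"} giving
#'   the number of candidates tied with it through the mismatch/templated
#'   criteria (>= 1).
#' @export
rankExplanations <- function(candidates) {
  if (!length(candidates)) stop("no candidate explanations", call. = FALSE)
  ord <- .explanationOrder(candidates)
  best <- candidates[[ord[1]]]
  keyOf <- function(e) c(e@cost, -e@mhLen, e@mismatchesInPairing,
                         1L - (e@templatedTop || e@templatedBottom))
  bk <- keyOf(best)
  co <- sum(vapply(candidates, function(e) identical(keyOf(e), bk), logical(1)))
  attr(best, "coOptimal") <- co
  best
}

#' Rebuild a junction from an explanation
#'
#' Applies the explanation's trims, insertion and mismatch-repair resolutions
#' to the assay ends; the result must equal the observed junction (the
#' reconstruction identity).
#' @param explanation a [JunctionExplanation-class].
#' @param assay the assay it refers to.
#' @param mmrAlleles for positions listed in \code{mmrPositions}, the
#'   resolved base; default uses the right-end allele (the recorded flip).
#' @return reconstructed top strand.
#' @export
reconstructJunction <- function(explanation, assay, mmrAlleles = NULL) {
  ctx <- .assayContext(assay)
  e <- explanation
  a <- ctx$nL - e@trimLeftProt
  left <- substr(ctx$L, 1L, a)
  if (length(e@mmrPositions)) {
    lc <- .chars(left)
    for (q in e@mmrPositions) {
      x <- q - (a + nchar(e@insertionTop) + 1L) + ctx$ov + e@trimRightRec + 1L
      lc[q] <- if (is.null(mmrAlleles)) substr(ctx$rightExt, x, x) else mmrAlleles[[as.character(q)]]
    }
    left <- paste(lc, collapse = "")
  }
  paste0(left, e@insertionTop, substr(ctx$R, e@trimRightRec + 1L, ctx$nR))
}

setMethod("show", "JunctionExplanation", function(object) {
  cat("JunctionExplanation (cost ", object@cost, ")\n",
      "  trims  left prot/rec: ", object@trimLeftProt, "/", object@trimLeftRec,
      "   right prot/rec: ", object@trimRightProt, "/", object@trimRightRec, "\n",
      "  insertion(top): '", object@insertionTop, "'",
      if (object@templatedTop) " [templated]", "\n",
      "  pairing ", object@pairingLen, " nt (", object@mismatchesInPairing,
      " mismatch), microhomology ", object@mhLen, " nt, bottom fill ",
      object@bottomFill, " nt",
      if (object@templatedBottom) " [templated]", "\n", sep = "")
})
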