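#' Endonuclease cut-site specification
#'
#' Describes a staggered double-strand cut inside a recognition sequence.
#' Offsets are 0-based and half-open: the top-strand scission falls between
#' positions \code{topCut - 1} and \code{topCut} of \code{recognition}, and the
#' bottom-strand scission at top-strand offset \code{bottomCut}.  For enzymes
#' leaving 3' overhangs the bottom scission lies \emph{left} of the top one,
#' so the overhang length is \code{topCut - bottomCut} (4 for HO and I-SceI).
#'
#' @slot name single identifier, e.g. \code{"I-SceI"}.
#' @slot recognition recognition sequence on the top strand (A/C/G/T).
#' @slot topCut,bottomCut integer scission offsets (see description).
#' @export
setClass("CutSiteSpec",
  representation(name = "character", recognition = "character",
                 topCut = "integer", bottomCut = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    ok <- try(.checkDna(object@recognition, "recognition"), silent = TRUE)
    if (inherits(ok, "try-error")) msg <- c(msg, attr(ok, "condition")$message)
    n <- nchar(object@recognition)
    if (object@topCut < 0L || object@topCut > n)
      msg <- c(msg, "topCut outside recognition sequence")
    if (object@bottomCut < 0L || object@bottomCut > n)
      msg <- c(msg, "bottomCut outside recognition sequence")
    if (length(msg)) msg else TRUE
  })

#' One broken chromosome end
#'
#' A double-strand break end as it enters a junction: double-stranded context
#' given on the top strand, plus a single-stranded 3' overhang.  A left end is
#' joined at its right edge, so its 3' protrusion is on the top strand; a right
#' end is joined at its left edge and protrudes on the bottom strand.  The
#' overhang is always written 5'->3' on its own strand.
#'
#' @slot side \code{"left"} or \code{"right"} relative to the junction.
#' @slot duplexTop top-strand sequence of the end.  For a left end this
#'   \emph{includes} the overhang as its last bases; for a right end it starts
#'   at the recessed top-strand terminus and the overhang is a separate
#'   bottom-strand extension protruding leftwards.
#' @slot overhang overhang sequence, 5'->3' on the protruding strand.
#' @slot overhangStrand \code{"top"} (left end) or \code{"bottom"} (right end).
#' @export
setClass("DsbEnd",
  representation(side = "character", duplexTop = "character",
                 overhang = "character", overhangStrand = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@side %in% c("left", "right"))
      msg <- c(msg, "side must be 'left' or 'right'")
    if (!object@overhangStrand %in% c("top", "bottom"))
      msg <- c(msg, "overhangStrand must be 'top' or 'bottom'")
    for (s in c("duplexTop", "overhang")) {
      ok <- try(.checkDna(slot(object, s), s), silent = TRUE)
      if (inherits(ok, "try-error")) msg <- c(msg, attr(ok, "condition")$message)
    }
    if (object@side == "left" && object@overhangStrand != "top")
      msg <- c(msg, "a left end joined with a 3' overhang protrudes on the top strand")
    if (object@side == "right" && object@overhangStrand != "bottom")
      msg <- c(msg, "a right end joined with a 3' overhang protrudes on the bottom strand")
    if (object@side == "left" &&
        !endsWith(object@duplexTop, object@overhang))
      msg <- c(msg, "left end duplexTop must end with its overhang")
    if (length(msg)) msg else TRUE
  })

#' Translocation assay configuration
#'
#' The two DSB ends whose joining is assayed, the fixed anchor sequences used
#' to validate observed junctions, and the bounds of the explanation search.
#' \code{system} is \code{"partial"} when the two 4-nt overhangs can anneal at
#' their tips in at least one register, \code{"noncomp"} when they cannot in
#' any register, and \code{"cis"} for the intrachromosomal variant (treated as
#' noncomp geometry).
#'
#' @slot name assay identifier.
#' @slot system \code{"partial"}, \code{"noncomp"} or \code{"cis"}.
#' @slot leftEnd,rightEnd [DsbEnd-class] objects.
#' @slot leftAnchor,rightAnchor fixed outer context; every valid junction top
#'   strand begins with \code{leftAnchor} and ends with \code{rightAnchor}.
#' @slot maxDeletion,maxInsertion search bounds in nucleotides.
#' @export
setClass("TranslocationAssay",
  representation(name = "character", system = "character",
                 leftEnd = "DsbEnd", rightEnd = "DsbEnd",
                 leftAnchor = "character", rightAnchor = "character",
                 maxDeletion = "integer", maxInsertion = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!object@system %in% c("partial", "noncomp", "cis"))
      msg <- c(msg, "system must be 'partial', 'noncomp' or 'cis'")
    if (object@leftEnd@side != "left" || object@rightEnd@side != "right")
      msg <- c(msg, "leftEnd/rightEnd sides are inconsistent")
    if (nchar(object@leftEnd@overhang) != nchar(object@rightEnd@overhang))
      msg <- c(msg, "the two overhangs must have equal length")
    if (object@maxDeletion < 1L || object@maxInsertion < 1L)
      msg <- c(msg, "maxDeletion and maxInsertion must be positive")
    if (!startsWith(object@leftEnd@duplexTop, object@leftAnchor))
      msg <- c(msg, "leftAnchor absent from left end context")
    if (!endsWith(object@rightEnd@duplexTop, object@rightAnchor))
      msg <- c(msg, "rightAnchor absent from right end context")
    comp <- .usableRegisters(object@leftEnd@overhang, object@rightEnd@overhang)
    if (object@system == "partial" && length(comp) == 0L)
      msg <- c(msg, "partial system requires terminal complementarity in >=1 register")
    if (object@system %in% c("noncomp", "cis") && length(comp) > 0L)
      msg <- c(msg, paste0("noncomplementary system but overhangs anneal in register ",
                           paste(comp, collapse = ",")))
    if (length(msg)) msg else TRUE
  })

#' A candidate repair event explaining one junction
#'
#' Describes, on the final junction's top-strand coordinates, the minimal
#' processing that converts the two assay ends into the observed sequence:
#' per-strand trims at each end, inserted bases, the annealing (pairing)
#' register, microhomology at the joint, templated-fill flags, and the count
#' of tolerated mismatches inside the pairing.
#'
#' Trim slots: \code{trimLeftProt}/\code{trimRightProt} remove nucleotides from
#' the 3' terminus of the protruding strand of the left (top) and right
#' (bottom) end; \code{trimLeftRec}/\code{trimRightRec} remove from the
#' recessed strands.  \code{insertionTop} holds top-strand bases attributable
#' to neither parent.  \code{mhLen} is the maximal contiguous run of junction
#' bases attributable to both parents at the joint.  \code{pairingLen} is the
#' physical annealing overlap between the retained left top strand and the
#' retained right bottom strand.  \code{bottomFill} counts bottom-strand
#' positions synthesised de novo.
#' @export
setClass("JunctionExplanation",
  representation(trimLeftProt = "integer", trimLeftRec = "integer",
                 trimRightProt = "integer", trimRightRec = "integer",
                 insertionTop = "character",
                 mhLen = "integer", pairingLen = "integer",
                 mismatchesInPairing = "integer",
                 templatedTop = "logical", templatedBottom = "logical",
                 bottomFill = "integer", cost = "integer",
                 mmrPositions = "integer"),
  validity = function(object) {
    msg <- character(0)
    trims <- c(object@trimLeftProt, object@trimLeftRec,
               object@trimRightProt, object@trimRightRec)
    if (any(trims < 0L)) msg <- c(msg, "trims must be >= 0")
    if (object@mismatchesInPairing > 1L)
      msg <- c(msg, "at most one tolerated mismatch in the pairing")
    if (length(msg)) msg else TRUE
  })
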