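## Annealing registers: two facing 3' overhangs can pair at their tips in
## register k (k terminal bases of each) iff the last k bases of the left
## (top-strand) overhang equal the first k bases of the reverse complement of
## the right (bottom-strand) overhang.
.usableRegisters <- function(leftOv, rightOv) {
  rcR <- .revcomp(rightOv)
  n <- min(nchar(leftOv), nchar(rcR))
  which(vapply(seq_len(n), function(k) {
    substr(leftOv, nchar(leftOv) - k + 1L, nchar(leftOv)) == substr(rcR, 1L, k)
  }, logical(1)))
}

#' Annealing registers of two facing overhangs
#'
#' Returns the registers (numbers of terminal bases) in which the two 3'
#' overhangs of an assay can anneal with full Watson-Crick pairing.  A
#' partially-complementary assay has at least one usable register; a
#' non-complementary assay has none.
#' @param assay a [TranslocationAssay-class].
#' @return integer vector of usable registers (possibly empty).
#' @export
usableRegisters <- function(assay) {
  stopifnot(is(assay, "TranslocationAssay"))
  .usableRegisters(assay@leftEnd@overhang, assay@rightEnd@overhang)
}

#' Construct a DSB end
#'
#' @param side \code{"left"} or \code{"right"} relative to the junction.
#' @param duplexTop top-strand context (for a left end, ends with the
#'   overhang; for a right end, starts at the recessed top terminus).
#' @param overhang overhang sequence 5'->3' on the protruding strand.
#' @return a [DsbEnd-class].
#' @export
dsbEnd <- function(side, duplexTop, overhang) {
  new("DsbEnd", side = side,
      duplexTop = .checkDna(toupper(duplexTop), "duplexTop"),
      overhang = .checkDna(toupper(overhang), "overhang"),
      overhangStrand = if (side == "left") "top" else "bottom")
}

#' Construct a translocation assay
#'
#' @param name assay identifier.
#' @param system \code{"partial"}, \code{"noncomp"} or \code{"cis"}.
#' @param leftEnd,rightEnd the two [DsbEnd-class] objects.
#' @param leftAnchor,rightAnchor fixed outer context used to validate
#'   junctions (defaults: outer 12 nt of each end context).
#' @param maxDeletion,maxInsertion explanation search bounds (nt).
#' @return a [TranslocationAssay-class].
#' @export
translocationAssay <- function(name, system, leftEnd, rightEnd,
                               leftAnchor = substr(leftEnd@duplexTop, 1L, 12L),
                               rightAnchor = substr(rightEnd@duplexTop,
                                                    nchar(rightEnd@duplexTop) - 11L,
                                                    nchar(rightEnd@duplexTop)),
                               maxDeletion = 25L, maxInsertion = 6L) {
  obj <- new("TranslocationAssay", name = name, system = system,
             leftEnd = leftEnd, rightEnd = rightEnd,
             leftAnchor = toupper(leftAnchor), rightAnchor = toupper(rightAnchor),
             maxDeletion = as.integer(maxDeletion),
             maxInsertion = as.integer(maxInsertion))
  validObject(obj)
  obj
}

#' @describeIn translocationAssay assay system accessor.
#' @param assay a [TranslocationAssay-class].
#' @export
assaySystem <- function(assay) assay@system

#' Load an assay configuration file
#'
#' Reads a YAML assay definition (end contexts, overhangs, anchors, bounds and
#' an optional karyotype block) and returns a validated assay.  The
#' complementarity class declared in the file is checked against the overhang
#' sequences: a \code{partial} assay must anneal in at least one register, a
#' \code{noncomp} assay in none.
#'
#' @param path path to the configuration file.
#' @return a [TranslocationAssay-class]; any karyotype block is attached as
#'   \code{attr(x, "karyotype")} (see [karyotypeModel()]).
#' @examples
#' assay <- loadAssay(system.file("extdata", "assay_partial.yaml",
#'                                package = "nhejTransloc"))
#' usableRegisters(assay)
#' @export
loadAssay <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (fld in c("name", "system", "left_end", "right_end"))
    if (is.null(cfg[[fld]])) stop("assay config missing field '", fld, "'", call. = FALSE)
  left <- dsbEnd("left", cfg$left_end$duplex_top, cfg$left_end$overhang)
  right <- dsbEnd("right", cfg$right_end$duplex_top, cfg$right_end$overhang)
  expected <- cfg$overhang_length %||% 4L
  if (nchar(left@overhang) != expected || nchar(right@overhang) != expected)
    stop("overhang length differs from configured length (", expected, ")",
         call. = FALSE)
  assay <- translocationAssay(
    name = cfg$name, system = cfg$system, leftEnd = left, rightEnd = right,
    leftAnchor = cfg$left_anchor %||% substr(left@duplexTop, 1L, 12L),
    rightAnchor = cfg$right_anchor %||%
      substr(right@duplexTop, nchar(right@duplexTop) - 11L, nchar(right@duplexTop)),
    maxDeletion = cfg$max_deletion %||% 25L,
    maxInsertion = cfg$max_insertion %||% 6L)
  if (!is.null(cfg$karyotype)) {
    chroms <- do.call(rbind, lapply(cfg$karyotype$chromosomes, function(x)
      data.frame(name = x$name, lengthKb = x$length_kb, breakKb = x$break_kb)))
    pairs <- do.call(rbind, lapply(cfg$karyotype$translocants, function(x)
      data.frame(name = x$name, leftOf = x$left_of, rightOf = x$right_of)))
    attr(assay, "karyotype") <- karyotypeModel(chroms, pairs)
  }
  assay
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in assay definitions
#'
#' Loads one of the assay configurations shipped with the package:
#' \code{"partial"} (HO x I-SceI ends with partially complementary 4-nt 3'
#' overhangs) or \code{"noncomp"} (the I-SceI site inverted, giving completely
#' non-complementary overhangs).  End and flank sequences are synthetic
#' reconstructions consistent with the assays' published repair signatures;
#' see the package vignette.
#' @param name \code{"partial"} or \code{"noncomp"}.
#' @return a [TranslocationAssay-class].
#' @export
builtinAssay <- function(name = c("partial", "noncomp")) {
  name <- match.arg(name)
  loadAssay(system.file("extdata", paste0("assay_", name, ".yaml"),
                        package = "nhejTransloc", mustWork = TRUE))
}

setMethod("show", "CutSiteSpec", function(object) {
  cat("CutSiteSpec", object@name, "\n  recognition:", object@recognition,
      "\n  scissions (top/bottom, 0-based):", object@topCut, "/", object@bottomCut,
      "-> 3' overhang of", object@topCut - object@bottomCut, "nt\n")
})

setMethod("show", "DsbEnd", function(object) {
  cat("DsbEnd (", object@side, " end)\n  duplexTop: ", object@duplexTop,
      "\n  3' overhang (", object@overhangStrand, " strand): ",
      object@overhang, "\n", sep = "")
})

setMethod("show", "TranslocationAssay", function(object) {
  regs <- usableRegisters(object)
  cat("TranslocationAssay '", object@name, "' (", object@system, ")\n",
      "  left  end: ...", substr(object@leftEnd@duplexTop,
                                 max(1L, nchar(object@leftEnd@duplexTop) - 14L),
                                 nchar(object@leftEnd@duplexTop)),
      "  [3' overhang ", object@leftEnd@overhang, "]\n",
      "  right end: ", substr(object@rightEnd@duplexTop, 1L, 15L),
      "...  [3' overhang ", object@rightEnd@overhang, " on bottom]\n",
      "  annealing registers: ",
      if (length(regs)) paste(regs, collapse = ",") else "none",
      "\n  bounds: deletion <= ", object@maxDeletion,
      " nt, insertion <= ", object@maxInsertion, " nt\n", sep = "")
})
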