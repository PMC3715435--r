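#' Construct a cut-site specification
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (top strand, A/C/G/T).
#' @param topCut,bottomCut 0-based scission offsets on the top-strand
#'   coordinate system; a 3' overhang of length \code{topCut - bottomCut}
#'   is produced when \code{topCut > bottomCut}.
#' @return A [CutSiteSpec-class] object.
#' @examples
#' sceI <- cutSiteSpec("I-SceI", "TAGGGATAACAGGGTAAT", topCut = 9, bottomCut = 5)
#' overhangLength(sceI)
#' @export
cutSiteSpec <- function(name, recognition, topCut, bottomCut) {
  new("CutSiteSpec", name = name,
      recognition = .checkDna(toupper(recognition), "recognition"),
      topCut = as.integer(topCut), bottomCut = as.integer(bottomCut))
}

#' @describeIn cutSiteSpec length of the 3' overhang the cut leaves
#'   (positive for 3'-protruding ends).
#' @param site a [CutSiteSpec-class].
#' @export
overhangLength <- function(site) site@topCut - site@bottomCut

#' Apply a staggered cut to a duplex
#'
#' Cuts a duplex (given as its top strand) at the unique occurrence of the
#' recognition sequence, returning the two broken ends.  The left end carries
#' the bases between the bottom and top scissions as a top-strand 3' overhang;
#' the right end carries their reverse complement as a bottom-strand 3'
#' overhang.  Re-ligating the two ends with full annealing and no edits
#' reconstructs the input exactly.
#'
#' @param duplexTop duplex top strand containing the recognition site once.
#' @param site a [CutSiteSpec-class] with \code{topCut > bottomCut}.
#' @return A list with elements \code{left} and \code{right}, both
#'   [DsbEnd-class] objects.
#' @examples
#' sceI <- cutSiteSpec("I-SceI", "TAGGGATAACAGGGTAAT", topCut = 9, bottomCut = 5)
#' ends <- applyCut(paste0("GGCC", sceI@recognition, "TTAA"), sceI)
#' ends$left@overhang   # "ATAA"
#' @export
applyCut <- function(duplexTop, site) {
  stopifnot(is(site, "CutSiteSpec"))
  duplexTop <- .checkDna(toupper(duplexTop), "duplexTop")
  if (overhangLength(site) <= 0L)
    stop("unsupported-overhang: cut must leave a 3' overhang (topCut > bottomCut)",
         call. = FALSE)
  hits <- gregexpr(site@recognition, duplexTop, fixed = TRUE)[[1]]
  if (length(hits) != 1L || hits[1] == -1L)
    stop("ambiguous-cut: recognition sequence must occur exactly once (found ",
         if (hits[1] == -1L) 0L else length(hits), ")", call. = FALSE)
  off <- hits[1] - 1L                         # 0-based start of recognition
  topAbs <- off + site@topCut
  botAbs <- off + site@bottomCut
  n <- nchar(duplexTop)
  if (botAbs < 1L || topAbs > n - 1L)
    stop("cut falls at the duplex boundary; extend the flanking context",
         call. = FALSE)
  ovSeq <- substr(duplexTop, botAbs + 1L, topAbs)
  left <- new("DsbEnd", side = "left",
              duplexTop = substr(duplexTop, 1L, topAbs),
              overhang = ovSeq, overhangStrand = "top")
  right <- new("DsbEnd", side = "right",
               duplexTop = substr(duplexTop, topAbs + 1L, n),
               overhang = .revcomp(ovSeq), overhangStrand = "bottom")
  validObject(left); validObject(right)
  list(left = left, right = right)
}

#' Religate two ends with full annealing and no edits
#'
#' The identity control for [applyCut()]: complementary overhangs anneal over
#' their full length and the nicks are sealed, reconstructing the parental
#' top strand.
#' @param left,right [DsbEnd-class] objects from the same cut.
#' @return the religated top strand.
#' @export
religate <- function(left, right) {
  stopifnot(is(left, "DsbEnd"), is(right, "DsbEnd"))
  if (left@overhang != .revcomp(right@overhang))
    stop("overhangs are not fully complementary; religation is not defined",
         call. = FALSE)
  paste0(left@duplexTop, right@duplexTop)
}

#' Load cut-site specifications from a YAML file
#'
#' @param path configuration path; default: the specifications shipped with
#'   the package (I-SceI and HO).
#' @return named list of [CutSiteSpec-class] objects.
#' @export
loadCutSites <- function(path = system.file("extdata", "cutsites.yaml",
                                            package = "nhejTransloc",
                                            mustWork = TRUE)) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg$sites, function(s)
    cutSiteSpec(s$name, s$recognition, s$top_cut, s$bottom_cut))
  stats::setNames(out, vapply(cfg$sites, `[[`, character(1), "name"))
}
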