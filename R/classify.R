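#' Repair-type labels of the mechanistic taxonomy
#'
#' The partially-complementary system distinguishes four junction classes:
#' Type I (gap-filling-mediated: intact overhangs, short tip pairing, small
#' gaps filled by templated insertion), Type II (microhomology-mediated:
#' >= 4-nt microhomology between one overhang and flanking sequence of the
#' other end, with deletion), Type III (direct ligation with no gap-filling:
#' terminal nucleotides removed, >= 3-bp pairing tolerating one internal
#' mismatch), and Type IV (end-bridging: one protruding strand degraded, the
#' junction sealed by synthesis templated by the intact opposite overhang).
#' The non-complementary system distinguishes Type I (gap-filling on both
#' strands), Type II (microhomology plus gap-filling on one strand) and
#' Type III (microhomology with no gap-filling).
#'
#' @param system \code{"partial"} or \code{"noncomp"}.
#' @return named character vector: labels \code{I..IV} (partial) or
#'   \code{I..III} (noncomp) with their descriptions.
#' @export
repairTypeLabels <- function(system = c("partial", "noncomp")) {
  system <- match.arg(system)
  if (system == "partial")
    c(I = "Gap-filling-mediated",
      II = "MH-mediated",
      III = "Direct ligation with no gap-filling",
      IV = "End-bridging")
  else
    c(I = "Gap-filling (2-strands)",
      II = "MH-mediated and Gap-filling (1-strand)",
      III = "MH-mediated no Gap-filling")
}

#' Classify a repair explanation into the mechanistic taxonomy
#'
#' Deterministic decision tree over the explanation's geometry.  Precedence
#' when several clauses hold: I > III > IV > II (partial) and I > II > III
#' (non-complementary), preferring interpretations that preserve more end
#' structure.
#'
#' @param explanation a [JunctionExplanation-class].
#' @param assay the [TranslocationAssay-class] the explanation refers to.
#' @return type label (\code{"I"}..\code{"IV"}) or \code{NA_character_} when
#'   the explanation fits no clause of its system.
#' @export
classifyExplanation <- function(explanation, assay) {
  stopifnot(is(explanation, "JunctionExplanation"),
            is(assay, "TranslocationAssay"))
  e <- explanation
  ov <- nchar(assay@leftEnd@overhang)
  ins <- nchar(e@insertionTop)
  trims0 <- e@trimLeftProt == 0L && e@trimLeftRec == 0L &&
    e@trimRightProt == 0L && e@trimRightRec == 0L
  sys <- if (assay@system == "partial") "partial" else "noncomp"

  if (sys == "partial") {
    if (trims0 && ins > 0L && e@templatedTop &&
        (e@bottomFill == 0L || e@templatedBottom))
      return("I")
    if (ins == 0L &&
        e@trimLeftProt <= 1L && e@trimRightProt <= 1L &&
        e@trimLeftProt + e@trimRightProt >= 1L &&
        e@trimLeftRec == 0L && e@trimRightRec == 0L &&
        e@pairingLen >= 3L && e@mismatchesInPairing <= 1L)
      return("III")
    if ((e@trimLeftProt >= ov - 1L && e@trimRightProt == 0L &&
         e@trimRightRec == 0L && ins > 0L && e@templatedTop &&
         e@pairingLen <= 1L) ||
        (e@trimRightProt >= ov - 1L && e@trimLeftProt == 0L &&
         e@trimLeftRec == 0L && ins == 0L && e@bottomFill > 0L &&
         e@templatedBottom && e@pairingLen <= 1L))
      return("IV")
    if (ins == 0L && e@mhLen >= 4L &&
        (e@trimRightRec > 0L || e@trimLeftRec > 0L ||
         e@trimRightProt > ov || e@trimLeftProt > ov))
      return("II")
    return(NA_character_)
  }

  ## non-complementary system
  anneal <- e@pairingLen >= 1L || e@mhLen >= 1L
  if (trims0 && ins > 0L && e@templatedTop &&
      e@bottomFill > 0L && e@templatedBottom)
    return("I")
  if (anneal && xor(ins > 0L, e@bottomFill > 0L))
    return("II")
  if (anneal && ins == 0L && e@bottomFill == 0L)
    return("III")
  NA_character_
}

#' Classify one junction
#'
#' Enumerates all explanations, selects the most parsimonious
#' ([rankExplanations()]), and classifies it.  A junction is
#' \emph{unclassifiable} when no explanation exists within bounds or the
#' winning explanation fits no taxonomy clause; it is \emph{ambiguous} when
#' co-optimal explanations map to different repair types.
#'
#' @param junction junction top strand (character).
#' @param assay a [TranslocationAssay-class].
#' @param id optional junction identifier.
#' @return list with elements \code{id}, \code{type}, \code{explanation}
#'   (or NULL), \code{alternates} (co-optimal count), \code{ambiguous},
#'   \code{unclassifiable}.
#' @export
classifyJunction <- function(junction, assay, id = NA_character_) {
  cands <- enumerateExplanations(junction, assay)
  if (!length(cands))
    return(list(id = id, type = NA_character_, explanation = NULL,
                alternates = 0L, ambiguous = FALSE, unclassifiable = TRUE))
  best <- rankExplanations(cands)
  co <- attr(best, "coOptimal")
  type <- classifyExplanation(best, assay)
  ambiguous <- FALSE
  if (co > 1L) {
    types <- vapply(cands[seq_len(co)], classifyExplanation, character(1),
                    assay = assay)
    ambiguous <- length(unique(types)) > 1L
  }
  list(id = id, type = type, explanation = best, alternates = co,
       ambiguous = ambiguous, unclassifiable = is.na(type))
}

#' Classify a cohort of junctions
#'
#' @param junctions named character vector of junction top strands (names are
#'   junction ids), or a \code{DNAStringSet}.
#' @param assay a [TranslocationAssay-class]; all junctions must belong to it.
#' @return list with \code{perJunction} (data.frame: id, type, cost, trims,
#'   insertion, mh, pairing, mismatches, templated flags, alternates, flags)
#'   and \code{distribution} (a [typeDistribution()] over classified
#'   junctions; unclassifiable/ambiguous are reported separately and excluded
#'   from percentages).
#' @export
classifyCohort <- function(junctions, assay) {
  if (is(junctions, "DNAStringSet"))
    junctions <- stats::setNames(as.character(junctions), names(junctions))
  if (is.null(names(junctions)) || any(!nzchar(names(junctions))))
    names(junctions) <- paste0("jct", seq_along(junctions))
  emptyRow <- data.frame(
    id = character(0), type = character(0), cost = integer(0),
    trimLeftProt = integer(0), trimLeftRec = integer(0),
    trimRightProt = integer(0), trimRightRec = integer(0),
    insertion = character(0), mhLen = integer(0), pairingLen = integer(0),
    mismatches = integer(0), templatedTop = logical(0),
    templatedBottom = logical(0), alternates = integer(0),
    ambiguous = logical(0), stringsAsFactors = FALSE)
  rows <- lapply(seq_along(junctions), function(k) {
    cl <- classifyJunction(junctions[[k]], assay, id = names(junctions)[k])
    e <- cl$explanation
    data.frame(
      id = cl$id, type = ifelse(is.na(cl$type), "unclassifiable", cl$type),
      cost = if (is.null(e)) NA_integer_ else e@cost,
      trimLeftProt = if (is.null(e)) NA_integer_ else e@trimLeftProt,
      trimLeftRec = if (is.null(e)) NA_integer_ else e@trimLeftRec,
      trimRightProt = if (is.null(e)) NA_integer_ else e@trimRightProt,
      trimRightRec = if (is.null(e)) NA_integer_ else e@trimRightRec,
      insertion = if (is.null(e)) NA_character_ else e@insertionTop,
      mhLen = if (is.null(e)) NA_integer_ else e@mhLen,
      pairingLen = if (is.null(e)) NA_integer_ else e@pairingLen,
      mismatches = if (is.null(e)) NA_integer_ else e@mismatchesInPairing,
      templatedTop = if (is.null(e)) NA else e@templatedTop,
      templatedBottom = if (is.null(e)) NA else e@templatedBottom,
      alternates = cl$alternates, ambiguous = cl$ambiguous,
      stringsAsFactors = FALSE)
  })
  perJunction <- if (length(rows)) do.call(rbind, rows) else emptyRow
  keep <- !perJunction$ambiguous & perJunction$type != "unclassifiable"
  counts <- table(factor(perJunction$type[keep],
                         levels = names(repairTypeLabels(
                           if (assay@system == "partial") "partial" else "noncomp"))))
  dist <- typeDistribution(as.integer(counts), names(counts),
                           system = if (assay@system == "partial") "partial" else "noncomp")
  dist$unclassifiable <- sum(perJunction$type == "unclassifiable")
  dist$ambiguous <- sum(perJunction$ambiguous)
  list(perJunction = perJunction, distribution = dist)
}

#' Repair-type distribution of a cohort
#'
#' Counts are ground truth; percentages are rendered from them by rounding to
#' the nearest integer (half away from zero).  An empty cohort has undefined
#' percentages (NA).
#'
#' @param counts integer vector of per-type counts.
#' @param types type labels (default: taxonomy labels for \code{system}).
#' @param system \code{"partial"} or \code{"noncomp"}.
#' @return object of class \code{"typeDistribution"}: list with \code{types},
#'   \code{counts}, \code{n}, \code{percent}.
#' @examples
#' typeDistribution(c(16, 5, 2, 1))$percent   # 67 21 8 4
#' @export
typeDistribution <- function(counts, types = NULL,
                             system = c("partial", "noncomp")) {
  system <- match.arg(system)
  if (is.null(types)) types <- names(repairTypeLabels(system))
  counts <- as.integer(counts)
  if (length(counts) != length(types))
    stop("counts and types lengths differ", call. = FALSE)
  if (any(counts < 0L)) stop("negative counts", call. = FALSE)
  n <- sum(counts)
  pct <- if (n == 0L) rep(NA_real_, length(counts))
         else .roundHalfUp(100 * counts / n)
  structure(list(types = types, counts = stats::setNames(counts, types),
                 n = n, percent = stats::setNames(pct, types),
                 system = system, unclassifiable = 0L, ambiguous = 0L),
            class = "typeDistribution")
}

#' @export
print.typeDistribution <- function(x, ...) {
  cat("Repair-type distribution (", x$system, " system), n = ", x$n, "\n", sep = "")
  if (x$n == 0L) { cat("  (empty cohort; percentages undefined)\n"); return(invisible(x)) }
  for (t in x$types)
    cat(sprintf("  Type %-4s %3d%% (%d)\n", t, x$percent[[t]], x$counts[[t]]))
  if (x$unclassifiable) cat("  unclassifiable:", x$unclassifiable, "\n")
  if (x$ambiguous) cat("  ambiguous:", x$ambiguous, "\n")
  invisible(x)
}
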