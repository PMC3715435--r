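#' Read junctions from FASTA
#'
#' One record per translocant (id = record name).  When an assay is supplied,
#' records are validated: alphabet restricted to A/C/G/T, length at least the
#' two anchors, and the top strand must begin with the left anchor and end
#' with the right anchor.  Rejected records are dropped with a message and
#' listed in the \code{"rejected"} attribute (id, reason).
#'
#' @param path FASTA file path.
#' @param assay optional [TranslocationAssay-class] for validation.
#' @return named character vector of junction top strands; attribute
#'   \code{"rejected"} holds a data.frame of dropped records.
#' @export
readJunctions <- function(path, assay = NULL) {
  xs <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(xs)))
    stop("duplicate junction ids in ", path, call. = FALSE)
  seqs <- toupper(as.character(xs))
  ids <- names(xs)
  reasons <- character(length(seqs))
  reasons[grepl("[^ACGT]", seqs)] <- "alphabet-violation"
  if (!is.null(assay)) {
    tooShort <- !nzchar(reasons) &
      nchar(seqs) < nchar(assay@leftAnchor) + nchar(assay@rightAnchor)
    reasons[tooShort] <- "shorter-than-anchors"
    bad <- !nzchar(reasons) &
      !(startsWith(seqs, assay@leftAnchor) & endsWith(seqs, assay@rightAnchor))
    reasons[bad] <- "anchor-missing"
  }
  keep <- !nzchar(reasons)
  rejected <- data.frame(id = ids[!keep], reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    message("rejected ", nrow(rejected), " junction(s): ",
            paste(rejected$id, rejected$reason, sep = ":", collapse = ", "))
  out <- stats::setNames(seqs[keep], ids[keep])
  attr(out, "rejected") <- rejected
  out
}

#' Write junctions to FASTA
#'
#' @param junctions named character vector (or a cohort data.frame from
#'   [simulateCohort()], using its \code{id} and \code{seq} columns).
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeJunctions <- function(junctions, path) {
  if (is.data.frame(junctions))
    junctions <- stats::setNames(junctions$seq, junctions$id)
  xs <- Biostrings::DNAStringSet(junctions)
  Biostrings::writeXStringSet(xs, path, width = 80L)
  invisible(path)
}

.renderPercentCell <- function(percent, count) {
  if (is.na(percent)) "nd" else sprintf("%d%% (%d)", percent, count)
}

#' Render a repair-type summary row
#'
#' One strain row in the published table layout: cohort size then
#' \code{"percent\% (count)"} per type.
#' @param dist a [typeDistribution()].
#' @param strain strain name for the first column.
#' @return data.frame with one row.
#' @export
renderTypeRow <- function(dist, strain = "cohort") {
  stopifnot(inherits(dist, "typeDistribution"))
  cells <- vapply(dist$types, function(t)
    .renderPercentCell(dist$percent[[t]], dist$counts[[t]]), character(1))
  out <- data.frame(strain = strain, sequenced = dist$n, stringsAsFactors = FALSE)
  for (t in dist$types) out[[paste0("type", t)]] <- cells[[t]]
  out
}

#' Write the classification report
#'
#' Writes (1) a per-junction TSV with the chosen explanation of every
#' junction, (2) a summary TSV row in the published table layout, and (3) a
#' JSON file with full detail.  Output is byte-stable for identical input.
#'
#' @param classified result of [classifyCohort()].
#' @param prefix output path prefix; files \code{<prefix>_junctions.tsv},
#'   \code{<prefix>_summary.tsv}, \code{<prefix>.json} are written.
#' @param strain strain label for the summary row.
#' @param seed seed recorded in the report header (NA to omit).
#' @return character vector of the paths written, invisibly.
#' @export
writeReport <- function(classified, prefix, strain = "cohort", seed = NA) {
  pj <- paste0(prefix, "_junctions.tsv")
  ps <- paste0(prefix, "_summary.tsv")
  pJson <- paste0(prefix, ".json")
  hdr <- sprintf("# nhejTransloc report; seed=%s", as.character(seed))
  con <- file(pj, "w"); writeLines(hdr, con)
  utils::write.table(classified$perJunction, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  con <- file(ps, "w"); writeLines(hdr, con)
  utils::write.table(renderTypeRow(classified$distribution, strain), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(seed = seed, strain = strain,
         distribution = list(types = classified$distribution$types,
                             counts = classified$distribution$counts,
                             n = classified$distribution$n,
                             percent = classified$distribution$percent,
                             unclassifiable = classified$distribution$unclassifiable,
                             ambiguous = classified$distribution$ambiguous),
         junctions = classified$perJunction),
    pJson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(junctions = pj, summary = ps, json = pJson))
}

#' Simulate, classify and report in one pass
#'
#' End-to-end driver: simulates a cohort under a strain profile, round-trips
#' it through FASTA, classifies it, and (optionally) writes the report files.
#' Deterministic for fixed (profile, n, assay, seed).
#'
#' @param profile a [strainProfile()] or the name of a default profile.
#' @param n cohort size.
#' @param assay a [TranslocationAssay-class] or a built-in assay name.
#' @param seed integer seed.
#' @param dir optional output directory; when given, FASTA, truth TSV and the
#'   report files are written there.
#' @return list with \code{cohort} (simulated data.frame), \code{classified}
#'   (see [classifyCohort()]), \code{truthAgreement} (proportion of junctions
#'   whose call equals the generating mechanism) and \code{files}.
#' @export
runPipeline <- function(profile, n, assay, seed = 1L, dir = NULL) {
  if (is.character(assay)) assay <- builtinAssay(assay)
  sys <- if (assay@system == "partial") "partial" else "noncomp"
  if (is.character(profile)) profile <- strainProfiles(sys)[[profile]]
  cohort <- simulateCohort(profile, n, assay, seed = seed)
  junctions <- stats::setNames(cohort$seq, cohort$id)
  files <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, paste0(profile$name, ".fasta"))
    writeJunctions(cohort, fa)
    junctions <- readJunctions(fa, assay)
    tt <- file.path(dir, paste0(profile$name, "_truth.tsv"))
    utils::write.table(cohort[, c("id", "truth")], tt, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(fasta = fa, truth = tt)
  }
  classified <- classifyCohort(junctions, assay)
  calls <- stats::setNames(classified$perJunction$type, classified$perJunction$id)
  agree <- mean(calls[cohort$id] == cohort$truth)
  if (!is.null(dir)) {
    rep <- writeReport(classified, file.path(dir, profile$name),
                       strain = profile$name, seed = seed)
    files <- c(files, rep)
  }
  list(cohort = cohort, classified = classified,
       truthAgreement = agree, files = files)
}
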