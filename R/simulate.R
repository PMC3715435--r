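#' Strain profile: a repair-type mixture for cohort simulation
#'
#' @param name strain identifier.
#' @param typeProbs named numeric vector of repair-type probabilities
#'   (names from [repairTypeLabels()]); must sum to 1 within 1e-9.
#' @param system \code{"partial"} or \code{"noncomp"}.
#' @param mmrResolutionProb probability that the tolerated pairing mismatch
#'   of a partial-system Type III junction is resolved to the left-end allele
#'   by mismatch repair.
#' @return object of class \code{"strainProfile"}.
#' @export
strainProfile <- function(name, typeProbs, system = c("partial", "noncomp"),
                          mmrResolutionProb = 0.5) {
  system <- match.arg(system)
  labels <- names(repairTypeLabels(system))
  if (!setequal(names(typeProbs), labels))
    stop("typeProbs must be named over types ", paste(labels, collapse = ","),
         call. = FALSE)
  typeProbs <- typeProbs[labels]
  if (abs(sum(typeProbs) - 1) > 1e-9)
    stop("type probabilities must sum to 1", call. = FALSE)
  if (mmrResolutionProb < 0 || mmrResolutionProb > 1)
    stop("mmrResolutionProb must be in [0,1]", call. = FALSE)
  structure(list(name = name, system = system, typeProbs = typeProbs,
                 mmrResolutionProb = mmrResolutionProb),
            class = "strainProfile")
}

## Printed per-genotype event counts of the two systems; probabilities of the
## default profiles are counts/n.
.PARTIAL_COUNTS <- list(
  "WT" = c(I = 16, II = 5, III = 2, IV = 1),
  "pol4d" = c(I = 0, II = 12, III = 8, IV = 1),
  "pol4d_POL4" = c(I = 24, II = 2, III = 9, IV = 0),
  "pol4d_pol4-D367A,D369A" = c(I = 0, II = 3, III = 12, IV = 2),
  "pol4d_pol4-dBRCT" = c(I = 0, II = 7, III = 9, IV = 2),
  "pol4d_pol4-T64A" = c(I = 26, II = 0, III = 5, IV = 4),
  "pol4d_pol4-T540A" = c(I = 13, II = 6, III = 10, IV = 7),
  "tel1d" = c(I = 9, II = 6, III = 4, IV = 8),
  "tel1d_pol4d" = c(I = 6, II = 4, III = 10, IV = 3),
  "tel1d_pol4d_POL4" = c(I = 13, II = 7, III = 7, IV = 3),
  "tel1d_pol4d_pol4-T540A" = c(I = 8, II = 6, III = 11, IV = 5))

.NONCOMP_COUNTS <- list(
  "WT" = c(I = 7, II = 18, III = 0),
  "pol4d" = c(I = 0, II = 7, III = 13),
  "pol4d_POL4" = c(I = 15, II = 11, III = 5),
  "pol4d_pol4-T64A" = c(I = 15, II = 11, III = 1),
  "pol4d_pol4-T540A" = c(I = 6, II = 12, III = 19))

#' Default strain profiles
#'
#' One profile per sequenced genotype of each assay system, with type
#' probabilities equal to the published per-type event counts divided by the
#' number of junctions sequenced.
#' @param system \code{"partial"} or \code{"noncomp"}.
#' @return named list of [strainProfile()] objects.
#' @export
strainProfiles <- function(system = c("partial", "noncomp")) {
  system <- match.arg(system)
  src <- if (system == "partial") .PARTIAL_COUNTS else .NONCOMP_COUNTS
  out <- lapply(names(src), function(nm)
    strainProfile(nm, src[[nm]] / sum(src[[nm]]), system = system))
  stats::setNames(out, names(src))
}

#' Published per-type junction counts
#'
#' @param system \code{"partial"} or \code{"noncomp"}.
#' @return named list of integer count vectors per genotype.
#' @export
strainCounts <- function(system = c("partial", "noncomp")) {
  system <- match.arg(system)
  if (system == "partial") .PARTIAL_COUNTS else .NONCOMP_COUNTS
}

#' Microhomology sites between an overhang tail and the opposing flank
#'
#' Positions (in the right end's top-sense content, bottom-overhang region
#' excluded) where the last \code{len} retained bases of the left end's
#' protruding strand match the right end's sequence, within the deletion
#' bound.  These are the annealing sites available to microhomology-mediated
#' repair.
#'
#' @param assay a [TranslocationAssay-class].
#' @param len microhomology length (1..overhang length).
#' @param trimLeftProt bases already removed from the left protruding strand
#'   (the tail is taken from the retained sequence).
#' @return integer vector of right-end deletion sizes (right top-strand 5'
#'   trims) at which the tail anneals; empty if none.
#' @export
findMicrohomologySites <- function(assay, len, trimLeftProt = 0L) {
  ctx <- .assayContext(assay)
  a <- ctx$nL - trimLeftProt
  tail <- substr(ctx$L, a - len + 1L, a)
  if (nchar(tail) < len) return(integer(0))
  out <- integer(0)
  maxTRr <- min(ctx$maxDel, ctx$nR - ctx$rAnch)
  for (tRr in seq_len(maxTRr)) {          # x = ov + tRr; flank sites only
    x <- ctx$ov + tRr
    if (x - len + 1L >= ctx$ov + 1L &&
        substr(ctx$rightExt, x - len + 1L, x) == tail)
      out <- c(out, tRr)
  }
  out
}

## Effective annealing length at a microhomology site: starting from the
## junction-proximal end of the left ssDNA, the longest pairing block with at
## most one internal mismatch (the tolerance the explanation engine applies).
## A Type II (one-strand-fill) site must NOT pair across the whole overhang,
## otherwise the junction is mechanistically a no-fill event.
.effectivePairing <- function(ctx, tRr, trimLeftProt = 0L) {
  a <- ctx$nL - trimLeftProt
  ss <- min(ctx$ov - trimLeftProt, ctx$ov)       # left ssDNA length
  x <- ctx$ov + tRr
  v <- vapply(0:(ss - 1L), function(j)
    substr(ctx$L, a - j, a - j) == substr(ctx$rightExt, x - j, x - j),
    logical(1))
  best <- 0L
  for (k in seq_len(ss))
    if (v[k] && sum(!v[seq_len(k)]) <= 1L) best <- k
  best
}

#' Simulate one junction under a given repair mechanism
#'
#' Executes the mechanism literally on the assay ends: anneal at the
#' type-specific register, trim, fill templated gaps, ligate.  Deterministic
#' for a fixed seed.
#'
#' @param type repair-type label, valid for the assay system.
#' @param assay a [TranslocationAssay-class].
#' @param profile a [strainProfile()] (supplies the mismatch-repair
#'   resolution probability; defaults to the WT profile of the system).
#' @param seed integer seed (NULL: use current RNG state).
#' @return list with \code{seq} (junction top strand), \code{truth} (type),
#'   and \code{detail} (mechanism parameters drawn).
#' @export
simulateJunction <- function(type, assay, profile = NULL, seed = NULL) {
  sys <- if (assay@system == "partial") "partial" else "noncomp"
  if (!type %in% names(repairTypeLabels(sys)))
    stop("type ", type, " is not valid for the ", sys, " system", call. = FALSE)
  if (is.null(profile))
    profile <- strainProfiles(sys)[["WT"]]
  ctx <- .assayContext(assay)
  .withSeed(seed, {
    detail <- list()
    seq <- if (sys == "partial") {
      switch(type,
        I = {  # tip pairing in a usable register, templated fill of the gaps
          regs <- usableRegisters(assay)
          regs <- regs[regs < ctx$ov]
          if (!length(regs)) stop("no usable partial register for Type I", call. = FALSE)
          k <- if (length(regs) > 1L) sample(regs, 1L) else regs
          detail$register <- k
          paste0(ctx$L, substr(ctx$rightExt, k + 1L, ctx$ov), ctx$R)
        },
        II = {  # full-overhang microhomology in the opposing flank
          sites <- findMicrohomologySites(assay, ctx$ov)
          if (!length(sites))
            stop("configuration error: no >=", ctx$ov,
                 "-nt microhomology site in this assay", call. = FALSE)
          tRr <- if (length(sites) > 1L) sample(sites, 1L) else sites
          detail$deletion <- tRr
          paste0(ctx$L, substr(ctx$R, tRr + 1L, ctx$nR))
        },
        III = {  # trim both 3' termini, 3-bp pairing, mismatch repair
          a <- ctx$nL - 1L
          j <- paste0(substr(ctx$L, 1L, a), ctx$R)
          lo <- a + 2L - ctx$ov            # pairing after trimming 1+1
          mmPos <- Filter(function(q) {
            x <- q - a + ctx$ov            # rightExt index under position q
            substr(ctx$L, q, q) != substr(ctx$rightExt, x, x)
          }, seq(max(lo, ctx$nL - ctx$ov + 1L), a))
          resolved <- "left"
          if (length(mmPos) && stats::runif(1) > profile$mmrResolutionProb) {
            resolved <- "right"
            jc <- .chars(j)
            for (q in mmPos) {
              x <- q - a + ctx$ov
              jc[q] <- substr(ctx$rightExt, x, x)
            }
            j <- paste(jc, collapse = "")
          }
          detail$mmrResolved <- resolved
          j
        },
        IV = {  # blunt the left protruding strand, synthesise across the
                # intact right overhang, ligate
          paste0(substr(ctx$L, 1L, ctx$nL - ctx$ov),
                 substr(ctx$rightExt, 1L, ctx$ov), ctx$R)
        })
    } else {
      switch(type,
        I = {  # no pairing possible: bridge and fill both strands
          paste0(ctx$L, substr(ctx$rightExt, 1L, ctx$ov), ctx$R)
        },
        II = {  # m-nt microhomology of the intact overhang tail in the
                # opposing flank; the remaining overhang bases leave a
                # one-strand gap that is filled
          siteOf <- function(m) Filter(function(tRr)
            .effectivePairing(ctx, tRr) < ctx$ov,   # must leave a gap to fill
            findMicrohomologySites(assay, m))
          avail <- Filter(function(m) length(siteOf(m)) > 0, seq_len(ctx$ov - 1L))
          if (!length(avail))
            stop("configuration error: no microhomology site for Type II", call. = FALSE)
          m <- if (length(avail) > 1L) sample(avail, 1L) else avail
          sites <- siteOf(m)
          tRr <- if (length(sites) > 1L) sample(sites, 1L) else sites
          detail$mh <- m; detail$deletion <- tRr
          paste0(ctx$L, substr(ctx$R, tRr + 1L, ctx$nR))
        },
        III = {  # trim the overhang to m bases that anneal fully: no fill
          avail <- Filter(function(m)
            length(findMicrohomologySites(assay, m, trimLeftProt = ctx$ov - m)) > 0,
            seq_len(ctx$ov - 1L))
          if (!length(avail))
            stop("configuration error: no microhomology site for Type III", call. = FALSE)
          m <- if (length(avail) > 1L) sample(avail, 1L) else avail
          sites <- findMicrohomologySites(assay, m, trimLeftProt = ctx$ov - m)
          tRr <- if (length(sites) > 1L) sample(sites, 1L) else sites
          detail$mh <- m; detail$deletion <- tRr
          paste0(substr(ctx$L, 1L, ctx$nL - (ctx$ov - m)),
                 substr(ctx$R, tRr + 1L, ctx$nR))
        })
    }
    ## self-check: emitted junction must span the anchors and the alphabet
    stopifnot(startsWith(seq, assay@leftAnchor), endsWith(seq, assay@rightAnchor))
    list(seq = .checkDna(seq, "simulated junction"), truth = type, detail = detail)
  })
}

#' Simulate a cohort of junctions under a strain profile
#'
#' Types are drawn i.i.d. from the profile's mixture; each junction is then
#' generated on its own RNG substream (derived from \code{seed} and the
#' junction index), so cohorts are reproducible regardless of iteration
#' order.
#'
#' @param profile a [strainProfile()].
#' @param n cohort size (>= 0).
#' @param assay a [TranslocationAssay-class] matching the profile's system.
#' @param seed integer seed.
#' @return data.frame with columns \code{id}, \code{truth}, \code{seq}.
#' @export
simulateCohort <- function(profile, n, assay, seed = 1L) {
  stopifnot(inherits(profile, "strainProfile"), n >= 0)
  sys <- if (assay@system == "partial") "partial" else "noncomp"
  if (profile$system != sys)
    stop("profile system (", profile$system, ") does not match assay (", sys, ")",
         call. = FALSE)
  if (n == 0L)
    return(data.frame(id = character(0), truth = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  types <- .withSeed(seed,
    sample(names(profile$typeProbs), n, replace = TRUE, prob = profile$typeProbs))
  sims <- lapply(seq_len(n), function(k)
    simulateJunction(types[k], assay, profile, seed = .subSeed(seed, k)))
  data.frame(id = sprintf("%s_%03d", profile$name, seq_len(n)),
             truth = vapply(sims, `[[`, character(1), "truth"),
             seq = vapply(sims, `[[`, character(1), "seq"),
             stringsAsFactors = FALSE)
}

#' Simulate a plating experiment
#'
#' Colony counts for the frequency assay: the pre-induction plate counts all
#' \code{nCells} cells; survivors and selected translocants are binomial
#' draws with the given true per-cell probabilities.
#'
#' @param trueFreq true translocation frequency per plated cell (0..1).
#' @param nCells number of cells assayed (>= 0).
#' @param seed integer seed.
#' @param trueSurvival true survival probability (default 1).
#' @return a [platingExperiment()] with unit dilutions.
#' @export
simulatePlating <- function(trueFreq, nCells, seed = NULL, trueSurvival = 1) {
  if (trueFreq < 0 || trueFreq > 1) stop("trueFreq must be in [0,1]", call. = FALSE)
  if (nCells < 0) stop("nCells must be >= 0", call. = FALSE)
  .withSeed(seed, {
    platingExperiment(
      coloniesSC = nCells,
      coloniesSGal = stats::rbinom(1L, nCells, trueSurvival),
      coloniesSGalLeu = stats::rbinom(1L, nCells, trueFreq))
  })
}
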