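#' A plating experiment (colony counts with dilutions)
#'
#' Counts of colonies on the pre-induction nonselective plate (SC), the
#' post-induction nonselective plate (SGal) and the selective plate
#' (SGal-Leu), with the dilution factor applied to each aliquot (cells =
#' colonies x dilution).  Dilutions default to 1 and must be supplied
#' explicitly otherwise.
#'
#' @param coloniesSC,coloniesSGal,coloniesSGalLeu non-negative colony counts.
#' @param dilutionSC,dilutionSGal,dilutionSGalLeu positive scale factors.
#' @return object of class \code{"platingExperiment"}.
#' @export
platingExperiment <- function(coloniesSC, coloniesSGal, coloniesSGalLeu,
                              dilutionSC = 1, dilutionSGal = 1,
                              dilutionSGalLeu = 1) {
  counts <- c(coloniesSC, coloniesSGal, coloniesSGalLeu)
  dils <- c(dilutionSC, dilutionSGal, dilutionSGalLeu)
  if (any(counts < 0)) stop("colony counts must be >= 0", call. = FALSE)
  if (any(dils <= 0)) stop("dilution factors must be > 0", call. = FALSE)
  structure(list(coloniesSC = coloniesSC, coloniesSGal = coloniesSGal,
                 coloniesSGalLeu = coloniesSGalLeu,
                 dilutionSC = dilutionSC, dilutionSGal = dilutionSGal,
                 dilutionSGalLeu = dilutionSGalLeu),
            class = "platingExperiment")
}

#' Survival and translocation frequency of a plating experiment
#'
#' Survival is the dilution-corrected ratio of SGal to SC colonies;
#' translocation frequency the ratio of SGal-Leu to SC colonies.  Pure
#' arithmetic, exact.  The intrachromosomal (in-cis) assay uses the same
#' estimator with 5-FOA-resistant colonies in place of SGal-Leu.
#'
#' @param exp a [platingExperiment()].
#' @return list with \code{survival} and \code{translocFreq}.
#' @examples
#' frequencies(platingExperiment(1000, 500, 0))$survival   # 0.5
#' @export
frequencies <- function(exp) {
  stopifnot(inherits(exp, "platingExperiment"))
  total <- exp$coloniesSC * exp$dilutionSC
  if (total <= 0)
    stop("undefined-frequency: zero total cells on the SC plate", call. = FALSE)
  list(survival = (exp$coloniesSGal * exp$dilutionSGal) / total,
       translocFreq = (exp$coloniesSGalLeu * exp$dilutionSGalLeu) / total)
}

#' Summarise replicate frequencies
#'
#' The headline summary of replicate experiments is the median (with the
#' standard deviation alongside).
#' @param x numeric vector of replicate frequencies (>= 1 value).
#' @return list with \code{n}, \code{median}, \code{sd}.
#' @export
summarizeReplicates <- function(x) {
  if (!length(x)) stop("at least one replicate required", call. = FALSE)
  list(n = length(x), median = stats::median(x),
       sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
}

#' Fold change between two medians
#'
#' The ratio of the larger to the smaller median, reported as
#' \code{"N-fold increase"}/\code{"decrease"} relative to the reference.
#' Rounding: nearest integer below 100, one significant figure at or above
#' 100.
#'
#' @param refMedian,testMedian positive medians (reference first).
#' @return list with \code{ratio} (exact), \code{rounded}, \code{direction}
#'   (\code{"increase"}, \code{"decrease"} or \code{"none"}) and
#'   \code{label}.
#' @examples
#' foldChange(0.27, 0.01)$label    # "27-fold decrease"
#' foldChange(1.49, 0.005)$label   # "300-fold decrease"
#' @export
foldChange <- function(refMedian, testMedian) {
  if (refMedian <= 0 || testMedian <= 0)
    stop("undefined fold change: medians must be > 0", call. = FALSE)
  ratio <- max(refMedian, testMedian) / min(refMedian, testMedian)
  rounded <- if (ratio < 100) .roundHalfUp(ratio) else signif(ratio, 1)
  direction <- if (testMedian > refMedian) "increase"
               else if (testMedian < refMedian) "decrease" else "none"
  label <- if (direction == "none") sprintf("%d-fold", as.integer(rounded))
           else sprintf("%s-fold %s", format(rounded, scientific = FALSE), direction)
  list(ratio = ratio, rounded = rounded, direction = direction, label = label)
}

#' Mann-Whitney comparison of two replicate groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact permutation
#' p-value when the smaller group has at most 8 observations and there are no
#' ties, tie-corrected normal approximation otherwise.
#'
#' @param groupA,groupB numeric vectors (each >= 1 value).
#' @return list with \code{U} (statistic for group A), \code{p} (two-sided)
#'   and \code{exact}.
#' @examples
#' mannWhitney(1:4, 10:13)$p    # 2/choose(8,4)
#' @export
mannWhitney <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  exact <- min(length(groupA), length(groupB)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(groupA, groupB, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Chi-square comparison of two repair-type distributions
#'
#' Pearson chi-square on the 2 x k counts table with no continuity
#' correction; categories empty in both groups are dropped.  Degrees of
#' freedom are (categories - 1); a warning flag is raised when any expected
#' count falls below 5.
#'
#' @param a,b [typeDistribution()] objects (or named count vectors) over the
#'   same categories.
#' @return list with \code{chi2}, \code{df}, \code{p},
#'   \code{expectedBelow5}.
#' @export
compareTypeDistributions <- function(a, b) {
  getCounts <- function(x) {
    if (inherits(x, "typeDistribution")) x$counts
    else if (!is.null(names(x))) x
    else stop("counts must be named or a typeDistribution", call. = FALSE)
  }
  ca <- getCounts(a); cb <- getCounts(b)
  if (!identical(names(ca), names(cb)))
    stop("category mismatch between the two distributions", call. = FALSE)
  if (sum(ca) < 1 || sum(cb) < 1)
    stop("each distribution needs n >= 1", call. = FALSE)
  m <- rbind(ca, cb)
  m <- m[, colSums(m) > 0, drop = FALSE]
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expectedBelow5 = any(ct$expected < 5))
}

#' Compare strains end to end
#'
#' Convenience wrapper: medians, fold change and Mann-Whitney p for two
#' groups of replicate frequencies.
#' @param refFreqs,testFreqs replicate frequency vectors.
#' @return list with \code{refMedian}, \code{testMedian}, \code{fold}
#'   (see [foldChange()]) and \code{test} (see [mannWhitney()]).
#' @export
compareFrequencies <- function(refFreqs, testFreqs) {
  ref <- summarizeReplicates(refFreqs)
  tst <- summarizeReplicates(testFreqs)
  list(refMedian = ref$median, testMedian = tst$median,
       fold = foldChange(ref$median, tst$median),
       test = mannWhitney(refFreqs, testFreqs))
}
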