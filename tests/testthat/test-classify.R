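rcOv <- function(assay) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(assay@rightEnd@overhang)))

test_that("canonical partial-system signatures classify to their types", {
  L <- partialAssay@leftEnd@duplexTop
  R <- partialAssay@rightEnd@duplexTop
  # Type I: intact overhangs, 2-nt tip pairing, templated +CA fill
  expect_equal(classifyJunction(paste0(L, "CA", R), partialAssay)$type, "I")
  # Type I in the 1-nt pairing register (+ACA fill)
  expect_equal(classifyJunction(paste0(L, "ACA", R), partialAssay)$type, "I")
  # Type III: one terminal base trimmed from each protruding strand,
  # 3-bp pairing with one internal mismatch, no insertion
  cl3 <- classifyJunction(paste0(substr(L, 1, nchar(L) - 1), R), partialAssay)
  expect_equal(cl3$type, "III")
  expect_equal(cl3$explanation@pairingLen, 3L)
  expect_equal(cl3$explanation@mismatchesInPairing, 1L)
  # Type IV: one protruding strand degraded, synthesis across the intact
  # opposite overhang
  j4 <- paste0(substr(L, 1, nchar(L) - 4), rcOv(partialAssay), R)
  expect_equal(classifyJunction(j4, partialAssay)$type, "IV")
  # Type II: 4-nt microhomology with deletion
  s <- findMicrohomologySites(partialAssay, 4L)[1]
  j2 <- paste0(L, substr(R, s + 1, nchar(R)))
  cl2 <- classifyJunction(j2, partialAssay)
  expect_equal(cl2$type, "II")
  expect_false(cl2$ambiguous)
})

test_that("the mismatch-repair flipped Type III allele classifies identically", {
  # force both resolutions through the simulator
  pLeft <- strainProfile("mmrL", c(I = 0, II = 0, III = 1, IV = 0),
                         "partial", mmrResolutionProb = 1)
  pRight <- strainProfile("mmrR", c(I = 0, II = 0, III = 1, IV = 0),
                          "partial", mmrResolutionProb = 0)
  jL <- simulateJunction("III", partialAssay, pLeft, seed = 1)$seq
  jR <- simulateJunction("III", partialAssay, pRight, seed = 1)$seq
  expect_false(identical(jL, jR))          # the two post-repair alleles differ
  expect_equal(classifyJunction(jL, partialAssay)$type, "III")
  expect_equal(classifyJunction(jR, partialAssay)$type, "III")
})

test_that("canonical noncomplementary-system signatures classify to their types", {
  L <- noncompAssay@leftEnd@duplexTop
  R <- noncompAssay@rightEnd@duplexTop
  # Type I: both overhangs intact, templated fill across the junction on
  # both strands
  cn1 <- classifyJunction(paste0(L, rcOv(noncompAssay), R), noncompAssay)
  expect_equal(cn1$type, "I")
  expect_true(cn1$explanation@templatedTop && cn1$explanation@templatedBottom)
  # Type II and III via the simulator's annealing-site search
  for (tp in c("II", "III")) for (sd in 1:5) {
    sim <- simulateJunction(tp, noncompAssay, seed = sd)
    expect_equal(classifyJunction(sim$seq, noncompAssay)$type, tp)
  }
})

test_that("noise-free simulated cohorts recover the generating distribution", {
  wt <- strainProfiles("partial")$WT
  cohort <- simulateCohort(wt, 24L, partialAssay, seed = 9)
  cl <- classifyCohort(stats::setNames(cohort$seq, cohort$id), partialAssay)
  calls <- stats::setNames(cl$perJunction$type, cl$perJunction$id)
  expect_identical(unname(calls[cohort$id]), cohort$truth)
  truth <- table(factor(cohort$truth, levels = c("I", "II", "III", "IV")))
  expect_equal(unname(cl$distribution$counts), as.integer(truth))
})

test_that("cohort distributions render published-style percentages", {
  d <- typeDistribution(c(16L, 5L, 2L, 1L))
  expect_equal(unname(d$percent), c(67, 21, 8, 4))
  expect_equal(d$n, 24L)
  # empty cohort: undefined percentages, zero counts
  d0 <- typeDistribution(c(0L, 0L, 0L, 0L))
  expect_equal(d0$n, 0L)
  expect_true(all(is.na(d0$percent)))
})

test_that("unclassifiable junctions are reported, never dropped", {
  # an untemplated 6-nt insertion with trimmed ends fits no taxonomy clause
  L <- partialAssay@leftEnd@duplexTop
  R <- partialAssay@rightEnd@duplexTop
  j <- paste0(substr(L, 1, nchar(L) - 6), "CCCCCC", substr(R, 7, nchar(R)))
  cl <- classifyJunction(j, partialAssay)
  expect_true(cl$unclassifiable)
  cc <- classifyCohort(c(a = paste0(L, "CA", R), b = j), partialAssay)
  expect_equal(nrow(cc$perJunction), 2L)
  expect_equal(cc$distribution$unclassifiable, 1L)
  expect_equal(cc$distribution$n, 1L)     # excluded from percentages
})
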