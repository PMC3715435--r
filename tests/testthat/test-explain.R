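test_that("a perfectly religated control junction has the zero-edit explanation", {
  # build a control assay whose overhangs are fully complementary
  sceI <- loadCutSites()[["I-SceI"]]
  duplex <- paste0("CCTGAGTCAAGTTCGG", sceI@recognition, "TTGACCTGAGGTCAAC")
  ends <- applyCut(duplex, sceI)
  ctrl <- translocationAssay("ctrl", "partial", ends$left, ends$right)
  ex <- enumerateExplanations(duplex, ctrl)
  expect_gt(length(ex), 0L)
  best <- rankExplanations(ex)
  expect_equal(best@cost, 0L)
  expect_equal(best@pairingLen, 4L)
  expect_equal(best@mismatchesInPairing, 0L)
  expect_equal(nchar(best@insertionTop), 0L)
})

test_that("the templated +CA junction is explained with intact ends", {
  j <- paste0(partialAssay@leftEnd@duplexTop, "CA",
              partialAssay@rightEnd@duplexTop)
  best <- rankExplanations(enumerateExplanations(j, partialAssay))
  expect_equal(best@trimLeftProt + best@trimLeftRec +
               best@trimRightProt + best@trimRightRec, 0L)
  expect_equal(best@insertionTop, "CA")
  expect_true(best@templatedTop)
  expect_equal(best@pairingLen, 2L)
  # the complementary-strand gap is filled too: the published +AT signature
  expect_equal(best@bottomFill, 2L)
  expect_true(best@templatedBottom)
})

test_that("enumeration equals the independent brute-force string search", {
  set.seed(101)
  for (assay in list(partialAssay, noncompAssay))
    for (k in 1:60) {
      J <- randomJunction(assay)
      got <- familyKeys(enumerateExplanations(J, assay))
      expect_identical(got, bruteForceFamilies(J, assay))
    }
})

test_that("every emitted explanation satisfies the reconstruction identity", {
  set.seed(202)
  for (assay in list(partialAssay, noncompAssay))
    for (k in 1:40) {
      J <- randomJunction(assay)
      for (e in enumerateExplanations(J, assay))
        expect_identical(reconstructJunction(e, assay), J)
    }
})

test_that("ranking equals an independent argmin and is deterministic", {
  set.seed(303)
  for (k in 1:150) {
    assay <- if (k %% 2) partialAssay else noncompAssay
    J <- randomJunction(assay)
    cands <- enumerateExplanations(J, assay)
    if (!length(cands)) next
    w1 <- rankExplanations(cands)
    w2 <- rankExplanations(rev(cands))       # order of candidates irrelevant
    expect_identical(explKey(w1), explKey(oracleBest(cands)))
    expect_identical(explKey(w1), explKey(w2))
  }
})

test_that("a 4-nt microhomology beats an equal-cost untemplated reading", {
  sites <- findMicrohomologySites(partialAssay, 4L)
  expect_gt(length(sites), 0L)
  j <- paste0(partialAssay@leftEnd@duplexTop,
              substr(partialAssay@rightEnd@duplexTop, sites[1] + 1L,
                     nchar(partialAssay@rightEnd@duplexTop)))
  best <- rankExplanations(enumerateExplanations(j, partialAssay))
  expect_gte(best@mhLen, 4L)
  expect_equal(nchar(best@insertionTop), 0L)
})

test_that("raising the bounds never removes an explanation", {
  shrink <- function(assay, del, ins) {
    translocationAssay(assay@name, assay@system, assay@leftEnd, assay@rightEnd,
                       leftAnchor = assay@leftAnchor,
                       rightAnchor = assay@rightAnchor,
                       maxDeletion = del, maxInsertion = ins)
  }
  set.seed(404)
  for (k in 1:25) {
    J <- randomJunction(partialAssay, maxTrim = 5L, maxIns = 3L)
    small <- familyKeys(enumerateExplanations(J, shrink(partialAssay, 8L, 3L)))
    large <- familyKeys(enumerateExplanations(J, shrink(partialAssay, 20L, 6L)))
    expect_true(all(small %in% large))
  }
})

test_that("malformed junctions are rejected with reasons", {
  expect_error(enumerateExplanations("ACGT", partialAssay), "malformed-input")
  j <- paste0("TTTTTTTTTTTT", substr(partialAssay@leftEnd@duplexTop, 13L, 39L),
              partialAssay@rightEnd@duplexTop)
  expect_error(enumerateExplanations(j, partialAssay), "anchor-missing")
})
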