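test_that("cohort simulation is seed-deterministic and respects n", {
  wt <- strainProfiles("partial")$WT
  a <- simulateCohort(wt, 12L, partialAssay, seed = 5)
  b <- simulateCohort(wt, 12L, partialAssay, seed = 5)
  expect_identical(a, b)
  c <- simulateCohort(wt, 12L, partialAssay, seed = 6)
  expect_false(identical(a$seq, c$seq))
  expect_equal(nrow(simulateCohort(wt, 0L, partialAssay, seed = 5)), 0L)
})

test_that("type III with forced left resolution loses exactly 2 nt and inserts none", {
  p <- strainProfile("x", c(I = 0, II = 0, III = 1, IV = 0), "partial",
                     mmrResolutionProb = 1)
  sim <- simulateJunction("III", partialAssay, p, seed = 3)
  e <- rankExplanations(enumerateExplanations(sim$seq, partialAssay))
  expect_equal(e@trimLeftProt + e@trimRightProt, 2L)   # one from each 3' end
  expect_equal(nchar(e@insertionTop), 0L)
  refLen <- nchar(partialAssay@leftEnd@duplexTop) +
    nchar(partialAssay@rightEnd@duplexTop)
  expect_equal(nchar(sim$seq), refLen - 1L)            # top strand 1 nt short
})

test_that("simulated junctions always reconstruct under the classifier", {
  for (sys in c("partial", "noncomp")) {
    assay <- if (sys == "partial") partialAssay else noncompAssay
    for (tp in names(repairTypeLabels(sys)))
      for (sd in 1:4) {
        sim <- simulateJunction(tp, assay, seed = sd)
        ex <- enumerateExplanations(sim$seq, assay)
        expect_gt(length(ex), 0L)
        expect_identical(reconstructJunction(rankExplanations(ex), assay), sim$seq)
      }
  }
})

test_that("invalid types and mismatched profiles are rejected", {
  expect_error(simulateJunction("IV", noncompAssay), "not valid")
  wtN <- strainProfiles("noncomp")$WT
  expect_error(simulateCohort(wtN, 5L, partialAssay, seed = 1), "match")
  expect_error(strainProfile("x", c(I = 0.5, II = 0.6, III = 0, IV = 0),
                             "partial"), "sum to 1")
})

test_that("plating simulation obeys its trivial limits", {
  expect_equal(simulatePlating(0, 1000L, seed = 1)$coloniesSGalLeu, 0L)
  expect_equal(simulatePlating(1, 1000L, seed = 1)$coloniesSGalLeu, 1000L)
  expect_error(simulatePlating(0.5, -3L), ">= 0")
})

test_that("default strain profiles reproduce the published mixtures", {
  wt <- strainProfiles("partial")$WT
  expect_equal(unname(wt$typeProbs), c(16, 5, 2, 1) / 24)
  wtN <- strainProfiles("noncomp")$WT
  expect_equal(unname(wtN$typeProbs), c(7, 18, 0) / 25)
})
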