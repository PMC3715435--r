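test_that("I-SceI cut yields 4-nt 3' overhangs and religation round-trips", {
  sites <- loadCutSites()
  sceI <- sites[["I-SceI"]]
  expect_equal(overhangLength(sceI), 4L)
  duplex <- paste0("GGCCTTAACC", sceI@recognition, "AATTGGCCAA")
  ends <- applyCut(duplex, sceI)
  expect_equal(nchar(ends$left@overhang), 4L)
  expect_equal(nchar(ends$right@overhang), 4L)
  expect_equal(ends$left@overhang, "ATAA")
  expect_equal(religate(ends$left, ends$right), duplex)
})

test_that("HO cut matches the assay right-end geometry", {
  ho <- loadCutSites()[["HO"]]
  duplex <- paste0("CCGGAA", ho@recognition, "ATAACGGTTC")
  ends <- applyCut(duplex, ho)
  expect_equal(ends$left@overhang, "AACA")
  expect_equal(ends$right@overhang, "TGTT")   # bottom strand, 5'->3'
  expect_true(startsWith(ends$right@duplexTop, "GTATA"))
})

test_that("degenerate and ambiguous cuts are rejected", {
  blunt <- cutSiteSpec("blunt", "GGATCC", topCut = 3, bottomCut = 3)
  expect_error(applyCut("AAAGGATCCTTT", blunt), "unsupported-overhang")
  sceI <- loadCutSites()[["I-SceI"]]
  expect_error(applyCut("AAAACCCC", sceI), "ambiguous-cut")
  expect_error(applyCut(paste0("AA", sceI@recognition, sceI@recognition, "TT"),
                        sceI), "ambiguous-cut")
})

test_that("cut/religate identity holds for random duplexes with one site", {
  sceI <- loadCutSites()[["I-SceI"]]
  set.seed(11)
  n <- 0L
  while (n < 50L) {
    duplex <- paste0(randomSeq(25), sceI@recognition, randomSeq(25))
    # skip the rare second accidental occurrence
    if (length(gregexpr(sceI@recognition, duplex, fixed = TRUE)[[1]]) != 1L) next
    ends <- applyCut(duplex, sceI)
    expect_identical(religate(ends$left, ends$right), duplex)
    n <- n + 1L
  }
})

test_that("the two overhangs of one cut are reverse complements", {
  set.seed(5)
  for (k in 1:20) {
    rec <- randomSeq(12)
    site <- cutSiteSpec("rnd", rec, topCut = 8, bottomCut = 4)
    duplex <- paste0(randomSeq(10), rec, randomSeq(10))
    if (length(gregexpr(rec, duplex, fixed = TRUE)[[1]]) != 1L) next
    ends <- applyCut(duplex, site)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ends$right@overhang)))
    expect_identical(ends$left@overhang, rc)
  }
})
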