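test_that("local AU content counts A/T in truncated flanks, excluding N", {
  # pure-AU and pure-GC flanks
  expect_equal(auContent(paste0(strrep("A", 35), "GGGGGG", strrep("A", 35)),
                         35, 41), 1.0)
  expect_equal(auContent(paste0(strrep("GC", 20), "AAAAAA", strrep("GC", 20)),
                         40, 46), 0.0)
  # LRP6 worked example: flanks "ACGTACG" + "TACGT" carry 6 AU of 12
  expect_equal(auContent(LRP6_WT, 7, 14), 6 / 12)
  # site spanning the whole UTR has no flank residues
  expect_true(is.na(auContent("TTGCCAA", 0, 7)))
  # N residues drop out of numerator and denominator:
  # left flank "NN" contributes nothing, right flank "AGG" gives 1 of 3
  expect_equal(auContent("NNATTGCCAAGG", 2, 9), 1 / 3)
})

test_that("AU content is invariant under G<->C and flips under AT<->GC", {
  set.seed(21)
  for (i in 1:10) {
    utr <- random_dna(120)
    a <- auContent(utr, 50, 57)
    expect_equal(auContent(chartr("GC", "CG", utr), 50, 57), a)
    expect_equal(auContent(chartr("ATGC", "GCAT", utr), 50, 57), 1 - a)
  }
})

test_that("3'-supplementary pairing finds a planted complement run", {
  mir <- "UUUGGCAAUGGUAGAACUCACACU"
  # place revcomp(nt 12-17) so that miRNA position k pairs target
  # register - (k - 2): supplementary hexamer at [0,6), 3 spacer nt,
  # then the 7mer-m8 site at [9,16) with register 15
  supp <- revComp(substr(mir, 12, 17))
  utr <- paste0(supp, "GGG", seedMotifs(mir)[["7mer-m8"]], "ACGTACGT")
  gr <- scanUTR(c(m = mir), c(u = utr))
  reg <- S4Vectors::mcols(gr)$register0[1]
  expect_equal(threePrimePairing(mir, utr, reg), 6L)
})

test_that("3'-supplementary pairing is 0 without room or complementarity", {
  mir <- MIR182
  utr <- paste0(seedMotifs(mir)[["7mer-m8"]], "ACGTACGT")  # site at 0
  gr <- scanUTR(c(m = mir), c(u = utr))
  expect_equal(threePrimePairing(mir, utr,
                                 S4Vectors::mcols(gr)$register0[1]), 0L)
  utrN <- paste0(strrep("N", 30), seedMotifs(mir)[["7mer-m8"]], "ACGT")
  grN <- scanUTR(c(m = mir), c(u = utrN))
  expect_equal(threePrimePairing(mir, utrN,
                                 S4Vectors::mcols(grN)$register0[1]), 0L)
})

test_that("positional features follow the coordinate identities", {
  pf <- positionalFeatures(LRP6_WT, 7, 14)   # 19-nt UTR
  expect_equal(pf$dist_stop, 7L)
  expect_equal(pf$dist_end, 5L)
  expect_equal(pf$rel_pos, 5 / 19)
  expect_true(pf$near_stop)

  expect_equal(positionalFeatures(strrep("A", 30), 0, 6)$dist_stop, 0L)
  expect_equal(positionalFeatures(strrep("A", 30), 24, 30)$dist_end, 0L)
  expect_false(positionalFeatures(strrep("A", 40), 20, 26)$near_stop)
})

test_that("cooperative pairs obey the gap window", {
  # two 6-nt sites: [0,6) and [26,32) -> gap 20
  gr <- make_sites(c(0L, 26L), c(6L, 6L), 100L)
  pairs <- cooperativeSites(gr)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gap, 20L)

  far <- make_sites(c(0L, 106L), c(6L, 6L), 200L)
  expect_equal(nrow(cooperativeSites(far)), 0L)
  expect_equal(nrow(cooperativeSites(make_sites(0L, 6L, 100L))), 0L)

  mixed <- suppressWarnings(
    c(make_sites(0L, 6L, 100L, utr_id = "a"),
      make_sites(20L, 6L, 100L, utr_id = "b")))
  expect_error(cooperativeSites(mixed), "same UTR")
})

test_that("cooperative pairs match brute-force enumeration on random sites", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    starts <- sort(sample(0:180, n))
    lens <- sample(6:8, n, replace = TRUE)
    gr <- make_sites(starts, lens, 200L)
    got <- cooperativeSites(gr)
    # brute force over all unordered pairs
    exp_n <- 0L
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      gap <- if (starts[j] >= starts[i] + lens[i]) {
        starts[j] - (starts[i] + lens[i])
      } else if (starts[i] >= starts[j] + lens[j]) {
        starts[i] - (starts[j] + lens[j])
      } else -1L
      if (gap >= 8L && gap <= 40L) exp_n <- exp_n + 1L
    }
    expect_equal(nrow(got), exp_n)
    expect_true(all(got$gap >= 8L & got$gap <= 40L))
  }
})

test_that("annotation assembles all features and is pure", {
  mir <- MIR182
  motif <- seedMotifs(mir)[["7mer-m8"]]
  mirnas <- MiRNASet(c("hsa-miR-182-5p" = mir))

  # single site with pure-A flanks (the trailing A upgrades it to an 8mer)
  one <- Biostrings::DNAStringSet(
    c(u = paste0(strrep("A", 30), motif, strrep("A", 30))))
  s1 <- annotateSites(scanSeedSites(mirnas, one), mirnas, one)
  m1 <- as.data.frame(S4Vectors::mcols(s1))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$site_type, "8mer")
  expect_equal(m1$local_au, 1.0)
  expect_equal(m1$coop_partners, "")

  # two sites ~20 nt apart: cooperative partners, positional identity
  two <- Biostrings::DNAStringSet(
    c(u = paste0(strrep("A", 30), motif, strrep("A", 20), motif,
                 strrep("A", 30))))
  sites <- scanSeedSites(mirnas, two)
  ann <- annotateSites(sites, mirnas, two)
  mc <- as.data.frame(S4Vectors::mcols(ann))
  expect_equal(nrow(mc), 2L)
  expect_equal(mc$dist_stop + (mc$end0 - mc$start0) + mc$dist_end,
               rep(Biostrings::width(two)[1], 2))
  expect_true(all(mc$rel_pos <= 0.5))
  expect_equal(mc$coop_partners,
               c("hsa-miR-182-5p@57", "hsa-miR-182-5p@30"))
  expect_identical(annotateSites(sites, mirnas, two), ann)  # pure
})
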