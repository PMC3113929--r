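test_that("primer sites are found with exact and anchored matching", {
  set.seed(301)
  tmpl <- randomDna(600)
  fwd <- Primer("f", substr(tmpl, 1, 20), "forward")
  expect_identical(findPrimerSites(fwd, tmpl), 1L)
  rev <- Primer("r", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tmpl, 581, 600)))), "reverse")
  expect_identical(findPrimerSites(rev, tmpl), 581L)  # ends at template end
  ## one internal mismatch is tolerated only when allowed
  mm <- substr(tmpl, 101, 120)
  substr(mm, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                              substr(mm, 5, 5))[1]
  pm <- Primer("m", mm, "forward")
  expect_length(findPrimerSites(pm, tmpl, max_mismatch = 0), 0L)
  expect_identical(findPrimerSites(pm, tmpl, max_mismatch = 1), 101L)
  ## but never inside the 3'-terminal anchor
  mm3 <- substr(tmpl, 101, 120)
  substr(mm3, 19, 19) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mm3, 19, 19))[1]
  pm3 <- Primer("m3", mm3, "forward")
  expect_length(findPrimerSites(pm3, tmpl, max_mismatch = 1,
                                anchor_3prime = 3), 0L)
})

test_that("indel-spanning primers do not bind the copy lacking the indel", {
  fx <- referenceFixtures()
  fA <- fx$primers$ahfad2A$inner$fwd
  fB <- fx$primers$ahfad2B$inner$fwd
  expect_length(findPrimerSites(fA, fx$loci$ahfad2A), 1L)
  expect_length(findPrimerSites(fA, fx$loci$ahfad2B), 0L)
  expect_length(findPrimerSites(fB, fx$loci$ahfad2B), 1L)
  expect_length(findPrimerSites(fB, fx$loci$ahfad2A), 0L)
})

test_that("amplification produces the homeolog doublet or a single product", {
  fx <- referenceFixtures()
  outer <- fx$primers$arah2.01$outer   # shared across both albumin copies
  p1 <- amplify(fx$loci$arah2.01, outer$fwd, outer$rev)
  p2 <- amplify(fx$loci$arah2.02, outer$fwd, outer$rev)
  expect_length(p1, 1L); expect_length(p2, 1L)
  expect_false(ampliconLength(p1[[1]]) == ampliconLength(p2[[1]]))
  ## gene-specific inner pair amplifies only its own copy
  inner <- fx$primers$arah2.01$inner
  expect_length(amplify(fx$loci$arah2.02, inner$fwd, inner$rev), 0L)
  ## forward site downstream of the reverse site yields nothing
  swapped <- amplify(fx$loci$arah2.01, Primer("f", as.character(
    Biostrings::reverseComplement(fx$primers$arah2.01$inner$rev@seq)),
    "forward"), Primer("r", as.character(Biostrings::reverseComplement(
      fx$primers$arah2.01$inner$fwd@seq)), "reverse"))
  expect_length(swapped, 0L)
})

test_that("amplicons are exact substrings of their template", {
  fx <- referenceFixtures()
  for (g in names(fx$loci)) {
    amp <- fixtureAmplicons()[[g]]
    expect_identical(as.character(ampliconSeq(amp)),
                     as.character(Biostrings::subseq(
                       locusSeq(fx$loci[[g]]), amp@start, amp@end)))
    expect_identical(ampliconLength(amp),
                     amp@end - amp@start + 1L)
  }
})

test_that("nested amplification equals direct inner amplification", {
  fx <- referenceFixtures()
  for (g in names(fx$loci)) {
    sch <- fx$primers[[g]]
    nested <- nestedAmplify(fx$loci[[g]], sch$outer, sch$inner)
    direct <- amplify(fx$loci[[g]], sch$inner$fwd, sch$inner$rev)
    expect_length(direct, 1L)
    expect_identical(nested@start, direct[[1]]@start)
    expect_identical(nested@end, direct[[1]]@end)
    expect_identical(as.character(ampliconSeq(nested)),
                     as.character(ampliconSeq(direct[[1]])))
  }
  ## idempotence: inner pair equal to the outer pair
  sch <- fx$primers$arah2.01
  same <- nestedAmplify(fx$loci$arah2.01, sch$inner, sch$inner)
  direct <- amplify(fx$loci$arah2.01, sch$inner$fwd, sch$inner$rev)[[1]]
  expect_identical(same@start, direct@start)
  expect_identical(same@end, direct@end)
  ## inner primers binding outside the outer product raise a nesting error
  expect_error(nestedAmplify(fx$loci$arah1.01,
                             outer = fx$primers$arah1.01$inner,
                             inner = fx$primers$arah1.01$outer),
               "outer product")
})

test_that("fixture amplicon lengths match the screen design", {
  lens <- vapply(fixtureAmplicons(), ampliconLength, integer(1))
  expect_identical(lens[c("arah1.01", "arah1.02", "arah2.01", "arah2.02",
                          "ahfad2A", "ahfad2B")],
                   c(arah1.01 = 2211L, arah1.02 = 1666L,
                     arah2.01 = 1278L, arah2.02 = 1226L,
                     ahfad2A = 1228L, ahfad2B = 1221L))
})

test_that("homeolog specificity is validated per copy", {
  fx <- referenceFixtures()
  for (fam in names(fx$pairs)) {
    pair <- fx$pairs[[fam]]
    for (gm in pairCopies(pair)) {
      sch <- fx$primers[[geneId(gm)]]$inner
      rep <- checkSpecificity(pair, sch$fwd, sch$rev)
      expect_true(rep$pass)
      expect_identical(sum(rep$products > 0), 1L)
    }
  }
  ## primers binding both copies FAIL with a both-copy report
  outer <- fx$primers$arah2.01$outer
  rep <- checkSpecificity(fx$pairs$arah2, outer$fwd, outer$rev)
  expect_false(rep$pass)
  expect_identical(unname(rep$products), c(1L, 1L))
  ## primers binding neither copy FAIL with a zero-copy report
  alien <- Primer("x", strrep("ACGT", 5), "forward")
  alien_r <- Primer("y", strrep("TGCA", 5), "reverse")
  rep0 <- checkSpecificity(fx$pairs$arah2, alien, alien_r)
  expect_false(rep0$pass)
  expect_identical(unname(rep0$products), c(0L, 0L))
})

test_that("primer and amplicon tables round-trip to disk", {
  fx <- referenceFixtures()
  prs <- unlist(fx$primers$ahfad2A, recursive = FALSE)
  f <- tempfile(fileext = ".tsv")
  writePrimerTable(prs, f)
  back <- readPrimerTable(f)
  expect_length(back, length(prs))
  for (i in seq_along(prs)) {
    expect_identical(as.character(back[[i]]@seq),
                     as.character(prs[[i]]@seq))
    expect_identical(back[[i]]@orientation, prs[[i]]@orientation)
  }
  fa <- tempfile(fileext = ".fa")
  writeAmplicons(fixtureAmplicons(), fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_length(seqs, 6L)
  expect_match(names(seqs)[1], "arah1.01 \\d+-\\d+")
  unlink(c(f, fa))
})
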