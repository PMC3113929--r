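test_that("codon bookkeeping maps CDS positions to residues", {
  ci <- codonIndex(c(145L, 3L, 448L, 164L, 185L, 208L, 304L, 761L))
  expect_identical(ci$codon, c(49L, 1L, 150L, 55L, 62L, 70L, 102L, 254L))
  expect_identical(ci$offset, c(1L, 3L, 1L, 2L, 2L, 1L, 1L, 2L))
  expect_error(codonIndex(0L), "1-based")
})

test_that("coding substitutions are classified through the genetic code", {
  fx <- referenceFixtures()
  ## disrupted start codon
  e <- classifyMutation(fx$loci$arah2.02, 3L, "G", "A")
  expect_identical(e$effect_class, "start_loss")
  expect_identical(e$codon_index, 1L)
  ## premature stop: CGA -> TGA at the first base of codon 102,
  ## strictly 101 residues precede the stop
  e <- classifyMutation(fx$loci$arah1.02, 304L, "C", "T")
  expect_identical(e$effect_class, "nonsense")
  expect_identical(e$codon_index, 102L)
  expect_identical(e$truncated_length, 101L)
  ## missense with codon arithmetic through two introns
  e <- classifyMutation(fx$loci$arah1.01, 1392L, "C", "T")
  expect_identical(e$effect_class, "missense")
  expect_identical(e$codon_index, 333L)
  expect_identical(c(e$wt_aa, e$mut_aa), c("R", "W"))
  ## single-base insertion: frameshift
  e <- classifyMutation(fx$loci$ahfad2B, 442L, "A", "A", "insertion")
  expect_identical(e$effect_class, "frameshift")
  ## upstream and intron positions
  e <- classifyMutation(fx$loci$arah2.02, -315L, "G", "A")
  expect_identical(e$effect_class, "upstream")
  gm <- fx$loci$arah1.01
  ipos <- 640L  # inside intron 1
  iref <- as.character(Biostrings::subseq(locusSeq(gm),
                                          atgToLocus(ipos, gm),
                                          atgToLocus(ipos, gm)))
  alt <- setdiff(c("A", "C", "G", "T"), iref)[1]
  expect_identical(classifyMutation(gm, ipos, iref, alt)$effect_class,
                   "intron")
  ## reference inconsistency is an error
  expect_error(classifyMutation(fx$loci$arah1.02, 304L, "G", "T"),
               "reference mismatch")
  ## in-frame indels are not frameshifts
  e <- classifyMutation(fx$loci$ahfad2B, 442L, "A", "AAA", "insertion")
  expect_identical(e$effect_class, "inframe")
})

test_that("no substitution at codon position 2 can be silent", {
  ## enumerate all 61 sense codons in one synthetic CDS and mutate the
  ## middle base of each to every alternative
  bases <- c("A", "C", "G", "T")
  codons <- setdiff(as.vector(outer(outer(bases, bases, paste0), bases,
                                    paste0)), c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  gm <- GeneModel("all61", cds, 0L, IRanges::IRanges(1L, nchar(cds)))
  for (k in seq_along(codons)) {
    pos <- 3L + 3L * (k - 1L) + 2L          # middle base of codon k + 1
    ref <- substr(cds, pos, pos)
    for (alt in setdiff(bases, ref)) {
      e <- classifyMutation(gm, pos, ref, alt)
      expect_false(e$effect_class == "silent")
    }
  }
})

test_that("classification agrees with a full-CDS translate-and-diff oracle", {
  fx <- referenceFixtures()
  oracle <- function(gm, cds_pos, alt) {
    cds <- as.character(cdsSeq(gm))
    mut <- cds
    substr(mut, cds_pos, cds_pos) <- alt
    pw <- translateCds(cds); pm <- translateCds(mut)
    ci <- codonIndex(cds_pos)$codon
    if (ci == 1L && substr(mut, 1, 3) != "ATG") return("start_loss")
    aw <- substr(pw, ci, ci); am <- substr(pm, ci, ci)
    if (am == "*") "nonsense" else if (aw == am) "silent" else "missense"
  }
  set.seed(5)
  for (g in names(fx$loci)) {
    gm <- fx$loci[[g]]
    cds <- as.character(cdsSeq(gm))
    for (cds_pos in sample(nchar(cds) - 3L, 40)) {   # spare the stop codon
      ref <- substr(cds, cds_pos, cds_pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      atg <- locusToAtg(cdsToLocus(cds_pos, gm), gm)
      e <- classifyMutation(gm, atg, ref, alt)
      expect_identical(e$effect_class, oracle(gm, cds_pos, alt))
    }
  }
})

test_that("the mutation catalog is reproduced class-by-class", {
  fx <- referenceFixtures()
  eff <- classifyMutations(fx$loci, fx$mutations)
  consistent <- !eff$anomalous
  expect_identical(sum(consistent), 24L)
  expect_identical(eff$effect_class[consistent],
                   eff$predicted_class[consistent])
  ## the three anomalous rows cannot be reproduced by contiguous
  ## 1-based CDS numbering and are flagged, not forced
  expect_false(any(eff$effect_class[eff$anomalous] ==
                   eff$predicted_class[eff$anomalous]))
})

test_that("epitope overlap uses closed protein-coordinate intervals", {
  fx <- referenceFixtures()
  ep <- fx$epitopes$arah1.01
  expect_identical(epitopeOverlap(333L, ep), "12")
  expect_identical(epitopeOverlap(326L, ep), "12")   # boundary included
  expect_identical(epitopeOverlap(335L, ep), "12")
  expect_length(epitopeOverlap(336L, ep), 0L)
  expect_length(epitopeOverlap(1L, ep[0, ]), 0L)
  ## the D70N change falls in the second DPYSPS motif
  e <- classifyMutation(fx$loci$arah2.02, 208L, "G", "A")
  expect_identical(epitopeOverlap(e$codon_index, fx$epitopes$arah2.02),
                   "DPYSPS-2")
  ## R62Q lies just before the first motif
  e62 <- classifyMutation(fx$loci$arah2.02, 185L, "G", "A")
  expect_false("DPYSPS-1" %in%
               epitopeOverlap(e62$codon_index, fx$epitopes$arah2.02))
})

test_that("the substitution spectrum separates canonical from atypical", {
  fx <- referenceFixtures()
  sp <- spectrumSummary(fx$mutations)
  expect_identical(sp$total, 27L)
  expect_identical(sp$canonical, 22L)
  expect_identical(nrow(sp$atypical), 5L)
  expect_identical(sp$indel, 2L)
  expect_identical(sp$other_sub, 3L)     # the three A>G substitutions
  empty <- spectrumSummary(fx$mutations[0, ])
  expect_identical(empty$total, 0L)
  expect_identical(empty$canonical, 0L)
  one <- spectrumSummary(data.frame(ref = "A", alt = "G",
                                    kind = "substitution"))
  expect_identical(nrow(one$atypical), 1L)
})
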