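## a 10-kb single-exon locus for distributional checks: ATG + alternating
## filler (GC-rich enough for canonical placement) + terminal stop
bigLocus <- function() {
  body <- strrep("GCAGTC", 1662)   # 9972 bp, no stop codons in frame
  GeneModel("big", paste0("ATG", body, "TAA"), 0L,
            IRanges::IRanges(1L, 9978L))
}

test_that("zero density and zero contaminants give an empty population", {
  fx <- referenceFixtures()
  pop <- simulateM2(fx$loci, 10, MutagenesisParams(density = 0), seed = 1)
  expect_identical(nrow(genotypes(pop)), 0L)
  expect_length(individuals(pop), 10L)
})

test_that("the same seed reproduces the same population", {
  fx <- referenceFixtures()
  p1 <- simulateM2(fx$loci, 150, MutagenesisParams(density = 2e-5),
                   seed = 99)
  p2 <- simulateM2(fx$loci, 150, MutagenesisParams(density = 2e-5),
                   seed = 99)
  expect_identical(genotypes(p1), genotypes(p2))
  p3 <- simulateM2(fx$loci, 150, MutagenesisParams(density = 2e-5),
                   seed = 100)
  expect_false(identical(genotypes(p1), genotypes(p3)))
})

test_that("canonical mutations are exclusively G>A or C>T transitions", {
  gm <- bigLocus()
  pop <- simulateM2(list(big = gm), 300,
                    MutagenesisParams(density = 5e-5,
                                      canonical_fraction = 1), seed = 4)
  g <- genotypes(pop)
  expect_gt(nrow(g), 50)
  expect_true(all((g$ref == "G" & g$alt == "A") |
                  (g$ref == "C" & g$alt == "T")))
})

test_that("Mendelian transmission gives 2 het : 1 hom and 3/4 retention", {
  gm <- bigLocus()
  n <- 5000L
  density <- 1e-4
  pop <- simulateM2(list(big = gm), n, MutagenesisParams(density = density),
                    seed = 11)
  g <- genotypes(pop)
  tb <- table(factor(g$zygosity, c("het", "hom")))
  ## 1:2:1 segregation among retained mutations
  expect_gt(stats::chisq.test(tb, p = c(2 / 3, 1 / 3))$p.value, 0.01)
  ## realized retained density = induced density x 3/4, within 3 SE
  len <- length(locusSeq(gm))
  expected <- density * 0.75 * len * n
  expect_lt(abs(nrow(g) - expected), 3 * sqrt(expected))
})

test_that("contaminant alleles enter heterozygously at their frequency", {
  fx <- referenceFixtures()
  ct <- fx$contaminants
  ct$freq <- c(0.05, 0.05)
  pop <- simulateM2(fx$loci, 800,
                    MutagenesisParams(density = 0, contaminants = ct),
                    seed = 21)
  g <- genotypes(pop)
  expect_true(all(g$origin == "contaminant"))
  expect_true(all(g$zygosity == "het"))
  for (j in seq_len(nrow(ct))) {
    carriers <- sum(g$gene_id == ct$gene_id[j])
    expect_lt(abs(carriers - 800 * 0.05), 3 * sqrt(800 * 0.05 * 0.95))
  }
  ## the insertion contaminant carries its inserted string
  ins <- g[g$kind == "insertion", ]
  expect_true(all(ins$alt == "A"))
})

test_that("fixture generation is bit-stable across runs", {
  fx <- referenceFixtures()
  prefixes <- c(
    arah1.01 = "GGAATAGACGAAAAATTTGTGGGCGCTCCGCTTTGCTGCA",
    arah1.02 = "GGAATAGACGAAAAATTTGTGGGCACGAGAGGGTACTAAG",
    arah2.01 = "CACGAAGGTGAAGTGGTAAGTGATGGTCTTGCACGACTAG",
    arah2.02 = "CACGAAGGTGAAGTGGTAAGTGATAGGTATCCTCCTCGGG",
    ahfad2A  = "TAAGGGCATCGGCGAGCCTGGGGGCACCGATGCTGGATCA",
    ahfad2B  = "TAAGGGCATCGGCGAGCCTGGGGGCACCGATGCTGGATCA")
  lens <- c(arah1.01 = 2695L, arah1.02 = 2470L, arah2.01 = 1320L,
            arah2.02 = 1366L, ahfad2A = 1859L, ahfad2B = 1840L)
  for (g in names(prefixes)) {
    s <- as.character(locusSeq(fx$loci[[g]]))
    expect_identical(substr(s, 1, 40), unname(prefixes[g]))
    expect_identical(nchar(s), unname(lens[g]))
  }
  ## checksum over all six loci
  expect_identical(sum(vapply(fx$loci, function(m)
    sum(utf8ToInt(as.character(locusSeq(m)))), numeric(1))), 828201)
  ## and generation does not disturb the caller's RNG
  set.seed(123); before <- runif(1)
  .tillploid_fx <- referenceFixtures()
  set.seed(123); expect_identical(runif(1), before)
})

test_that("fixture pairs carry their discriminating indels", {
  fx <- referenceFixtures()
  ## 19-bp indel 80 bp upstream of the desaturase start codons
  feat <- fx$pairs$ahfad2@discriminating_features
  expect_identical(feat$position, -80L)
  expect_identical(feat$length, 19L)
  a <- fx$loci$ahfad2A; b <- fx$loci$ahfad2B
  expect_identical(upstreamLen(a) - upstreamLen(b), 19L)
  ## upstream sequence is identical outside the insertion
  ua <- as.character(Biostrings::subseq(locusSeq(a), 1, 320))
  ub <- as.character(Biostrings::subseq(locusSeq(b), 1, 320))
  expect_identical(ua, ub)
  ## the albumin-like pair differs by a 36-bp in-frame CDS insertion
  expect_identical(cdsLength(fx$loci$arah2.02) - cdsLength(fx$loci$arah2.01),
                   36L)
})

test_that("genotype tables are written in VCF-like form", {
  fx <- referenceFixtures()
  pop <- simulateM2(fx$loci, 25, MutagenesisParams(density = 5e-5),
                    seed = 8)
  f <- tempfile(fileext = ".tsv")
  writeGenotypeTable(pop, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_identical(names(tab)[1:4], c("CHROM", "POS", "REF", "ALT"))
  expect_identical(ncol(tab), 29L)
  g <- genotypes(pop)
  expect_identical(nrow(tab), nrow(unique(g[c("gene_id", "pos", "alt")])))
  gt <- as.matrix(tab[-(1:4)])
  expect_identical(sum(gt == "0/1"), sum(g$zygosity == "het"))
  expect_identical(sum(gt == "1/1"), sum(g$zygosity == "hom"))
  unlink(f)
})
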