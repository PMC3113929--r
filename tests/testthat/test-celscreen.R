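## small helper: amplicon + a genotype row factory for one gene
h2amp <- function() fixtureAmplicons()$arah2.01

grow <- function(id, pos, zyg = "het", alt = "T", kind = "substitution",
                 gene = "arah2.01") {
  data.frame(id = id, gene_id = gene, pos = pos, ref = "C", alt = alt,
             kind = kind, zygosity = zyg, origin = "test")
}

test_that("pooling partitions individuals plate-major", {
  p8 <- makePools(sprintf("i%d", 1:8), 4)
  expect_identical(unique(p8$well), c("P1-A1", "P1-A2"))
  expect_identical(p8$pool, rep(1:2, each = 4L))
  p5 <- makePools(sprintf("i%d", 1:5), 4)
  expect_identical(as.integer(table(p5$pool)), c(4L, 1L))
  p1 <- makePools(sprintf("i%d", 1:3), 1)
  expect_identical(p1$pool, 1:3)                 # individual screening mode
  ## 97th pool rolls over to plate 2
  p <- makePools(sprintf("i%d", 1:(97 * 4)), 4)
  expect_identical(p$well[385], "P2-A1")
})

test_that("heteroduplex sites require two distinct alleles in the pool", {
  amp <- h2amp()
  s <- amp@start + 500L
  empty <- grow("x", 1L)[0, ]
  ## all wild type: nothing to cleave
  expect_length(heteroduplexSites(empty, 4, amp), 0L)
  ## one heterozygous member
  expect_identical(heteroduplexSites(grow("a", s), 4, amp), s)
  ## a homozygote screened alone is invisible until mixed with wild type
  hom <- grow("a", s, zyg = "hom")
  expect_length(heteroduplexSites(hom, 1, amp), 0L)
  expect_identical(heteroduplexSites(hom, 1, amp, include_wt = TRUE), s)
  ## the same homozygote inside a four-fold pool is visible
  expect_identical(heteroduplexSites(hom, 4, amp), s)
  ## four identical homozygotes with no wild type are again invisible
  hom4 <- do.call(rbind, lapply(letters[1:4], grow, pos = s, zyg = "hom"))
  expect_length(heteroduplexSites(hom4, 4, amp), 0L)
  ## sites outside the amplicon are ignored
  expect_length(heteroduplexSites(grow("a", amp@end + 10L), 4, amp), 0L)
})

test_that("cleavage fragments occupy both channels and sum to L", {
  amp <- h2amp()
  L <- ampliconLength(amp)       # 1278
  sig <- cleavageSignals(amp@start + 449L, amp)
  expect_identical(sig$size[sig$channel == 700], 450L)
  expect_identical(sig$size[sig$channel == 800], 828L)
  sig1 <- cleavageSignals(amp@start, amp)      # boundary offset 1
  expect_setequal(sig1$size, c(1L, L - 1L))
  expect_error(cleavageSignals(amp@start - 5L, amp), "outside")
  ## conservation at random sites
  set.seed(7)
  for (d in sample(L, 25)) {
    s <- cleavageSignals(amp@start + d - 1L, amp)
    expect_identical(sum(s$size), L)
  }
})

test_that("detection applies the both-channels-sum rule with edge exclusion", {
  L <- 1278L
  sig <- data.frame(channel = c(700L, 800L), size = c(450, 828))
  expect_identical(detectCalls(sig, L)$cut_position, 450)
  edge <- data.frame(channel = c(700L, 800L), size = c(50, 1228))
  expect_identical(nrow(detectCalls(edge, L)), 0L)
  bad <- data.frame(channel = c(700L, 800L), size = c(450, 700))
  expect_identical(nrow(detectCalls(bad, L)), 0L)
  ## strict inequalities at the 100-bp edge
  at_edge <- data.frame(channel = c(700L, 800L), size = c(100, 1178))
  expect_identical(nrow(detectCalls(at_edge, L)), 0L)
  just_in <- data.frame(channel = c(700L, 800L), size = c(101, 1177))
  expect_identical(nrow(detectCalls(just_in, L)), 1L)
  ## co-migrating duplicate calls are merged with a warning
  dup <- data.frame(channel = rep(c(700L, 800L), each = 2),
                    size = c(450, 450, 828, 828))
  expect_warning(calls <- detectCalls(dup, L), "merged")
  expect_identical(calls$cut_position, 450)
})

test_that("deconvolution recovers the carrier and its zygosity", {
  amp <- h2amp()
  s <- amp@start + 600L
  members <- c("w1", "w2", "m", "w3")
  het <- grow("m", s)
  expect_identical(deconvolutePool(s, members, het, amp),
                   data.frame(id = "m", zygosity = "het"))
  hom <- grow("m", s, zyg = "hom")
  expect_identical(deconvolutePool(s, members, hom, amp),
                   data.frame(id = "m", zygosity = "hom"))
  two <- rbind(grow("m", s), grow("w2", s, zyg = "hom"))
  dec <- deconvolutePool(s, members, two, amp)
  expect_setequal(dec$id, c("m", "w2"))
  ## a spurious call no member explains is an inconsistency error
  expect_error(deconvolutePool(s, members, grow("m", s)[0, ], amp),
               "inconsisten")
})

test_that("the end-to-end screen finds planted variants and only those", {
  fx <- referenceFixtures()
  ## zero-density population: nothing confirmed
  p0 <- simulateM2(fx$loci, 12, MutagenesisParams(density = 0), seed = 2)
  r0 <- runScreen(p0, primers = fx$primers)
  expect_identical(nrow(r0$confirmed), 0L)
  ## one heterozygote planted mid-amplicon: exactly that record
  amp <- fixtureAmplicons()$arah2.01
  mid <- amp@start + 600L
  g <- grow("M2_00003", mid)
  pop <- new("Population", individuals = sprintf("M2_%05d", 1:8),
             groups = rep("g", 8), genotypes = g,
             params = MutagenesisParams(), loci = fx$loci)
  r1 <- runScreen(pop, primers = fx$primers)
  expect_identical(nrow(r1$confirmed), 1L)
  expect_identical(r1$confirmed$individual, "M2_00003")
  expect_identical(r1$confirmed$pos, mid)
  expect_identical(r1$confirmed$zygosity, "het")
  expect_identical(r1$confirmed$well, "P1-A1")
  ## a variant 40 bp from the labeled end is lost to edge exclusion
  g2 <- grow("M2_00002", amp@start + 39L)
  pop2 <- new("Population", individuals = sprintf("M2_%05d", 1:8),
              groups = rep("g", 8), genotypes = g2,
              params = MutagenesisParams(), loci = fx$loci)
  r2 <- runScreen(pop2, primers = fx$primers)
  expect_identical(nrow(r2$confirmed), 0L)
})

test_that("screening is complete inside the detectable window", {
  ## every variant at an interior offset carried by any pool member is
  ## detected and deconvoluted with the correct zygosity (zero size noise)
  fx <- referenceFixtures()
  amps <- fixtureAmplicons()
  pop <- simulateM2(fx$loci, 120, MutagenesisParams(density = 4e-5),
                    seed = 31)
  truth <- genotypes(pop)
  expect_gt(nrow(truth), 15)
  res <- runScreen(pop, primers = fx$primers)
  inside <- vapply(seq_len(nrow(truth)), function(i) {
    a <- amps[[truth$gene_id[i]]]
    d <- truth$pos[i] - a@start + 1L
    d > 100L && d < ampliconLength(a) - 100L
  }, logical(1))
  want <- truth[inside, ]
  got <- res$confirmed
  expect_setequal(paste(got$individual, got$gene_id, got$pos),
                  paste(want$id, want$gene_id, want$pos))
  m <- match(paste(got$individual, got$gene_id, got$pos),
             paste(want$id, want$gene_id, want$pos))
  expect_identical(got$zygosity, want$zygosity[m])
})

test_that("edge exclusion loses the expected fraction of mutations", {
  amp <- h2amp()
  L <- ampliconLength(amp)
  set.seed(17)
  d <- sample.int(L, 2000, replace = TRUE)
  detected <- sum(vapply(d, function(x) {
    nrow(detectCalls(cleavageSignals(amp@start + x - 1L, amp), L))
  }, integer(1)))
  expected <- 2000 * (L - 200) / L
  se <- sqrt(2000 * ((L - 200) / L) * (200 / L))
  expect_lt(abs(detected - expected), 3 * se)
})
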