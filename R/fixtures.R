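## Deterministic synthetic fixture genes.
##
## referenceFixtures() builds three synthetic homeologous gene pairs that
## reproduce, by construction, every sequence context needed by the
## package's worked examples: an intronless 2S-albumin-like pair (arah2),
## an intron-bearing vicilin-like pair (arah1) whose A-subgenome amplicon
## carries six BslI sites laid out for a CAPS truncation marker, and an
## intronless desaturase-like pair (ahfad2) distinguished by a 19-bp indel
## 80 bp upstream of the start codon. All sequences are synthetic
## stand-ins: filler bases are random under a fixed internal seed, and
## only the documented codons, reference bases and restriction sites are
## constrained. Generation is bit-stable across runs and independent of
## the caller's RNG state.

ALL_CODONS <- as.vector(outer(outer(DNA_BASES4, DNA_BASES4, paste0),
                              DNA_BASES4, paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

randChars <- function(n) sample(DNA_BASES4, n, replace = TRUE)

## CDS as characters: random non-stop codons with locked codons applied.
## codon_locks: named character vector, names = codon indices.
buildCds <- function(n_codons, codon_locks) {
  cod <- sample(NONSTOP_CODONS, n_codons, replace = TRUE)
  idx <- as.integer(names(codon_locks))
  cod[idx] <- codon_locks
  chars <- unlist(strsplit(cod, "", fixed = TRUE), use.names = FALSE)
  locked <- logical(3L * n_codons)
  for (i in idx) locked[(3L * i - 2L):(3L * i)] <- TRUE
  list(chars = chars, locked = locked)
}

## Assemble upstream + exons/introns + downstream into one locus.
## exon_breaks: CDS positions after which an intron is inserted;
## intron_lens: parallel intron lengths.
assembleGene <- function(gene_id, subgenome, upstream_len, cds,
                         exon_breaks = integer(), intron_lens = integer(),
                         downstream_len) {
  up <- randChars(upstream_len)
  down <- randChars(downstream_len)
  n_cds <- length(cds$chars)
  bnd <- c(0L, exon_breaks, n_cds)
  chars <- up
  locked <- logical(upstream_len)
  cds2locus <- integer(n_cds)
  starts <- integer(); ends <- integer()
  for (i in seq_len(length(bnd) - 1L)) {
    idx <- (bnd[i] + 1L):bnd[i + 1L]
    starts <- c(starts, length(chars) + 1L)
    cds2locus[idx] <- length(chars) + seq_along(idx)
    chars <- c(chars, cds$chars[idx])
    locked <- c(locked, cds$locked[idx])
    ends <- c(ends, length(chars))
    if (i <= length(intron_lens)) {
      chars <- c(chars, randChars(intron_lens[i]))
      locked <- c(locked, logical(intron_lens[i]))
    }
  }
  chars <- c(chars, down)
  locked <- c(locked, logical(downstream_len))
  locus2cds <- rep(NA_integer_, length(chars))
  locus2cds[cds2locus] <- seq_len(n_cds)
  list(gene_id = gene_id, subgenome = subgenome,
       upstream_len = upstream_len, chars = chars, locked = locked,
       cds2locus = cds2locus, locus2cds = locus2cds,
       cds_intervals = IRanges::IRanges(starts, ends))
}

codonAt <- function(chars, cds2locus, cds_pos) {
  ci <- (cds_pos - 1L) %/% 3L
  paste(chars[cds2locus[(3L * ci + 1L):(3L * ci + 3L)]], collapse = "")
}

## Overwrite bases at `at` and lock them.
plantBases <- function(g, at, bases) {
  idx <- at + seq_along(bases) - 1L
  g$chars[idx] <- bases
  g$locked[idx] <- TRUE
  g
}

## Plant the four fixed bases (CC......GG.) of a BslI site; the 7 N
## positions stay free.
plantBslI <- function(g, at) {
  g <- plantBases(g, at, c("C", "C"))
  plantBases(g, at + 9L, c("G", "G"))
}

## Remove all matches of IUPAC patterns except the kept start positions,
## flipping unlocked fixed-position bases; never creates a stop codon.
scrubPatterns <- function(chars, locked, locus2cds, cds2locus, keep) {
  for (iter in seq_len(500L)) {
    changed <- FALSE
    subj <- Biostrings::DNAString(charsSeq(chars))
    for (pat in names(keep)) {
      hits <- IRanges::start(Biostrings::matchPattern(
        Biostrings::DNAString(pat), subj, fixed = FALSE))
      bad <- setdiff(hits, keep[[pat]])
      if (!length(bad)) next
      s <- bad[1L]
      pl <- seqChars(pat)
      done <- FALSE
      for (off in which(pl != "N")) {
        p <- s + off - 1L
        if (locked[p]) next
        for (b in DNA_BASES4) {
          if (b == chars[p] || b == pl[off]) next
          old <- chars[p]; chars[p] <- b
          cp <- locus2cds[p]
          if (!is.na(cp) &&
              codonAt(chars, cds2locus, cp) %in% STOP_CODONS) {
            chars[p] <- old
            next
          }
          done <- TRUE
          break
        }
        if (done) break
      }
      if (!done) stopf("cannot scrub pattern %s at position %d", pat, s)
      changed <- TRUE
      break
    }
    if (!changed) return(chars)
  }
  stopf("pattern scrubbing did not converge")
}

scrubGene <- function(g, keep) {
  g$chars <- scrubPatterns(g$chars, g$locked, g$locus2cds, g$cds2locus,
                           keep)
  g
}

asGeneModel <- function(g, notes = "synthetic fixture") {
  GeneModel(g$gene_id, charsSeq(g$chars), g$upstream_len, g$cds_intervals,
            subgenome = g$subgenome, notes = notes)
}

subPrimer <- function(name, chars, from, to, orientation = "forward") {
  s <- charsSeq(chars[from:to])
  if (orientation == "reverse") s <- revComp(s)
  Primer(name, s, orientation)
}

.fx_cache <- new.env(parent = emptyenv())

#' Built-in synthetic homeolog fixtures
#'
#' Three synthetic homeologous gene pairs with the full screening
#' apparatus around them, generated deterministically (bit-stable, internal
#' fixed seed, caller's RNG untouched):
#' \itemize{
#'   \item \code{arah2.01}/\code{arah2.02}: an intronless 2S-albumin-like
#'     pair; the copies differ by a 36-bp in-frame CDS insertion and
#'     divergent flanking sequence. Copy .02 carries two DPYSPS epitope
#'     motifs at residues 64-69 and 70-75.
#'   \item \code{arah1.01}/\code{arah1.02}: an intron-bearing vicilin-like
#'     pair. Copy .02 has ATG-anchored position 304 as the first base of
#'     codon 102 (codon CGA), and its 1,666-bp amplicon carries exactly six
#'     BslI sites; the wild-type digest contains adjacent 230- and 63-bp
#'     fragments whose separating site is destroyed by a C304T mutation
#'     (CAPS marker layout). Copy .01 has an EcoRI site in intron 1 and two
#'     adjacent AseI sites in intron 2; neither copy contains a HindIII
#'     site (Southern fragment-count layouts, see [southernLayout()]).
#'   \item \code{ahfad2A}/\code{ahfad2B}: an intronless desaturase-like
#'     pair distinguished by a 19-bp indel 80 bp upstream of the start
#'     codons, on which the gene-specific primers anchor.
#' }
#'
#' Every catalogued mutation context is planted: e.g. codon 49 = CTT
#' (C145>T gives L49F), codon 102 of arah1.02 = CGA (C304>T gives a
#' premature stop), codon 150 of ahfad2A = AAT (A448>G gives N150D), the
#' A-run at CDS 442 of ahfad2B (A-insertion frameshift), and the upstream
#' G at ATG-anchored -315 of arah2.02.
#'
#' @return List with \code{loci} (named list of six
#'   \linkS4class{GeneModel}s), \code{pairs} (named list of three
#'   \linkS4class{HomeologPair}s), \code{primers} (per-gene nested primer
#'   schemes for [nestedAmplify()]/[runScreen()]), \code{mutations} (the
#'   curated 27-row mutation catalog: \code{gene_id}, \code{atg_pos},
#'   \code{ref}, \code{alt}, \code{kind}, \code{predicted_class},
#'   \code{aa_change}, \code{treatment}, \code{population},
#'   \code{plant_id}, \code{anomalous}), \code{epitopes} (per-gene epitope
#'   interval tables) and \code{contaminants} (non-EMS contaminant-allele
#'   table for [MutagenesisParams()]).
#' @examples
#' fx <- referenceFixtures()
#' fx$pairs$arah1
#' @export
referenceFixtures <- function() {
  if (!is.null(.fx_cache$fx)) return(.fx_cache$fx)
  fx <- withSeed(20110512L, buildFixtures())
  .fx_cache$fx <- fx
  fx
}

buildFixtures <- function() {
  ## ---- arah2: intronless pair --------------------------------------------
  h2a <- assembleGene("arah2.01", "A", 400L,
    buildCds(160L, c(`1` = "ATG", `27` = "ACA", `49` = "CTT", `55` = "CGT",
                     `62` = "CGG", `64` = "CTG", `81` = "GCG", `82` = "GCA",
                     `119` = "ACG", `160` = "TAA")),
    downstream_len = 440L)
  h2b <- assembleGene("arah2.02", "B", 450L,
    buildCds(172L, c(`1` = "ATG", `62` = "CGA",
                     `64` = "GAT", `65` = "CCA", `66` = "TAT", `67` = "TCT",
                     `68` = "CCA", `69` = "TCT",
                     `70` = "GAT", `71` = "CCT", `72` = "TAC", `73` = "TCA",
                     `74` = "CCG", `75` = "TCG", `172` = "TAA")),
    downstream_len = 400L)
  h2b <- plantBases(h2b, 136L, "G")   # ATG-anchored -315

  ## shared outer-primer blocks (both copies amplified by one outer pair)
  h2F0 <- randChars(24L); h2R0 <- randChars(24L)
  h2a <- plantBases(h2a, 1L, h2F0)
  h2b <- plantBases(h2b, 1L, h2F0)
  h2a <- plantBases(h2a, length(h2a$chars) - 23L, h2R0)
  h2b <- plantBases(h2b, length(h2b$chars) - 23L, h2R0)

  ## ---- arah1: intron-bearing pair ----------------------------------------
  h1b <- assembleGene("arah1.01", "B", 400L,
    buildCds(500L, c(`1` = "ATG", `196` = "CTG", `333` = "CGG",
                     `405` = "CCA", `437` = "GAA", `500` = "TAA")),
    exon_breaks = c(600L, 900L), intron_lens = c(100L, 295L),
    downstream_len = 400L)
  h1a <- assembleGene("arah1.02", "A", 400L,
    buildCds(500L, c(`1` = "ATG", `25` = "CCT", `28` = "GGA",
                     `101` = "AGC", `102` = "CGA", `104` = "CTG",
                     `105` = "GCT", `122` = "ATC", `123` = "CAA",
                     `125` = "AAG", `126` = "GAA", `500` = "TAA")),
    exon_breaks = c(600L, 900L), intron_lens = c(150L, 120L),
    downstream_len = 300L)

  ## copy .01: EcoRI in intron 1, two adjacent AseI in intron 2, no HindIII
  h1b <- plantBases(h1b, 1040L, seqChars("GAATTC"))
  h1b <- plantBases(h1b, 1500L, seqChars("ATTAAT"))
  h1b <- plantBases(h1b, 1536L, seqChars("ATTAAT"))
  ## copy .02: EcoRI in intron 1; six BslI sites inside the 1,666-bp
  ## amplicon (upstream, three in exon 1 via locked codons, intron 1,
  ## intron 2) whose cut ladder yields the 230/63 bp adjacent fragments
  h1a <- plantBases(h1a, 1040L, seqChars("GAATTC"))
  bsl_starts <- c(351L, 473L, 703L, 766L, 1050L, 1500L)
  for (s in bsl_starts) h1a <- plantBslI(h1a, s)

  h1F0 <- randChars(24L); h1R0 <- randChars(24L)
  h1b <- plantBases(h1b, 1L, h1F0)
  h1a <- plantBases(h1a, 1L, h1F0)
  h1b <- plantBases(h1b, length(h1b$chars) - 23L, h1R0)
  h1a <- plantBases(h1a, length(h1a$chars) - 23L, h1R0)

  ## scrub stray restriction sites the layouts depend on
  six <- function(keep_ecori) list(GAATTC = keep_ecori,
                                   AAGCTT = integer(), ATTAAT = integer())
  h1b_keep <- six(1040L); h1b_keep$ATTAAT <- c(1500L, 1536L)
  h1b <- scrubGene(h1b, h1b_keep)
  h1a_keep <- six(1040L)
  h1a_keep$CCNNNNNNNGG <- bsl_starts
  h1a <- scrubGene(h1a, h1a_keep)

  ## ---- ahfad2: intronless pair with a 19-bp upstream indel ---------------
  u <- randChars(400L)          # shared upstream, diverged only by the indel
  ins19 <- randChars(19L)
  fadA_cds <- buildCds(380L, c(`1` = "ATG", `150` = "AAT", `240` = "CTG",
                               `254` = "CCA", `380` = "TAA"))
  fadB_cds <- buildCds(380L, c(`1` = "ATG", `148` = "AAA", `189` = "ACA",
                               `380` = "TAA"))
  fadA <- assembleGene("ahfad2A", "A", 419L, fadA_cds,
                       downstream_len = 300L)
  fadB <- assembleGene("ahfad2B", "B", 400L, fadB_cds,
                       downstream_len = 300L)
  fadA <- plantBases(fadA, 1L, c(u[1:320], ins19, u[321:400]))
  fadB <- plantBases(fadB, 1L, u)

  loci_raw <- list(arah1.01 = h1b, arah1.02 = h1a, arah2.01 = h2a,
                   arah2.02 = h2b, ahfad2A = fadA, ahfad2B = fadB)
  loci <- lapply(loci_raw, asGeneModel)

  ## ---- primer schemes -----------------------------------------------------
  pr <- function(gene, fi, ri, fo = NULL, ro = NULL, shared_fwd = NULL,
                 shared_rev = NULL) {
    g <- loci_raw[[gene]]
    list(
      outer = list(
        fwd = if (is.null(shared_fwd))
          subPrimer(paste0(gene, "-F0"), g$chars, fo[1L], fo[2L])
        else shared_fwd,
        rev = if (is.null(shared_rev))
          subPrimer(paste0(gene, "-R0"), g$chars, ro[1L], ro[2L], "reverse")
        else shared_rev),
      inner = list(
        fwd = subPrimer(paste0(gene, "-F1"), g$chars, fi[1L], fi[2L]),
        rev = subPrimer(paste0(gene, "-R1"), g$chars, ri[1L], ri[2L],
                        "reverse")))
  }
  h1Fo <- Primer("arah1-F0", charsSeq(h1F0), "forward")
  h1Ro <- Primer("arah1-R0", revComp(charsSeq(h1R0)), "reverse")
  h2Fo <- Primer("arah2-F0", charsSeq(h2F0), "forward")
  h2Ro <- Primer("arah2-R0", revComp(charsSeq(h2R0)), "reverse")
  primers <- list(
    arah1.01 = pr("arah1.01", fi = c(301L, 322L), ri = c(2490L, 2511L),
                  shared_fwd = h1Fo, shared_rev = h1Ro),
    arah1.02 = pr("arah1.02", fi = c(321L, 342L), ri = c(1965L, 1986L),
                  shared_fwd = h1Fo, shared_rev = h1Ro),
    arah2.01 = pr("arah2.01", fi = c(26L, 45L), ri = c(1284L, 1303L),
                  shared_fwd = h2Fo, shared_rev = h2Ro),
    arah2.02 = pr("arah2.02", fi = c(26L, 45L), ri = c(1232L, 1251L),
                  shared_fwd = h2Fo, shared_rev = h2Ro),
    ahfad2A = pr("ahfad2A", fi = c(310L, 331L), ri = c(1516L, 1537L),
                 fo = c(300L, 327L), ro = c(1601L, 1624L)),
    ahfad2B = pr("ahfad2B", fi = c(305L, 326L), ri = c(1504L, 1525L),
                 fo = c(296L, 323L), ro = c(1560L, 1583L)))

  ## primer binding sites must be unique on their own template
  for (g in names(primers)) {
    for (p in unlist(primers[[g]], recursive = FALSE))
      stopifnot(length(findPrimerSites(p, loci[[g]])) == 1L)
  }

  pairs <- list(
    arah1 = HomeologPair("arah1", copy_a = loci$arah1.02,
      copy_b = loci$arah1.01,
      discriminating_features = data.frame(
        position = c(1050L, 1900L), kind = c("indel", "indel"),
        length = c(155L, 225L))),
    arah2 = HomeologPair("arah2", copy_a = loci$arah2.01,
      copy_b = loci$arah2.02,
      discriminating_features = data.frame(
        position = 190L, kind = "indel", length = 36L)),
    ahfad2 = HomeologPair("ahfad2", copy_a = loci$ahfad2A,
      copy_b = loci$ahfad2B,
      discriminating_features = data.frame(
        position = -80L, kind = "indel", length = 19L)))

  mutations <- fixtureMutationCatalog()
  ## reference-base consistency of the catalog against the planted contexts
  for (i in seq_len(nrow(mutations))) {
    gm <- loci[[mutations$gene_id[i]]]
    p <- atgToLocus(mutations$atg_pos[i], gm)
    stopifnot(as.character(Biostrings::subseq(locusSeq(gm), p, p)) ==
                mutations$ref[i])
  }

  epitopes <- list(
    arah1.01 = data.frame(label = "12", start = 326L, end = 335L),
    arah2.02 = data.frame(label = c("epitope-6", "DPYSPS-1", "DPYSPS-2"),
                          start = c(58L, 64L, 70L), end = c(63L, 69L, 75L)))

  contaminants <- data.frame(
    gene_id = c("ahfad2A", "ahfad2B"),
    atg_pos = c(448L, 442L), alt = c("G", "A"),
    kind = c("substitution", "insertion"),
    freq = c(3 / 3420, 2 / 3420))

  list(loci = loci, pairs = pairs, primers = primers,
       mutations = mutations, epitopes = epitopes,
       contaminants = contaminants)
}

## The curated 27-mutation catalog used as the reference screen. The three
## rows whose printed coordinates are inconsistent with contiguous 1-based
## CDS numbering (a codon-position-3 change reported as missense; two
## codon-position-2 changes reported as silent, where silence is
## impossible) are flagged anomalous and excluded from effect-class
## concordance checks, but keep their reference bases and remain screenable
## variants.
fixtureMutationCatalog <- function() {
  t1 <- "0.4% EMS/12 hr."
  t2 <- "1.2% EMS/4.5 hr."
  row <- function(gene_id, atg_pos, ref, alt, kind, predicted_class,
                  aa_change, treatment, population, plant_id,
                  anomalous = FALSE)
    data.frame(gene_id = gene_id, atg_pos = atg_pos, ref = ref, alt = alt,
               kind = kind, predicted_class = predicted_class,
               aa_change = aa_change, treatment = treatment,
               population = population, plant_id = plant_id,
               anomalous = anomalous)
  df <- rbind(
    row("arah2.01", 145L, "C", "T", "substitution", "missense", "L49F",
        t1, "05", "20-6"),
    row("arah2.01", 164L, "G", "A", "substitution", "missense", "R55H",
        t1, "05", "37-4"),
    row("arah2.01", 192L, "G", "A", "substitution", "silent", "",
        t1, "05", "37-4"),
    row("arah2.01", 186L, "G", "A", "substitution", "silent", "",
        t1, "07G", "78-4"),
    row("arah2.01", 80L, "C", "T", "substitution", "silent", "",
        t1, "07G", "90-4", TRUE),
    row("arah2.01", 357L, "G", "A", "substitution", "silent", "",
        t1, "07JKEMS1", "65"),
    row("arah2.01", 186L, "G", "A", "substitution", "silent", "",
        t1, "08GH", "250"),
    row("arah2.02", 185L, "G", "A", "substitution", "missense", "R62Q",
        t1, "07G", "89-5"),
    row("arah2.02", 3L, "G", "A", "substitution", "start_loss",
        "disrupted start codon", t1, "08GH", "2"),
    row("arah1.01", 1392L, "C", "T", "substitution", "missense", "R333W",
        t1, "07G", "95-1"),
    row("arah1.01", 586L, "C", "T", "substitution", "silent", "",
        t1, "07JKEMS1", "99"),
    row("arah1.02", 304L, "C", "T", "substitution", "nonsense", "R102*",
        t1, "07JKEMS1", "133"),
    row("ahfad2A", 448L, "A", "G", "substitution", "missense", "N150D",
        t1, "05", "4-3"),
    row("ahfad2A", 448L, "A", "G", "substitution", "missense", "N150D",
        t1, "05", "55-4"),
    row("ahfad2A", 448L, "A", "G", "substitution", "missense", "N150D",
        t1, "05", "138-10"),
    row("ahfad2A", 718L, "C", "T", "substitution", "silent", "",
        t1, "07G", "113-5"),
    row("ahfad2A", 761L, "C", "T", "substitution", "missense", "P254L",
        t1, "07JKEMS1", "72"),
    row("ahfad2B", 442L, "A", "A", "insertion", "frameshift", "",
        t1, "05", "69-8"),
    row("ahfad2B", 442L, "A", "A", "insertion", "frameshift", "",
        t1, "07G", "81-4"),
    row("ahfad2B", 566L, "C", "T", "substitution", "silent", "",
        t1, "07JKEMS1", "2", TRUE),
    row("arah2.01", 243L, "G", "A", "substitution", "missense", "A82T",
        t2, "06EF", "13-6", TRUE),
    row("arah2.01", 192L, "G", "A", "substitution", "silent", "",
        t2, "06LREMS1", "8-4"),
    row("arah2.02", 208L, "G", "A", "substitution", "missense", "D70N",
        t2, "06EF", "23-7"),
    row("arah2.02", 208L, "G", "A", "substitution", "missense", "D70N",
        t2, "06EF", "26-1"),
    row("arah2.02", -315L, "G", "A", "substitution", "upstream",
        "probably silent", t2, "06EF", "62-6"),
    row("arah1.01", 1609L, "C", "T", "substitution", "missense", "P405L",
        t2, "06EF", "53-3"),
    row("arah1.01", 1704L, "G", "A", "substitution", "missense", "E437K",
        t2, "06EF", "56-3"))
  rownames(df) <- NULL
  df
}

#' Reconstruct the reference M2 screen population
#'
#' Builds the two-treatment M2 population behind the package's worked
#' example: 2,441 individuals of the first treatment group and 979 of the
#' second, with each catalogued mutation planted heterozygously in its
#' recorded plant. Running [runScreen()] on this population reproduces the
#' per-gene, per-group confirmed-mutation counts of the summary report.
#'
#' @param fx fixtures from [referenceFixtures()].
#' @return A \linkS4class{Population} of 3,420 individuals.
#' @export
referenceScreenPopulation <- function(fx = referenceFixtures()) {
  mut <- fx$mutations
  sizes <- c(2441L, 979L)
  labels <- unique(mut$treatment)
  ids <- c(sprintf("EMS04_%04d", seq_len(sizes[1L])),
           sprintf("EMS12_%04d", seq_len(sizes[2L])))
  grp <- rep(labels, sizes)
  ## give catalogued plants their recorded ids, in place
  key <- unique(mut[c("treatment", "population", "plant_id")])
  for (i in seq_len(nrow(key))) {
    slot <- which(grp == key$treatment[i])[i]  # distinct slot per plant
    ids[slot] <- paste0(key$population[i], ":", key$plant_id[i])
  }
  carriers <- paste0(mut$population, ":", mut$plant_id)
  stopifnot(all(carriers %in% ids))
  geno <- data.frame(
    id = carriers, gene_id = mut$gene_id,
    pos = vapply(seq_len(nrow(mut)), function(i)
      atgToLocus(mut$atg_pos[i], fx$loci[[mut$gene_id[i]]]), integer(1L)),
    ref = mut$ref, alt = mut$alt, kind = mut$kind,
    zygosity = "het", origin = "catalog")
  new("Population", individuals = ids, groups = grp, genotypes = geno,
      params = MutagenesisParams(), loci = fx$loci)
}

#' Assemble a two-copy genomic layout for Southern fragment counting
#'
#' Embeds both copies of a homeolog pair in long random flanks with a
#' spacer between them, and plants flank/spacer restriction sites so that
#' the classic copy-number configurations arise with the built-in enzymes
#' on the vicilin-like fixture pair: HindIII (no site in either gene) cuts
#' the layout into two nearly equal ~6.5/6.4-kb gene-bearing fragments
#' (co-migrating); EcoRI (one site inside each copy) yields four
#' probe-visible fragments; AseI (two adjacent sites in one intron of copy
#' .01 only) yields three, the 36-bp inter-site fragment being below the
#' detectability floor.
#'
#' @param pair a \linkS4class{HomeologPair} (default: the vicilin-like
#'   fixture pair).
#' @param flank flanking sequence per side, bp (>= 3200).
#' @param spacer inter-copy spacer, bp (>= 1200).
#' @return List with \code{seq} (assembled layout string),
#'   \code{probe_regions} (\linkS4class{IRanges}: the two probe-homologous
#'   gene regions) and \code{copies} (gene ids), suitable for
#'   [probeFragmentCount()].
#' @export
southernLayout <- function(pair = referenceFixtures()$pairs$arah1,
                           flank = 5000L, spacer = 2000L) {
  stopifnot(flank >= 3200L, spacer >= 1200L)
  copy1 <- pairCopy(pair, "B")   # arah1.01-like: internal EcoRI + AseI
  copy2 <- pairCopy(pair, "A")
  L1 <- length(locusSeq(copy1)); L2 <- length(locusSeq(copy2))
  withSeed(20110513L, {
    chars <- c(randChars(flank), seqChars(locusSeq(copy1)),
               randChars(spacer), seqChars(locusSeq(copy2)),
               randChars(flank))
    locked <- rep(FALSE, length(chars))
    locked[(flank + 1L):(flank + L1)] <- TRUE
    locked[(flank + L1 + spacer + 1L):(flank + L1 + spacer + L2)] <- TRUE
    plant <- function(at, motif) {
      idx <- at + seq_len(nchar(motif)) - 1L
      chars[idx] <<- seqChars(motif)
      locked[idx] <<- TRUE
      at
    }
    ## HindIII: two ~6.5-kb gene fragments
    hM <- plant(flank + L1 + spacer - 100L, "AAGCTT")
    h1 <- plant(hM - 6500L, "AAGCTT")
    hR <- plant(hM + 6400L, "AAGCTT")
    ## EcoRI: bounded flank/spacer sites around the in-gene sites
    e1 <- plant(flank - 1000L, "GAATTC")
    eS <- plant(flank + L1 + 905L, "GAATTC")
    eR <- plant(flank + L1 + spacer + L2 + 835L, "GAATTC")
    ## AseI: bounded sites around the two adjacent in-gene sites
    a1 <- plant(flank - 800L, "ATTAAT")
    aS <- plant(flank + L1 + 1105L, "ATTAAT")
    aR <- plant(flank + L1 + spacer + L2 + 1335L, "ATTAAT")
    keep <- list(
      AAGCTT = c(h1, hM, hR),
      GAATTC = c(e1, flank + 1040L, eS, flank + L1 + spacer + 1040L, eR),
      ATTAAT = c(a1, flank + 1500L, flank + 1536L, aS, aR))
    chars <- scrubPatterns(chars, locked,
                           locus2cds = rep(NA_integer_, length(chars)),
                           cds2locus = integer(), keep = keep)
    list(seq = charsSeq(chars),
         probe_regions = IRanges::IRanges(
           start = c(flank + 1L, flank + L1 + spacer + 1L),
           end = c(flank + L1, flank + L1 + spacer + L2)),
         copies = c(geneId(copy1), geneId(copy2)))
  })
}
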