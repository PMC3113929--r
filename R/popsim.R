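## EMS M2 population simulator.
##
## Model: each M1 plant receives Poisson(density x locus length) induced
## mutations per locus, heterozygously (no chimera modeling -- one pod per
## M1 plant). A canonical mutation is a G->A (at G sites) or C->T (at C
## sites) transition placed uniformly over G/C sites of the stored strand;
## non-canonical mutations land anywhere with a random alternate base.
## Each M1 mutation reaches the single sampled M2 descendant as homozygous
## with probability 1/4, heterozygous 1/2, lost 1/4. Contaminant alleles
## (seed-stock impurities, not mutagen products) are assigned independently
## per individual at fixed frequencies, heterozygously.

#' Construct MutagenesisParams
#'
#' @param density expected induced mutations per bp per M1 plant. The
#'   default 4/(3 * 966000) makes the retained M2 density (3/4 of induced)
#'   equal to one mutation per 966,000 bp.
#' @param canonical_fraction probability that a mutation follows the EMS
#'   G:C->A:T spectrum (default 1).
#' @param contaminants data.frame (\code{gene_id}, \code{atg_pos},
#'   \code{alt}, \code{kind}, \code{freq}) of non-EMS contaminant alleles;
#'   default none.
#' @return A \linkS4class{MutagenesisParams}.
#' @export
MutagenesisParams <- function(density = 4 / (3 * 966000),
                              canonical_fraction = 1,
                              contaminants = data.frame(
                                gene_id = character(), atg_pos = integer(),
                                alt = character(), kind = character(),
                                freq = numeric())) {
  new("MutagenesisParams", density = density,
      canonical_fraction = canonical_fraction, contaminants = contaminants)
}

setMethod("show", "MutagenesisParams", function(object) {
  cat(sprintf(
    "MutagenesisParams: density %.3g /bp/M1, canonical fraction %.2f, %d contaminant allele(s)\n",
    object@density, object@canonical_fraction, nrow(object@contaminants)))
})

setMethod("show", "Population", function(object) {
  cat(sprintf("Population: %d individuals (%s), %d loci, %d genotype record(s)\n",
              length(object@individuals),
              paste(sprintf("%s: %d", names(table(object@groups)),
                            table(object@groups)), collapse = "; "),
              length(object@loci), nrow(object@genotypes)))
})

#' @describeIn Population individual ids, in order.
#' @param x a \code{Population}.
#' @export
individuals <- function(x) x@individuals

#' @describeIn Population long-format genotype table.
#' @export
genotypes <- function(x) x@genotypes

#' @describeIn Population treatment-group label per individual.
#' @export
groups <- function(x) x@groups

emptyGenotypes <- function() {
  data.frame(id = character(), gene_id = character(), pos = integer(),
             ref = character(), alt = character(), kind = character(),
             zygosity = character(), origin = character())
}

#' Simulate an EMS-mutagenized M2 population
#'
#' See the package vignette for the mutagenesis model. The simulation is
#' fully reproducible from \code{seed}; the caller's RNG state is left
#' untouched.
#'
#' @param loci named list of \linkS4class{GeneModel}s.
#' @param n population size (number of M2 individuals).
#' @param params a \linkS4class{MutagenesisParams}.
#' @param seed integer RNG seed.
#' @param group treatment-group label applied to all individuals.
#' @param id_prefix prefix for generated individual ids.
#' @return A \linkS4class{Population}.
#' @examples
#' fx <- referenceFixtures()
#' pop <- simulateM2(fx$loci, 50, MutagenesisParams(density = 1e-4), seed = 1)
#' pop
#' @export
simulateM2 <- function(loci, n, params = MutagenesisParams(), seed = 1L,
                       group = "EMS", id_prefix = "M2") {
  stopifnot(n >= 1L)
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, geneId, character(1L))
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n))
  gc_pos <- lapply(loci, function(gm) {
    ch <- seqChars(gm@locus_seq)
    which(ch %in% c("G", "C"))
  })
  base_at <- lapply(loci, function(gm) seqChars(gm@locus_seq))
  acc <- list()
  withSeed(seed, {
    for (i in seq_len(n)) {
      for (g in names(loci)) {
        gm <- loci[[g]]
        len <- length(gm@locus_seq)
        m <- rpois(1L, params@density * len)
        if (m == 0L) next
        used <- integer()
        for (k in seq_len(m)) {
          ## Mendelian transmission of the heterozygous M1 mutation
          u <- runif(1L)
          zyg <- if (u < 0.25) "hom" else if (u < 0.75) "het" else NA
          pos <- NA_integer_
          for (attempt in 1:25) {
            if (runif(1L) < params@canonical_fraction) {
              p <- gc_pos[[g]][sample.int(length(gc_pos[[g]]), 1L)]
              a <- if (base_at[[g]][p] == "G") "A" else "T"
            } else {
              p <- sample.int(len, 1L)
              a <- sample(setdiff(DNA_BASES4, base_at[[g]][p]), 1L)
            }
            if (!p %in% used) { pos <- p; alt <- a; break }
            warning("site already mutated in this individual; re-drawing")
          }
          if (is.na(pos) || is.na(zyg)) next
          used <- c(used, pos)
          acc[[length(acc) + 1L]] <- list(ids[i], g, pos, base_at[[g]][pos],
                                          alt, "substitution", zyg, "ems")
        }
      }
    }
    ct <- params@contaminants
    if (nrow(ct)) {
      for (j in seq_len(nrow(ct))) {
        gm <- loci[[ct$gene_id[j]]]
        pos <- atgToLocus(ct$atg_pos[j], gm)
        carriers <- which(runif(n) < ct$freq[j])
        for (i in carriers)
          acc[[length(acc) + 1L]] <- list(ids[i], ct$gene_id[j], pos,
                                          seqChars(gm@locus_seq)[pos],
                                          ct$alt[j], ct$kind[j], "het",
                                          "contaminant")
      }
    }
  })
  geno <- if (length(acc)) {
    data.frame(id = vapply(acc, `[[`, "", 1L),
               gene_id = vapply(acc, `[[`, "", 2L),
               pos = vapply(acc, function(x) as.integer(x[[3L]]), 0L),
               ref = vapply(acc, `[[`, "", 4L),
               alt = vapply(acc, `[[`, "", 5L),
               kind = vapply(acc, `[[`, "", 6L),
               zygosity = vapply(acc, `[[`, "", 7L),
               origin = vapply(acc, `[[`, "", 8L))
  } else emptyGenotypes()
  ## a contaminant may coincide with an EMS draw; keep the first record
  geno <- geno[!duplicated(geno[c("id", "gene_id", "pos")]), ]
  new("Population", individuals = ids, groups = rep(group, n),
      genotypes = geno, params = params, loci = loci)
}

#' Combine populations (e.g. different mutagen treatments)
#'
#' @param ... \linkS4class{Population}s over the same loci.
#' @return A single \linkS4class{Population}; ids must not collide.
#' @export
combinePopulations <- function(...) {
  pops <- list(...)
  new("Population",
      individuals = unlist(lapply(pops, individuals)),
      groups = unlist(lapply(pops, groups)),
      genotypes = do.call(rbind, lapply(pops, genotypes)),
      params = pops[[1L]]@params, loci = pops[[1L]]@loci)
}

#' Write a population as a VCF-like genotype table
#'
#' Tab-delimited with columns CHROM (gene id), POS (locus coordinate), REF,
#' ALT, then one column per individual carrying 0/0, 0/1 or 1/1.
#'
#' @param population a \linkS4class{Population}.
#' @param file output path.
#' @export
writeGenotypeTable <- function(population, file) {
  g <- genotypes(population)
  key <- unique(g[c("gene_id", "pos", "ref", "alt")])
  key <- key[order(key$gene_id, key$pos), , drop = FALSE]
  ids <- individuals(population)
  mat <- matrix("0/0", nrow = nrow(key), ncol = length(ids),
                dimnames = list(NULL, ids))
  if (nrow(g)) {
    ki <- match(paste(g$gene_id, g$pos, g$alt),
                paste(key$gene_id, key$pos, key$alt))
    mat[cbind(ki, match(g$id, ids))] <-
      ifelse(g$zygosity == "hom", "1/1", "0/1")
  }
  out <- cbind(data.frame(CHROM = key$gene_id, POS = key$pos,
                          REF = key$ref, ALT = key$alt), mat)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
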