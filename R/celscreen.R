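## The screening engine: four-fold pooling, heteroduplex mismatch
## enumeration, CEL1 dual-channel cleavage prediction, the
## both-channels-sum detection rule with edge exclusion, and pool
## deconvolution with zygosity calling.
##
## Heteroduplex/homoduplex kinetics are reduced to a set rule: a site is
## cleavable iff at least two distinct alleles are present among the pooled
## amplicon haplotypes. Detection is binary (band present/absent); partial
## digestion is not modeled.

#' Partition a population into screening pools
#'
#' Individuals are partitioned in input order into consecutive pools of
#' \code{pool_size} (the last pool may be smaller). Wells are labeled
#' A1..H12 in 96-well plate-major order, prefixed with the plate number.
#'
#' @param population a \linkS4class{Population} (or character vector of
#'   ids).
#' @param pool_size members per pool (default 4; 1 = individual screening).
#' @return data.frame with one row per individual: \code{id}, \code{well},
#'   \code{pool} (pool index).
#' @export
makePools <- function(population, pool_size = 4L) {
  pool_size <- as.integer(pool_size)
  stopifnot(pool_size >= 1L)
  ids <- if (is(population, "Population")) individuals(population)
         else population
  pool <- (seq_along(ids) - 1L) %/% pool_size + 1L
  w <- pool - 1L
  well <- sprintf("P%d-%s%d", w %/% 96L + 1L,
                  LETTERS[(w %% 96L) %/% 12L + 1L], w %% 12L + 1L)
  data.frame(id = ids, well = well, pool = pool)
}

#' Enumerate heteroduplex-cleavable sites in a pooled sample
#'
#' A site is cleavable when at least two distinct alleles occur among the
#' pooled amplicon haplotypes: heterozygous carriers contribute both
#' alleles, homozygous carriers the alternate only, non-carrying members
#' the reference. \code{include_wt} adds reference haplotypes regardless,
#' modeling 1:1 mixing with wild-type DNA (this is what exposes
#' homozygotes screened alone).
#'
#' @param geno genotype rows (as in [genotypes()]) of the pool members for
#'   one gene; positions are locus coordinates.
#' @param n_members number of individuals in the pool.
#' @param amplicon the screened \linkS4class{Amplicon}; sites outside it
#'   are ignored.
#' @param include_wt add wild-type reference haplotypes.
#' @return Sorted integer vector of cleavable locus positions.
#' @export
heteroduplexSites <- function(geno, n_members, amplicon,
                              include_wt = FALSE) {
  g <- geno[geno$pos >= amplicon@start & geno$pos <= amplicon@end, ,
            drop = FALSE]
  if (!nrow(g)) return(integer())
  out <- integer()
  for (p in unique(g$pos)) {
    rows <- g[g$pos == p, , drop = FALSE]
    alts <- unique(paste(rows$kind, rows$alt))
    ref_present <- include_wt || any(rows$zygosity == "het") ||
      nrow(rows) < n_members
    if (length(alts) + as.integer(ref_present) >= 2L)
      out <- c(out, p)
  }
  sort(out)
}

#' Predict the two labeled cleavage fragments of a CEL1 cut
#'
#' A cut at amplicon offset \code{d} releases a 5'-labeled fragment of
#' \code{d} bp (700 channel) and a 3'-labeled fragment of \code{L - d} bp
#' (800 channel); the two always sum to the amplicon length. For indels the
#' rule is applied at the first changed base.
#'
#' @param site locus position of the variant (within the amplicon).
#' @param amplicon the \linkS4class{Amplicon}.
#' @return data.frame with columns \code{channel} (700/800) and \code{size}
#'   (bp).
#' @export
cleavageSignals <- function(site, amplicon) {
  L <- ampliconLength(amplicon)
  d <- as.integer(site) - amplicon@start + 1L
  if (any(d < 1L | d > L)) stopf("site outside the amplicon")
  data.frame(channel = rep(c(700L, 800L), each = length(d)),
             size = c(d, L - d))
}

#' Apply the both-channels-sum detection rule
#'
#' A putative mutation is called for every (700-channel size a, 800-channel
#' size b) pair with \code{a + b = L} (within \code{sum_tol}) whose cut
#' position falls strictly inside the analyzable window
#' (\code{edge < a < L - edge}); unpaired signals produce no call. Calls at
#' identical cut positions (co-migrating bands) are merged with a warning.
#'
#' @param signals data.frame of \code{channel}/\code{size} rows (as from
#'   [cleavageSignals()]).
#' @param L amplicon length in bp.
#' @param edge unanalyzable region at each gel edge, bp (default 100).
#' @param sum_tol tolerance on \code{a + b - L} for noisy sizing
#'   (default 0).
#' @return data.frame with column \code{cut_position} (bp from the labeled
#'   5' end).
#' @export
detectCalls <- function(signals, L, edge = 100L, sum_tol = 0) {
  stopifnot(edge >= 0L)
  a <- signals$size[signals$channel == 700L]
  b <- signals$size[signals$channel == 800L]
  cuts <- numeric()
  for (x in a) if (any(abs(x + b - L) <= sum_tol)) cuts <- c(cuts, x)
  cuts <- cuts[cuts > edge & cuts < L - edge]
  if (anyDuplicated(cuts)) {
    warning("co-migrating cleavage fragments merged into a single call")
    cuts <- unique(cuts)
  }
  data.frame(cut_position = cuts)
}

#' Deconvolute a pool hit to individuals with zygosity
#'
#' Re-screens each pool member twice, alone and mixed 1:1 with wild type:
#' positive in both is heterozygous; positive only when mixed is homozygous
#' (the mutant homoduplex alone is not cleavable); negative in both is wild
#' type. If no member explains the pool hit, an inconsistency error is
#' raised (it signals a simulation or bookkeeping bug, not a negative
#' result).
#'
#' @param site locus position of the pool-level call.
#' @param member_ids ids of the pool members.
#' @param geno genotype rows of the pool members for the screened gene.
#' @param amplicon the screened \linkS4class{Amplicon}.
#' @return data.frame with columns \code{id} and \code{zygosity} for every
#'   member carrying the variant.
#' @export
deconvolutePool <- function(site, member_ids, geno, amplicon) {
  hits <- list()
  for (m in member_ids) {
    mg <- geno[geno$id == m, , drop = FALSE]
    alone <- site %in% heteroduplexSites(mg, 1L, amplicon, include_wt = FALSE)
    mixed <- site %in% heteroduplexSites(mg, 1L, amplicon, include_wt = TRUE)
    if (alone && mixed)
      hits[[length(hits) + 1L]] <- data.frame(id = m, zygosity = "het")
    else if (mixed)
      hits[[length(hits) + 1L]] <- data.frame(id = m, zygosity = "hom")
  }
  if (!length(hits))
    stopf("no pool member explains the hit at %d: inconsistent bookkeeping",
          site)
  do.call(rbind, hits)
}

#' Run the full TILLING screen
#'
#' End-to-end pipeline per gene: nested homeolog-specific amplification,
#' four-fold pooling, heteroduplex formation, CEL1 cleavage, dual-channel
#' detection with edge exclusion, and pool deconvolution with zygosity
#' calling. Returns one confirmed record per (individual, gene, site).
#'
#' @param population a \linkS4class{Population}.
#' @param loci named list of \linkS4class{GeneModel}s to screen (default:
#'   the population's loci).
#' @param primers named list (per gene id) of primer schemes, each a list
#'   with \code{outer} and \code{inner} elements (lists of \code{fwd} and
#'   \code{rev} \linkS4class{Primer}s).
#' @param pool_size individuals per pool (default 4).
#' @param edge unanalyzable bp at each amplicon end (default 100).
#' @param size_noise Gaussian fragment-sizing error, bp standard deviation
#'   (default 0; detection then requires exact size sums).
#' @param seed RNG seed used only when \code{size_noise > 0}.
#' @return List with \code{confirmed} (data.frame: individual, group, gene,
#'   locus and ATG-anchored coordinates, ref, alt, kind, zygosity, well),
#'   \code{tally} (a screen tally for [table1Report()]/[kbPerSnp()]) and
#'   \code{amplicons} (named list of screened \linkS4class{Amplicon}s).
#' @examples
#' fx <- referenceFixtures()
#' pop <- simulateM2(fx$loci, 40, MutagenesisParams(density = 2e-5), seed = 2)
#' res <- runScreen(pop, primers = fx$primers)
#' head(res$confirmed)
#' @export
runScreen <- function(population, loci = population@loci, primers,
                      pool_size = 4L, edge = 100L, size_noise = 0,
                      seed = 1L) {
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, geneId, character(1L))
  amps <- lapply(names(loci), function(g)
    nestedAmplify(loci[[g]], primers[[g]]$outer, primers[[g]]$inner))
  names(amps) <- names(loci)
  pools <- makePools(population, pool_size)
  geno <- genotypes(population)
  grp <- setNames(groups(population), individuals(population))
  acc <- list()
  run1 <- function() {
    for (g in names(loci)) {
      amp <- amps[[g]]
      gg <- geno[geno$gene_id == g & geno$pos >= amp@start &
                 geno$pos <= amp@end, , drop = FALSE]
      if (!nrow(gg)) next
      active <- unique(pools$pool[pools$id %in% gg$id])
      for (pl in active) {
        members <- pools$id[pools$pool == pl]
        well <- pools$well[pools$pool == pl][1L]
        mg <- gg[gg$id %in% members, , drop = FALSE]
        sites <- heteroduplexSites(mg, length(members), amp)
        if (!length(sites)) next
        sig <- cleavageSignals(sites, amp)
        if (size_noise > 0)
          sig$size <- round(sig$size + rnorm(nrow(sig), 0, size_noise))
        calls <- detectCalls(sig, ampliconLength(amp), edge,
                             sum_tol = if (size_noise > 0)
                               max(1, round(3 * size_noise)) else 0)
        for (cut in calls$cut_position) {
          site <- amp@start + as.integer(round(cut)) - 1L
          ## with sizing noise the nearest true heteroduplex site is used
          if (!site %in% sites)
            site <- sites[which.min(abs(sites - (amp@start + cut - 1L)))]
          dec <- deconvolutePool(site, members, mg, amp)
          for (r in seq_len(nrow(dec))) {
            v <- mg[mg$id == dec$id[r] & mg$pos == site, , drop = FALSE]
            acc[[length(acc) + 1L]] <<- data.frame(
              individual = dec$id[r], group = unname(grp[dec$id[r]]),
              gene_id = g, pos = site,
              atg_pos = locusToAtg(site, loci[[g]]),
              ref = v$ref[1L], alt = v$alt[1L], kind = v$kind[1L],
              zygosity = dec$zygosity[r], well = well)
          }
        }
      }
    }
  }
  if (size_noise > 0) withSeed(seed, run1()) else run1()
  confirmed <- if (length(acc)) do.call(rbind, acc) else
    data.frame(individual = character(), group = character(),
               gene_id = character(), pos = integer(), atg_pos = integer(),
               ref = character(), alt = character(), kind = character(),
               zygosity = character(), well = character())
  lens <- vapply(amps, ampliconLength, integer(1L))
  list(confirmed = confirmed,
       tally = screenTally(confirmed, population,
                           data.frame(gene_id = names(lens),
                                      length = unname(lens))),
       amplicons = amps)
}

#' Write the confirmed-mutation table
#'
#' Tab-delimited: individual, gene, ATG-anchored coordinate, ref, alt,
#' zygosity, pool well.
#'
#' @param confirmed the \code{confirmed} data.frame from [runScreen()].
#' @param file output path.
#' @export
writeConfirmedMutations <- function(confirmed, file) {
  write.table(confirmed[c("individual", "gene_id", "atg_pos", "ref",
                          "alt", "zygosity", "well")],
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
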