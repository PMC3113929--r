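#' @import methods
NULL

## shared constants (this file loads first in collation order)
DNA_BASES4 <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")   # standard genetic code

#' GeneModel: a single-locus gene model anchored at its start codon
#'
#' A \code{GeneModel} holds the genomic sequence of one gene copy (always
#' stored on the plus strand), the number of bases included 5' of the start
#' codon (\code{upstream_len}), and the CDS structure as 1-based inclusive
#' locus-coordinate intervals. It is the coordinate anchor for all mutation
#' arithmetic: ATG-anchored coordinates, locus coordinates and CDS
#' coordinates are interconverted through it.
#'
#' Validity requires: CDS intervals non-overlapping, strictly increasing and
#' within the locus; the first CDS base at locus position
#' \code{upstream_len + 1}; concatenated CDS length a multiple of 3, starting
#' with ATG and free of internal stop codons.
#'
#' @slot gene_id single gene identifier.
#' @slot subgenome subgenome label, \code{"A"} or \code{"B"}.
#' @slot locus_seq \linkS4class{DNAString} locus sequence (plus strand).
#' @slot upstream_len integer, bases 5' of the A of ATG.
#' @slot cds_intervals \linkS4class{IRanges} of CDS exon intervals
#'   (1-based inclusive locus coordinates).
#' @slot notes free-text annotation.
#'
#' @seealso [GeneModel()], [atgToLocus()], [locusToCds()], [cdsSeq()]
#' @name GeneModel-class
#' @aliases GeneModel-class
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    gene_id       = "character",
    subgenome     = "character",
    locus_seq     = "DNAString",
    upstream_len  = "integer",
    cds_intervals = "IRanges",
    notes         = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@gene_id) != 1L || !nzchar(object@gene_id))
    msg <- c(msg, "gene_id must be a single non-empty string")
  if (!object@subgenome %in% c("A", "B"))
    msg <- c(msg, "subgenome must be 'A' or 'B'")
  n <- length(object@locus_seq)
  iv <- object@cds_intervals
  if (length(iv) == 0L) {
    msg <- c(msg, "at least one CDS interval is required")
    return(if (length(msg)) msg else TRUE)
  }
  st <- IRanges::start(iv); en <- IRanges::end(iv)
  if (any(st < 1L) || any(en > n))
    msg <- c(msg, "cds_intervals must lie within the locus")
  if (is.unsorted(st, strictly = TRUE) ||
      any(st[-1L] <= en[-length(en)]))
    msg <- c(msg, "cds_intervals must be non-overlapping and strictly increasing")
  if (st[1L] != object@upstream_len + 1L)
    msg <- c(msg, "first CDS base must sit at locus position upstream_len + 1")
  cds <- paste(vapply(seq_along(iv), function(i)
    as.character(Biostrings::subseq(object@locus_seq, st[i], en[i])),
    character(1L)), collapse = "")
  if (nchar(cds) %% 3L != 0L)
    msg <- c(msg, "concatenated CDS length must be a multiple of 3")
  else {
    if (substr(cds, 1L, 3L) != "ATG")
      msg <- c(msg, "CDS must begin with ATG")
    ncod <- nchar(cds) %/% 3L
    if (ncod > 1L) {
      cods <- substring(cds, seq(1L, by = 3L, length.out = ncod - 1L),
                        seq(3L, by = 3L, length.out = ncod - 1L))
      if (any(cods %in% STOP_CODONS))
        msg <- c(msg, "CDS contains an internal stop codon")
    }
  }
  if (length(msg)) msg else TRUE
})

#' HomeologPair: the two subgenome copies of one gene family
#'
#' Bundles the A- and B-subgenome \linkS4class{GeneModel}s of a gene family
#' together with the sequence features (indels, substitutions) that
#' discriminate the two copies and anchor gene-specific primers.
#'
#' @slot family_id gene-family identifier shared by both copies.
#' @slot copy_a,copy_b the two \linkS4class{GeneModel}s.
#' @slot discriminating_features data.frame with columns \code{position}
#'   (ATG-anchored coordinate), \code{kind} (\code{"indel"} or
#'   \code{"substitution"}) and \code{length} (bp).
#'
#' @name HomeologPair-class
#' @exportClass HomeologPair
setClass("HomeologPair",
  representation(
    family_id = "character",
    copy_a = "GeneModel",
    copy_b = "GeneModel",
    discriminating_features = "data.frame"
  )
)

setValidity("HomeologPair", function(object) {
  msg <- character()
  if (length(object@family_id) != 1L || !nzchar(object@family_id))
    msg <- c(msg, "family_id must be a single non-empty string")
  df <- object@discriminating_features
  if (nrow(df) && !all(c("position", "kind", "length") %in% names(df)))
    msg <- c(msg, "discriminating_features needs position/kind/length columns")
  if (length(msg)) msg else TRUE
})

#' MutagenesisParams: EMS mutagenesis model parameters
#'
#' Parameters of the EMS M1 mutagenesis model used by [simulateM2()]:
#' the expected number of induced mutations per bp per M1 plant, the
#' fraction of mutations following the canonical EMS G:C->A:T spectrum,
#' and optional non-EMS contaminant alleles segregating in the seed stock.
#'
#' The default density, 4/(3 * 966000) per bp, is chosen so that the
#' retained M2 mutation density (3/4 of induced mutations survive the
#' 1 hom : 2 het : 1 lost Mendelian transmission) equals one mutation per
#' 966,000 bp.
#'
#' @slot density expected induced mutations per bp per M1 individual.
#' @slot canonical_fraction probability a mutation is a G->A or C->T
#'   transition (default 1).
#' @slot contaminants data.frame with columns \code{gene_id},
#'   \code{atg_pos}, \code{alt}, \code{kind} (\code{"substitution"} or
#'   \code{"insertion"}) and \code{freq} (per-individual probability of
#'   carrying the allele heterozygously).
#'
#' @name MutagenesisParams-class
#' @exportClass MutagenesisParams
setClass("MutagenesisParams",
  representation(
    density = "numeric",
    canonical_fraction = "numeric",
    contaminants = "data.frame"
  )
)

setValidity("MutagenesisParams", function(object) {
  msg <- character()
  if (length(object@density) != 1L || object@density < 0)
    msg <- c(msg, "density must be a single non-negative number")
  cf <- object@canonical_fraction
  if (length(cf) != 1L || cf < 0 || cf > 1)
    msg <- c(msg, "canonical_fraction must lie in [0, 1]")
  ct <- object@contaminants
  if (nrow(ct)) {
    need <- c("gene_id", "atg_pos", "alt", "kind", "freq")
    if (!all(need %in% names(ct)))
      msg <- c(msg, "contaminants needs gene_id/atg_pos/alt/kind/freq columns")
    else if (any(ct$freq < 0 | ct$freq > 1))
      msg <- c(msg, "contaminant frequencies must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Population: a simulated M2 population
#'
#' An ordered collection of M2 individuals with their genotypes over a set
#' of gene models. Genotypes are stored long-format: one row per
#' (individual, gene, site) with reference and alternate alleles, variant
#' kind and zygosity (\code{"het"} or \code{"hom"}).
#'
#' @slot individuals character vector of unique individual ids, in order.
#' @slot groups treatment-group label per individual (parallel to
#'   \code{individuals}).
#' @slot genotypes data.frame with columns \code{id}, \code{gene_id},
#'   \code{pos} (locus coordinate), \code{ref}, \code{alt}, \code{kind},
#'   \code{zygosity}, \code{origin}.
#' @slot params the \linkS4class{MutagenesisParams} used (or defaults).
#' @slot loci named list of \linkS4class{GeneModel}s.
#'
#' @name Population-class
#' @exportClass Population
setClass("Population",
  representation(
    individuals = "character",
    groups = "character",
    genotypes = "data.frame",
    params = "MutagenesisParams",
    loci = "list"
  )
)

setValidity("Population", function(object) {
  msg <- character()
  if (anyDuplicated(object@individuals))
    msg <- c(msg, "individual ids must be unique")
  if (length(object@groups) != length(object@individuals))
    msg <- c(msg, "groups must be parallel to individuals")
  g <- object@genotypes
  need <- c("id", "gene_id", "pos", "ref", "alt", "kind", "zygosity")
  if (!all(need %in% names(g)))
    msg <- c(msg, paste("genotypes needs columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(g) && !all(g$id %in% object@individuals))
      msg <- c(msg, "genotype ids must be known individuals")
    if (nrow(g) && !all(g$zygosity %in% c("het", "hom")))
      msg <- c(msg, "zygosity must be 'het' or 'hom'")
    if (anyDuplicated(g[c("id", "gene_id", "pos")]))
      msg <- c(msg, "at most one alt allele per site per individual")
  }
  if (length(msg)) msg else TRUE
})

#' Primer: a PCR primer
#'
#' @slot name primer name.
#' @slot seq \linkS4class{DNAString}, 15-35 nt, ACGT alphabet.
#' @slot orientation \code{"forward"} or \code{"reverse"}. Reverse primers
#'   are stored 5'->3' on the minus strand; site finding matches their
#'   reverse complement on the template.
#'
#' @name Primer-class
#' @exportClass Primer
setClass("Primer",
  representation(name = "character", seq = "DNAString",
                 orientation = "character")
)

setValidity("Primer", function(object) {
  msg <- character()
  n <- length(object@seq)
  if (n < 15L || n > 35L)
    msg <- c(msg, "primer length must be 15-35 nt")
  if (grepl("[^ACGT]", as.character(object@seq)))
    msg <- c(msg, "primer must use the ACGT alphabet")
  if (!object@orientation %in% c("forward", "reverse"))
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  if (length(msg)) msg else TRUE
})

#' Amplicon: a PCR product located on its template
#'
#' @slot gene_id template gene id.
#' @slot start,end 1-based inclusive locus coordinates on the template.
#' @slot seq \linkS4class{DNAString}; always an exact substring of the
#'   template, so \code{length(seq) == end - start + 1}.
#'
#' @name Amplicon-class
#' @exportClass Amplicon
setClass("Amplicon",
  representation(gene_id = "character", start = "integer",
                 end = "integer", seq = "DNAString")
)

setValidity("Amplicon", function(object) {
  msg <- character()
  if (object@end < object@start)
    msg <- c(msg, "end must be >= start")
  if (length(object@seq) != object@end - object@start + 1L)
    msg <- c(msg, "sequence length must equal end - start + 1")
  if (length(msg)) msg else TRUE
})

#' CapsAssay: a CAPS (cleaved amplified polymorphic sequence) marker assay
#'
#' Describes a restriction digest that discriminates the wild-type and
#' mutant alleles of an amplicon: the full fragment-size multisets of both
#' digests and the diagnostic sizes unique to each allele.
#'
#' @slot enzyme enzyme name.
#' @slot wt_fragments,mut_fragments numeric fragment-size multisets; for a
#'   substitution both sum to the amplicon length.
#' @slot mutant_diagnostic largest size present only in the mutant digest
#'   (NA if none).
#' @slot wt_diagnostic largest size present only in the wild-type digest
#'   (NA if none).
#'
#' @name CapsAssay-class
#' @exportClass CapsAssay
setClass("CapsAssay",
  representation(enzyme = "character",
                 wt_fragments = "numeric", mut_fragments = "numeric",
                 mutant_diagnostic = "numeric", wt_diagnostic = "numeric")
)
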