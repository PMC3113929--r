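## Degenerate restriction-site mapping, CAPS marker design/genotyping and
## Southern-style probe fragment counting.
##
## Only top-strand matching is performed: the built-in enzymes all have
## palindromic (or N-padded palindromic) recognition sites, which a
## double-strand scan would report twice.

#' Built-in restriction enzyme table
#'
#' IUPAC recognition strings and top-strand cut offsets (the cut falls
#' after \code{cut_offset} bases of the site). BslI is modeled as
#' CCNNNNNNNGG cutting CCNNNNN^NNGG (offset 7).
#'
#' @param extra optional data.frame with the same columns (\code{name},
#'   \code{recognition}, \code{cut_offset}) appended to the built-ins.
#' @return data.frame of enzymes.
#' @examples
#' enzymes()
#' @export
enzymes <- function(extra = NULL) {
  tab <- data.frame(
    name = c("EcoRI", "HindIII", "AseI", "BslI"),
    recognition = c("GAATTC", "AAGCTT", "ATTAAT", "CCNNNNNNNGG"),
    cut_offset = c(1L, 1L, 2L, 7L))
  if (!is.null(extra)) tab <- rbind(tab, extra[names(tab)])
  tab
}

getEnzyme <- function(enzyme) {
  if (is.data.frame(enzyme)) return(enzyme[1L, ])
  tab <- enzymes()
  i <- match(enzyme, tab$name)
  if (is.na(i)) stopf("unknown enzyme '%s'", enzyme)
  tab[i, ]
}

#' Find restriction sites (degenerate IUPAC matching, top strand)
#'
#' @param seq a string, \code{DNAString} or \linkS4class{Amplicon}.
#' @param enzyme enzyme name (see [enzymes()]) or a one-row enzyme
#'   data.frame.
#' @return Integer vector of 1-based match start positions.
#' @examples
#' restrictionSites("AAGAATTCAA", "EcoRI")  # 3
#' @export
restrictionSites <- function(seq, enzyme) {
  enz <- getEnzyme(enzyme)
  s <- if (is(seq, "Amplicon")) seq@seq
       else if (is.character(seq)) Biostrings::DNAString(seq) else seq
  IRanges::start(Biostrings::matchPattern(
    Biostrings::DNAString(enz$recognition), s, fixed = FALSE))
}

#' Digest a linear molecule into fragment sizes
#'
#' \code{n} cut positions produce \code{n + 1} fragments whose sizes sum to
#' the sequence length.
#'
#' @inheritParams restrictionSites
#' @return Integer vector of fragment sizes, 5' to 3'.
#' @export
digestFragments <- function(seq, enzyme) {
  enz <- getEnzyme(enzyme)
  s <- if (is(seq, "Amplicon")) seq@seq
       else if (is.character(seq)) Biostrings::DNAString(seq) else seq
  len <- length(s)
  cuts <- sort(restrictionSites(s, enz) + enz$cut_offset - 1L)
  cuts <- cuts[cuts >= 1L & cuts < len]
  diff(c(0L, cuts, len))
}

applyMutationToSeq <- function(seq_chars, offset, ref, alt, kind) {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"))
  if (kind == "substitution") {
    if (seq_chars[offset] != ref)
      stopf("reference mismatch at offset %d: expected %s, found %s",
            offset, ref, seq_chars[offset])
    seq_chars[offset] <- alt
    seq_chars
  } else if (kind == "insertion") {
    append(seq_chars, seqChars(alt), after = offset)
  } else {
    seq_chars[-(offset:(offset + nchar(ref) - 1L))]
  }
}

#' Design a CAPS assay for a mutation
#'
#' Applies the mutation to the wild-type amplicon, digests both alleles
#' with each candidate enzyme, and returns the first assay for which both
#' a mutant-diagnostic and a wild-type-diagnostic fragment size exist. A
#' destroyed site merges two adjacent wild-type fragments (the
#' mutant-diagnostic is their sum); a created site splits one. The largest
#' allele-unique size is reported as the diagnostic. If no candidate
#' discriminates, \code{NULL} is returned (a no-assay result, not an
#' error).
#'
#' @param wt_amplicon the wild-type \linkS4class{Amplicon} (or sequence).
#' @param offset 1-based position of the mutation within the amplicon.
#' @param ref,alt reference and alternate alleles (for insertions,
#'   \code{alt} is the inserted string).
#' @param kind \code{"substitution"}, \code{"insertion"} or
#'   \code{"deletion"}.
#' @param candidates enzyme names or data.frame (default: all built-ins).
#' @return A \linkS4class{CapsAssay}, or \code{NULL}.
#' @export
capsDesign <- function(wt_amplicon, offset, ref, alt,
                       kind = "substitution", candidates = enzymes()) {
  wt <- if (is(wt_amplicon, "Amplicon")) as.character(wt_amplicon@seq)
        else as.character(wt_amplicon)
  if (offset < 1L || offset > nchar(wt))
    stopf("mutation offset outside the amplicon")
  mut <- charsSeq(applyMutationToSeq(seqChars(wt), offset, ref, alt, kind))
  if (is.character(candidates))
    candidates <- enzymes()[match(candidates, enzymes()$name), ]
  for (i in seq_len(nrow(candidates))) {
    enz <- candidates[i, ]
    wf <- digestFragments(wt, enz)
    mf <- digestFragments(mut, enz)
    mut_only <- multisetDiff(mf, wf)
    wt_only <- multisetDiff(wf, mf)
    if (length(mut_only) && length(wt_only))
      return(new("CapsAssay", enzyme = enz$name,
                 wt_fragments = as.numeric(wf), mut_fragments = as.numeric(mf),
                 mutant_diagnostic = as.numeric(max(mut_only)),
                 wt_diagnostic = as.numeric(max(wt_only))))
  }
  NULL
}

## multiset difference of integer size lists
multisetDiff <- function(a, b) {
  for (x in b) {
    i <- match(x, a)
    if (!is.na(i)) a <- a[-i]
  }
  a
}

setMethod("show", "CapsAssay", function(object) {
  cat(sprintf("CapsAssay (%s): mutant-diagnostic %g bp, wt-diagnostic %g bp\n",
              object@enzyme, object@mutant_diagnostic, object@wt_diagnostic))
  cat("  wt fragments: ", paste(sort(object@wt_fragments, decreasing = TRUE),
                                collapse = ", "), "\n", sep = "")
  cat("  mut fragments:", paste(sort(object@mut_fragments, decreasing = TRUE),
                                collapse = ", "), "\n")
})

#' Call a genotype from observed CAPS fragment sizes
#'
#' Mutant diagnostic present without the wild-type diagnostic: homozygous
#' mutant. Both present: heterozygote. Wild-type diagnostic only: wild
#' type. Neither: failed digest (error).
#'
#' @param observed numeric vector of observed fragment sizes.
#' @param assay a \linkS4class{CapsAssay} with both diagnostics.
#' @return \code{"wt"}, \code{"het"} or \code{"hom"}.
#' @export
capsGenotype <- function(observed, assay) {
  if (is.na(assay@mutant_diagnostic) || is.na(assay@wt_diagnostic))
    stopf("assay lacks a diagnostic fragment")
  has_mut <- assay@mutant_diagnostic %in% observed
  has_wt <- assay@wt_diagnostic %in% observed
  if (has_mut && has_wt) "het"
  else if (has_mut) "hom"
  else if (has_wt) "wt"
  else stopf("neither diagnostic fragment observed: failed digest")
}

#' Count probe-visible Southern fragments over a two-copy locus
#'
#' Digests a genomic layout containing both homeologs embedded in flanking
#' sequence, and counts the fragments a gene probe would light up: size at
#' least \code{min_detectable} and overlap of at least \code{min_overlap}
#' bp with a probe-homologous region (both copies are probe-homologous).
#' Counted fragments within 5\% relative size of one another are flagged as
#' co-migrating (unresolvable on a blot).
#'
#' @param layout list with elements \code{seq} (the assembled locus,
#'   string or \code{DNAString}) and \code{probe_regions}
#'   (\linkS4class{IRanges} of probe-homologous intervals); see
#'   [southernLayout()].
#' @param enzyme enzyme name or one-row enzyme data.frame.
#' @param min_detectable smallest visible fragment, bp (default 100).
#' @param min_overlap minimum probe overlap, bp (default 50).
#' @return List with \code{count}, \code{sizes} (counted fragment sizes)
#'   and \code{comigrating} (logical, parallel to sizes).
#' @export
probeFragmentCount <- function(layout, enzyme, min_detectable = 100L,
                               min_overlap = 50L) {
  enz <- getEnzyme(enzyme)
  s <- if (is.character(layout$seq)) Biostrings::DNAString(layout$seq)
       else layout$seq
  len <- length(s)
  cuts <- sort(restrictionSites(s, enz) + enz$cut_offset - 1L)
  cuts <- cuts[cuts >= 1L & cuts < len]
  bounds <- c(0L, cuts, len)
  frag <- IRanges::IRanges(start = bounds[-length(bounds)] + 1L,
                           end = bounds[-1L])
  ov <- IRanges::findOverlaps(frag, layout$probe_regions, minoverlap = 1L)
  ovw <- tapply(
    IRanges::width(IRanges::pintersect(
      frag[S4Vectors::queryHits(ov)],
      layout$probe_regions[S4Vectors::subjectHits(ov)])),
    S4Vectors::queryHits(ov), max)
  keep <- rep(FALSE, length(frag))
  keep[as.integer(names(ovw))] <- ovw >= min_overlap
  keep <- keep & IRanges::width(frag) >= min_detectable
  sizes <- IRanges::width(frag)[keep]
  comig <- vapply(seq_along(sizes), function(i)
    any(abs(sizes[-i] - sizes[i]) / pmax(sizes[-i], sizes[i]) <= 0.05),
    logical(1L))
  list(count = length(sizes), sizes = sizes, comigrating = comig)
}
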