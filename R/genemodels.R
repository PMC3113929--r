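## Gene models and coordinate arithmetic.
##
## Three coordinate systems meet here:
##   locus coordinates : 1-based positions on the stored (+ strand) sequence
##   ATG-anchored      : 1-based from the A of ATG; negative = upstream,
##                       there is no position 0 (-1 abuts +1)
##   CDS coordinates   : 1-based offsets within the concatenated CDS

#' Construct a GeneModel
#'
#' @param gene_id single gene identifier (also the FASTA record id).
#' @param locus_seq locus sequence: a string or \linkS4class{DNAString},
#'   plus strand. Reverse-strand genes must be reverse-complemented before
#'   loading; the package stores all models on the plus strand.
#' @param upstream_len number of bases included 5' of the A of ATG.
#' @param cds_intervals \linkS4class{IRanges} (or 2-column matrix of
#'   start/end) of CDS exon intervals, 1-based inclusive locus coordinates.
#' @param subgenome subgenome label, \code{"A"} or \code{"B"}.
#' @param notes free-text annotation.
#'
#' @return A validated \linkS4class{GeneModel}.
#' @examples
#' gm <- GeneModel("toy", "AAATGGCGTAATT", upstream_len = 2,
#'                 cds_intervals = IRanges::IRanges(3, 11))
#' cdsSeq(gm)
#' @export
GeneModel <- function(gene_id, locus_seq, upstream_len, cds_intervals,
                      subgenome = "A", notes = "") {
  if (is.matrix(cds_intervals))
    cds_intervals <- IRanges::IRanges(start = cds_intervals[, 1L],
                                      end = cds_intervals[, 2L])
  if (is.character(locus_seq))
    locus_seq <- Biostrings::DNAString(locus_seq)
  new("GeneModel", gene_id = gene_id, subgenome = subgenome,
      locus_seq = locus_seq, upstream_len = as.integer(upstream_len),
      cds_intervals = cds_intervals, notes = notes)
}

#' @describeIn GeneModel gene identifier accessor.
#' @param x,object a \code{GeneModel}.
#' @export
geneId <- function(x) x@gene_id

#' @describeIn GeneModel subgenome label accessor.
#' @export
subgenome <- function(x) x@subgenome

#' @describeIn GeneModel locus sequence accessor (\code{DNAString}).
#' @export
locusSeq <- function(x) x@locus_seq

#' @describeIn GeneModel bases included upstream of the start codon.
#' @export
upstreamLen <- function(x) x@upstream_len

#' @describeIn GeneModel CDS exon intervals (\code{IRanges}).
#' @export
cdsIntervals <- function(x) x@cds_intervals

#' @describeIn GeneModel concatenated CDS sequence (\code{DNAString}).
#' @export
cdsSeq <- function(x) {
  iv <- x@cds_intervals
  Biostrings::DNAString(paste(vapply(seq_along(iv), function(i)
    as.character(Biostrings::subseq(x@locus_seq, IRanges::start(iv)[i],
                                    IRanges::end(iv)[i])),
    character(1L)), collapse = ""))
}

#' @describeIn GeneModel concatenated CDS length in bp.
#' @export
cdsLength <- function(x) sum(IRanges::width(x@cds_intervals))

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s' (subgenome %s)\n", object@gene_id,
              object@subgenome))
  cat(sprintf("  locus: %d bp, upstream of ATG: %d bp\n",
              length(object@locus_seq), object@upstream_len))
  cat(sprintf("  CDS: %d exon(s), %d bp (%d codons)\n",
              length(object@cds_intervals), cdsLength(object),
              cdsLength(object) %/% 3L))
})

#' Construct a HomeologPair
#'
#' @param family_id gene-family identifier.
#' @param copy_a,copy_b the A- and B-subgenome \linkS4class{GeneModel}s.
#' @param discriminating_features data.frame (\code{position}, \code{kind},
#'   \code{length}) of copy-discriminating sequence features; at least one
#'   is required if gene-specific primers are to be validated against the
#'   pair.
#' @return A \linkS4class{HomeologPair}.
#' @export
HomeologPair <- function(family_id, copy_a, copy_b,
                         discriminating_features = data.frame(
                           position = integer(), kind = character(),
                           length = integer())) {
  new("HomeologPair", family_id = family_id, copy_a = copy_a,
      copy_b = copy_b, discriminating_features = discriminating_features)
}

#' @describeIn HomeologPair accessor for one copy.
#' @param x a \code{HomeologPair}.
#' @param which \code{"A"} or \code{"B"}.
#' @export
pairCopy <- function(x, which = c("A", "B")) {
  switch(match.arg(which), A = x@copy_a, B = x@copy_b)
}

#' @describeIn HomeologPair both copies as a named list.
#' @export
pairCopies <- function(x) {
  out <- list(x@copy_a, x@copy_b)
  names(out) <- c(geneId(x@copy_a), geneId(x@copy_b))
  out
}

setMethod("show", "HomeologPair", function(object) {
  cat(sprintf("HomeologPair '%s': %s (A) / %s (B), %d discriminating feature(s)\n",
              object@family_id, geneId(object@copy_a), geneId(object@copy_b),
              nrow(object@discriminating_features)))
})

#' Convert ATG-anchored coordinates to locus coordinates
#'
#' Position 1 is the A of ATG; negative positions count upstream with no
#' position 0, so -1 is the base immediately 5' of the ATG. The map is
#' strictly monotonic over ..., -2, -1, 1, 2, ...
#'
#' @param pos integer vector of ATG-anchored positions (no zeros).
#' @param gm a \linkS4class{GeneModel}.
#' @return Integer vector of 1-based locus positions.
#' @examples
#' gm <- GeneModel("toy", paste0(strrep("A", 4), "ATGAAATAG"), 4,
#'                 IRanges::IRanges(5, 13))
#' atgToLocus(c(-1, 1), gm)  # 4, 5
#' @export
atgToLocus <- function(pos, gm) {
  pos <- as.integer(pos)
  if (any(pos == 0L))
    stopf("ATG-anchored coordinates have no position 0 (-1 abuts +1)")
  out <- ifelse(pos >= 1L, gm@upstream_len + pos, gm@upstream_len + pos + 1L)
  bad <- out < 1L | out > length(gm@locus_seq)
  if (any(bad))
    stopf("position %d maps outside the locus (1..%d)",
          pos[which(bad)[1L]], length(gm@locus_seq))
  out
}

#' Convert locus coordinates to ATG-anchored coordinates
#'
#' Inverse of [atgToLocus()].
#'
#' @inheritParams atgToLocus
#' @param pos integer vector of locus positions.
#' @return Integer vector of ATG-anchored positions.
#' @export
locusToAtg <- function(pos, gm) {
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > length(gm@locus_seq)))
    stopf("locus position out of bounds")
  ifelse(pos > gm@upstream_len, pos - gm@upstream_len,
         pos - gm@upstream_len - 1L)
}

#' Map locus positions onto the concatenated CDS
#'
#' Returns, for each position, the 1-based offset within the concatenated
#' CDS when the position falls in a CDS exon, or a region label otherwise
#' (\code{"upstream"}, \code{"intron"}, \code{"downstream"}).
#'
#' @inheritParams locusToAtg
#' @return data.frame with columns \code{locus_pos}, \code{region}
#'   (\code{"cds"}, \code{"upstream"}, \code{"intron"}, \code{"downstream"})
#'   and \code{cds_pos} (integer, NA outside the CDS).
#' @examples
#' gm <- GeneModel("toy", paste0("ATG", strrep("C", 6), "AAATAG"), 0,
#'                 rbind(c(1, 3), c(10, 15)))
#' locusToCds(c(2, 5, 11), gm)
#' @export
locusToCds <- function(pos, gm) {
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > length(gm@locus_seq)))
    stopf("locus position out of bounds")
  iv <- gm@cds_intervals
  st <- IRanges::start(iv); en <- IRanges::end(iv)
  off <- cumsum(c(0L, IRanges::width(iv)))[seq_along(iv)]
  region <- character(length(pos)); cds <- rep(NA_integer_, length(pos))
  for (k in seq_along(pos)) {
    p <- pos[k]
    i <- which(p >= st & p <= en)
    if (length(i)) {
      region[k] <- "cds"; cds[k] <- off[i] + (p - st[i] + 1L)
    } else if (p <= gm@upstream_len) region[k] <- "upstream"
    else if (p > en[length(en)]) region[k] <- "downstream"
    else region[k] <- "intron"
  }
  data.frame(locus_pos = pos, region = region, cds_pos = cds)
}

#' Map CDS positions back to locus coordinates
#'
#' Inverse of [locusToCds()] on CDS positions:
#' \code{cdsToLocus(locusToCds(p, gm)$cds_pos, gm) == p} for every CDS
#' position \code{p}.
#'
#' @inheritParams locusToAtg
#' @param pos integer vector of 1-based concatenated-CDS positions.
#' @return Integer vector of locus positions.
#' @export
cdsToLocus <- function(pos, gm) {
  pos <- as.integer(pos)
  iv <- gm@cds_intervals
  w <- IRanges::width(iv)
  ends <- cumsum(w)
  starts <- c(1L, ends[-length(ends)] + 1L)
  if (any(pos < 1L | pos > ends[length(ends)]))
    stopf("CDS position out of bounds (CDS is %d bp)", ends[length(ends)])
  vapply(pos, function(p) {
    i <- which(p >= starts & p <= ends)[1L]
    IRanges::start(iv)[i] + (p - starts[i])
  }, integer(1L))
}

#' Translate a CDS with the standard genetic code
#'
#' Stops are rendered as \code{"*"}; with \code{to_first_stop = TRUE}
#' translation halts at (and excludes) the first stop codon.
#'
#' @param cds a string or \code{DNAString}; length must be a multiple of 3
#'   and the alphabet ACGT.
#' @param to_first_stop stop at the first stop codon.
#' @return Protein string.
#' @examples
#' translateCds("ATGCGATAA")  # "MR*"
#' @export
translateCds <- function(cds, to_first_stop = FALSE) {
  s <- as.character(cds)
  if (nchar(s) %% 3L != 0L) stopf("CDS length must be a multiple of 3")
  if (grepl("[^ACGT]", s)) stopf("CDS must use the ACGT alphabet")
  ## no.init.codon: single codons are translated literally, not as
  ## alternative initiators (CTG/TTG would otherwise become M)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE)))
  if (to_first_stop) sub("\\*.*$", "", aa) else aa
}

#' @describeIn GeneModel translated protein (through the first stop).
#' @export
proteinSeq <- function(x) translateCds(cdsSeq(x), to_first_stop = TRUE)

## ---- FASTA / GFF3 interface ------------------------------------------------

#' Write gene models as FASTA plus a GFF3 feature table
#'
#' One FASTA record per gene copy (id = gene id). The GFF3 carries a
#' \code{gene} feature per model with \code{upstream_len} and
#' \code{subgenome} attributes, and one \code{CDS} feature per exon
#' interval (1-based inclusive, as GFF3 specifies).
#'
#' @param models list of \linkS4class{GeneModel}s.
#' @param fasta,gff output file paths.
#' @return Invisibly, the two paths.
#' @export
writeGeneModels <- function(models, fasta, gff) {
  seqs <- Biostrings::DNAStringSet(lapply(models, function(m) m@locus_seq))
  names(seqs) <- vapply(models, geneId, character(1L))
  Biostrings::writeXStringSet(seqs, fasta)
  lens <- vapply(models, function(m) length(m@locus_seq), integer(1L))
  ids <- vapply(models, geneId, character(1L))
  rows <- do.call(rbind, lapply(models, function(m) {
    iv <- m@cds_intervals
    cum <- cumsum(c(0L, IRanges::width(iv)))[seq_along(iv)]
    data.frame(
      seqnames = geneId(m),
      start = c(1L, IRanges::start(iv)),
      end = c(length(m@locus_seq), IRanges::end(iv)),
      type = c("gene", rep("CDS", length(iv))),
      ID = c(geneId(m), paste0(geneId(m), ".cds", seq_along(iv))),
      Parent = c(NA_character_, rep(geneId(m), length(iv))),
      upstream_len = c(as.character(m@upstream_len),
                       rep(NA_character_, length(iv))),
      subgenome = c(m@subgenome, rep(NA_character_, length(iv))),
      phase = c(NA_integer_, (3L - cum %% 3L) %% 3L))
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(rows$seqnames, levels = ids),
    ranges = IRanges::IRanges(rows$start, rows$end), strand = "+",
    type = rows$type, ID = rows$ID, Parent = rows$Parent,
    upstream_len = rows$upstream_len, subgenome = rows$subgenome,
    phase = rows$phase,
    seqlengths = stats::setNames(lens, ids))
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' Read gene models from FASTA plus a GFF3 feature table
#'
#' Counterpart of [writeGeneModels()].
#'
#' @param fasta,gff input file paths.
#' @return Named list of \linkS4class{GeneModel}s.
#' @export
readGeneModels <- function(fasta, gff) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(gff, format = "gff3")
  genes <- gr[gr$type == "gene"]
  out <- lapply(seq_along(genes), function(i) {
    gid <- as.character(genes$ID[i])
    cds <- gr[gr$type == "CDS" &
              as.character(GenomicRanges::seqnames(gr)) == gid]
    cds <- cds[order(GenomicRanges::start(cds))]
    GeneModel(gid, as.character(seqs[[gid]]),
              upstream_len = as.integer(as.character(genes$upstream_len[i])),
              cds_intervals = IRanges::IRanges(GenomicRanges::start(cds),
                                               GenomicRanges::end(cds)),
              subgenome = as.character(genes$subgenome[i]))
  })
  names(out) <- vapply(out, geneId, character(1L))
  out
}
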