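## In-silico nested, gene-specific PCR.
##
## Primer specificity in an allotetraploid comes from indel-spanning
## primers, not thermodynamics, so matching is ungapped with an exact
## 3'-terminal anchor; melting temperature and touchdown programs are
## deliberately out of scope.

#' Construct a Primer
#'
#' @param name primer name.
#' @param seq primer sequence, 5'->3', 15-35 nt ACGT.
#' @param orientation \code{"forward"} or \code{"reverse"}.
#' @return A \linkS4class{Primer}.
#' @export
Primer <- function(name, seq, orientation = c("forward", "reverse")) {
  new("Primer", name = name, seq = Biostrings::DNAString(as.character(seq)),
      orientation = match.arg(orientation))
}

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer '%s' (%s, %d nt): %s\n", object@name,
              object@orientation, length(object@seq),
              as.character(object@seq)))
})

#' @describeIn Amplicon amplicon length in bp.
#' @param x an \code{Amplicon}.
#' @export
ampliconLength <- function(x) x@end - x@start + 1L

#' @describeIn Amplicon amplicon sequence (\code{DNAString}).
#' @export
ampliconSeq <- function(x) x@seq

setMethod("show", "Amplicon", function(object) {
  cat(sprintf("Amplicon on '%s': %d..%d (%d bp)\n", object@gene_id,
              object@start, object@end, ampliconLength(object)))
})

#' Locate primer binding sites on a template
#'
#' Ungapped matching with at most \code{max_mismatch} mismatches and zero
#' mismatches within the 3'-terminal \code{anchor_3prime} bases. Reverse
#' primers are matched as their reverse complement (their 3' anchor lies at
#' the left edge of the match on the plus strand).
#'
#' @param primer a \linkS4class{Primer}.
#' @param template template sequence (string, \code{DNAString} or
#'   \linkS4class{GeneModel}).
#' @param max_mismatch allowed mismatches outside the anchor (default 0).
#' @param anchor_3prime length of the exact 3' anchor (default 3).
#' @return Integer vector of 1-based start positions of the match on the
#'   plus strand.
#' @export
findPrimerSites <- function(primer, template, max_mismatch = 0L,
                            anchor_3prime = 3L) {
  if (anchor_3prime > length(primer@seq))
    stopf("anchor_3prime exceeds primer length")
  tmpl <- if (is(template, "GeneModel")) template@locus_seq
          else if (is.character(template)) Biostrings::DNAString(template)
          else template
  pat <- if (primer@orientation == "reverse")
    Biostrings::reverseComplement(primer@seq) else primer@seq
  hits <- Biostrings::matchPattern(pat, tmpl, max.mismatch = max_mismatch)
  st <- IRanges::start(hits)
  if (max_mismatch > 0L && length(st) && anchor_3prime > 0L) {
    w <- length(pat)
    keep <- vapply(st, function(s) {
      anc <- if (primer@orientation == "reverse")
        c(s, s + anchor_3prime - 1L)           # 3' end at left edge
      else c(s + w - anchor_3prime, s + w - 1L) # 3' end at right edge
      as.character(Biostrings::subseq(tmpl, anc[1L], anc[2L])) ==
        as.character(Biostrings::subseq(pat,
          anc[1L] - s + 1L, anc[2L] - s + 1L))
    }, logical(1L))
    st <- st[keep]
  }
  st
}

#' Amplify a template with a primer pair
#'
#' One product per (forward site, downstream reverse site) pair within
#' \code{max_product}. The product spans from the first base of the forward
#' site to the last base of the reverse site. No compatible site pair
#' yields an empty list, not an error.
#'
#' @param template a \linkS4class{GeneModel} (or sequence).
#' @param fwd,rev forward and reverse \linkS4class{Primer}s.
#' @param max_product maximum product length in bp (default 5000; all
#'   screen amplicons here are < 2.3 kb, the cap only prevents pathological
#'   pairings).
#' @inheritParams findPrimerSites
#' @return List of \linkS4class{Amplicon}s.
#' @export
amplify <- function(template, fwd, rev, max_product = 5000L,
                    max_mismatch = 0L, anchor_3prime = 3L) {
  gid <- if (is(template, "GeneModel")) geneId(template) else "template"
  tmpl <- if (is(template, "GeneModel")) template@locus_seq
          else if (is.character(template)) Biostrings::DNAString(template)
          else template
  fs <- findPrimerSites(fwd, tmpl, max_mismatch, anchor_3prime)
  rs <- findPrimerSites(rev, tmpl, max_mismatch, anchor_3prime)
  out <- list()
  for (f in fs) for (r in rs) {
    en <- r + length(rev@seq) - 1L
    if (en >= f + length(fwd@seq) - 1L && en - f + 1L <= max_product)
      out[[length(out) + 1L]] <- new("Amplicon", gene_id = gid,
        start = as.integer(f), end = as.integer(en),
        seq = Biostrings::subseq(tmpl, f, en))
  }
  out
}

#' Nested amplification: outer enrichment PCR, then labeled inner PCR
#'
#' The inner amplicon is computed on the outer product sequence, then
#' reported in template coordinates; when the inner sites are unique on the
#' full template this equals direct inner amplification.
#'
#' @param template a \linkS4class{GeneModel}.
#' @param outer,inner lists with elements \code{fwd} and \code{rev}
#'   (\linkS4class{Primer}s).
#' @inheritParams amplify
#' @return A single \linkS4class{Amplicon} (error if the outer PCR fails
#'   or the inner primers do not bind within the outer product).
#' @export
nestedAmplify <- function(template, outer, inner, max_product = 5000L,
                          max_mismatch = 0L, anchor_3prime = 3L) {
  outs <- amplify(template, outer$fwd, outer$rev, max_product,
                  max_mismatch, anchor_3prime)
  if (!length(outs))
    stopf("outer primers yield no product on '%s'",
          if (is(template, "GeneModel")) geneId(template) else "template")
  for (op in outs) {
    ins <- amplify(as.character(op@seq), inner$fwd, inner$rev, max_product,
                   max_mismatch, anchor_3prime)
    if (length(ins) == 1L) {
      ia <- ins[[1L]]
      return(new("Amplicon", gene_id = op@gene_id,
                 start = op@start + ia@start - 1L,
                 end = op@start + ia@end - 1L, seq = ia@seq))
    }
    if (length(ins) > 1L)
      stopf("inner primers bind at multiple sites within the outer product")
  }
  stopf("inner primers do not bind within the outer product (nesting error)")
}

#' Validate homeolog specificity of an inner primer pair
#'
#' Runs the inner PCR on both copies of a pair; the pair PASSes iff exactly
#' one copy yields a product.
#'
#' @param pair a \linkS4class{HomeologPair}.
#' @param fwd,rev the gene-specific inner \linkS4class{Primer}s.
#' @inheritParams amplify
#' @return List with \code{pass} (logical), \code{products} (named integer:
#'   product count per copy) and \code{lengths} (product lengths per copy).
#' @export
checkSpecificity <- function(pair, fwd, rev, max_product = 5000L,
                             max_mismatch = 0L, anchor_3prime = 3L) {
  copies <- pairCopies(pair)
  prods <- lapply(copies, amplify, fwd = fwd, rev = rev,
                  max_product = max_product, max_mismatch = max_mismatch,
                  anchor_3prime = anchor_3prime)
  counts <- vapply(prods, length, integer(1L))
  list(pass = sum(counts > 0L) == 1L, products = counts,
       lengths = lapply(prods, function(p)
         vapply(p, ampliconLength, integer(1L))))
}

#' Read / write primer tables
#'
#' Tab-delimited with columns \code{name}, \code{orientation},
#' \code{sequence}.
#'
#' @param file path.
#' @return \code{readPrimerTable}: named list of \linkS4class{Primer}s.
#' @export
readPrimerTable <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    Primer(df$name[i], df$sequence[i], df$orientation[i]))
  names(out) <- df$name
  out
}

#' @rdname readPrimerTable
#' @param primers list of \linkS4class{Primer}s.
#' @export
writePrimerTable <- function(primers, file) {
  df <- data.frame(name = vapply(primers, function(p) p@name, character(1L)),
                   orientation = vapply(primers, function(p) p@orientation,
                                        character(1L)),
                   sequence = vapply(primers, function(p)
                     as.character(p@seq), character(1L)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write amplicons as FASTA with coordinates in the description line
#'
#' @param amplicons list of \linkS4class{Amplicon}s.
#' @param file path.
#' @export
writeAmplicons <- function(amplicons, file) {
  seqs <- Biostrings::DNAStringSet(lapply(amplicons, ampliconSeq))
  names(seqs) <- vapply(amplicons, function(a)
    sprintf("%s %d-%d (%d bp)", a@gene_id, a@start, a@end,
            ampliconLength(a)), character(1L))
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
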