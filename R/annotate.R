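## Mutation-effect annotation with codon bookkeeping, epitope overlap and
## EMS-spectrum summaries.

#' Codon bookkeeping for a CDS position
#'
#' @param cds_pos 1-based position(s) in the concatenated CDS.
#' @return data.frame with \code{codon} (\code{ceiling(cds_pos / 3)}) and
#'   \code{offset} (1-3 within the codon).
#' @examples
#' codonIndex(c(145, 3, 448))  # codons 49, 1, 150
#' @export
codonIndex <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (any(cds_pos < 1L)) stopf("CDS positions are 1-based")
  codon <- (cds_pos + 2L) %/% 3L
  data.frame(codon = codon, offset = cds_pos - 3L * (codon - 1L))
}

#' Classify a mutation into an effect class
#'
#' ATG-anchored coordinates; negative positions are upstream. Coding
#' substitutions are classified by translating the wild-type and mutant
#' codons: \code{silent}, \code{missense}, \code{nonsense} (with
#' \code{truncated_length} = residues strictly before the premature stop)
#' or \code{start_loss} (codon 1 no longer ATG; the notes record whether
#' any downstream in-frame ATG exists). Indels whose length is not a
#' multiple of 3 are \code{frameshift}, with \code{truncated_length} found
#' by re-translating the shifted CDS to its first stop; in-frame indels are
#' class \code{inframe}. Non-coding positions yield \code{upstream},
#' \code{intron} or \code{downstream}.
#'
#' @param gm the \linkS4class{GeneModel}.
#' @param atg_pos ATG-anchored coordinate (negative = upstream, no zero).
#' @param ref reference base(s); must match the gene model (a
#'   reference-consistency error otherwise).
#' @param alt alternate base, or the inserted string for insertions.
#' @param kind \code{"substitution"}, \code{"insertion"} or
#'   \code{"deletion"}.
#' @return List of class \code{"Effect"}: \code{effect_class},
#'   \code{codon_index}, \code{codon_offset}, \code{wt_aa}, \code{mut_aa},
#'   \code{truncated_length}, \code{notes}.
#' @examples
#' fx <- referenceFixtures()
#' classifyMutation(fx$loci[["arah1.02"]], 304, "C", "T")  # nonsense
#' @export
classifyMutation <- function(gm, atg_pos, ref, alt,
                             kind = "substitution") {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"))
  locus <- atgToLocus(atg_pos, gm)
  have <- as.character(Biostrings::subseq(gm@locus_seq, locus,
                                          locus + nchar(ref) - 1L))
  if (have != ref)
    stopf("reference mismatch at %d: gene model has %s, mutation says %s",
          atg_pos, have, ref)
  eff <- list(effect_class = NA_character_, codon_index = NA_integer_,
              codon_offset = NA_integer_, wt_aa = NA_character_,
              mut_aa = NA_character_, truncated_length = NA_integer_,
              notes = "")
  class(eff) <- "Effect"
  map <- locusToCds(locus, gm)
  if (map$region != "cds") {
    eff$effect_class <- map$region
    return(eff)
  }
  cds <- as.character(cdsSeq(gm))
  ci <- codonIndex(map$cds_pos)
  eff$codon_index <- ci$codon
  eff$codon_offset <- ci$offset
  if (kind == "substitution") {
    wt_codon <- substr(cds, 3L * ci$codon - 2L, 3L * ci$codon)
    mut_codon <- wt_codon
    substr(mut_codon, ci$offset, ci$offset) <- alt
    eff$wt_aa <- translateCds(wt_codon)
    eff$mut_aa <- translateCds(mut_codon)
    if (ci$codon == 1L && mut_codon != "ATG") {
      eff$effect_class <- "start_loss"
      ncod <- nchar(cds) %/% 3L
      downstream <- vapply(2:ncod, function(k)
        substr(cds, 3L * k - 2L, 3L * k), character(1L))
      eff$notes <- if ("ATG" %in% downstream)
        sprintf("in-frame ATG at codon %d could reinitiate",
                which(downstream == "ATG")[1L] + 1L)
      else "no downstream in-frame ATG: protein knockout expected"
    } else if (eff$mut_aa == "*") {
      eff$effect_class <- "nonsense"
      eff$truncated_length <- ci$codon - 1L
      eff$notes <- sprintf(
        "premature stop at codon %d; %d residues precede the stop",
        ci$codon, ci$codon - 1L)
    } else if (eff$mut_aa == eff$wt_aa) {
      eff$effect_class <- "silent"
    } else {
      eff$effect_class <- "missense"
    }
  } else {
    len <- if (kind == "insertion") nchar(alt) else nchar(ref)
    mut_cds <- charsSeq(applyMutationToSeq(seqChars(cds), map$cds_pos,
                                           ref, alt, kind))
    if (len %% 3L != 0L) {
      eff$effect_class <- "frameshift"
      ncod <- nchar(mut_cds) %/% 3L
      prot <- translateCds(substr(mut_cds, 1L, 3L * ncod),
                           to_first_stop = TRUE)
      shifted <- translateCds(substr(mut_cds, 1L, 3L * ncod))
      if (grepl("\\*", shifted)) {
        eff$truncated_length <- nchar(prot)
        eff$notes <- sprintf("frameshift; %d residues before the new stop",
                             nchar(prot))
      } else {
        eff$notes <- "frameshift; no stop before the end of the model"
      }
    } else {
      eff$effect_class <- "inframe"
      eff$notes <- sprintf("in-frame %s of %d bp", kind, len)
    }
  }
  eff
}

#' @export
print.Effect <- function(x, ...) {
  cat(sprintf("Effect: %s", x$effect_class))
  if (!is.na(x$codon_index)) {
    cat(sprintf(" (codon %d", x$codon_index))
    if (!is.na(x$wt_aa)) cat(sprintf(", %s -> %s", x$wt_aa, x$mut_aa))
    cat(")")
  }
  if (nzchar(x$notes)) cat(" --", x$notes)
  cat("\n")
  invisible(x)
}

#' Classify a table of mutations
#'
#' @param loci named list of \linkS4class{GeneModel}s.
#' @param mutations data.frame with columns \code{gene_id},
#'   \code{atg_pos}, \code{ref}, \code{alt}, \code{kind}.
#' @return The input with appended columns \code{effect_class},
#'   \code{codon_index}, \code{wt_aa}, \code{mut_aa},
#'   \code{truncated_length}, \code{effect_notes}.
#' @export
classifyMutations <- function(loci, mutations) {
  effs <- lapply(seq_len(nrow(mutations)), function(i)
    classifyMutation(loci[[mutations$gene_id[i]]], mutations$atg_pos[i],
                     mutations$ref[i], mutations$alt[i], mutations$kind[i]))
  mutations$effect_class <- vapply(effs, `[[`, "", "effect_class")
  mutations$codon_index <- vapply(effs, `[[`, 0L, "codon_index")
  mutations$wt_aa <- vapply(effs, `[[`, "", "wt_aa")
  mutations$mut_aa <- vapply(effs, `[[`, "", "mut_aa")
  mutations$truncated_length <- vapply(effs, `[[`, 0L, "truncated_length")
  mutations$effect_notes <- vapply(effs, `[[`, "", "notes")
  mutations
}

#' Epitope overlap of a coding effect
#'
#' @param codon_index residue number of the affected codon (protein
#'   coordinates as supplied by the user; closed intervals, boundary
#'   residues included).
#' @param epitopes data.frame with columns \code{label}, \code{start},
#'   \code{end} (protein-coordinate intervals).
#' @return Character vector of overlapping epitope labels.
#' @examples
#' epitopeOverlap(333, data.frame(label = "12", start = 326, end = 335))
#' @export
epitopeOverlap <- function(codon_index, epitopes) {
  if (is.na(codon_index)) stopf("effect has no codon index")
  if (!nrow(epitopes)) return(character())
  epitopes$label[codon_index >= epitopes$start &
                 codon_index <= epitopes$end]
}

#' Summarize the substitution spectrum of a mutation set
#'
#' Tallies canonical EMS transitions (G->A, C->T) against everything else;
#' atypical records (non-canonical substitutions and indels) likely reflect
#' seed-stock impurity rather than mutagen action.
#'
#' @param mutations data.frame with columns \code{ref}, \code{alt},
#'   \code{kind}.
#' @return List with \code{g_to_a}, \code{c_to_t}, \code{other_sub},
#'   \code{indel}, \code{canonical}, \code{total} counts and
#'   \code{atypical} (the offending rows).
#' @export
spectrumSummary <- function(mutations) {
  sub <- mutations$kind == "substitution"
  ga <- sub & mutations$ref == "G" & mutations$alt == "A"
  ct <- sub & mutations$ref == "C" & mutations$alt == "T"
  list(g_to_a = sum(ga), c_to_t = sum(ct),
       other_sub = sum(sub & !ga & !ct), indel = sum(!sub),
       canonical = sum(ga | ct), total = nrow(mutations),
       atypical = mutations[!(ga | ct), , drop = FALSE])
}

#' Read / write mutation tables in compact notation
#'
#' Tab-delimited tables using the compact change notation "C145>T" /
#' "A442insA"; any extra columns are carried through.
#'
#' @param file path.
#' @return \code{readMutationTable}: data.frame with \code{gene_id},
#'   \code{atg_pos}, \code{ref}, \code{alt}, \code{kind} plus extras.
#' @export
readMutationTable <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  m <- regmatches(df$change,
                  regexec("^([ACGT])(-?\\d+)(>|ins|del)([ACGT]*)$",
                          df$change))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) stopf("unparseable change notation: %s", df$change[bad][1L])
  df$ref <- vapply(m, `[`, "", 2L)
  df$atg_pos <- as.integer(vapply(m, `[`, "", 3L))
  op <- vapply(m, `[`, "", 4L)
  df$alt <- vapply(m, `[`, "", 5L)
  df$kind <- c(">" = "substitution", ins = "insertion",
               del = "deletion")[op]
  df$change <- NULL
  df
}

#' @rdname readMutationTable
#' @param mutations data.frame with \code{gene_id}, \code{atg_pos},
#'   \code{ref}, \code{alt}, \code{kind} (extra columns are written too).
#' @export
writeMutationTable <- function(mutations, file) {
  op <- c(substitution = ">", insertion = "ins", deletion = "del")
  mutations$change <- paste0(mutations$ref, mutations$atg_pos,
                             op[mutations$kind],
                             ifelse(mutations$kind == "deletion", "",
                                    mutations$alt))
  keep <- c("gene_id", "change",
            setdiff(names(mutations),
                    c("gene_id", "change", "atg_pos", "ref", "alt",
                      "kind")))
  write.table(mutations[keep], file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
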