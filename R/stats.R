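## Mutation-frequency estimation with the 200-bp edge correction and
## screening-summary reporting.

#' Effective screened length of an amplicon
#'
#' 200 bp are subtracted per amplicon to adjust for the ~100-bp regions at
#' the top and bottom of a TILLING gel image that cannot be analyzed.
#'
#' @param L amplicon length(s), bp; must exceed 200.
#' @return \code{L - 200}.
#' @examples
#' effectiveBp(1278)  # 1078
#' @export
effectiveBp <- function(L) {
  if (any(L <= 200)) stopf("amplicon length must exceed 200 bp")
  L - 200
}

#' Edge-corrected mutation density (kb per mutation)
#'
#' Total effectively screened base pairs divided by the number of confirmed
#' mutations: \code{sum(effectiveBp(lengths)) * n_individuals /
#' n_mutations}.
#'
#' @param lengths amplicon lengths, bp (one per screened gene).
#' @param n_individuals individuals screened (each for all amplicons).
#' @param n_mutations confirmed mutation count; 0 yields an NA density (an
#'   undefined result, not an error).
#' @return List with \code{kb} (rounded to the nearest integer kb),
#'   \code{kb_exact}, \code{bp}, \code{effective_bp_per_individual},
#'   \code{n_individuals}, \code{n_mutations}.
#' @examples
#' kbPerSnp(c(2211, 1666, 1278, 1226, 1228, 1221), 3420, 27)$kb  # 966
#' @export
kbPerSnp <- function(lengths, n_individuals, n_mutations) {
  eff <- sum(effectiveBp(lengths))
  bp <- if (n_mutations >= 1) eff * n_individuals / n_mutations else NA_real_
  list(kb = if (is.na(bp)) NA_real_ else round(bp / 1000),
       kb_exact = bp / 1000, bp = bp,
       effective_bp_per_individual = eff,
       n_individuals = n_individuals, n_mutations = n_mutations)
}

#' Build a screen tally from confirmed mutations
#'
#' @param confirmed confirmed-mutation data.frame (needs \code{gene_id} and
#'   \code{group} columns; one row per confirmed mutation).
#' @param population the screened \linkS4class{Population} (supplies group
#'   sizes), or a data.frame with \code{group}/\code{screened} columns.
#' @param amplicons data.frame with \code{gene_id} and \code{length} (bp).
#' @return An object of class \code{ScreenTally}: list with
#'   \code{amplicons}, \code{groups} (label, individuals screened) and
#'   \code{counts} (gene_id, group, n).
#' @export
screenTally <- function(confirmed, population, amplicons) {
  grp <- if (is(population, "Population")) {
    tb <- table(groups(population))
    data.frame(group = names(tb), screened = as.integer(tb))
  } else population
  counts <- expand.grid(gene_id = amplicons$gene_id, group = grp$group,
                        stringsAsFactors = FALSE)
  counts$n <- vapply(seq_len(nrow(counts)), function(i)
    sum(confirmed$gene_id == counts$gene_id[i] &
        confirmed$group == counts$group[i]), integer(1L))
  structure(list(amplicons = amplicons, groups = grp, counts = counts),
            class = "ScreenTally")
}

#' @export
print.ScreenTally <- function(x, ...) {
  cat(sprintf("ScreenTally: %d amplicon(s), %d group(s), %d confirmed mutation(s)\n",
              nrow(x$amplicons), nrow(x$groups), sum(x$counts$n)))
  invisible(x)
}

#' Screening-summary report (amplicons, counts, kb/SNP)
#'
#' Reproduces the standard TILLING summary layout: one row per gene
#' (amplicon bp, effective bp, per-group and total confirmed mutation
#' counts), a totals row, plants-screened and kb/SNP rows per group and
#' overall. The overall density equals total effective bp over all groups
#' divided by total mutations.
#'
#' @param tally a \code{ScreenTally} from [screenTally()] or
#'   [runScreen()].
#' @param file optional CSV output path.
#' @return An object of class \code{FrequencyReport}: list with
#'   \code{table} (per-gene data.frame), \code{plants_screened},
#'   \code{kb_per_snp} and \code{kb_per_snp_exact} (named: one entry per
#'   group plus \code{"overall"}), and \code{effective_bp_per_individual}.
#' @export
table1Report <- function(tally, file = NULL) {
  amp <- tally$amplicons
  grps <- tally$groups$group
  tab <- data.frame(gene = amp$gene_id, amplicon_bp = amp$length,
                    effective_bp = effectiveBp(amp$length))
  for (g in grps)
    tab[[g]] <- vapply(amp$gene_id, function(gene)
      sum(tally$counts$n[tally$counts$gene_id == gene &
                         tally$counts$group == g]), integer(1L))
  tab$total <- if (length(grps) > 1L) rowSums(tab[, grps]) else tab[[grps]]
  totals <- data.frame(gene = "Total",
                       amplicon_bp = sum(tab$amplicon_bp),
                       effective_bp = sum(tab$effective_bp))
  for (g in grps) totals[[g]] <- sum(tab[[g]])
  totals$total <- sum(tab$total)
  tab <- rbind(tab, totals)
  screened <- setNames(tally$groups$screened, grps)
  kb <- kb_exact <- setNames(numeric(length(grps) + 1L),
                             c(grps, "overall"))
  for (g in grps) {
    r <- kbPerSnp(amp$length, screened[[g]],
                  sum(tally$counts$n[tally$counts$group == g]))
    kb[g] <- r$kb; kb_exact[g] <- r$kb_exact
  }
  r <- kbPerSnp(amp$length, sum(screened), sum(tally$counts$n))
  kb["overall"] <- r$kb; kb_exact["overall"] <- r$kb_exact
  out <- structure(list(table = tab, plants_screened = screened,
                        kb_per_snp = kb, kb_per_snp_exact = kb_exact,
                        effective_bp_per_individual =
                          sum(effectiveBp(amp$length))),
                   class = "FrequencyReport")
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
  }
  out
}

#' @export
print.FrequencyReport <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("Plants screened:",
      paste(sprintf("%s: %d", names(x$plants_screened),
                    x$plants_screened), collapse = "; "),
      sprintf("(total %d)\n", sum(x$plants_screened)))
  cat("kb/SNP:", paste(sprintf("%s: %s", names(x$kb_per_snp),
                               format(x$kb_per_snp)), collapse = "; "), "\n")
  invisible(x)
}
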