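## shared fixtures; referenceFixtures() is memoized inside the package so
## repeated calls are free

fixtureAmplicons <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- referenceFixtures()
    out <- lapply(names(fx$loci), function(g)
      nestedAmplify(fx$loci[[g]], fx$primers[[g]]$outer,
                    fx$primers[[g]]$inner))
    names(out) <- names(fx$loci)
    cache <<- out
    out
  }
})

## a tiny intronless gene for coordinate unit tests:
## 10 bp upstream, 4-codon CDS (ATG GCG TGC TAA), 8 bp downstream
toyGene <- function(upstream_len = 10L) {
  up <- strrep("A", upstream_len)
  GeneModel("toy", paste0(up, "ATGGCGTGCTAA", "GGGGCCCC"), upstream_len,
            IRanges::IRanges(upstream_len + 1L, upstream_len + 12L))
}

## a gene with two exons: upstream 0, CDS [1..3] + intron [4..9] + CDS
## [10..18]: ATG | intron | GCGTGCTAA
twoExonGene <- function() {
  GeneModel("twoexon", paste0("ATG", "TTTTTT", "GCGTGCTAA", "AAAA"), 0L,
            rbind(c(1L, 3L), c(10L, 18L)))
}

## brute-force IUPAC site scanner used as the independent oracle
IUPAC_MAP <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

bruteForceSites <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s); k <- length(p)
  out <- integer()
  for (i in seq_len(n - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1L] %in% IUPAC_MAP[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i)
  }
  out
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
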