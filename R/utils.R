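## internal helpers shared across modules

#' @importFrom methods new is validObject slot
#' @importFrom stats rpois rnorm runif
#' @importFrom utils read.delim write.table
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Character-vector <-> string helpers; sequences are manipulated as
## character vectors during fixture construction and as DNAString elsewhere.
seqChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1L]]
charsSeq <- function(x) paste(x, collapse = "")

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
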