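#' @importFrom stats rbinom rgeom rpois runif setNames complete.cases
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Translate a nucleotide string in frame 0 using the standard genetic code;
# trailing partial codon is dropped. Codons with non-ACGT characters give "X".
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# Gene name without the allele suffix (IGHV3-1*01 -> IGHV3-1).
gene_of <- function(call) sub("\\*.*$", "", call)

# V family: gene name up to (excluding) the first hyphen (IGHV3-1*01 -> IGHV3).
family_of <- function(call) sub("-.*$", "", gene_of(call))

# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)
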