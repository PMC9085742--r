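#' @import data.table
#' @importFrom methods is
#' @importFrom stats median rnorm runif rnbinom rlnorm var sd pnorm cor lm coef
#' @importFrom utils head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# BsaI / Esp3I recognition sites, both strands; golden-gate cloning requires
# their absence from barcodes and cloning junctions.
ENZYME_SITES <- c("GGTCTC", "CGTCTC", "GAGACC", "GAGACG")
ENZYME_REGEX <- paste(ENZYME_SITES, collapse = "|")
HOMOPOLYMER_REGEX <- "A{5}|C{5}|G{5}|T{5}"

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Deterministic rounding used for all planted-fraction counts: floor(n*frac + 0.5)
frac_count <- function(n, frac) as.integer(floor(n * frac + 0.5))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

element_id <- function(variant_id, allele) paste(variant_id, allele, sep = "_")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
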