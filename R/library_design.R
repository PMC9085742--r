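# Fixed flanking sequences of the synthesized oligo. Chosen so that no
# BsaI/Esp3I site can span a junction regardless of insert content: the
# 5' adapter ends in "TT" (no enzyme-site prefix ends in T) and both the
# cloning spacer and the 3' adapter start with "AA" (no enzyme-site suffix
# starts with A). Placeholders for assay-specific priming sequences.
OLIGO_ADAPTER_5 <- "ACTGGCCGCTTCACTT"
OLIGO_SPACER    <- "AAGGTACCTCTAGATT"
OLIGO_ADAPTER_3 <- "AACGCCTGCAGGTCAA"

#' Filter candidate rare variants by the library-design criteria
#'
#' Keeps single-nucleotide variants with MAF strictly below 0.001, detected
#' by at least two sequencing technologies, and within `window_bp` of the
#' nearest TSS (boundary inclusive). Variants flagged as seen in multiple
#' probands, previously reported causative, or with predicted coding impact
#' are dropped, as are malformed records (per-record reason attached).
#'
#' @param variants data.table of candidate variants.
#' @param tss TSS annotation (data.table: contig, pos).
#' @param window_bp maximum distance to the nearest TSS (default 100 kb).
#' @param maf_max exclusive MAF upper bound.
#' @return the retained variants with a `dist_to_tss` column (signed,
#'   pos - nearest TSS); attribute `rejected` is a data.table of
#'   (variant_id, reason).
#' @export
filter_variants <- function(variants, tss, window_bp = 100000L,
                            maf_max = 0.001) {
  if (is.null(tss) || nrow(tss) == 0L) stop_config("TSS annotation is empty")
  v <- as.data.table(variants)
  reason <- rep(NA_character_, nrow(v))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(!v$ref_allele %in% DNA_BASES | !v$alt_allele %in% DNA_BASES,
       "allele not a single A/C/G/T")
  flag(v$ref_allele == v$alt_allele, "ref equals alt")
  flag(is.na(v$pos) | v$pos < 1L, "invalid position")
  flag(is.na(v$maf) | v$maf < 0 | v$maf > 1, "invalid MAF")
  flag(v$maf >= maf_max, sprintf("MAF >= %g", maf_max))
  flag(v$n_technologies < 2L, "detected by < 2 technologies")
  flag(isTRUE_vec(v$seen_in_multiple_probands), "seen in multiple probands")
  flag(isTRUE_vec(v$known_causative), "known causative")
  flag(isTRUE_vec(v$coding_impact), "predicted coding impact")
  d <- nearest_tss_distance(v, as.data.table(tss))
  flag(is.na(d) | abs(d) > window_bp,
       sprintf("> %d bp from nearest TSS", window_bp))
  v[, dist_to_tss := d]
  kept <- v[is.na(reason)]
  rejected <- data.table(variant_id = v$variant_id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  if (nrow(rejected))
    message(sprintf("filter_variants: dropped %d/%d variant(s)",
                    nrow(rejected), nrow(v)))
  setattr(kept, "rejected", rejected)
  kept[]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Extract the genomic insert window around a variant
#'
#' Returns the plus-strand sequence of `length` nt with the variant base at
#' 1-based offset `ceiling(length/2)` (for the default 100 nt: 49 bases
#' upstream, the variant, 50 downstream).
#'
#' @param reference a [Biostrings::DNAStringSet] (or named character) of
#'   contigs.
#' @param contig,pos variant coordinates (1-based).
#' @param length insert length.
#' @return character insert sequence.
#' @export
extract_window <- function(reference, contig, pos, length = 100L) {
  chars <- if (is.character(reference)) reference else as.character(reference)
  if (!contig %in% names(chars)) stop_config("contig '%s' not in reference", contig)
  up <- as.integer(ceiling(length / 2) - 1L)
  start <- pos - up
  end <- start + length - 1L
  if (start < 1L || end > nchar(chars[[contig]]))
    stop_config("window [%d,%d] off the edge of contig '%s'", start, end, contig)
  substr(chars[[contig]], start, end)
}

#' All four single-nucleotide analogs of an insert
#'
#' @param insert insert sequence.
#' @param offset 1-based position of the variant within the insert.
#' @return named character vector of 4 sequences (names A, C, G, T), one per
#'   nucleotide at `offset`.
#' @export
make_analogs <- function(insert, offset) {
  if (offset < 1L || offset > nchar(insert))
    stop_config("offset %d outside insert of length %d", offset, nchar(insert))
  out <- vapply(DNA_BASES, function(b) {
    s <- insert
    substr(s, offset, offset) <- b
    s
  }, character(1))
  out
}

barcode_mask_keys <- function(x, len) {
  lapply(seq_len(len), function(i)
    paste0(substr(x, 1L, i - 1L), substr(x, i + 1L, len)))
}

#' Generate a table of distinct sequencing barcodes
#'
#' Draws random `length`-mers and keeps those that avoid the BsaI (GGTCTC)
#' and Esp3I (CGTCTC) recognition sites on either strand, homopolymer runs of
#' 5+, and GC content outside 25-75%; the retained set additionally has
#' minimum pairwise Hamming distance 2 (enforced by per-position masked-key
#' deduplication), so a single sequencing error cannot convert one barcode
#' into another.
#'
#' @param n_sequences number of library sequences needing barcodes.
#' @param per_seq barcodes per sequence.
#' @param length barcode length (nt).
#' @param rng_seed integer seed; the table is deterministic given the seed.
#' @return data.table (seq_index, slot, barcode), `n_sequences * per_seq`
#'   rows, all barcodes distinct.
#' @export
assign_barcodes <- function(n_sequences, per_seq = 5L, length = 12L,
                            rng_seed = 1L) {
  n_needed <- n_sequences * per_seq
  if (n_needed == 0L)
    return(data.table(seq_index = integer(), slot = integer(),
                      barcode = character()))
  if (4^length < 20 * n_needed)
    stop_config("barcode space 4^%d too small for %d barcodes", length, n_needed)
  gc_lo <- ceiling(0.25 * length)
  gc_hi <- floor(0.75 * length)
  with_seed(rng_seed, {
    pool <- character(0)
    for (try in 1:10) {
      batch_n <- max(50000L, 2L * n_needed)
      m <- matrix(sample(DNA_BASES, batch_n * length, replace = TRUE),
                  nrow = batch_n)
      cand <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      gc <- rowSums(m == "G" | m == "C")
      ok <- gc >= gc_lo & gc <= gc_hi &
        !grepl(ENZYME_REGEX, cand) & !grepl(HOMOPOLYMER_REGEX, cand)
      pool <- unique(c(pool, cand[ok]))
      # masked-key dedup: survivors have pairwise Hamming distance >= 2
      keep <- rep(TRUE, length(pool))
      for (key in barcode_mask_keys(pool, length))
        keep <- keep & !duplicated(key)
      pool <- pool[keep]
      if (length(pool) >= n_needed) break
    }
    if (length(pool) < n_needed)
      stop_config("barcode constraint space exhausted: %d of %d after retries (length=%d)",
                  length(pool), n_needed, length)
    data.table(seq_index = rep(seq_len(n_sequences), each = per_seq),
               slot = rep(seq_len(per_seq), n_sequences),
               barcode = pool[seq_len(n_needed)])
  })
}

#' Design the barcoded MPRA oligo library
#'
#' For each (filtered) variant, extracts the 100-nt insert centered on the
#' variant position, creates the four single-nucleotide analogs, labels each
#' allele (`reference`, `variant`, or `alternative`), and attaches `per_seq`
#' unique barcodes per analog. The full synthesized oligo is
#' adapter + insert + cloning spacer + barcode + adapter; the fixed flanks
#' guarantee no BsaI/Esp3I site can span a junction.
#'
#' @param variants filtered variant table (needs ref_allele / alt_allele).
#' @param reference contig sequences ([Biostrings::DNAStringSet] or named
#'   character).
#' @param per_seq barcodes per analog (default 5).
#' @param insert_len insert length (default 100).
#' @param seed barcode RNG seed.
#' @return object of class `mpra_library`: list with `oligos` (data.table,
#'   one row per oligo) and `skipped` (variants whose window fell off a
#'   contig edge).
#' @export
build_library <- function(variants, reference, per_seq = 5L,
                          insert_len = 100L, seed = 1L) {
  v <- as.data.table(variants)
  chars <- if (is.character(reference)) reference else as.character(reference)
  up <- as.integer(ceiling(insert_len / 2) - 1L)
  offset <- up + 1L
  clen <- nchar(chars)[match(v$contig, names(chars))]
  ok <- !is.na(clen) & v$pos - up >= 1L & v$pos - up + insert_len - 1L <= clen
  skipped <- v[!ok, .(variant_id,
                      reason = "insert window off contig edge")]
  if (nrow(skipped))
    message(sprintf("build_library: skipped %d variant(s) at contig edges",
                    nrow(skipped)))
  v <- v[ok]
  n <- nrow(v)
  if (n == 0L) {
    lib <- list(oligos = data.table(
      oligo_id = character(), variant_id = character(), allele = character(),
      label = character(), barcode = character(), insert = character(),
      full_oligo = character()), skipped = skipped)
    return(structure(lib, class = "mpra_library"))
  }
  ins_ref <- substr(chars[v$contig], v$pos - up, v$pos - up + insert_len - 1L)
  center <- substr(ins_ref, offset, offset)
  if (!all(center == v$ref_allele))
    stop_config("reference allele mismatch at %d variant(s): annotation and reference sequence disagree",
                sum(center != v$ref_allele))
  # 4 analogs per variant, vectorized over the whole table
  ol <- v[rep(seq_len(n), each = 4L),
          .(variant_id, ref_allele, alt_allele)]
  ol[, allele := rep(DNA_BASES, n)]
  ol[, insert := {
    s <- rep(ins_ref, each = 4L)
    substr(s, offset, offset) <- allele
    s
  }]
  ol[, label := fifelse(allele == ref_allele, "reference",
                        fifelse(allele == alt_allele, "variant", "alternative"))]
  bc <- assign_barcodes(nrow(ol), per_seq = per_seq, rng_seed = seed)
  oligos <- ol[bc$seq_index]
  oligos[, `:=`(slot = bc$slot, barcode = bc$barcode)]
  oligos[, oligo_id := sprintf("%s_%s_bc%d", variant_id, allele, slot)]
  oligos[, full_oligo := paste0(OLIGO_ADAPTER_5, insert, OLIGO_SPACER,
                                barcode, OLIGO_ADAPTER_3)]
  validate_oligo_junctions(oligos, insert_len)
  oligos <- oligos[, .(oligo_id, variant_id, allele, label, slot, barcode,
                       insert, full_oligo)]
  structure(list(oligos = oligos[], skipped = skipped),
            class = "mpra_library")
}

# junction windows (5 nt each side of every boundary) and barcodes must be
# free of golden-gate sites; the insert interior is genomic and exempt
validate_oligo_junctions <- function(oligos, insert_len) {
  a5 <- nchar(OLIGO_ADAPTER_5)
  sp <- nchar(OLIGO_SPACER)
  bl <- nchar(oligos$barcode[1])
  cuts <- c(a5, a5 + insert_len, a5 + insert_len + sp,
            a5 + insert_len + sp + bl)
  for (cut in cuts) {
    win <- substr(oligos$full_oligo, pmax(1L, cut - 4L), cut + 5L)
    if (any(grepl(ENZYME_REGEX, win)))
      stop("oligo junction creates a BsaI/Esp3I site; adapters misconfigured")
  }
  if (any(grepl(ENZYME_REGEX, oligos$barcode)))
    stop("barcode contains a BsaI/Esp3I site")
  invisible(TRUE)
}

#' @export
print.mpra_library <- function(x, ...) {
  cat(sprintf("MPRA library: %d oligos (%d elements, %d variants); %d skipped\n",
              nrow(x$oligos),
              nrow(unique(x$oligos[, .(variant_id, allele)])),
              length(unique(x$oligos$variant_id)),
              nrow(x$skipped)))
  invisible(x)
}
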