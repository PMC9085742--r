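#' Count barcode tags in a targeted-sequencing FASTQ
#'
#' The first `tag_len` bases of each read are the barcode tag. Reads shorter
#' than `tag_len` or with an ambiguous base (N) in the tag are dropped and
#' counted.
#'
#' @param fastq path to a FASTQ file (plain or gzipped), or a
#'   [Biostrings::DNAStringSet] of reads.
#' @param tag_len tag length (default 12).
#' @return list: `counts` (named integer, tag -> reads), `total`,
#'   `dropped_short`, `dropped_n`.
#' @export
parse_tags <- function(fastq, tag_len = 12L) {
  reads <- if (is(fastq, "DNAStringSet")) fastq else {
    tryCatch(Biostrings::readDNAStringSet(fastq, format = "fastq"),
             error = function(e)
               stop_config("failed to read FASTQ '%s': %s", fastq,
                           conditionMessage(e)))
  }
  total <- length(reads)
  long_enough <- Biostrings::width(reads) >= tag_len
  tags <- substr(as.character(reads[long_enough]), 1L, tag_len)
  has_n <- grepl("[^ACGT]", tags)
  counts <- c(table(tags[!has_n]))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, total = total,
       dropped_short = sum(!long_enough),
       dropped_n = sum(has_n))
}

#' Assign tag counts to library barcodes
#'
#' Exact matching by default. With `max_mismatch = 1`, an unmatched tag is
#' rescued only if exactly one barcode lies within Hamming distance 1
#' (ambiguous tags stay unmatched); the library's pairwise-distance >= 2
#' guarantee makes this rescue safe.
#'
#' @param tag_counts named integer vector from [parse_tags()].
#' @param barcode_table data.table with a `barcode` column (injective).
#' @param max_mismatch 0 (exact) or 1.
#' @return list: `barcode_counts` (integer vector aligned with
#'   `barcode_table`, zeros kept), `matched`, `ambiguous`, `unmatched` (read
#'   totals), `match_rate`.
#' @export
match_barcodes <- function(tag_counts, barcode_table, max_mismatch = 0L) {
  bt <- as.data.table(barcode_table)
  if (anyDuplicated(bt$barcode)) stop_config("barcode table is not injective")
  tags <- names(tag_counts)
  n_reads <- sum(tag_counts)
  hit <- match(tags, bt$barcode)
  bc_counts <- rep(0L, nrow(bt))
  exact <- !is.na(hit)
  if (any(exact)) {
    agg <- rowsum(as.integer(tag_counts[exact]), group = hit[exact])
    bc_counts[as.integer(rownames(agg))] <- as.integer(agg)
  }
  ambiguous <- 0L
  if (max_mismatch >= 1L && any(!exact) && nrow(bt) > 0L) {
    len <- nchar(bt$barcode[1])
    rest <- tags[!exact]
    pairs <- vector("list", len)
    bc_keys <- barcode_mask_keys(bt$barcode, len)
    tag_keys <- barcode_mask_keys(rest, len)
    for (i in seq_len(len)) {
      bcdt <- data.table(mask = bc_keys[[i]], bc_i = seq_len(nrow(bt)))
      tgdt <- data.table(mask = tag_keys[[i]], tag_i = seq_along(rest))
      j <- bcdt[tgdt, on = "mask", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(j)) pairs[[i]] <- j[, .(tag_i, bc_i)]
    }
    pairs <- unique(rbindlist(pairs))
    if (nrow(pairs)) {
      nbc <- pairs[, .(n_bc = uniqueN(bc_i), bc_i = bc_i[1]), by = tag_i]
      uniq <- nbc[n_bc == 1L]
      amb <- nbc[n_bc > 1L]
      if (nrow(uniq)) {
        add <- rowsum(as.integer(tag_counts[!exact][uniq$tag_i]),
                      group = uniq$bc_i)
        bc_counts[as.integer(rownames(add))] <-
          bc_counts[as.integer(rownames(add))] + as.integer(add)
      }
      ambiguous <- sum(tag_counts[!exact][amb$tag_i])
    }
  }
  matched <- sum(bc_counts)
  list(barcode_counts = bc_counts, matched = matched, ambiguous = ambiguous,
       unmatched = n_reads - matched - ambiguous,
       match_rate = if (n_reads > 0) matched / n_reads else 0)
}

#' Collapse per-barcode counts to per-element counts
#'
#' An element's count is the sum of the reads over its barcodes (five in the
#' default design). Elements whose barcodes all have zero counts are kept so
#' the matrix dimension always matches the design.
#'
#' @param barcode_counts integer vector aligned with `barcode_table` rows.
#' @param barcode_table data.table with `barcode`, `variant_id`, `allele`.
#' @return data.table (variant_id, allele, count), one row per element, in
#'   stable (variant_id, allele) order.
#' @export
collapse_elements <- function(barcode_counts, barcode_table) {
  bt <- as.data.table(barcode_table)
  bt2 <- copy(bt)[, count := as.integer(barcode_counts)]
  out <- bt2[, .(count = sum(count)), keyby = .(variant_id, allele)]
  out[]
}

#' Count one sample's FASTQ into per-element counts
#'
#' @inheritParams parse_tags
#' @inheritParams match_barcodes
#' @return list: `elements` (data.table variant_id, allele, count) and `qc`
#'   (one-row data.table of read-fate totals; matched + ambiguous +
#'   unmatched + dropped = total).
#' @export
count_sample <- function(fastq, barcode_table, tag_len = 12L,
                         max_mismatch = 0L) {
  tg <- parse_tags(fastq, tag_len = tag_len)
  mb <- match_barcodes(tg$counts, barcode_table, max_mismatch = max_mismatch)
  qc <- data.table(total = tg$total, matched = mb$matched,
                   ambiguous = mb$ambiguous, unmatched = mb$unmatched,
                   dropped = tg$dropped_short + tg$dropped_n,
                   match_rate = mb$match_rate)
  list(elements = collapse_elements(mb$barcode_counts, barcode_table), qc = qc)
}

#' Assemble the element x sample count matrix
#'
#' @param sample_sheet data.table: sample_id, condition (pDNA/cDNA),
#'   replicate, fastq (file path).
#' @param barcode_table data.table: barcode, variant_id, allele.
#' @param max_mismatch barcode mismatch tolerance (see [match_barcodes()]).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`; per-sample QC in `metadata()$qc`.
#' @export
assemble_matrix <- function(sample_sheet, barcode_table, max_mismatch = 0L) {
  ss <- as.data.table(sample_sheet)
  if (anyDuplicated(ss$sample_id))
    stop_config("duplicate sample id(s): %s",
                paste(unique(ss$sample_id[duplicated(ss$sample_id)]),
                      collapse = ", "))
  missing <- ss$fastq[!file.exists(ss$fastq)]
  if (length(missing))
    stop_config("FASTQ file(s) not found: %s", paste(missing, collapse = ", "))
  per <- lapply(ss$fastq, count_sample, barcode_table = barcode_table,
                max_mismatch = max_mismatch)
  elements <- per[[1]]$elements[, .(variant_id, allele)]
  counts <- vapply(per, function(p) p$elements$count,
                   integer(nrow(elements)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(elements))
  dimnames(counts) <- list(element_id(elements$variant_id, elements$allele),
                           ss$sample_id)
  qc <- rbindlist(lapply(per, `[[`, "qc"))
  qc[, sample_id := ss$sample_id]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(elements),
    colData = S4Vectors::DataFrame(ss, row.names = ss$sample_id))
  S4Vectors::metadata(se)$qc <- qc[]
  se
}
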