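# File-format readers/writers for the pipeline's external interfaces.
# Conventions: variant tables are 1-based (VCF-like TSV); interval files are
# 0-based half-open BED; HPO annotation TSVs carry the term universe size in
# a "# universe=<N>" header line.

#' @rdname mpra_io
#' @param sequences a [Biostrings::DNAStringSet].
#' @param path output/input file path.
#' @export
write_reference_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Pipeline file formats
#'
#' Small readers/writers for the TSV/BED/FASTA interfaces between pipeline
#' stages. All TSVs are tab-separated with a header row.
#'
#' @name mpra_io
#' @rdname mpra_io
#' @param tss data.table (contig, pos, strand, gene_id), 1-based positions.
#' @export
write_tss_bed <- function(tss, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = tss$contig,
    ranges = IRanges::IRanges(start = tss$pos, width = 1L),
    strand = tss$strand)
  gr$name <- tss$gene_id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname mpra_io
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table(contig = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = gr$name)
}

#' @rdname mpra_io
#' @param sites GRanges with `tf_name` column.
#' @export
write_tf_bed <- function(sites, path) {
  gr <- sites
  gr$name <- gr$tf_name
  gr$tf_name <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname mpra_io
#' @export
read_tf_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$tf_name <- gr$name
  gr$name <- NULL
  gr
}

#' @rdname mpra_io
#' @param x a data.table.
#' @export
write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname mpra_io
#' @export
read_variants_tsv <- function(path) {
  v <- fread(path, sep = "\t")
  logical_cols <- intersect(c("seen_in_multiple_probands", "known_causative",
                              "coding_impact"), names(v))
  for (cl in logical_cols) set(v, j = cl, value = as.logical(v[[cl]]))
  v
}

#' @rdname mpra_io
#' @param annotations data.table (entity_id, terms comma-joined).
#' @param universe integer universe size, stored in the file header.
#' @export
write_hpo_tsv <- function(annotations, path, universe) {
  stopifnot(all(c("entity_id", "terms") %in% names(annotations)))
  writeLines(c(sprintf("# universe=%d", as.integer(universe)),
               "entity_id\tterms",
               paste(annotations$entity_id, annotations$terms, sep = "\t")),
             path)
  invisible(path)
}

#' @rdname mpra_io
#' @export
read_hpo_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^# universe=(\\d+)$", header))[[1]]
  if (length(m) < 2L)
    stop_config("HPO file '%s' lacks a '# universe=<N>' header", path)
  ann <- fread(path, sep = "\t", skip = 1L)
  list(annotations = ann, universe = as.integer(m[2]))
}

#' @rdname mpra_io
#' @param se SummarizedExperiment with a `counts` assay.
#' @param counts_path,samples_path count matrix / sample sheet TSVs.
#' @export
write_count_matrix <- function(se, counts_path, samples_path) {
  k <- SummarizedExperiment::assay(se, "counts")
  rd <- as.data.table(SummarizedExperiment::rowData(se)[, c("variant_id", "allele")])
  out <- cbind(rd, as.data.table(k))
  fwrite(out, counts_path, sep = "\t")
  cd <- as.data.table(SummarizedExperiment::colData(se))
  fwrite(cd[, .(sample_id, condition, replicate)], samples_path, sep = "\t")
  invisible(counts_path)
}

#' @rdname mpra_io
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- fread(counts_path, sep = "\t")
  ss <- fread(samples_path, sep = "\t")
  meta <- c("variant_id", "allele")
  missing_samples <- setdiff(ss$sample_id, names(tab))
  if (length(missing_samples))
    stop_config("count matrix lacks sample column(s): %s",
                paste(missing_samples, collapse = ", "))
  k <- as.matrix(tab[, ss$sample_id, with = FALSE])
  rownames(k) <- element_id(tab$variant_id, tab$allele)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = k),
    rowData = S4Vectors::DataFrame(tab[, meta, with = FALSE]),
    colData = S4Vectors::DataFrame(ss, row.names = ss$sample_id))
}

#' @rdname mpra_io
#' @param library an `mpra_library`.
#' @param fasta_path,table_path oligo FASTA / barcode table TSV paths.
#' @export
write_library <- function(library, fasta_path, table_path) {
  ol <- library$oligos
  seqs <- Biostrings::DNAStringSet(ol$full_oligo)
  names(seqs) <- ol$oligo_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  fwrite(ol[, .(barcode, variant_id, allele, label, oligo_id)],
         table_path, sep = "\t")
  invisible(fasta_path)
}

#' @rdname mpra_io
#' @export
read_barcode_table <- function(path) fread(path, sep = "\t")
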