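#' Run the full synthetic MPRA pipeline
#'
#' Chains every stage on a simulated cohort: reference + TSS generation,
#' cohort variant simulation, design-criteria filtering, ground-truth
#' planting, oligo library design, count simulation (optionally via FASTQ
#' emission and barcode counting, exercising the quantification stage),
#' activity testing, variant-effect calling, TF/HPO generation, overlap
#' testing and prioritization.
#'
#' @param config an [sim_config()].
#' @param out_dir optional directory; when given, every interface file
#'   (FASTA, BED, TSVs, FASTQ) is written there.
#' @param via_fastq emit FASTQ and re-count reads instead of using the
#'   simulated matrix directly (slower; exercises [assemble_matrix()]).
#' @param alpha activity significance level.
#' @param z_threshold,q_threshold prioritization thresholds.
#' @return list with all intermediate and final objects: `reference`,
#'   `variants`, `truth`, `library`, `counts` (SummarizedExperiment),
#'   `activity`, `effects`, `tf_hpo`, `overlap_tests`, `prioritized`.
#' @export
run_pipeline <- function(config, out_dir = NULL, via_fastq = FALSE,
                         alpha = 0.05, z_threshold = 2, q_threshold = 0.05) {
  ref <- generate_reference(config)
  vars <- generate_cohort_variants(config, ref)
  kept <- filter_variants(vars, ref$tss, window_bp = config$window_bp)
  truth <- plant_truth(config, kept)
  lib <- build_library(kept, ref$sequences, per_seq = config$barcodes_per_element,
                       insert_len = config$insert_len, seed = config$seed)
  sim <- simulate_counts(config, lib, truth)
  counts <- sim
  if (via_fastq) {
    fq_dir <- if (is.null(out_dir)) tempfile("fastq") else file.path(out_dir, "fastq")
    sheet <- emit_fastq(sim, fq_dir)
    bt <- S4Vectors::metadata(sim)$barcode_table
    counts <- assemble_matrix(sheet, bt)
  }
  act <- test_activity(counts, alpha = alpha)
  eff <- variant_effects(act, kept, z_threshold = z_threshold)
  tfhpo <- generate_tf_and_hpo(config, kept, truth)
  tf_map <- intersect_tf(kept, tfhpo$sites)
  ov <- hpo_overlap_tests(kept, tf_map, tfhpo$proband_hpo, tfhpo$tf_hpo,
                          tfhpo$universe)
  pri <- prioritize(ov, eff, q_threshold = q_threshold,
                    z_threshold = z_threshold)
  res <- list(reference = ref, variants = kept, truth = truth, library = lib,
              counts = counts, activity = act, effects = eff, tf_hpo = tfhpo,
              overlap_tests = ov, prioritized = pri)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_reference_fasta(res$reference$sequences, p("reference.fa"))
  write_tss_bed(res$reference$tss, p("tss.bed"))
  write_tsv(res$variants, p("variants.tsv"))
  write_library(res$library, p("library.fa"), p("barcodes.tsv"))
  write_count_matrix(res$counts, p("counts.tsv"), p("samples.tsv"))
  write_tsv(res$activity, p("activity.tsv"))
  write_tsv(res$effects, p("variant_effects.tsv"))
  write_tf_bed(res$tf_hpo$sites, p("tf_clusters.bed"))
  write_hpo_tsv(res$tf_hpo$tf_hpo, p("tf_hpo.tsv"), res$tf_hpo$universe)
  write_hpo_tsv(res$tf_hpo$proband_hpo, p("proband_hpo.tsv"),
                res$tf_hpo$universe)
  write_tsv(res$overlap_tests, p("overlap_tests.tsv"))
  write_tsv(res$prioritized, p("prioritized.tsv"))
  write_tsv(data.table(
    variant_id = res$truth$effects$variant_id,
    direction = res$truth$effects$direction), p("truth_effects.tsv"))
  invisible(out_dir)
}
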