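#' Simulation configuration for the synthetic MPRA cohort
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' the published study design this pipeline targets: 111 probands contributing
#' 1958 de novo and 1101 inherited rare variants within +/- 100 kb of a TSS,
#' ~20% of reference elements with real regulatory activity (split evenly
#' between activators and repressors), ~4.5% of variants with a genuine
#' allelic effect (decrease:increase roughly 51:40), five 12-nt barcodes per
#' element, and negative-binomial sequencing noise around a lognormal
#' per-oligo plasmid abundance.
#'
#' @param seed integer RNG seed; all generator operations are deterministic
#'   functions of the config (including this seed).
#' @param n_probands cohort size.
#' @param n_de_novo,n_inherited number of de novo / inherited rare SNVs.
#' @param contig_lengths named integer vector, synthetic contig sizes in bp.
#' @param n_tss number of annotated transcription start sites to place.
#' @param window_bp half-width of the TSS window in bp (variants fall within
#'   this distance of a TSS).
#' @param frac_active_ref fraction of reference elements with planted
#'   regulatory activity.
#' @param frac_effect_variants fraction of variants with a planted allelic
#'   effect.
#' @param activity_log2fc,allelic_log2fc planted effect magnitudes (log2).
#' @param mean_depth_per_oligo expected plasmid-library depth per barcode.
#' @param depth_sdlog lognormal sdlog of per-barcode abundance (synthesis /
#'   cloning unevenness).
#' @param nb_dispersion negative-binomial dispersion alpha (> 0), variance
#'   \eqn{\mu + \alpha \mu^2}, applied per barcode.
#' @param n_cdna_reps,n_pdna_reps number of cDNA (biological) and pDNA
#'   (technical) replicates sequenced.
#' @param n_tfs number of transcription factors with ChIP clusters.
#' @param tf_bound_frac fraction of variants falling inside at least one TF
#'   binding interval.
#' @param hpo_universe total number of annotated HPO terms (the universe N of
#'   the hypergeometric overlap test).
#' @param terms_per_entity HPO terms annotated to each TF and each proband.
#' @param n_planted_overlaps number of (proband, TF) pairs with forced HPO
#'   term overlap, planted at variants that also carry an allelic effect.
#' @param barcodes_per_element barcodes per library element.
#' @param insert_len genomic insert length (nt).
#'
#' @return an object of class `mpra_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_probands = 111L,
                       n_de_novo = 1958L,
                       n_inherited = 1101L,
                       contig_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_tss = 60L,
                       window_bp = 100000L,
                       frac_active_ref = 0.20,
                       frac_effect_variants = 0.045,
                       activity_log2fc = 1,
                       allelic_log2fc = 1,
                       mean_depth_per_oligo = 500,
                       depth_sdlog = 0.5,
                       nb_dispersion = 0.05,
                       n_cdna_reps = 3L,
                       n_pdna_reps = 2L,
                       n_tfs = 20L,
                       tf_bound_frac = 0.3,
                       hpo_universe = 5000L,
                       terms_per_entity = 20L,
                       n_planted_overlaps = 8L,
                       barcodes_per_element = 5L,
                       insert_len = 100L) {
  cfg <- list(
    seed = as.integer(seed), n_probands = as.integer(n_probands),
    n_de_novo = as.integer(n_de_novo), n_inherited = as.integer(n_inherited),
    contig_lengths = contig_lengths, n_tss = as.integer(n_tss),
    window_bp = as.integer(window_bp),
    frac_active_ref = frac_active_ref,
    frac_effect_variants = frac_effect_variants,
    activity_log2fc = activity_log2fc, allelic_log2fc = allelic_log2fc,
    mean_depth_per_oligo = mean_depth_per_oligo, depth_sdlog = depth_sdlog,
    nb_dispersion = nb_dispersion,
    n_cdna_reps = as.integer(n_cdna_reps),
    n_pdna_reps = as.integer(n_pdna_reps),
    n_tfs = as.integer(n_tfs), tf_bound_frac = tf_bound_frac,
    hpo_universe = as.integer(hpo_universe),
    terms_per_entity = as.integer(terms_per_entity),
    n_planted_overlaps = as.integer(n_planted_overlaps),
    barcodes_per_element = as.integer(barcodes_per_element),
    insert_len = as.integer(insert_len)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "mpra_sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_probands", "n_tss", "window_bp", "n_cdna_reps", "n_pdna_reps",
              "n_tfs", "hpo_universe", "terms_per_entity",
              "barcodes_per_element", "insert_len")
  for (f in counts)
    if (cfg[[f]] <= 0L) stop_config("'%s' must be positive", f)
  if (cfg$n_de_novo < 0L || cfg$n_inherited < 0L)
    stop_config("variant counts must be non-negative")
  if (cfg$n_de_novo + cfg$n_inherited < 1L)
    stop_config("at least one variant must be simulated")
  for (f in c("frac_active_ref", "frac_effect_variants", "tf_bound_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_config("'%s' must lie in [0,1]", f)
  if (cfg$nb_dispersion <= 0) stop_config("'nb_dispersion' must be > 0")
  if (cfg$n_cdna_reps < 2L || cfg$n_pdna_reps < 2L)
    stop_config("at least two replicates per condition are required")
  if (is.null(names(cfg$contig_lengths)) || any(names(cfg$contig_lengths) == ""))
    stop_config("'contig_lengths' must be a named vector")
  if (any(cfg$contig_lengths < 2 * cfg$window_bp + cfg$insert_len))
    stop_config("every contig must be at least 2*window_bp + insert_len long")
  if (cfg$terms_per_entity > cfg$hpo_universe)
    stop_config("'terms_per_entity' exceeds the HPO universe size")
  if (cfg$n_planted_overlaps > 0 && cfg$frac_effect_variants <= 0)
    stop_config("planted HPO overlaps require planted effect variants")
  invisible(cfg)
}

#' @export
print.mpra_sim_config <- function(x, ...) {
  cat("MPRA simulation config:",
      sprintf("%d probands, %d de novo + %d inherited variants",
              x$n_probands, x$n_de_novo, x$n_inherited),
      sprintf("window +/-%d bp, %d TSS on %d contig(s)",
              x$window_bp, x$n_tss, length(x$contig_lengths)),
      sprintf("planted: %.1f%% active refs, %.1f%% effect variants",
              100 * x$frac_active_ref, 100 * x$frac_effect_variants),
      sprintf("depth %g/oligo, NB dispersion %g, %d pDNA + %d cDNA reps",
              x$mean_depth_per_oligo, x$nb_dispersion,
              x$n_pdna_reps, x$n_cdna_reps),
      sep = "\n  ")
  invisible(x)
}

#' Read a simulation config from a JSON file
#'
#' Scalar fields override `sim_config()` defaults; `contig_lengths` is given
#' as a JSON object mapping contig name to length.
#'
#' @param path JSON file.
#' @return `mpra_sim_config`
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_config("unknown config field(s): %s", paste(bad, collapse = ", "))
  if (!is.null(raw$contig_lengths)) raw$contig_lengths <- unlist(raw$contig_lengths)
  do.call(sim_config, raw)
}
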