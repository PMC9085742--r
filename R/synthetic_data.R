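#' Generate a synthetic reference sequence and TSS annotation
#'
#' Stands in for a genome assembly plus RefSeq TSS annotations: each contig is
#' uniform-random A/C/G/T, and `n_tss` transcription start sites are placed
#' uniformly at least `window_bp` from contig ends (so every variant window
#' around a TSS stays on-contig).
#'
#' @param config an [sim_config()] object.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and `tss`
#'   (data.table: contig, pos (1-based), strand, gene_id).
#' @export
generate_reference <- function(config) {
  stopifnot(is(config, "mpra_sim_config"))
  lens <- config$contig_lengths
  pad <- config$window_bp + config$insert_len
  if (any(lens < 2 * pad))
    stop_config("contig(s) too short to place a TSS %d bp from both ends", pad)
  with_seed(config$seed, {
    seqs <- Biostrings::DNAStringSet(vapply(lens, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1)))
    names(seqs) <- names(lens)
    contig <- sample(names(lens), config$n_tss, replace = TRUE,
                     prob = lens / sum(lens))
    pos <- vapply(contig, function(ct) {
      sample.int(lens[[ct]] - 2L * pad, 1L) + pad
    }, integer(1))
    tss <- data.table(
      contig = contig, pos = as.integer(pos),
      strand = sample(c("+", "-"), config$n_tss, replace = TRUE),
      gene_id = sprintf("gene%04d", seq_len(config$n_tss))
    )
    setkey(tss, contig, pos)
    list(sequences = seqs, tss = tss[])
  })
}

# signed distance (pos - tss_pos) to the nearest TSS, per variant
nearest_tss_distance <- function(variants, tss) {
  stopifnot(nrow(tss) > 0)
  t2 <- data.table(contig = tss$contig, pos = tss$pos, tss_pos = tss$pos,
                   tss_gene = tss$gene_id)
  setkey(t2, contig, pos)
  q <- data.table(contig = variants$contig, pos = variants$pos)
  hit <- t2[q, on = .(contig, pos), roll = "nearest"]
  ifelse(is.na(hit$tss_pos), NA_integer_,
         as.integer(q$pos - hit$tss_pos))
}

#' Simulate a cohort of rare noncoding SNVs
#'
#' Draws `n_de_novo + n_inherited` single-nucleotide variants, each within
#' `window_bp` of a TSS, with the reference allele read from the synthetic
#' genome, MAF < 0.001, and detection by >= 2 sequencing technologies. The
#' distance-to-TSS distribution is a uniform/near-TSS mixture, mildly
#' enriched near 0 as observed in trio cohorts.
#'
#' @param config an [sim_config()] object.
#' @param reference output of [generate_reference()].
#' @return data.table of variants (one row per SNV) with cohort metadata.
#' @export
generate_cohort_variants <- function(config, reference) {
  stopifnot(is(config, "mpra_sim_config"))
  tss <- reference$tss
  seqs <- reference$sequences
  n <- config$n_de_novo + config$n_inherited
  w <- config$window_bp
  with_seed(config$seed + 1L, {
    src <- tss[sample.int(nrow(tss), n, replace = TRUE)]
    near <- runif(n) < 0.35  # near-TSS enrichment component
    mag <- ifelse(near,
                  pmin(abs(rnorm(n, 0, w / 3)), w),
                  runif(n, 0, w))
    offset <- as.integer(round(mag) * sample(c(-1L, 1L), n, replace = TRUE))
    pos <- src$pos + offset
    # clamp inside the insert window; TSS placement guarantees room
    half <- config$insert_len %/% 2L
    lens <- config$contig_lengths[src$contig]
    pos <- pmax(pmin(pos, as.integer(lens) - half), half + 1L)
    chars <- as.character(seqs)
    ref <- unname(substr(chars[src$contig], pos, pos))
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    inheritance <- rep(c("de_novo", "inherited"),
                       c(config$n_de_novo, config$n_inherited))
    probands <- sprintf("proband%03d", seq_len(config$n_probands))
    # inherited variants come from a subset of probands, as in trio cohorts
    inh_probands <- probands[seq_len(max(1L, config$n_probands %/% 2L))]
    proband_id <- ifelse(inheritance == "de_novo",
                         sample(probands, n, replace = TRUE),
                         sample(inh_probands, n, replace = TRUE))
    v <- data.table(
      variant_id = sprintf("var%05d", seq_len(n)),
      contig = src$contig, pos = as.integer(pos),
      ref_allele = ref, alt_allele = alt,
      proband_id = proband_id, inheritance = inheritance,
      maf = runif(n, 0, 0.001),
      n_technologies = sample(2:4, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      seen_in_multiple_probands = FALSE,
      known_causative = FALSE,
      coding_impact = FALSE
    )
    v[, dist_to_tss := nearest_tss_distance(v, tss)]
    if (any(abs(v$dist_to_tss) > w))
      stop("internal error: variant placed outside the TSS window")
    v[]
  })
}

#' Plant ground-truth regulatory activity, allelic effects and HPO overlaps
#'
#' Tags a deterministic `frac_active_ref` of reference elements as activators
#' or repressors (split ~50/50) and a `frac_effect_variants` subset of
#' variants with an allelic effect (decrease:increase ~51:40). Effect
#' variants are drawn from the active set so that a decrease is a loss of
#' activator function and an increase a loss of repression, matching the
#' mechanism classes the effect caller reports. `n_planted_overlaps`
#' (proband, TF) pairs with forced HPO-term overlap are planted on effect
#' variants, giving the end-to-end doubly-planted positives.
#'
#' All planted-fraction counts use the rounding rule `floor(n*frac + 0.5)`.
#'
#' @param config an [sim_config()] object.
#' @param variants data.table from [generate_cohort_variants()].
#' @return object of class `mpra_truth`: list of data.tables `activity`
#'   (variant_id, sign, log2fc), `effects` (variant_id, direction, delta) and
#'   `overlaps` (variant_id, proband_id, tf_name).
#' @export
plant_truth <- function(config, variants) {
  stopifnot(is(config, "mpra_sim_config"))
  n <- nrow(variants)
  n_active <- frac_count(n, config$frac_active_ref)
  n_eff <- frac_count(n, config$frac_effect_variants)
  if (n_eff > n_active)
    stop_config("frac_effect_variants must not exceed frac_active_ref (effect variants carry active reference elements)")
  if (config$n_planted_overlaps > n_eff)
    stop_config("n_planted_overlaps (%d) exceeds the number of planted effect variants (%d)",
                config$n_planted_overlaps, n_eff)
  with_seed(config$seed + 2L, {
    ids <- variants$variant_id
    eff_ids <- sort(sample(ids, n_eff))
    n_dec <- frac_count(n_eff, 51 / 91)  # decrease:increase ~ 51:40
    dec <- rep(FALSE, n_eff)
    if (n_eff > 0) dec[sample.int(n_eff, n_dec)] <- TRUE
    effects <- data.table(
      variant_id = eff_ids,
      direction = ifelse(dec, "decrease", "increase"),
      delta = ifelse(dec, -config$allelic_log2fc, config$allelic_log2fc)
    )
    # active refs: effect variants first (decrease -> activator ref,
    # increase -> repressor ref), then fill to n_active split ~50/50 overall
    n_act_total <- frac_count(n_active, 0.5)  # activators among active
    fill_ids <- sort(sample(setdiff(ids, eff_ids), n_active - n_eff))
    n_act_fill <- max(0L, min(length(fill_ids), n_act_total - sum(dec)))
    fill_act <- rep(FALSE, length(fill_ids))
    if (n_act_fill > 0) fill_act[sample.int(length(fill_ids), n_act_fill)] <- TRUE
    activity <- rbind(
      data.table(variant_id = eff_ids, sign = ifelse(dec, 1L, -1L)),
      data.table(variant_id = fill_ids, sign = ifelse(fill_act, 1L, -1L))
    )
    activity[, log2fc := sign * config$activity_log2fc]
    setkey(activity, variant_id)
    overlaps <- data.table(variant_id = character(), proband_id = character(),
                           tf_name = character())
    if (config$n_planted_overlaps > 0) {
      # prefer effect variants from distinct probands so each planted pair's
      # forced term overlap is not diluted by a shared proband
      cand <- data.table(variant_id = eff_ids,
                         proband_id = variants[match(eff_ids, variant_id),
                                               proband_id])
      cand <- cand[sample(.N)]
      cand <- rbind(cand[!duplicated(proband_id)],
                    cand[duplicated(proband_id)])
      pick <- cand[seq_len(config$n_planted_overlaps)]
      tf_names <- sprintf("TF%02d", seq_len(config$n_tfs))
      overlaps <- data.table(
        variant_id = pick$variant_id,
        proband_id = pick$proband_id,
        tf_name = sample(tf_names, config$n_planted_overlaps,
                         replace = config$n_planted_overlaps > config$n_tfs)
      )
      setkey(overlaps, variant_id)
    }
    structure(list(activity = activity[], effects = effects[],
                   overlaps = overlaps[]),
              class = "mpra_truth")
  })
}

# planted log2 expression modifier per element; see plant_truth() for the
# model: effect variants carry activity only on reference and variant alleles
planted_log2_effect <- function(elements, truth) {
  a <- truth$activity[match(elements$variant_id, variant_id), log2fc]
  a[is.na(a)] <- 0
  d <- truth$effects[match(elements$variant_id, variant_id), delta]
  is_eff <- !is.na(d)
  e <- a
  e[is_eff & elements$label == "alternative"] <- 0
  sel <- is_eff & elements$label == "variant"
  e[sel] <- a[sel] + d[sel]
  e
}

#' Simulate plasmid and cDNA barcode counts for a designed library
#'
#' Per-barcode plasmid abundance is lognormal around
#' `mean_depth_per_oligo`; pDNA replicate counts are negative-binomial around
#' that abundance, and cDNA replicate counts around `abundance * 2^e`, where
#' `e` is the element's planted log2 effect (activity, plus the allelic delta
#' on variant alleles). Element counts are the sum over the element's five
#' barcodes.
#'
#' @param config an [sim_config()] object.
#' @param library an `mpra_library` from [build_library()].
#' @param truth an `mpra_truth` from [plant_truth()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (element x sample), rowData (variant_id, allele, label),
#'   colData (condition, replicate); barcode-level counts and the barcode
#'   table are kept in `metadata()` for FASTQ emission.
#' @export
simulate_counts <- function(config, library, truth) {
  stopifnot(is(config, "mpra_sim_config"), is(library, "mpra_library"))
  bt <- library$oligos
  if (is.null(bt) || nrow(bt) == 0L) stop_config("library has no barcode table")
  elements <- unique(bt[, .(variant_id, allele, label)])
  setkey(elements, variant_id, allele)
  e_planted <- planted_log2_effect(elements, truth)
  elements[, planted_log2 := e_planted]
  eid <- element_id(bt$variant_id, bt$allele)
  row_of <- match(eid, element_id(elements$variant_id, elements$allele))
  n_bc <- nrow(bt)
  alpha <- config$nb_dispersion
  samples <- data.table(
    sample_id = c(sprintf("pDNA_%d", seq_len(config$n_pdna_reps)),
                  sprintf("cDNA_%d", seq_len(config$n_cdna_reps))),
    condition = rep(c("pDNA", "cDNA"),
                    c(config$n_pdna_reps, config$n_cdna_reps)),
    replicate = c(seq_len(config$n_pdna_reps), seq_len(config$n_cdna_reps))
  )
  with_seed(config$seed + 3L, {
    sdl <- config$depth_sdlog
    lambda <- rlnorm(n_bc, meanlog = log(config$mean_depth_per_oligo) -
                       sdl^2 / 2, sdlog = sdl)
    mu_cdna <- lambda * 2^(elements$planted_log2[row_of])
    bc_counts <- matrix(0L, n_bc, nrow(samples),
                        dimnames = list(bt$barcode, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- if (samples$condition[j] == "pDNA") lambda else mu_cdna
      bc_counts[, j] <- as.integer(rnbinom(n_bc, mu = mu, size = 1 / alpha))
    }
    counts <- rowsum(bc_counts, group = row_of, reorder = TRUE)
    rownames(counts) <- element_id(elements$variant_id, elements$allele)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(elements),
      colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id)
    )
    S4Vectors::metadata(se)$barcode_counts <- bc_counts
    S4Vectors::metadata(se)$barcode_table <- bt[, .(barcode, variant_id, allele, oligo_id)]
    se
  })
}

FASTQ_FILLER <- "CTGACTGACTGACTGACTGACTGACTGACTGACTGACT"  # 38 nt, site-free

#' Emit simulated reads as FASTQ, one file per sample
#'
#' Each barcode is emitted at exactly its simulated count; reads are the
#' 12-nt barcode followed by a constant filler (first 12 bases = tag, as in
#' targeted MPRA sequencing). Counting these reads back reproduces the
#' simulated count matrix exactly.
#'
#' @param sim SummarizedExperiment from [simulate_counts()].
#' @param dir output directory (created if needed).
#' @return data.table sample sheet (sample_id, condition, replicate, fastq).
#' @export
emit_fastq <- function(sim, dir) {
  bc_counts <- S4Vectors::metadata(sim)$barcode_counts
  if (is.null(bc_counts)) stop_config("missing barcode-level counts; rerun simulate_counts()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cd <- as.data.table(SummarizedExperiment::colData(sim))
  barcodes <- rownames(bc_counts)
  paths <- character(nrow(cd))
  for (j in seq_len(nrow(cd))) {
    cnt <- bc_counts[, j]
    seqs <- rep(paste0(barcodes, FASTQ_FILLER), cnt)
    paths[j] <- file.path(dir, paste0(cd$sample_id[j], ".fastq"))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- sprintf("%s_read%07d", cd$sample_id[j], seq_along(x))
    Biostrings::writeXStringSet(
      x, paths[j], format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(x))))
  }
  sheet <- data.table(cd[, .(sample_id, condition, replicate)], fastq = paths)
  sheet[]
}

#' Generate synthetic TF binding clusters and HPO annotations
#'
#' `n_tfs` factors receive binding intervals; `tf_bound_frac` of variants are
#' covered by at least one interval, every planted (proband, TF) pair's
#' variant is covered by its TF, and background intervals away from variants
#' are added. Each TF and proband is annotated with `terms_per_entity` HPO
#' accessions from a universe of `hpo_universe`; planted pairs share 80% of
#' their terms (far beyond chance for the default sizes).
#'
#' @param config an [sim_config()] object.
#' @param variants data.table of variants.
#' @param truth an `mpra_truth` (for the planted overlap pairs).
#' @return list: `sites` ([GenomicRanges::GRanges] with `tf_name`),
#'   `tf_hpo` / `proband_hpo` (data.tables: entity_id, terms comma-joined),
#'   `universe` (integer N).
#' @export
generate_tf_and_hpo <- function(config, variants, truth) {
  stopifnot(is(config, "mpra_sim_config"))
  if (config$terms_per_entity > config$hpo_universe)
    stop_config("terms_per_entity exceeds hpo_universe")
  tf_names <- sprintf("TF%02d", seq_len(config$n_tfs))
  universe <- sprintf("HP:%07d", seq_len(config$hpo_universe))
  t <- config$terms_per_entity
  with_seed(config$seed + 4L, {
    n <- nrow(variants)
    bound <- runif(n) < config$tf_bound_frac
    bound[variants$variant_id %in% truth$overlaps$variant_id] <- TRUE
    idx <- which(bound)
    site <- data.table(
      contig = variants$contig[idx],
      pos = variants$pos[idx],
      tf_name = sample(tf_names, length(idx), replace = TRUE)
    )
    # planted pairs: ensure the planted TF binds the variant site
    if (nrow(truth$overlaps)) {
      m <- match(truth$overlaps$variant_id, variants$variant_id[idx])
      site$tf_name[m] <- truth$overlaps$tf_name
    }
    ext_l <- sample(50:300, nrow(site), replace = TRUE)
    ext_r <- sample(50:300, nrow(site), replace = TRUE)
    # background intervals (may or may not touch variants)
    bg_n <- config$n_tfs * 20L
    bg_contig <- sample(names(config$contig_lengths), bg_n, replace = TRUE)
    bg_start <- vapply(bg_contig, function(ct)
      sample.int(as.integer(config$contig_lengths[[ct]]) - 400L, 1L), integer(1))
    gr <- GenomicRanges::GRanges(
      seqnames = c(site$contig, bg_contig),
      ranges = IRanges::IRanges(
        start = c(site$pos - ext_l, bg_start),
        end = c(site$pos + ext_r, bg_start + sample(100:400, bg_n, replace = TRUE))),
      tf_name = c(site$tf_name, sample(tf_names, bg_n, replace = TRUE))
    )
    draw_terms <- function(ids) {
      data.table(entity_id = ids,
                 terms = vapply(ids, function(i)
                   paste(sample(universe, t), collapse = ","), character(1),
                   USE.NAMES = FALSE))
    }
    probands <- sort(unique(variants$proband_id))
    tf_hpo <- draw_terms(tf_names)
    proband_hpo <- draw_terms(probands)
    if (nrow(truth$overlaps)) {
      # force ~80% term overlap per planted pair; when a proband carries
      # several planted pairs its forced terms are split between the TFs
      k_full <- max(1L, ceiling(0.8 * t))
      by_pr <- split(seq_len(nrow(truth$overlaps)), truth$overlaps$proband_id)
      for (pid in names(by_pr)) {
        rows <- by_pr[[pid]]
        k_each <- max(1L, min(k_full, t %/% length(rows)))
        forced <- character(0)
        tf_union <- character(0)
        for (r in rows) {
          tfi <- match(truth$overlaps$tf_name[r], tf_hpo$entity_id)
          tft <- strsplit(tf_hpo$terms[tfi], ",", fixed = TRUE)[[1]]
          tf_union <- union(tf_union, tft)
          avail <- setdiff(tft, forced)
          forced <- c(forced, sample(avail, min(k_each, length(avail))))
        }
        pri <- match(pid, proband_hpo$entity_id)
        orig <- strsplit(proband_hpo$terms[pri], ",", fixed = TRUE)[[1]]
        newt <- head(c(forced, setdiff(orig, tf_union)), t)
        proband_hpo$terms[pri] <- paste(newt, collapse = ",")
      }
    }
    list(sites = sort(gr), tf_hpo = tf_hpo, proband_hpo = proband_hpo,
         universe = config$hpo_universe)
  })
}
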