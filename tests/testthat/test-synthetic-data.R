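test_that("sim_config validates its invariants", {
  expect_s3_class(tiny_config(), "mpra_sim_config")
  expect_error(tiny_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(tiny_config(frac_active_ref = 1.2), "frac_active_ref")
  expect_error(tiny_config(terms_per_entity = 600L), "universe")
  expect_error(tiny_config(contig_lengths = c(chr1 = 10)), "contig")
  expect_error(tiny_config(n_pdna_reps = 1L), "replicates")
})

test_that("generate_reference honours length/count contracts and determinism", {
  cfg <- tiny_config()
  ref <- generate_reference(cfg)
  expect_equal(unname(Biostrings::width(ref$sequences)),
               unname(as.integer(cfg$contig_lengths)))
  expect_true(all(strsplit(as.character(ref$sequences[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  expect_equal(nrow(ref$tss), cfg$n_tss)
  # TSS at least window_bp + insert from the contig ends
  pad <- cfg$window_bp + cfg$insert_len
  lens <- cfg$contig_lengths[ref$tss$contig]
  expect_true(all(ref$tss$pos > pad & ref$tss$pos <= lens - pad))
  ref2 <- generate_reference(cfg)
  expect_identical(as.character(ref$sequences), as.character(ref2$sequences))
  expect_identical(ref$tss, ref2$tss)
})

test_that("generate_cohort_variants: counts, window bound, SNV contract (full scan)", {
  cfg <- tiny_config()
  ref <- generate_reference(cfg)
  v <- generate_cohort_variants(cfg, ref)
  expect_equal(nrow(v), cfg$n_de_novo + cfg$n_inherited)
  expect_equal(sum(v$inheritance == "de_novo"), cfg$n_de_novo)
  expect_true(all(abs(v$dist_to_tss) <= cfg$window_bp))
  expect_true(all(v$ref_allele != v$alt_allele))
  expect_true(all(v$ref_allele %in% c("A", "C", "G", "T")))
  expect_true(all(v$maf < 0.001))
  expect_true(all(v$n_technologies >= 2L))
  # ref allele matches the reference sequence
  chars <- as.character(ref$sequences)
  expect_identical(unname(substr(chars[v$contig], v$pos, v$pos)), v$ref_allele)
  expect_identical(v, generate_cohort_variants(cfg, ref))
})

test_that("plant_truth: deterministic rounding rule, degenerate and reproducible", {
  cfg <- tiny_config(n_de_novo = 600L, n_inherited = 400L,
                     n_planted_overlaps = 0L)
  ref <- generate_reference(cfg)
  v <- generate_cohort_variants(cfg, ref)
  tr <- plant_truth(cfg, v)
  expect_equal(nrow(tr$activity), floor(1000 * 0.2 + 0.5))     # 200 exactly
  expect_equal(nrow(tr$effects), floor(1000 * 0.045 + 0.5))    # 45 exactly
  # activator/repressor split ~50/50 by the stated rounding rule
  expect_equal(sum(tr$activity$sign > 0), floor(200 * 0.5 + 0.5))
  # decrease:increase ~ 51:40
  expect_equal(sum(tr$effects$direction == "decrease"),
               floor(45 * 51 / 91 + 0.5))
  # effect variants have active reference elements, coherent with direction
  m <- tr$activity[match(tr$effects$variant_id, variant_id)]
  expect_true(all(m$sign == ifelse(tr$effects$direction == "decrease", 1L, -1L)))
  expect_identical(tr, plant_truth(cfg, v))
  cfg0 <- tiny_config(frac_effect_variants = 0, n_planted_overlaps = 0L)
  v0 <- generate_cohort_variants(cfg0, generate_reference(cfg0))
  expect_equal(nrow(plant_truth(cfg0, v0)$effects), 0L)
})

test_that("simulate_counts marginal means match the generating model", {
  # 2,500 variants -> 10,000 elements at the default depth/dispersion
  cfg <- tiny_config(seed = 4L, n_de_novo = 2000L, n_inherited = 500L,
                     contig_lengths = c(chr1 = 2e6, chr2 = 2e6), n_tss = 20L,
                     mean_depth_per_oligo = 500, n_pdna_reps = 3L)
  ref <- generate_reference(cfg)
  v <- generate_cohort_variants(cfg, ref)
  tr <- plant_truth(cfg, v)
  lib <- quiet(build_library(v, ref$sequences, seed = cfg$seed))
  sim <- simulate_counts(cfg, lib, tr)
  k <- assay(sim, "counts")
  cond <- colData(sim)$condition
  planted <- rowData(sim)$planted_log2
  ratio <- log2(rowMeans(k[, cond == "cDNA"]) / rowMeans(k[, cond == "pDNA"]))
  for (lev in c(0, 1, -1)) {
    idx <- which(planted == lev)
    expect_gt(length(idx), 100)
    se_mean <- sd(ratio[idx]) / sqrt(length(idx))
    expect_lt(abs(mean(ratio[idx]) - lev), 3 * se_mean)
  }
  # determinism of the full count simulation
  sim2 <- simulate_counts(cfg, lib, tr)
  expect_identical(assay(sim, "counts"), assay(sim2, "counts"))
})

test_that("FASTQ emission round-trips exactly through the counting stage", {
  cfg <- tiny_config(seed = 9L, n_de_novo = 15L, n_inherited = 5L,
                     mean_depth_per_oligo = 20, n_planted_overlaps = 0L)
  ref <- generate_reference(cfg)
  v <- generate_cohort_variants(cfg, ref)
  tr <- plant_truth(cfg, v)
  lib <- quiet(build_library(v, ref$sequences, seed = cfg$seed))
  sim <- simulate_counts(cfg, lib, tr)
  dir <- withr::local_tempdir()
  sheet <- emit_fastq(sim, dir)
  se <- assemble_matrix(sheet, S4Vectors::metadata(sim)$barcode_table)
  expect_identical(assay(se, "counts"), assay(sim, "counts"))
  qc <- S4Vectors::metadata(se)$qc
  expect_equal(qc$matched, qc$total)  # exact multiplicity, exact matching
})

test_that("generate_tf_and_hpo plants detectable overlaps and round-trips BED", {
  cfg <- tiny_config(seed = 21L)
  ref <- generate_reference(cfg)
  v <- generate_cohort_variants(cfg, ref)
  tr <- plant_truth(cfg, v)
  th <- generate_tf_and_hpo(cfg, v, tr)
  # planted pairs: bound at the variant site and overlap far beyond chance
  tf_map <- intersect_tf(v, th$sites)
  ov <- hpo_overlap_tests(v, tf_map, th$proband_hpo, th$tf_hpo, th$universe)
  planted <- merge(tr$overlaps, ov,
                   by = c("variant_id", "proband_id", "tf_name"))
  expect_equal(nrow(planted), nrow(tr$overlaps))
  expect_true(all(planted$k >= ceiling(0.8 * cfg$terms_per_entity)))
  expect_true(all(planted$p < 1e-6))
  # BED round trip preserves coordinates and factor names
  path <- withr::local_tempfile(fileext = ".bed")
  write_tf_bed(th$sites, path)
  back <- read_tf_bed(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(th$sites))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(th$sites))
  expect_equal(back$tf_name, th$sites$tf_name)
})

test_that("null HPO model keeps BH-significant pair fraction at the nominal level", {
  # 1000 independent (proband, TF) pairs with random term sets, no planting
  set.seed(31)
  universe <- sprintf("HP:%07d", 1:2000)
  t <- 15L
  pr <- data.table(entity_id = sprintf("p%04d", 1:1000),
                   terms = replicate(1000, paste(sample(universe, t),
                                                 collapse = ",")))
  tf <- data.table(entity_id = sprintf("t%04d", 1:1000),
                   terms = replicate(1000, paste(sample(universe, t),
                                                 collapse = ",")))
  v <- data.table(variant_id = sprintf("v%04d", 1:1000),
                  proband_id = pr$entity_id)
  tf_map <- data.table(variant_id = v$variant_id, tf_name = tf$entity_id)
  ov <- hpo_overlap_tests(v, tf_map, pr, tf, 2000L)
  expect_lte(mean(ov$q < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})
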