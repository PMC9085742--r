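make_variant <- function(...) {
  base <- data.table(
    variant_id = "v1", contig = "chr1", pos = 150000L,
    ref_allele = "A", alt_allele = "G", proband_id = "p1",
    inheritance = "de_novo", maf = 5e-4, n_technologies = 2L,
    seen_in_multiple_probands = FALSE, known_causative = FALSE,
    coding_impact = FALSE)
  mod <- list(...)
  for (nm in names(mod)) set(base, j = nm, value = mod[[nm]])
  base
}
one_tss <- data.table(contig = "chr1", pos = 150000L)

test_that("filter_variants applies selection criteria at exact boundaries", {
  cases <- rbind(
    make_variant(variant_id = "keep"),
    make_variant(variant_id = "maf_at_bound", maf = 0.001),      # not strictly <
    make_variant(variant_id = "one_tech", n_technologies = 1L),
    make_variant(variant_id = "multi_proband", seen_in_multiple_probands = TRUE),
    make_variant(variant_id = "causative", known_causative = TRUE),
    make_variant(variant_id = "coding", coding_impact = TRUE),
    make_variant(variant_id = "at_window", pos = 150000L + 100000L),
    make_variant(variant_id = "past_window", pos = 150000L + 100001L),
    make_variant(variant_id = "bad_allele", alt_allele = "N"),
    make_variant(variant_id = "ref_eq_alt", alt_allele = "A"))
  kept <- quiet(filter_variants(cases, one_tss, window_bp = 100000L))
  expect_setequal(kept$variant_id, c("keep", "at_window"))   # 100 kb inclusive
  expect_equal(kept[variant_id == "at_window", dist_to_tss], 100000L)
  rej <- attr(kept, "rejected")
  expect_match(rej[variant_id == "maf_at_bound", reason], "MAF")
  expect_match(rej[variant_id == "one_tech", reason], "technologies")
  expect_match(rej[variant_id == "past_window", reason], "TSS")
  expect_match(rej[variant_id == "bad_allele", reason], "allele")
  expect_error(filter_variants(cases, one_tss[0]), "empty")
})

test_that("extract_window centers the variant at offset 50 of 100", {
  set.seed(5)
  contig <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                  collapse = "")
  ref <- c(chr1 = contig)
  # variant at pos 50 of a 100-bp contig: insert is the whole contig
  expect_identical(extract_window(ref, "chr1", 50L), contig)
  # centering: insert[50] equals the reference base at the variant position
  w <- extract_window(ref, "chr1", 60L, length = 20L)
  expect_identical(substr(w, 10, 10), substr(contig, 60, 60))
  expect_error(extract_window(ref, "chr1", 49L), "edge")
  expect_error(extract_window(ref, "chr1", 51L), "edge")
  expect_error(extract_window(ref, "chr2", 50L), "contig")
})

test_that("make_analogs covers all four bases at exactly one position", {
  insert <- strrep("ACGT", 25)
  an <- make_analogs(insert, 37L)
  expect_length(an, 4L)
  expect_setequal(substr(an, 37, 37), c("A", "C", "G", "T"))
  expect_equal(length(unique(an)), 4L)
  # identical everywhere except the offset: pairwise Hamming distance 1
  combs <- utils::combn(4, 2)
  expect_true(all(str_hamming(an[combs[1, ]], an[combs[2, ]]) == 1L))
  expect_error(make_analogs(insert, 101L), "offset")
})

test_that("assign_barcodes: constraints, Hamming >= 2, determinism", {
  bt <- assign_barcodes(40L, per_seq = 5L, rng_seed = 3L)
  expect_equal(nrow(bt), 200L)
  expect_equal(anyDuplicated(bt$barcode), 0L)
  expect_equal(unique(nchar(bt$barcode)), 12L)
  # no BsaI/Esp3I site on either strand, no homopolymer >= 5, GC in [25,75]%
  expect_false(any(grepl("GGTCTC|CGTCTC", bt$barcode)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(bt$barcode)))
  expect_false(any(grepl("GGTCTC|CGTCTC", rc)))
  expect_false(any(grepl("A{5}|C{5}|G{5}|T{5}", bt$barcode)))
  gc <- vapply(strsplit(bt$barcode, ""), function(x) mean(x %in% c("G", "C")),
               numeric(1))
  expect_true(all(gc >= 0.25 & gc <= 0.75))
  # brute-force pairwise Hamming distance >= 2
  combs <- utils::combn(nrow(bt), 2L)
  d <- str_hamming(bt$barcode[combs[1, ]], bt$barcode[combs[2, ]])
  expect_true(all(d >= 2L))
  expect_identical(bt, assign_barcodes(40L, per_seq = 5L, rng_seed = 3L))
  expect_error(assign_barcodes(10L, per_seq = 5L, length = 2L), "space")
})

test_that("build_library cardinality, injectivity and reference analog", {
  cfg <- tiny_config(seed = 2L, n_de_novo = 8L, n_inherited = 4L)
  ref <- generate_reference(cfg)
  v <- generate_cohort_variants(cfg, ref)
  lib <- build_library(v, ref$sequences, seed = 1L)
  ol <- lib$oligos
  expect_equal(nrow(ol), nrow(v) * 4L * 5L)
  expect_equal(anyDuplicated(ol$barcode), 0L)
  # barcode -> (variant, allele) injective by construction
  expect_equal(uniqueN(ol[, .(variant_id, allele)]), nrow(v) * 4L)
  # exactly one analog per variant equals the reference window
  chars <- as.character(ref$sequences)
  for (vid in v$variant_id[1:3]) {
    vv <- v[variant_id == vid]
    refwin <- extract_window(chars, vv$contig, vv$pos)
    ins <- unique(ol[variant_id == vid, .(allele, label, insert)])
    expect_equal(sum(ins$insert == refwin), 1L)
    expect_equal(ins[insert == refwin, label], "reference")
    expect_equal(ins[insert == refwin, allele], vv$ref_allele)
    expect_equal(ins[label == "variant", allele], vv$alt_allele)
  }
  # insert length and center base contract
  expect_true(all(nchar(ol$insert) == 100L))
  expect_identical(substr(ol$insert, 50, 50), ol$allele)
  # deterministic rebuild is byte-identical
  expect_identical(ol, build_library(v, ref$sequences, seed = 1L)$oligos)
  # unit arithmetic and degenerate case
  lib1 <- build_library(v[1], ref$sequences, seed = 1L)
  expect_equal(nrow(lib1$oligos), 20L)
  lib0 <- build_library(v[0], ref$sequences, seed = 1L)
  expect_equal(nrow(lib0$oligos), 0L)
})

test_that("variants whose insert window leaves the contig are skipped with a log", {
  cfg <- tiny_config(seed = 2L, n_de_novo = 4L, n_inherited = 2L)
  ref <- generate_reference(cfg)
  v <- generate_cohort_variants(cfg, ref)
  v$pos[1] <- 10L  # window off the left edge
  expect_message(lib <- build_library(v, ref$sequences, seed = 1L), "skipped")
  expect_equal(nrow(lib$skipped), 1L)
  expect_equal(nrow(lib$oligos), (nrow(v) - 1L) * 20L)
})
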