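test_that("size_factors reproduces the median-of-ratios hand computation", {
  # geometric means (2.828, 5.657); both ratio columns constant ->
  # factors (1/sqrt(2), sqrt(2)) exactly
  k <- matrix(c(2, 4, 4, 8), nrow = 2)
  sf <- size_factors(k)
  expect_equal(sf, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> equal factors
  expect_equal(size_factors(cbind(c(3, 9, 5), c(3, 9, 5))), c(1, 1))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("normalization and statistics are invariant to depth-profile rescaling", {
  # median-of-ratios identifies relative depths: rescaling samples by
  # factors with product 1 must leave everything unchanged to float precision
  k <- sim_nb_matrix(400, mu = 300, disp = 0.05,
                     cond = c("pDNA", "pDNA", "cDNA", "cDNA", "cDNA"),
                     seed = 42L)
  cond <- c("pDNA", "pDNA", "cDNA", "cDNA", "cDNA")
  cvec <- c(4, 1 / 2, 1 / 4, 2, 1)   # product 1
  k2 <- sweep(k, 2L, cvec, "*")
  sf1 <- size_factors(k); sf2 <- size_factors(k2)
  expect_equal(sf2, sf1 * cvec, tolerance = 1e-9)           # equivariance
  y1 <- sweep(k, 2L, sf1, "/"); y2 <- sweep(k2, 2L, sf2, "/")
  expect_equal(y2, y1, tolerance = 1e-9)                    # normalized counts
  d1 <- estimate_dispersion(k, sf1, cond)
  d2 <- estimate_dispersion(k2, sf2, cond)
  expect_equal(d2$dispersion, d1$dispersion, tolerance = 1e-9)
  a1 <- test_activity(k, cond); a2 <- test_activity(k2, cond)
  expect_equal(a2$log2_activity, a1$log2_activity, tolerance = 1e-9)
  expect_equal(a2$se, a1$se, tolerance = 1e-9)
  expect_equal(a2$wald_p, a1$wald_p, tolerance = 1e-9)
  expect_identical(a2$call, a1$call)
  # a lone sample rescaling shifts only the overall anchor: the activity
  # log-fold-change is still exactly invariant
  k3 <- k; k3[, 1] <- k3[, 1] * 3
  a3 <- test_activity(k3, cond, dispersions = d1$dispersion)
  expect_equal(a3$log2_activity, a1$log2_activity, tolerance = 1e-9)
})

test_that("dispersion estimation recovers the generator (Poisson and NB)", {
  cond <- rep(c("pDNA", "cDNA"), each = 3L)
  # Poisson data (dispersion 0): estimates concentrate near the floor
  kp <- sim_nb_matrix(5000, mu = 500, disp = 0, cond = cond, seed = 7L)
  dp <- estimate_dispersion(kp, condition = cond)
  expect_lt(median(dp$dispersion), 0.01)
  expect_gte(min(dp$dispersion), 1e-8)
  # NB with dispersion 0.1: median recovered within [0.05, 0.2]
  kn <- sim_nb_matrix(5000, mu = 500, disp = 0.1, cond = cond, seed = 8L)
  dn <- estimate_dispersion(kn, condition = cond)
  expect_gt(median(dn$dispersion), 0.05)
  expect_lt(median(dn$dispersion), 0.2)
  # constant counts within condition: raw moment estimate floored
  kc <- matrix(rep(c(10L, 10L, 10L, 20L, 20L, 20L), each = 3L), nrow = 3L)
  dc <- estimate_dispersion(kc, sf = rep(1, 6), condition = cond)
  expect_true(all(dc$raw <= 0))
  expect_true(all(dc$dispersion < 0.01))
  expect_error(estimate_dispersion(kp[, c(1, 4)], condition = cond[c(1, 4)]),
               "replicates")
})

test_that("test_activity: label swap antisymmetry and zero handling", {
  cond <- c("pDNA", "pDNA", "cDNA", "cDNA", "cDNA")
  k <- sim_nb_matrix(300, mu = 300, disp = 0.02, cond = cond, seed = 3L,
                     lfc = rep(c(0, 1, -1), each = 100))
  a <- test_activity(k, cond)
  swapped <- ifelse(cond == "pDNA", "cDNA", "pDNA")
  b <- test_activity(k, swapped, dispersions = estimate_dispersion(
    k, size_factors(k), cond)$dispersion)
  expect_equal(b$log2_activity, -a$log2_activity, tolerance = 1e-12)
  expect_equal(b$wald_p, a$wald_p, tolerance = 1e-12)
  # planted effects are detected with the right sign
  expect_gt(mean(a$call[101:200] == "activator"), 0.8)
  expect_gt(mean(a$call[201:300] == "repressor"), 0.8)
  # all-zero element: NA statistics, excluded from the BH family
  k0 <- k; k0[5, ] <- 0L
  a0 <- test_activity(k0, cond)
  expect_true(is.na(a0$wald_p[5]) && is.na(a0$padj[5]))
  expect_identical(a0$call[5], "inactive")
  expect_equal(a0$padj[-5], bh_adjust(a0$wald_p[-5]))
  expect_error(test_activity(k, rep("pDNA", 5)), "cDNA")
})

test_that("summarize_activity fractions, split and TSS independence", {
  res <- data.table(element = sprintf("e%03d", 1:100),
                    padj = c(rep(0.01, 20), rep(0.5, 80)),
                    call = c(rep("activator", 12), rep("repressor", 8),
                             rep("inactive", 80)),
                    log2_activity = rnorm(100))
  s <- summarize_activity(res)
  expect_equal(s$fraction_significant, 0.20)
  expect_equal(s$split[call == "activator", N], 12L)
  # zero significant -> zero fraction, empty split
  res0 <- copy(res)[, call := "inactive"]
  s0 <- summarize_activity(res0)
  expect_equal(s0$fraction_significant, 0)
  expect_equal(nrow(s0$split), 0L)
  # activity planted independently of TSS distance: |rank correlation| small
  cfg <- tiny_config(seed = 17L, n_de_novo = 800L, n_inherited = 200L,
                     contig_lengths = c(chr1 = 2e6), n_tss = 12L,
                     mean_depth_per_oligo = 100, n_pdna_reps = 3L,
                     n_planted_overlaps = 0L)
  ref <- generate_reference(cfg)
  v <- generate_cohort_variants(cfg, ref)
  lib <- quiet(build_library(v, ref$sequences, seed = cfg$seed))
  sim <- simulate_counts(cfg, lib, plant_truth(cfg, v))
  act <- test_activity(sim)
  sm <- summarize_activity(act, v)
  expect_lt(abs(sm$tss_spearman), 0.1)  # 3/sqrt(n) at n = 1000 ref elements
  expect_equal(sm$by_inheritance[, sum(n)], nrow(v))
})
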