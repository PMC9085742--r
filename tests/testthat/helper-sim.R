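# Shared fixtures and independent oracles, built in code at test time.

suppressPackageStartupMessages({
  library(data.table)
  library(SummarizedExperiment)
})

# small, fast cohort for unit tests
tiny_config <- function(seed = 11L, ...) {
  defaults <- list(
    seed = seed, n_probands = 20L, n_de_novo = 60L, n_inherited = 40L,
    contig_lengths = c(chr1 = 4e5, chr2 = 4e5), n_tss = 10L,
    window_bp = 50000L, mean_depth_per_oligo = 50,
    n_pdna_reps = 2L, n_cdna_reps = 3L,
    hpo_universe = 500L, terms_per_entity = 10L, n_planted_overlaps = 3L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# exact hypergeometric upper tail by exhaustive enumeration of draws:
# universe 1..N, first K elements form the proband set, enumerate all
# C(N, n) draws of size n and count those sharing >= k elements
hyper_enum <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# brute-force variant-in-interval scan (0-based half-open sites)
brute_bound_tfs <- function(variants, sites_dt) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    pos0 <- variants$pos[i] - 1L
    hit <- sites_dt[contig == variants$contig[i] & start <= pos0 & pos0 < end]
    if (nrow(hit))
      out[[length(out) + 1L]] <- data.table(
        variant_id = variants$variant_id[i], tf_name = unique(hit$tf_name))
  }
  if (!length(out))
    return(data.table(variant_id = character(), tf_name = character()))
  unique(rbindlist(out))[order(variant_id, tf_name)]
}

# hamming distance between equal-length strings
str_hamming <- function(a, b) {
  mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b, USE.NAMES = FALSE)
}

# counts matrix with planted log2 effects, bypassing the full generator;
# conditions cond, per-sample depth via size factors 1
sim_nb_matrix <- function(n_elem, mu, disp, cond, lfc = rep(0, n_elem),
                          seed = 1L) {
  withr_seed <- function(code) code  # keep deterministic via set.seed below
  set.seed(seed)
  k <- matrix(0L, n_elem, length(cond))
  for (j in seq_along(cond)) {
    m <- if (cond[j] == "cDNA") mu * 2^lfc else rep(mu, n_elem)
    k[, j] <- if (disp > 0) rnbinom(n_elem, mu = m, size = 1 / disp)
              else rpois(n_elem, m)
  }
  rownames(k) <- sprintf("el%05d", seq_len(n_elem))
  colnames(k) <- sprintf("%s_%d", cond, seq_along(cond))
  k
}

quiet <- function(expr) suppressMessages(expr)
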