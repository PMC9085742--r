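#' Transcription factors bound at each variant position
#'
#' A TF is assigned to a variant when the variant's 1-based position,
#' converted to 0-based, lies inside a binding interval `[start, end)`.
#'
#' @param variants variant table (contig, pos 1-based).
#' @param sites a [GenomicRanges::GRanges] with a `tf_name` metadata column,
#'   or a data.table (contig, start, end, tf_name) in 0-based half-open BED
#'   coordinates.
#' @return data.table (variant_id, tf_name), one row per bound (variant, TF)
#'   pair; variants with no bound TF are absent.
#' @export
intersect_tf <- function(variants, sites) {
  v <- as.data.table(variants)
  if (!is(sites, "GRanges")) {
    s <- as.data.table(sites)
    sites <- GenomicRanges::GRanges(
      seqnames = s$contig,
      ranges = IRanges::IRanges(start = s$start + 1L, end = s$end),
      tf_name = s$tf_name)
  }
  known <- as.character(unique(GenomicRanges::seqnames(sites)))
  off <- setdiff(unique(v$contig), known)
  if (length(off))
    message(sprintf("intersect_tf: %d variant contig(s) absent from the site index",
                    length(off)))
  vr <- GenomicRanges::GRanges(seqnames = v$contig,
                               ranges = IRanges::IRanges(v$pos, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vr, sites))
  out <- unique(data.table(
    variant_id = v$variant_id[S4Vectors::queryHits(hits)],
    tf_name = sites$tf_name[S4Vectors::subjectHits(hits)]))
  setkey(out, variant_id, tf_name)
  out[]
}

#' Upper-tail hypergeometric overlap p-value
#'
#' P(X >= k) for X ~ Hypergeom(N, K, n): the probability that two sets of
#' sizes K and n drawn from a universe of N share at least k members.
#' Computed in log space (lgamma-based binomial coefficients with
#' log-sum-exp over the tail) for numerical stability.
#'
#' @param k observed overlap.
#' @param K,n set sizes.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  stopifnot(length(k) == 1 || length(K) == 1 || length(k) == length(K))
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 1))
    stop_config("negative argument to hypergeom_overlap")
  if (any(K > N) || any(n > N)) stop_config("set size exceeds universe")
  if (any(k > pmin(K, n))) stop_config("overlap k exceeds min(K, n)")
  mapply(function(k, K, n, N) {
    if (k == 0) return(1)
    i <- k:min(K, n)
    lo <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(lo)
    min(1, exp(m + log(sum(exp(lo - m)))))
  }, k, K, n, N)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)`, returned
#' in the input order and capped at 1.
#'
#' @param p p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop_config("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

parse_terms <- function(x) strsplit(x, ",", fixed = TRUE)

#' Proband-vs-TF HPO term overlap tests at variant sites
#'
#' For every variant bound by at least one TF, tests whether the HPO terms of
#' the variant's proband and of each bound TF overlap more than expected by
#' chance, using the upper-tail hypergeometric with the total number of
#' annotated HPO terms as the universe. Matching is by exact accession
#' identity; all (variant, proband, TF) tests are pooled into one BH family.
#'
#' @param variants variant table (variant_id, proband_id).
#' @param tf_map data.table (variant_id, tf_name) from [intersect_tf()].
#' @param proband_hpo,tf_hpo data.tables (entity_id, terms comma-joined).
#' @param universe total number of annotated HPO terms (N).
#' @return data.table OverlapTest: variant_id, proband_id, tf_name, k, K, n,
#'   N, shared_terms, p, q.
#' @export
hpo_overlap_tests <- function(variants, tf_map, proband_hpo, tf_hpo,
                              universe) {
  v <- as.data.table(variants)
  tests <- merge(as.data.table(tf_map),
                 v[, .(variant_id, proband_id)], by = "variant_id")
  if (nrow(tests) == 0L)
    return(data.table(variant_id = character(), proband_id = character(),
                      tf_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(),
                      shared_terms = character(), p = numeric(),
                      q = numeric()))
  pr <- parse_terms(proband_hpo$terms)
  names(pr) <- proband_hpo$entity_id
  tf <- parse_terms(tf_hpo$terms)
  names(tf) <- tf_hpo$entity_id
  missing_pr <- setdiff(tests$proband_id, names(pr))
  missing_tf <- setdiff(tests$tf_name, names(tf))
  if (length(missing_pr) || length(missing_tf))
    stop_config("missing HPO annotations for: %s",
                paste(c(missing_pr, missing_tf), collapse = ", "))
  K_all <- lengths(pr)
  n_all <- lengths(tf)
  if (any(c(K_all, n_all) > universe))
    stop_config("an HPO term set exceeds the universe size")
  shared <- mapply(function(p_id, t_id) intersect(pr[[p_id]], tf[[t_id]]),
                   tests$proband_id, tests$tf_name, SIMPLIFY = FALSE)
  tests[, `:=`(k = lengths(shared),
               K = as.integer(K_all[proband_id]),
               n = as.integer(n_all[tf_name]),
               N = as.integer(universe),
               shared_terms = vapply(shared, paste, character(1),
                                     collapse = ","))]
  tests[, p := hypergeom_overlap(k, K, n, N)]
  tests[, q := bh_adjust(p)]
  setkey(tests, variant_id, tf_name)
  tests[]
}

#' Rank variants by combined phenotype overlap and regulatory effect
#'
#' Tier 1: variants with at least one HPO overlap test at `q < q_threshold`
#' and a regulatory effect `|z| > z_threshold`. Tier 2: HPO-significant only.
#' Tier 3: regulatory effect only. Within tiers, variants sort by minimum q,
#' then |z| (descending), then variant id.
#'
#' @param overlap_tests OverlapTest table from [hpo_overlap_tests()].
#' @param effects VariantEffect table from [call_effects()].
#' @param q_threshold FDR threshold on the HPO overlap (default 0.05).
#' @param z_threshold |z| threshold on the regulatory effect (default 2).
#' @return data.table: variant_id, tier, min_q, z, call, mechanism, tfs
#'   (bound TFs with significant overlap), shared_terms; ranked, tier 0
#'   (neither signal) rows excluded.
#' @export
prioritize <- function(overlap_tests, effects, q_threshold = 0.05,
                       z_threshold = 2) {
  ov <- as.data.table(overlap_tests)
  ef <- as.data.table(effects)
  if (nrow(ov) && nrow(ef) &&
      !length(intersect(ov$variant_id, ef$variant_id)))
    stop_config("overlap tests and variant effects share no variants; were they computed on the same run?")
  hpo <- if (nrow(ov)) {
    sig <- ov[q < q_threshold]
    sig[, .(min_q = min(q),
            tfs = paste(unique(tf_name), collapse = ","),
            shared_terms = paste(unique(unlist(parse_terms(shared_terms))),
                                 collapse = ",")),
        by = variant_id]
  } else data.table(variant_id = character(), min_q = numeric(),
                    tfs = character(), shared_terms = character())
  eff <- ef[, .(variant_id, z, call, mechanism)][abs(z) > z_threshold]
  all_ids <- union(hpo$variant_id, eff$variant_id)
  out <- data.table(variant_id = all_ids)
  out <- merge(out, hpo, by = "variant_id", all.x = TRUE)
  out <- merge(out, ef[, .(variant_id, z, call, mechanism)],
               by = "variant_id", all.x = TRUE)
  out[, has_hpo := variant_id %in% hpo$variant_id]
  out[, has_eff := variant_id %in% eff$variant_id]
  out[, tier := fifelse(has_hpo & has_eff, 1L, fifelse(has_hpo, 2L, 3L))]
  out[, abs_z := fcoalesce(abs(z), 0)]
  out[, q_rank := fcoalesce(min_q, 1)]
  setorder(out, tier, q_rank, -abs_z, variant_id)
  out[, c("has_hpo", "has_eff", "abs_z", "q_rank") := NULL]
  out[]
}

#' Hypergeometric overlap of two gene sets
#'
#' Significance of the intersection of two gene sets from a common universe,
#' e.g. differentially expressed genes under two different perturbations.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param universe universe size (integer), or a character vector of genes.
#' @return upper-tail hypergeometric p-value of the observed intersection.
#' @export
gene_set_overlap <- function(set_a, set_b, universe) {
  a <- unique(set_a); b <- unique(set_b)
  if (is.character(universe)) {
    if (!all(c(a, b) %in% universe))
      stop_config("gene sets must be subsets of the universe")
    universe <- length(unique(universe))
  }
  if (length(a) > universe || length(b) > universe)
    stop_config("gene set larger than the universe")
  hypergeom_overlap(length(intersect(a, b)), length(a), length(b), universe)
}
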