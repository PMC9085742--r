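#' Reference-vs-variant activity differences
#'
#' For each variant with activity estimates on both its reference and its
#' observed variant allele, `delta = alt log2 activity - ref log2 activity`.
#' Variants with NA activity on either allele are excluded (with reasons).
#'
#' @param results ActivityResult table from [test_activity()] (needs
#'   variant_id / allele columns).
#' @param variants variant table with ref_allele / alt_allele.
#' @return data.table (variant_id, ref_activity, alt_activity, delta);
#'   attribute `excluded` records dropped variants.
#' @export
compute_deltas <- function(results, variants) {
  res <- as.data.table(results)
  if (!all(c("variant_id", "allele") %in% names(res)))
    stop_config("activity results lack variant_id/allele annotation")
  v <- as.data.table(variants)
  m <- merge(v[, .(variant_id, ref_allele, alt_allele)],
             res[, .(variant_id, allele, log2_activity)],
             by = "variant_id", allow.cartesian = TRUE)
  ref <- m[allele == ref_allele, .(variant_id, ref_activity = log2_activity)]
  alt <- m[allele == alt_allele, .(variant_id, alt_activity = log2_activity)]
  d <- merge(ref, alt, by = "variant_id", all = TRUE)
  bad <- d[is.na(ref_activity) | is.na(alt_activity)]
  excluded <- data.table(
    variant_id = c(bad$variant_id,
                   setdiff(v$variant_id, d$variant_id)),
    reason = c(fifelse(is.na(bad$ref_activity) & is.na(bad$alt_activity),
                       "both alleles missing",
                       fifelse(is.na(bad$ref_activity),
                               "reference allele NA", "variant allele NA")),
               rep("no activity estimates",
                   length(setdiff(v$variant_id, d$variant_id)))))
  d <- d[!is.na(ref_activity) & !is.na(alt_activity)]
  d[, delta := alt_activity - ref_activity]
  if (nrow(excluded))
    message(sprintf("compute_deltas: excluded %d variant(s)", nrow(excluded)))
  setattr(d, "excluded", excluded)
  d[]
}

#' Standardize activity differences to z-scores
#'
#' `z = (delta - mean(delta)) / sd(delta)` with the sample (n-1) standard
#' deviation, over the pooled distribution of all profiled variants.
#'
#' @param deltas numeric vector (>= 3 values).
#' @return numeric z-scores (mean 0, sd 1).
#' @export
standardize <- function(deltas) {
  if (length(deltas) < 3L)
    stop_config("need at least 3 deltas to standardize")
  s <- sd(deltas)
  if (!is.finite(s) || s == 0)
    stop_config("delta distribution is degenerate (sd = 0)")
  (deltas - mean(deltas)) / s
}

#' Call variant effects from z-scores
#'
#' `decreased` if z < -threshold, `increased` if z > threshold, else `none`.
#' Mechanism: `loss_of_function` for decreases; `loss_of_repression` for
#' increases whose reference element is called a repressor; increases on a
#' non-repressive reference are labelled by sign only (`none` mechanism).
#'
#' @param deltas data.table from [compute_deltas()].
#' @param activity ActivityResult table (for the reference-allele call).
#' @param variants variant table (ref_allele lookup).
#' @param z_threshold effect threshold on |z| (default 2).
#' @return data.table VariantEffect: variant_id, ref_activity, alt_activity,
#'   delta, z, call, mechanism.
#' @export
call_effects <- function(deltas, activity = NULL, variants = NULL,
                         z_threshold = 2) {
  d <- copy(as.data.table(deltas))
  d[, z := standardize(delta)]
  d[, call := fifelse(z < -z_threshold, "decreased",
                      fifelse(z > z_threshold, "increased", "none"))]
  ref_call <- rep(NA_character_, nrow(d))
  if (!is.null(activity) && !is.null(variants)) {
    act <- as.data.table(activity)
    v <- as.data.table(variants)
    ref_act <- merge(v[, .(variant_id, ref_allele)],
                     act[, .(variant_id, allele, acall = call)],
                     by = "variant_id")[allele == ref_allele]
    ref_call <- ref_act[match(d$variant_id, variant_id), acall]
  }
  d[, mechanism := fifelse(call == "decreased", "loss_of_function",
                           fifelse(call == "increased" &
                                     !is.na(ref_call) & ref_call == "repressor",
                                   "loss_of_repression", "none"))]
  d[]
}

#' Per-variant four-allele activity profiles and per-label aggregates
#'
#' Builds the (A, C, G, T) activity profile of every variant with all four
#' analogs measured, labels alleles reference / variant / alternative, and
#' aggregates mean activity by label over a chosen variant subset (typically
#' the significant-effect variants).
#'
#' @param results ActivityResult table with variant_id / allele.
#' @param variants variant table.
#' @param subset optional character vector of variant ids for the aggregate
#'   (default: all variants in `results`).
#' @return list: `profiles` (long data.table variant_id, allele, label,
#'   log2_activity), `aggregate` (label, n, mean_activity, mean_abs, sd),
#'   `skipped` (variants without a complete analog set).
#' @export
analog_summary <- function(results, variants, subset = NULL) {
  res <- as.data.table(results)
  v <- as.data.table(variants)
  prof <- merge(res[, .(variant_id, allele, log2_activity)],
                v[, .(variant_id, ref_allele, alt_allele)],
                by = "variant_id")
  prof[, label := fifelse(allele == ref_allele, "reference",
                          fifelse(allele == alt_allele, "variant",
                                  "alternative"))]
  complete <- prof[!is.na(log2_activity), .N, by = variant_id][N == 4L,
                                                               variant_id]
  skipped <- setdiff(unique(prof$variant_id), complete)
  if (length(skipped))
    message(sprintf("analog_summary: skipped %d variant(s) with incomplete analog sets",
                    length(skipped)))
  prof <- prof[variant_id %in% complete]
  agg_src <- if (is.null(subset)) prof else prof[variant_id %in% subset]
  aggregate <- agg_src[, .(n = .N, mean_activity = mean(log2_activity),
                           mean_abs = mean(abs(log2_activity)),
                           sd = sd(log2_activity)),
                       by = label]
  list(profiles = prof[, .(variant_id, allele, label, log2_activity)],
       aggregate = aggregate[order(label)],
       skipped = skipped)
}

#' Full variant-effect analysis
#'
#' Convenience wrapper: [compute_deltas()] then [call_effects()].
#'
#' @inheritParams compute_deltas
#' @inheritParams call_effects
#' @return VariantEffect data.table.
#' @export
variant_effects <- function(results, variants, z_threshold = 2) {
  d <- compute_deltas(results, variants)
  call_effects(d, activity = results, variants = variants,
               z_threshold = z_threshold)
}
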