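get_counts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

get_condition <- function(x, condition = NULL) {
  if (!is.null(condition)) return(as.character(condition))
  if (is(x, "SummarizedExperiment"))
    return(as.character(SummarizedExperiment::colData(x)$condition))
  stop_config("a 'condition' vector (pDNA/cDNA per sample) is required")
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factor: the median, over elements whose counts are
#' positive in every sample, of the ratio of the sample's count to the
#' element's geometric mean across samples. This is the standard
#' normalization for comparing cDNA abundance to plasmid-pool abundance.
#'
#' @param x count matrix (elements x samples) or a SummarizedExperiment with
#'   a `counts` assay.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  k <- get_counts(x)
  logk <- log(k)
  loggeo <- rowMeans(logk)
  use <- is.finite(loggeo)
  if (!any(use))
    stop_config("no element has positive counts in all samples; filter the matrix first")
  sf <- apply(logk[use, , drop = FALSE], 2L,
              function(col) exp(median(col - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop_config("non-positive size factor estimated; check the count matrix")
  sf
}

#' Per-element negative-binomial dispersion estimates
#'
#' Method-of-moments on normalized counts (count / size factor): per
#' condition, `alpha_raw = (var(y) - mean(y)) / mean(y)^2`, pooled across
#' conditions with degree-of-freedom weights. Raw estimates are shrunk
#' halfway toward a mean-dispersion trend `a0 + a1/mu` fitted across
#' elements, and floored at `1e-8`. Working entirely on normalized counts
#' keeps every downstream statistic invariant to per-sample rescaling of the
#' raw counts.
#'
#' @param x count matrix or SummarizedExperiment.
#' @param sf size factors (default [size_factors()]).
#' @param condition per-sample condition labels (taken from colData when `x`
#'   is a SummarizedExperiment).
#' @return data.table: element, base_mean, raw, trend, dispersion.
#' @export
estimate_dispersion <- function(x, sf = NULL, condition = NULL) {
  k <- get_counts(x)
  cond <- get_condition(x, condition)
  if (is.null(sf)) sf <- size_factors(x)
  tab <- table(cond)
  if (any(tab < 2L))
    stop_config("at least 2 replicates per condition are required to estimate dispersion")
  y <- sweep(k, 2L, sf, "/")
  num <- 0; den <- 0
  for (cd in names(tab)) {
    yc <- y[, cond == cd, drop = FALSE]
    m <- rowMeans(yc)
    v <- apply(yc, 1L, var)
    a <- (v - m) / m^2
    a[!is.finite(a)] <- NA_real_
    w <- ncol(yc) - 1L
    num <- num + w * fcoalesce(a, 0)
    den <- den + w * as.numeric(!is.na(a))
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  base_mean <- rowMeans(y)
  # mean-dispersion trend alpha(mu) = a0 + a1/mu, least squares on usable raws
  use <- is.finite(raw) & base_mean > 0
  trend <- rep(NA_real_, nrow(k))
  if (sum(use) >= 10) {
    fit <- lm(raw[use] ~ I(1 / base_mean[use]))
    cf <- pmax(coef(fit), 0)
    trend <- cf[1] + cf[2] / base_mean
  } else {
    trend <- rep(mean(raw[use], na.rm = TRUE), nrow(k))
  }
  trend <- pmax(trend, 1e-8)
  shrunk <- pmax((pmax(fcoalesce(raw, 0), 0) + trend) / 2, 1e-8)
  data.table(element = rownames(k) %||% as.character(seq_len(nrow(k))),
             base_mean = base_mean, raw = raw, trend = trend,
             dispersion = shrunk)
}

#' Test per-element regulatory activity (cDNA vs plasmid pool)
#'
#' For each element, fits a negative-binomial log-linear model on normalized
#' counts with a condition coefficient: `log2_activity` is the log2 ratio of
#' the cDNA group mean to the pDNA group mean, its standard error comes from
#' the NB Fisher information `n * q / (1 + alpha * q)` per group, and the
#' Wald p-value from the normal reference. P-values are Benjamini-Hochberg
#' adjusted across all tested elements; elements with all-zero counts get NA
#' statistics and are excluded from the BH family. Calls: `activator`
#' (positive, padj < alpha), `repressor` (negative, padj < alpha), else
#' `inactive`.
#'
#' @param x count matrix or SummarizedExperiment (conditions pDNA / cDNA).
#' @param condition per-sample labels when `x` is a bare matrix.
#' @param sf size factors (computed if NULL).
#' @param dispersions per-element dispersions (estimated if NULL).
#' @param alpha significance level for calls (default 0.05).
#' @return data.table ActivityResult: element, variant_id/allele when
#'   available, base_mean, log2_activity, se, wald_p, padj, call.
#' @export
test_activity <- function(x, condition = NULL, sf = NULL, dispersions = NULL,
                          alpha = 0.05) {
  k <- get_counts(x)
  cond <- get_condition(x, condition)
  if (!all(c("pDNA", "cDNA") %in% cond))
    stop_config("both pDNA and cDNA samples are required")
  if (is.null(sf)) sf <- size_factors(x)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(x, sf = sf, condition = cond)$dispersion
  y <- sweep(k, 2L, sf, "/")
  grp <- list(pDNA = which(cond == "pDNA"), cDNA = which(cond == "cDNA"))
  fit_group <- function(idx) {
    yg <- y[, idx, drop = FALSE]
    n <- length(idx)
    q <- rowMeans(yg)  # NB MLE of the group mean on the normalized scale
    q_f <- pmax(q, 0.5 / n)  # pseudo-floor for all-zero groups
    info <- n * q_f / (1 + dispersions * q_f)
    list(q = q, logq = log(q_f), var_logq = 1 / info)
  }
  p_fit <- fit_group(grp$pDNA)
  c_fit <- fit_group(grp$cDNA)
  lfc <- (c_fit$logq - p_fit$logq) / log(2)
  se <- sqrt(c_fit$var_logq + p_fit$var_logq) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  all_zero <- rowSums(k) == 0
  lfc[all_zero] <- NA_real_; se[all_zero] <- NA_real_; p[all_zero] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[!all_zero] <- bh_adjust(p[!all_zero])
  call <- fifelse(is.na(padj) | padj >= alpha, "inactive",
                  fifelse(lfc > 0, "activator", "repressor"))
  res <- data.table(element = rownames(k) %||% as.character(seq_along(p)),
                    base_mean = rowMeans(y),
                    log2_activity = lfc, se = se, wald_p = p, padj = padj,
                    call = call)
  if (is(x, "SummarizedExperiment")) {
    rd <- SummarizedExperiment::rowData(x)
    if (all(c("variant_id", "allele") %in% colnames(rd))) {
      res[, variant_id := rd$variant_id]
      res[, allele := rd$allele]
      setcolorder(res, c("element", "variant_id", "allele"))
    }
  }
  res[]
}

#' Summaries of reference-allele regulatory activity
#'
#' @param results ActivityResult table restricted or restrictable to
#'   reference elements (rows with `allele == ref` when variants are given).
#' @param variants variant table (for inheritance class and TSS distance);
#'   optional.
#' @return list: `fraction_significant`, `by_inheritance` (data.table),
#'   `split` (activator/repressor counts), `tss_table` (dist_to_tss,
#'   log2_activity) and `tss_spearman`.
#' @export
summarize_activity <- function(results, variants = NULL) {
  res <- as.data.table(results)
  if (!is.null(variants) && "allele" %in% names(res)) {
    v <- as.data.table(variants)
    res <- merge(res, v[, .(variant_id, ref_allele, inheritance, dist_to_tss)],
                 by = "variant_id")
    res <- res[allele == ref_allele]
  }
  tested <- res[!is.na(padj)]
  sig <- tested[call != "inactive"]
  frac <- if (nrow(tested)) nrow(sig) / nrow(tested) else 0
  by_inh <- NULL
  if ("inheritance" %in% names(tested))
    by_inh <- tested[, .(n = .N, frac_significant = mean(call != "inactive")),
                     by = inheritance]
  split <- sig[, .N, by = call]
  tss_table <- NULL; rho <- NA_real_
  if ("dist_to_tss" %in% names(tested)) {
    tss_table <- tested[, .(dist_to_tss, log2_activity)]
    if (nrow(tss_table) >= 3)
      rho <- suppressWarnings(
        cor(abs(tss_table$dist_to_tss), tss_table$log2_activity,
            method = "spearman"))
  }
  list(fraction_significant = frac, by_inheritance = by_inh, split = split,
       tss_table = tss_table, tss_spearman = rho)
}
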