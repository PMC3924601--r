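# Target calling from overexpression fold-change arrays.
#
# A gene is "changing" when it is repressed more than two-fold
# (mean log2 FC <= -1) at 5% FDR by a one-sided t-test across the
# replicate isolates; an experimentally supported target additionally
# carries a predicted, well-conserved binding site.

#' Well-conserved predicted targets of one family
#'
#' @param table target-prediction data.frame
#' @param family microRNA family name
#' @param pct_threshold conservation cutoff; genes with
#'   `pct > pct_threshold` (strict) are kept (default 0.5)
#' @return character vector of gene ids
#' @export
well_conserved_targets <- function(table, family, pct_threshold = 0.5) {
  rows <- table$mirna_family == family
  if (!any(rows)) stop_domain("family absent from table: ", family)
  keep <- rows & !is.na(table$pct) & table$pct > pct_threshold
  unique(table$gene_id[keep])
}

#' Call experimentally supported targets
#'
#' Per gene: mean log2 fold change across replicates and a one-sided
#' t-test for repression (mean < 0) are computed for every testable
#' gene; the BH correction runs over the `test_universe` —
#' `"predicted"` (default) corrects over the predicted-target
#' hypotheses only, `"all"` over every tested gene.  With triplicate
#' arrays the t-test has 2 degrees of freedom and its attainable
#' p-values are bounded in probability near 1e-3, so a genome-wide
#' correction has essentially no power; see the methods vignette.
#' `is_changing` requires q <= `fdr` and mean <= `fold_cutoff_log2`;
#' `is_experimental_target` additionally requires membership in the
#' predicted set.  Genes with missing replicates or zero variance are
#' excluded from testing and flagged in the `tested` column.
#'
#' @param fc genes x replicates matrix of log2 fold changes
#' @param predicted character vector of predicted target gene ids
#' @param fdr FDR level (default 0.05)
#' @param fold_cutoff_log2 mean log2 FC cutoff (default -1, two-fold)
#' @param test_universe multiplicity-correction universe: `"predicted"`
#'   or `"all"`
#' @return data.frame, one row per gene
#' @export
call_targets <- function(fc, predicted, fdr = 0.05,
                         fold_cutoff_log2 = -1,
                         test_universe = c("predicted", "all")) {
  test_universe <- match.arg(test_universe)
  Y <- unclass(fc)
  if (ncol(Y) < 2) stop_domain("need >= 2 replicate columns")
  stopifnot(fdr > 0, fdr < 1)
  n <- ncol(Y)
  complete <- rowSums(is.na(Y)) == 0L
  sds <- rep(NA_real_, nrow(Y))
  sds[complete] <- apply(Y[complete, , drop = FALSE], 1, stats::sd)
  tested <- complete & !is.na(sds) & sds > 0
  mu <- rowMeans(Y)
  tstat <- rep(NA_real_, nrow(Y))
  pval <- rep(NA_real_, nrow(Y))
  tstat[tested] <- mu[tested] / (sds[tested] / sqrt(n))
  pval[tested] <- stats::pt(tstat[tested], df = n - 1)
  in_universe <- tested
  if (test_universe == "predicted")
    in_universe <- tested & rownames(Y) %in% predicted
  qv <- rep(NA_real_, nrow(Y))
  if (any(in_universe))
    qv[in_universe] <- bh_fdr(pval[in_universe], fdr)$qvalues
  changing <- in_universe & qv <= fdr & mu <= fold_cutoff_log2
  changing[is.na(changing)] <- FALSE
  out <- data.frame(gene_id = rownames(Y),
                    mean_log2_fc = mu, t = tstat, p_one_sided = pval,
                    qvalue = qv, tested = tested,
                    is_changing = changing,
                    is_predicted_target = rownames(Y) %in% predicted,
                    stringsAsFactors = FALSE)
  out$is_experimental_target <- out$is_changing & out$is_predicted_target
  rownames(out) <- NULL
  out
}

#' Compare fold-change distributions of targets vs non-targets
#'
#' @param fc_targets,fc_nontargets numeric vectors of log2 fold changes
#' @return list with `ecdf_targets`, `ecdf_nontargets` (step functions),
#'   `ks_statistic`, `ks_p` (asymptotic two-sample Kolmogorov-Smirnov)
#' @export
ecdf_compare <- function(fc_targets, fc_nontargets) {
  if (length(fc_targets) == 0 || length(fc_nontargets) == 0)
    stop_domain("both vectors must be non-empty")
  ks <- suppressWarnings(stats::ks.test(fc_targets, fc_nontargets,
                                        exact = FALSE))
  list(ecdf_targets = stats::ecdf(fc_targets),
       ecdf_nontargets = stats::ecdf(fc_nontargets),
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
}

#' Convert a log2 fold change to percent repression
#'
#' `100 * (1 - 2^log2_fc)`: 0 for no change, 50 for two-fold repression.
#'
#' @param log2_fc finite log2 fold change (negative = repression)
#' @return percent repression
#' @export
percent_repression <- function(log2_fc) {
  stopifnot(all(is.finite(log2_fc)))
  100 * (1 - 2^log2_fc)
}

#' Mean timecourse trace of a target set
#'
#' @param targets character vector of gene ids
#' @param timecourse genes x arrays log2 expression matrix
#' @return named numeric vector: per-array mean over the target genes,
#'   array order preserved
#' @export
quiescence_pattern_of_targets <- function(targets, timecourse) {
  Y <- unclass(timecourse)
  present <- intersect(targets, rownames(Y))
  if (length(present) == 0)
    stop_domain("targets do not intersect the timecourse genes")
  colMeans(Y[present, , drop = FALSE])
}
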