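# Domain containers, TSV readers/writers, probe collapsing and small
# statistical utilities shared by every analysis stage.
#
# All expression data are feature x sample numeric matrices on the log2
# scale (intensities for one-channel microRNA arrays, ratios for the
# two-channel mRNA timecourse).  Missing measurements are NA; every
# non-missing entry must be finite.

#' Construct a validated expression matrix
#'
#' Wraps a numeric feature x sample matrix after checking the container
#' invariants: unique feature and sample identifiers, and finite values
#' wherever the measurement is not missing (`NA` marks missing cells).
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids)
#' @return the matrix, classed as `ExpressionMatrix`
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_domain("values must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if ((is.null(fid) && nrow(values) > 0) ||
      (is.null(sid) && ncol(values) > 0))
    stop_domain("values must carry feature rownames and sample colnames")
  if (anyDuplicated(fid)) stop_domain("duplicate feature ids")
  if (anyDuplicated(sid)) stop_domain("duplicate sample ids")
  if (any(!is.finite(values[!is.na(values)])))
    stop_domain("non-missing entries must be finite")
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%d missing)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

missing_mask <- function(expr) is.na(unclass(expr))

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Read an expression TSV (and optionally its sample annotation sheet)
#'
#' The expression file has a header of sample ids with first column
#' `feature_id`; cells are numeric, with empty or `NA` cells treated as
#' missing.  The annotation file must contain columns `sample_id`,
#' `condition`, `timepoint_h`, `isolate`, `replicate`, and every
#' expression column must have an annotation row.
#'
#' @param path expression TSV path
#' @param annotation_path optional annotation TSV path
#' @return list with `expr` (ExpressionMatrix) and `annotations`
#'   (data.frame or NULL), annotation rows ordered to match columns
#' @export
read_expression_tsv <- function(path, annotation_path = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (colnames(tab)[1] != "feature_id")
    stop_domain("expression TSV must start with a 'feature_id' column")
  sid <- colnames(tab)[-1]
  if (anyDuplicated(sid)) stop_domain("duplicated sample column header")
  fid <- tab[[1]]
  if (anyDuplicated(fid)) stop_domain("duplicated feature id")
  vals <- vapply(tab[-1], as.numeric, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = length(fid),
                 dimnames = list(fid, sid))
  expr <- expression_matrix(vals)
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- read_annotation_tsv(annotation_path)
    miss <- setdiff(sid, ann$sample_id)
    if (length(miss))
      stop_domain("annotation missing samples: ", paste(miss, collapse = ", "))
    ann <- ann[match(sid, ann$sample_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  list(expr = expr, annotations = ann)
}

#' Write an expression matrix as TSV
#'
#' Values are emitted with 17 significant digits so that reading the file
#' back reproduces them bit-exactly; missing cells are written as `NA`.
#'
#' @param expr expression matrix
#' @param path output path
#' @export
write_expression_tsv <- function(expr, path) {
  out <- cbind(feature_id = rownames(expr),
               apply(unclass(expr), 2, fmt_num))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

annotation_conditions <- c("proliferating", "serum_starved",
                           "contact_inhibited", "restimulated")

#' Read a sample annotation TSV
#' @param path TSV with columns sample_id, condition, timepoint_h,
#'   isolate, replicate
#' @return data.frame
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           na.strings = c("NA", ""),
                           colClasses = c(sample_id = "character",
                                          condition = "character",
                                          isolate = "character"))
  need <- c("sample_id", "condition", "timepoint_h", "isolate", "replicate")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop_domain("annotation lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(ann$condition), annotation_conditions)
  if (length(bad))
    stop_domain("unknown condition labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop_domain("duplicated sample_id")
  ann
}

#' Write a sample annotation TSV
#' @param annotations data.frame as returned by [read_annotation_tsv()]
#' @param path output path
#' @export
write_annotation_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a target-prediction table
#'
#' Columns: `mirna_family`, `gene_id`, `pct` (probability of conserved
#' targeting, in \[0,1\] or missing) and `context_score` (site efficacy;
#' more negative = stronger predicted repression).
#'
#' @param path TSV path
#' @return data.frame with unique (family, gene) rows
#' @export
read_target_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", na.strings = c("NA", ""),
                           colClasses = c(mirna_family = "character",
                                          gene_id = "character"))
  need <- c("mirna_family", "gene_id", "pct", "context_score")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop_domain("target table lacks columns: ", paste(miss, collapse = ", "))
  validate_target_table(tab)
  tab
}

validate_target_table <- function(tab) {
  if (anyDuplicated(tab[c("mirna_family", "gene_id")]))
    stop_domain("duplicated (family, gene) prediction")
  p <- tab$pct[!is.na(tab$pct)]
  if (any(p < 0 | p > 1)) stop_domain("pct outside [0,1]")
  invisible(tab)
}

#' Write a target-prediction table as TSV
#' @param table data.frame with target-prediction columns
#' @param path output path
#' @export
write_target_table <- function(table, path) {
  validate_target_table(table)
  out <- data.frame(mirna_family = table$mirna_family,
                    gene_id = table$gene_id,
                    pct = fmt_num(table$pct),
                    context_score = fmt_num(table$context_score))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

phase_labels <- c("g0g1", "s", "g2m")

#' Read a flow-cytometry phase count table
#'
#' Columns: `timepoint_h`, `transfection`, `day_batch`, `replicate`, and
#' integer cell counts `g0g1`, `s`, `g2m` (G0/G1, S, G2/M phases).
#'
#' @param path TSV path
#' @return data.frame of validated counts
#' @export
read_phase_counts <- function(path) {
  tab <- utils::read.delim(path, sep = "\t",
                           colClasses = c(transfection = "character",
                                          day_batch = "character"))
  validate_phase_counts(tab)
  tab
}

validate_phase_counts <- function(tab) {
  need <- c("timepoint_h", "transfection", "day_batch", "replicate",
            phase_labels)
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop_domain("phase table lacks columns: ", paste(miss, collapse = ", "))
  cnt <- as.matrix(tab[phase_labels])
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop_domain("phase counts must be non-negative integers")
  key <- tab[c("timepoint_h", "transfection", "day_batch", "replicate")]
  if (anyDuplicated(key))
    stop_domain("duplicated (timepoint, transfection, day, replicate) row")
  invisible(tab)
}

#' Write a phase count table as TSV
#' @param counts validated phase count data.frame
#' @param path output path
#' @export
write_phase_counts <- function(counts, path) {
  validate_phase_counts(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Collapse probe-level rows to gene-level rows
#'
#' A probe "generates signal" in a sample iff its entry is non-missing.
#' Probes detected in fewer than `detection_fraction` of samples are
#' dropped, unmapped probes are dropped, and where several surviving
#' probes map to one gene their values are averaged per sample, ignoring
#' missing entries.
#'
#' @param expr probe-level expression matrix
#' @param probe_gene_map data.frame with columns `probe_id`, `gene_id`
#' @param detection_fraction required fraction of arrays with signal,
#'   in (0, 1]; default 0.8
#' @return gene-level ExpressionMatrix (possibly 0-row, with a warning)
#' @export
collapse_probes_to_genes <- function(expr, probe_gene_map,
                                     detection_fraction = 0.8) {
  stopifnot(is.numeric(detection_fraction),
            detection_fraction > 0, detection_fraction <= 1)
  if (!all(c("probe_id", "gene_id") %in% colnames(probe_gene_map)))
    stop_domain("probe_gene_map needs columns probe_id, gene_id")
  det <- rowMeans(!is.na(expr))
  keep <- det >= detection_fraction
  expr <- unclass(expr)[keep, , drop = FALSE]
  gene <- probe_gene_map$gene_id[match(rownames(expr),
                                       probe_gene_map$probe_id)]
  expr <- expr[!is.na(gene), , drop = FALSE]
  gene <- gene[!is.na(gene)]
  if (nrow(expr) == 0L) {
    warning("no probes survive detection filtering and mapping")
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(expr),
                  dimnames = list(character(0), colnames(expr)))
    return(expression_matrix(out))
  }
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(expr),
                dimnames = list(genes, colnames(expr)))
  for (g in genes) {
    rows <- expr[gene == g, , drop = FALSE]
    m <- colMeans(rows, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[g, ] <- m
  }
  expression_matrix(out)
}

#' One-sample, one-sided t test against mean zero
#'
#' @param samples numeric vector, length >= 2, non-constant
#' @param alternative `"less"` (mean < 0) or `"greater"`
#' @return list with `t`, `p` and `df`
#' @export
one_sided_t_test <- function(samples, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 2L) stop_domain("need at least 2 observations")
  s <- stats::sd(samples)
  if (!is.finite(s) || s == 0) stop_domain("zero sample variance")
  t <- mean(samples) / (s / sqrt(n))
  p <- if (alternative == "less") stats::pt(t, df = n - 1)
       else stats::pt(t, df = n - 1, lower.tail = FALSE)
  list(t = t, p = p, df = n - 1L)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up q-values with enforced monotonicity; `significant` marks
#' q-value <= `q`.
#'
#' @param pvalues numeric vector of p-values in \[0,1\]
#' @param q target FDR level in (0,1)
#' @return list with `qvalues` and `significant`
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_domain("p-values must lie in [0,1]")
  stopifnot(q > 0, q < 1)
  m <- length(pvalues)
  o <- order(pvalues)
  qs <- pvalues[o] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  qvalues <- numeric(m)
  qvalues[o] <- qs
  list(qvalues = qvalues, significant = qvalues <= q)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y equal-length numeric vectors (n >= 4), non-constant
#' @param confidence confidence level, default 0.95
#' @return list with `r`, `lo`, `hi`
#' @export
pearson_ci <- function(x, y, confidence = 0.95) {
  n <- length(x)
  if (length(y) != n || n < 4L) stop_domain("need equal lengths >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_domain("constant input vector")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) return(list(r = r, lo = r, hi = r))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- stats::qnorm(1 - (1 - confidence) / 2)
  list(r = r, lo = tanh(z - crit * se), hi = tanh(z + crit * se))
}
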