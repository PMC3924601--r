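# Eigengene decomposition of the quiescence mRNA timecourse.
#
# Genes are rows, arrays columns.  The right singular vectors
# ("eigengenes") are orthonormal expression patterns over arrays; the
# first one tracks the proliferation/quiescence axis.  Each gene's
# projection onto the oriented first eigengene is its "proliferation
# index": positive = proliferation-associated, negative =
# quiescence-associated.

#' Drop genes with any missing value
#'
#' @param expr expression matrix
#' @return ExpressionMatrix containing exactly the complete rows
#' @export
filter_complete_genes <- function(expr) {
  keep <- rowSums(is.na(expr)) == 0L
  if (!any(keep)) stop_domain("no gene has complete data")
  expression_matrix(unclass(expr)[keep, , drop = FALSE])
}

#' Singular value decomposition into eigengenes
#'
#' Thin SVD of the complete genes x arrays matrix.  The first eigengene
#' is sign-oriented so that the coordinate of the quiescent-pole array
#' (by default the 96-h serum-starvation array, or the last array if the
#' id is absent) is negative; proliferation-associated genes then
#' project positively.
#'
#' @param expr complete expression matrix (use
#'   [filter_complete_genes()] first)
#' @param orient_sample sample id (or column index) of the
#'   quiescent-pole array used to fix the sign of eigengene 1
#' @return an `EigengeneDecomposition`: list with `eigengenes` (arrays x
#'   components, orthonormal columns), `singular_values`,
#'   `variance_fractions`, `gene_loadings` (U), `gene_ids`,
#'   `orientation_flipped`
#' @export
compute_svd <- function(expr, orient_sample = "SS_96h") {
  Y <- unclass(expr)
  if (any(is.na(Y))) stop_domain("matrix must be complete; filter first")
  if (ncol(Y) < 2) stop_domain("need >= 2 arrays")
  s <- svd(Y)
  if (length(s$d) > 1 && abs(s$d[1] - s$d[2]) < 1e-12 * max(s$d))
    warning("leading singular values tied; orientation is arbitrary")
  j <- if (is.numeric(orient_sample)) as.integer(orient_sample)
       else match(orient_sample, colnames(Y))
  if (is.na(j)) j <- ncol(Y)
  flipped <- s$v[j, 1] > 0
  if (flipped) { s$v[, 1] <- -s$v[, 1]; s$u[, 1] <- -s$u[, 1] }
  rownames(s$v) <- colnames(Y)
  colnames(s$v) <- paste0("eigengene", seq_along(s$d))
  structure(list(eigengenes = s$v, singular_values = s$d,
                 variance_fractions = s$d^2 / sum(s$d^2),
                 gene_loadings = s$u, gene_ids = rownames(Y),
                 orientation_flipped = flipped),
            class = "EigengeneDecomposition")
}

#' Per-gene proliferation index
#'
#' The projection of each gene's expression profile onto the oriented
#' first eigengene.
#'
#' @param decomp an `EigengeneDecomposition`
#' @param expr the same complete matrix decomposed by [compute_svd()]
#' @return named numeric vector, one value per gene
#' @export
proliferation_index <- function(decomp, expr) {
  Y <- unclass(expr)
  if (any(is.na(Y))) stop_domain("matrix must be complete")
  stopifnot(identical(rownames(Y), decomp$gene_ids))
  drop(Y %*% decomp$eigengenes[, 1])
}

#' Variance fraction of the k-th eigengene
#'
#' @param decomp an `EigengeneDecomposition`
#' @param k component index
#' @return fraction of total (uncentred) variance carried by component k
#' @export
variance_explained <- function(decomp, k = 1L) {
  if (k < 1 || k > length(decomp$variance_fractions))
    stop_domain("component index out of range")
  decomp$variance_fractions[k]
}

#' Hierarchical clustering of gene profiles
#'
#' Rows are centred (row mean subtracted) and L2-normalised, then
#' agglomerated by centroid linkage on squared Euclidean distances (a
#' monotone transform of 1 - Pearson correlation on such rows) and the
#' tree is cut into `n_clusters` groups.
#'
#' @param expr complete expression matrix
#' @param n_clusters number of clusters (default 4)
#' @return named integer vector of cluster labels
#' @export
hierarchical_cluster <- function(expr, n_clusters = 4L) {
  Y <- unclass(expr)
  if (any(is.na(Y))) stop_domain("matrix must be complete")
  if (n_clusters < 1 || n_clusters > nrow(Y))
    stop_domain("n_clusters must be in [1, n_genes]")
  Yc <- Y - rowMeans(Y)
  nrm <- sqrt(rowSums(Yc^2))
  nrm[nrm == 0] <- 1          # constant genes stay at the origin
  Yc <- Yc / nrm
  hc <- stats::hclust(stats::dist(Yc)^2, method = "centroid")
  stats::cutree(hc, k = n_clusters)
}
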