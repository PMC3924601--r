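# Bootstrap enrichment of predicted microRNA target sets.
#
# Each family's filtered target set is scored by the mean proliferation
# index of its genes; significance comes from comparing that mean (and
# its additive inverse, making the test two-tailed) to the means of
# randomly drawn gene sets of identical size.

#' Filter predicted target sets by context score and universe
#'
#' Keeps predictions with `context_score <= context_threshold` (more
#' negative = more confident) whose gene is in the expression universe,
#' deduplicates genes per family, and drops families left empty.
#'
#' @param table target-prediction data.frame
#' @param universe character vector of gene ids with expression data
#' @param context_threshold context-score cutoff (default -0.5)
#' @return named list: family -> character vector of genes
#' @export
filter_target_sets <- function(table, universe, context_threshold = -0.5) {
  if (length(universe) == 0) stop_domain("empty gene universe")
  stopifnot(is.finite(context_threshold))
  keep <- !is.na(table$context_score) &
    table$context_score <= context_threshold &
    table$gene_id %in% universe
  tab <- table[keep, , drop = FALSE]
  sets <- lapply(split(tab$gene_id, tab$mirna_family), unique)
  sets[lengths(sets) > 0]
}

#' Mean proliferation-index projection of a gene set
#'
#' Genes absent from the index domain are ignored; their count is
#' attached as attribute `n_dropped`.
#'
#' @param gene_set character vector of gene ids
#' @param index named proliferation-index vector
#' @return mean index over the genes present in the index
#' @export
mean_projection <- function(gene_set, index) {
  present <- intersect(gene_set, names(index))
  if (length(present) == 0)
    stop_domain("gene set does not intersect the index domain")
  structure(mean(index[present]),
            n_dropped = length(gene_set) - length(present))
}

#' Two-tailed bootstrap p-value for a target set's mean projection
#'
#' Draws `n_resamples` gene sets of the same size uniformly without
#' replacement from the index domain; the two-tailed exceedance count is
#' `#{null >= |obs|} + #{null <= -|obs|}`.  A zero count is reported as
#' the resolution bound `1/n_resamples` with `below_resolution = TRUE`;
#' `pvalue_corrected` is the (count+1)/(n+1) version.
#'
#' @param gene_set character vector of gene ids
#' @param index named proliferation-index vector (the universe)
#' @param n_resamples number of bootstrap draws (default 10000)
#' @param seed optional RNG seed
#' @return a `BootstrapEnrichment` list
#' @export
bootstrap_pvalue <- function(gene_set, index, n_resamples = 10000L,
                             seed = NULL) {
  stopifnot(n_resamples >= 1)
  obs <- mean_projection(gene_set, index)
  m <- length(intersect(gene_set, names(index)))
  if (m > length(index)) stop_domain("gene set larger than universe")
  with_seed(seed, {
    null <- vapply(seq_len(n_resamples), function(b)
      mean(index[sample.int(length(index), m)]), numeric(1))
    count <- sum(null >= abs(obs)) + sum(null <= -abs(obs))
    below <- count == 0L
    structure(list(set_size = m,
                   mean_projection = as.numeric(obs),
                   n_dropped = attr(obs, "n_dropped"),
                   n_resamples = as.integer(n_resamples),
                   n_as_or_more_extreme = as.integer(count),
                   pvalue = if (below) 1 / n_resamples else
                     count / n_resamples,
                   below_resolution = below,
                   pvalue_corrected = (count + 1) / (n_resamples + 1),
                   seed = seed),
              class = "BootstrapEnrichment")
  })
}

#' Enrichment table over all families (volcano input)
#'
#' Applies [filter_target_sets()] then [bootstrap_pvalue()] per family;
#' rows sorted by p-value, ties broken by |mean projection| descending.
#'
#' @param table target-prediction data.frame
#' @param index named proliferation-index vector
#' @param n_resamples bootstrap draws per family (default 10000)
#' @param context_threshold context-score cutoff (default -0.5)
#' @param seed optional RNG seed (per-family draws derive from it)
#' @return data.frame with one row per family
#' @export
enrichment_volcano <- function(table, index, n_resamples = 10000L,
                               context_threshold = -0.5, seed = NULL) {
  sets <- filter_target_sets(table, names(index), context_threshold)
  if (length(sets) == 0) stop_domain("no family survives filtering")
  rows <- lapply(seq_along(sets), function(j) {
    be <- bootstrap_pvalue(sets[[j]], index, n_resamples,
                           seed = derive_seed(seed, j))
    data.frame(mirna_family = names(sets)[j], set_size = be$set_size,
               mean_projection = be$mean_projection, pvalue = be$pvalue,
               below_resolution = be$below_resolution,
               pvalue_corrected = be$pvalue_corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, -abs(out$mean_projection)), ]
  rownames(out) <- NULL
  out
}
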