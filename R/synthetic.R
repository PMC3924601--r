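# Synthetic-data generators.
#
# Every generator is a pure function of its configuration: it seeds a
# local RNG stream derived from cfg$seed (restoring the caller's RNG
# state), plants structure matching the statistical assumptions of the
# downstream stage, and returns the planted values in a ground-truth
# record so recovery can be scored exactly.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the emulated experiment: 209 microRNAs profiled on
#' 9 one-channel arrays (3 fibroblast isolates x proliferating /
#' serum-starved / contact-inhibited), of which 68% respond to
#' quiescence; a 16-array mRNA log-ratio timecourse whose leading
#' quiescence-depth pattern carries ~40% of the variance; TargetScan-like
#' prediction tables with one planted family whose targets are
#' quiescence-induced; triplicate overexpression arrays with planted
#' -1.5 log2 repression of target genes; and Dirichlet-multinomial
#' three-phase cell-cycle counts in triplicate on two days.
#'
#' @param seed integer RNG seed
#' @param n_mirnas number of microRNA features (default 209, the number
#'   detected above background in the emulated experiment)
#' @param n_genes number of mRNA genes (default 2000; a desk-scale
#'   stand-in for a whole-genome array)
#' @param frac_quiescence_responsive fraction of microRNAs with a planted
#'   quiescence response (default 0.68)
#' @param effect_size_log2 magnitude of the planted quiescence
#'   coefficient, log2 units (default 1.5)
#' @param noise_sd Gaussian measurement noise sd, log2 units
#' @param surrogate_effect_sd scale of the hidden-batch (surrogate)
#'   effect; 0 disables it
#' @param n_isolates number of fibroblast isolates (>= 2)
#' @param prolif_pattern_share fraction of total timecourse variance
#'   carried by the planted proliferation/quiescence pattern
#' @param target_set_sizes per-family target-set sizes; the first entry
#'   is the planted family, the rest are decoys
#' @param planted_family name of the planted microRNA family
#' @param overexpression_repression_log2 planted mean log2 fold change of
#'   repressed genes upon overexpression (negative)
#' @param dirichlet_alphas named list of positive concentration triples,
#'   one per transfection group (G0/G1, S, G2/M order)
#' @param cells_per_sample flow-cytometry events per replicate
#' @param phase_timepoints_h timepoints (hours) for the phase-count table
#' @return a `SyntheticConfig` list
#' @export
synthetic_config <- function(seed = 1L,
                             n_mirnas = 209L,
                             n_genes = 2000L,
                             frac_quiescence_responsive = 0.68,
                             effect_size_log2 = 1.5,
                             noise_sd = 0.25,
                             surrogate_effect_sd = 0.5,
                             n_isolates = 3L,
                             prolif_pattern_share = 0.4,
                             target_set_sizes = rep(50L, 20L),
                             planted_family = "mir-29",
                             overexpression_repression_log2 = -1.5,
                             dirichlet_alphas = list(
                               NC       = c(24, 12, 4),
                               "mir-29" = c(10, 24, 6)),
                             cells_per_sample = 10000L,
                             phase_timepoints_h = c(20, 24, 28, 32)) {
  cfg <- list(seed = seed, n_mirnas = n_mirnas, n_genes = n_genes,
              frac_quiescence_responsive = frac_quiescence_responsive,
              effect_size_log2 = effect_size_log2, noise_sd = noise_sd,
              surrogate_effect_sd = surrogate_effect_sd,
              n_isolates = n_isolates,
              prolif_pattern_share = prolif_pattern_share,
              target_set_sizes = target_set_sizes,
              planted_family = planted_family,
              overexpression_repression_log2 = overexpression_repression_log2,
              dirichlet_alphas = dirichlet_alphas,
              cells_per_sample = cells_per_sample,
              phase_timepoints_h = phase_timepoints_h)
  class(cfg) <- "SyntheticConfig"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_mirnas >= 1, n_genes >= 1, cells_per_sample >= 1,
              frac_quiescence_responsive >= 0,
              frac_quiescence_responsive <= 1,
              effect_size_log2 > 0, noise_sd > 0, surrogate_effect_sd >= 0,
              prolif_pattern_share > 0, prolif_pattern_share <= 1,
              overexpression_repression_log2 < 0,
              all(target_set_sizes >= 1),
              length(planted_family) == 1L)
    if (n_isolates < 2)
      stop_domain("need >= 2 isolates: isolate terms otherwise unidentifiable")
    if (is.null(names(dirichlet_alphas)) || length(dirichlet_alphas) < 1)
      stop_domain("dirichlet_alphas must be a named list of groups")
    ok <- vapply(dirichlet_alphas,
                 function(a) length(a) == 3L && all(a > 0), logical(1))
    if (!all(ok))
      stop_domain("every dirichlet_alphas entry must be a positive triple")
  })
  invisible(cfg)
}

#' Generate one-channel microRNA arrays with planted quiescence effects
#'
#' Builds `n_isolates x 3` samples (proliferating, serum-starved,
#' contact-inhibited).  Each feature follows the additive model
#' `m + B_Q x_Q + B_S x_S + isolate offsets + B_SVA g + noise`: a
#' fraction of features carries `|B_Q| = effect_size_log2` with random
#' sign, and `g` is a random +/-1 hidden-batch pattern orthogonalised
#' against the design so the planted coefficients stay identifiable.
#'
#' @param cfg a [synthetic_config()]
#' @return list with `expr` (log2 ExpressionMatrix), `annotations`, and
#'   `truth` (responsive set with signed effects, unit surrogate vector,
#'   per-feature coefficients)
#' @export
gen_mirna_arrays <- function(cfg) {
  validate_synthetic_config(cfg)
  with_seed(derive_seed(cfg$seed, 1L), {
    isolates <- sprintf("iso%d", seq_len(cfg$n_isolates))
    conds <- c(proliferating = "P", serum_starved = "SS",
               contact_inhibited = "CI")
    ann <- expand.grid(condition = names(conds), isolate = isolates,
                       stringsAsFactors = FALSE)
    ann$sample_id <- paste(ann$isolate, conds[ann$condition], sep = "_")
    ann$timepoint_h <- NA_real_
    ann$replicate <- 1L
    ann <- ann[c("sample_id", "condition", "timepoint_h", "isolate",
                 "replicate")]
    n <- nrow(ann)
    ids <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))

    X <- build_design(ann)
    xQ <- X[, "x_Q"]; xS <- X[, "x_S"]

    m <- stats::rnorm(cfg$n_mirnas, mean = 8, sd = 1.5)
    n_resp <- round(cfg$frac_quiescence_responsive * cfg$n_mirnas)
    resp <- sort(sample.int(cfg$n_mirnas, n_resp))
    bQ <- numeric(cfg$n_mirnas)
    bQ[resp] <- sample(c(-1, 1), n_resp, replace = TRUE) *
      cfg$effect_size_log2
    bS <- stats::rnorm(cfg$n_mirnas, 0, 0.1)
    iso_cols <- grep("^x_iso_", colnames(X), value = TRUE)
    Biso <- matrix(stats::rnorm(cfg$n_mirnas * length(iso_cols), 0, 0.2),
                   nrow = cfg$n_mirnas)

    # hidden batch: +/-1 pattern, made orthogonal to the design columns
    g <- sample(c(-1, 1), n, replace = TRUE)
    g <- stats::residuals(stats::lm.fit(X, g))
    while (sqrt(sum(g^2)) < 1e-8) {
      g <- sample(c(-1, 1), n, replace = TRUE)
      g <- stats::residuals(stats::lm.fit(X, g))
    }
    g <- g / sqrt(sum(g^2))
    b_sva <- stats::rnorm(cfg$n_mirnas, 0, 1)

    Y <- outer(m, rep(1, n)) + outer(bQ, xQ) + outer(bS, xS) +
      Biso %*% t(X[, iso_cols, drop = FALSE]) +
      cfg$surrogate_effect_sd * outer(b_sva, g) +
      matrix(stats::rnorm(cfg$n_mirnas * n, 0, cfg$noise_sd),
             nrow = cfg$n_mirnas)
    dimnames(Y) <- list(ids, ann$sample_id)

    effects <- bQ[resp]; names(effects) <- ids[resp]
    list(expr = expression_matrix(Y),
         annotations = ann,
         truth = list(responsive_mirnas = effects,
                      surrogate_vector = stats::setNames(g, ann$sample_id),
                      b_q = stats::setNames(bQ, ids),
                      b_s = stats::setNames(bS, ids),
                      b_sva = stats::setNames(b_sva, ids),
                      baseline = stats::setNames(m, ids),
                      seed = cfg$seed))
  })
}

# fixed quiescence-depth coordinates of the 16-array timecourse:
# rising through serum starvation, falling through restimulation,
# maximal under contact inhibition (two timepoints, each in duplicate)
timecourse_layout <- function() {
  data.frame(
    sample_id = c(sprintf("SS_%sh", c(1, 2, 4, 8, 24, 96)),
                  sprintf("SR_%sh", c(1, 2, 4, 8, 24, 48)),
                  c("CI_7d_a", "CI_7d_b", "CI_14d_a", "CI_14d_b")),
    condition = rep(c("serum_starved", "restimulated", "contact_inhibited"),
                    c(6, 6, 4)),
    timepoint_h = c(1, 2, 4, 8, 24, 96, 1, 2, 4, 8, 24, 48,
                    168, 168, 336, 336),
    isolate = "iso1",
    replicate = c(rep(1L, 12), 1L, 2L, 1L, 2L),
    depth = c(0.10, 0.18, 0.32, 0.50, 0.80, 1.00,
              0.90, 0.75, 0.55, 0.35, 0.15, 0.05,
              1.00, 1.05, 1.10, 1.10),
    stringsAsFactors = FALSE)
}

#' Generate the 16-array mRNA quiescence timecourse
#'
#' Serum starvation (1-96 h), serum restimulation (1-48 h) and contact
#' inhibition (7 and 14 days in duplicate), as log2 ratios.  A fixed
#' quiescence-depth pattern carries `prolif_pattern_share` of the total
#' sum of squares; quiescence-class genes load positively on it,
#' proliferation-class genes negatively, neutral genes not at all.  The
#' remaining variance comes from two secondary patterns plus white noise.
#'
#' @param cfg a [synthetic_config()]
#' @return list with `expr`, `annotations` and `truth` (`gene_class`,
#'   the depth `pattern`, per-gene `loading`)
#' @export
gen_mrna_timecourse <- function(cfg) {
  validate_synthetic_config(cfg)
  with_seed(derive_seed(cfg$seed, 2L), {
    lay <- timecourse_layout()
    n <- nrow(lay)
    ids <- sprintf("G%05d", seq_len(cfg$n_genes))
    q <- lay$depth / sqrt(sum(lay$depth^2))

    n_pro <- round(0.3 * cfg$n_genes)
    n_qui <- round(0.3 * cfg$n_genes)
    cls <- rep("neutral", cfg$n_genes)
    cls[seq_len(n_pro)] <- "proliferation"
    cls[n_pro + seq_len(n_qui)] <- "quiescence"
    cls <- sample(cls)  # shuffle class labels over gene ids
    loading <- numeric(cfg$n_genes)
    loading[cls == "proliferation"] <- -abs(stats::rnorm(n_pro, 1, 0.3))
    loading[cls == "quiescence"] <- abs(stats::rnorm(n_qui, 1, 0.3))

    signal <- outer(loading, q)
    r1 <- stats::rnorm(n); r1 <- r1 - sum(r1 * q) * q; r1 <- r1 / sqrt(sum(r1^2))
    r2 <- stats::rnorm(n); r2 <- r2 - sum(r2 * q) * q
    r2 <- r2 - sum(r2 * r1) * r1; r2 <- r2 / sqrt(sum(r2^2))
    other <- outer(stats::rnorm(cfg$n_genes, 0, 0.5), r1) +
      outer(stats::rnorm(cfg$n_genes, 0, 0.5), r2) +
      matrix(stats::rnorm(cfg$n_genes * n, 0, 1), nrow = cfg$n_genes)
    share <- cfg$prolif_pattern_share
    scale <- if (share >= 1) 0 else
      sqrt(sum(signal^2) * (1 - share) / (share * sum(other^2)))
    Y <- signal + scale * other
    dimnames(Y) <- list(ids, lay$sample_id)

    list(expr = expression_matrix(Y),
         annotations = lay[c("sample_id", "condition", "timepoint_h",
                             "isolate", "replicate")],
         truth = list(gene_class = stats::setNames(cls, ids),
                      pattern = stats::setNames(lay$depth, lay$sample_id),
                      loading = stats::setNames(loading, ids),
                      seed = cfg$seed))
  })
}

#' Generate a TargetScan-style target-prediction table
#'
#' One planted family draws its targets from quiescence-class genes (so
#' its set is quiescence-induced downstream); decoy families draw
#' uniformly from the gene universe.  Member predictions receive context
#' scores below -0.5 so the configured set sizes survive the standard
#' filter, plus ~30% additional weak predictions per family with context
#' scores above -0.5 that the filter must remove.  PCT values for the
#' planted family are enriched above 0.5.
#'
#' @param cfg a [synthetic_config()]
#' @param truth ground truth from [gen_mrna_timecourse()]
#' @return list with `table` (prediction data.frame) and `truth`
#'   (`true_targets`: family -> gene set)
#' @export
gen_target_predictions <- function(cfg, truth) {
  validate_synthetic_config(cfg)
  with_seed(derive_seed(cfg$seed, 3L), {
    universe <- names(truth$gene_class)
    quiesc <- universe[truth$gene_class == "quiescence"]
    sizes <- as.integer(cfg$target_set_sizes)
    fams <- c(cfg$planted_family,
              sprintf("mir-dec%02d", seq_len(length(sizes) - 1L)))
    if (sizes[1] > length(quiesc))
      stop_domain("planted set size exceeds available quiescence-class genes")
    sets <- vector("list", length(fams)); names(sets) <- fams
    sets[[1]] <- sample(quiesc, sizes[1])
    for (j in seq_along(fams)[-1]) sets[[j]] <- sample(universe, sizes[j])

    rows <- lapply(seq_along(fams), function(j) {
      genes <- sets[[j]]
      k <- length(genes)
      pct <- if (j == 1L) stats::runif(k, 0.55, 0.95) else stats::runif(k)
      member <- data.frame(mirna_family = fams[j], gene_id = genes,
                           pct = pct,
                           context_score = stats::runif(k, -1.5, -0.55),
                           stringsAsFactors = FALSE)
      n_weak <- round(0.3 * k)
      weak_pool <- setdiff(universe, genes)
      weak <- data.frame(mirna_family = fams[j],
                         gene_id = sample(weak_pool, n_weak),
                         pct = stats::runif(n_weak),
                         context_score = stats::runif(n_weak, -0.45, -0.05),
                         stringsAsFactors = FALSE)
      rbind(member, weak)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    validate_target_table(tab)
    list(table = tab, truth = list(true_targets = sets, seed = cfg$seed))
  })
}

#' Generate triplicate overexpression log2 fold-change arrays
#'
#' Repressed genes (80% of the planted family's targets plus 20 random
#' off-target genes) receive mean log2 fold change
#' `overexpression_repression_log2`; all other genes have mean 0.  Each
#' of the three isolate replicates adds independent Gaussian noise.
#'
#' @param cfg a [synthetic_config()]
#' @param truth ground truth from [gen_target_predictions()] (needs
#'   `true_targets`) merged with gene ids from the timecourse truth
#' @param gene_ids character vector of all gene ids (the universe)
#' @return list with `expr` (genes x isolates log2 FC) and `truth`
#'   (`repressed_genes`)
#' @export
gen_overexpression_arrays <- function(cfg, truth, gene_ids) {
  validate_synthetic_config(cfg)
  with_seed(derive_seed(cfg$seed, 4L), {
    targets <- truth$true_targets[[cfg$planted_family]]
    if (is.null(targets)) stop_domain("planted family absent from truth")
    n_hit <- max(1L, round(0.8 * length(targets)))
    hit <- sample(targets, n_hit)
    extras <- sample(setdiff(gene_ids, targets), min(20L, length(gene_ids)))
    repressed <- sort(unique(c(hit, extras)))
    mu <- ifelse(gene_ids %in% repressed,
                 cfg$overexpression_repression_log2, 0)
    reps <- sprintf("iso%d_log2fc", seq_len(cfg$n_isolates))
    Y <- outer(mu, rep(1, length(reps))) +
      matrix(stats::rnorm(length(gene_ids) * length(reps), 0, cfg$noise_sd),
             nrow = length(gene_ids))
    dimnames(Y) <- list(gene_ids, reps)
    list(expr = expression_matrix(Y),
         truth = list(repressed_genes = repressed, seed = cfg$seed))
  })
}

#' Generate Dirichlet-multinomial cell-cycle phase counts
#'
#' For every transfection group and timepoint, replicate phase
#' proportions are drawn from the group's Dirichlet concentration triple
#' and converted to counts of `cells_per_sample` cells by a multinomial
#' draw; replication is triplicate on each of two days (6 replicates).
#'
#' @param cfg a [synthetic_config()]
#' @return list with `counts` (phase count data.frame) and `truth`
#'   (`alphas` per group)
#' @export
gen_phase_counts <- function(cfg) {
  validate_synthetic_config(cfg)
  with_seed(derive_seed(cfg$seed, 5L), {
    grid <- expand.grid(replicate = 1:3, day_batch = c("d1", "d2"),
                        transfection = names(cfg$dirichlet_alphas),
                        timepoint_h = cfg$phase_timepoints_h,
                        stringsAsFactors = FALSE)
    props <- t(vapply(grid$transfection, function(gr)
      rdirichlet(1, cfg$dirichlet_alphas[[gr]])[1, ], numeric(3)))
    cnt <- t(vapply(seq_len(nrow(grid)), function(i)
      stats::rmultinom(1, cfg$cells_per_sample, props[i, ])[, 1],
      numeric(3)))
    out <- data.frame(timepoint_h = grid$timepoint_h,
                      transfection = grid$transfection,
                      day_batch = grid$day_batch,
                      replicate = grid$replicate,
                      g0g1 = as.integer(cnt[, 1]),
                      s = as.integer(cnt[, 2]),
                      g2m = as.integer(cnt[, 3]),
                      stringsAsFactors = FALSE)
    validate_phase_counts(out)
    list(counts = out,
         truth = list(alphas = cfg$dirichlet_alphas, seed = cfg$seed))
  })
}
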