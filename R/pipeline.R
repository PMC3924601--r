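# End-to-end orchestration: synthetic generation (or user files) ->
# microRNA signature -> eigengene / proliferation index -> target-set
# enrichment -> overexpression target calling -> phase-composition LRT.
# Every stage's tables are written as TSV and a machine-readable JSON
# report summarises parameters, seeds and (in synthetic mode)
# planted-truth recovery metrics.

#' Build a pipeline configuration
#'
#' Defaults mirror the analysis' stated parameters: FDR 1% for the
#' microRNA signature, FDR 5% with a two-fold cutoff for target calling,
#' 10^4 bootstrap resamples, context-score threshold -0.5, conservation
#' threshold PCT > 0.5, chi-square LRT with 3 df.
#'
#' @param synthetic run on generated data (TRUE) or on user files
#' @param synth a [synthetic_config()] (synthetic mode)
#' @param paths named list of input paths for non-synthetic mode:
#'   `mirna_expr`, `mirna_annot`, `mrna_expr`, `mrna_annot`, `targets`,
#'   `overexpression_fc`, `phase_counts`
#' @param out_dir output directory
#' @param fdr_mirna signature FDR (default 0.01)
#' @param fdr_targets target-calling FDR (default 0.05)
#' @param fold_cutoff_log2 target-calling fold cutoff (default -1)
#' @param n_resamples bootstrap resamples (default 10000)
#' @param context_threshold context-score cutoff (default -0.5)
#' @param pct_threshold conservation cutoff (default 0.5)
#' @param n_permutations surrogate-analysis permutations (default 1000)
#' @param alpha_sva surrogate significance level (default 0.05)
#' @param control_transfection negative-control label (default "NC")
#' @param seed integer seed driving every stochastic stage
#' @return a `PipelineConfig` list
#' @export
pipeline_config <- function(synthetic = TRUE,
                            synth = synthetic_config(),
                            paths = list(),
                            out_dir = tempfile("mirq_"),
                            fdr_mirna = 0.01,
                            fdr_targets = 0.05,
                            fold_cutoff_log2 = -1,
                            n_resamples = 10000L,
                            context_threshold = -0.5,
                            pct_threshold = 0.5,
                            n_permutations = 1000L,
                            alpha_sva = 0.05,
                            control_transfection = "NC",
                            seed = 1L) {
  cfg <- list(synthetic = synthetic, synth = synth, paths = paths,
              out_dir = out_dir, fdr_mirna = fdr_mirna,
              fdr_targets = fdr_targets,
              fold_cutoff_log2 = fold_cutoff_log2,
              n_resamples = n_resamples,
              context_threshold = context_threshold,
              pct_threshold = pct_threshold,
              n_permutations = n_permutations, alpha_sva = alpha_sva,
              control_transfection = control_transfection, seed = seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `PipelineConfig`
#' @return character vector of issues; empty iff the config is runnable
#' @export
validate_config <- function(cfg) {
  issues <- character(0)
  chk <- function(ok, msg) if (!ok) issues <<- c(issues, msg)
  chk(is.numeric(cfg$fdr_mirna) && cfg$fdr_mirna > 0 && cfg$fdr_mirna < 1,
      "fdr_mirna must lie in (0,1)")
  chk(is.numeric(cfg$fdr_targets) && cfg$fdr_targets > 0 &&
        cfg$fdr_targets < 1, "fdr_targets must lie in (0,1)")
  chk(cfg$n_resamples >= 1, "n_resamples must be >= 1")
  chk(cfg$n_permutations >= 1, "n_permutations must be >= 1")
  chk(cfg$alpha_sva > 0 && cfg$alpha_sva < 1,
      "alpha_sva must lie in (0,1)")
  chk(cfg$fold_cutoff_log2 <= 0, "fold_cutoff_log2 must be <= 0")
  chk(cfg$pct_threshold >= 0 && cfg$pct_threshold < 1,
      "pct_threshold must lie in [0,1)")
  chk(is.finite(cfg$context_threshold), "context_threshold must be finite")
  if (cfg$synthetic) {
    ok <- tryCatch({ validate_synthetic_config(cfg$synth); TRUE },
                   error = function(e) FALSE)
    chk(ok, "synth is not a valid synthetic configuration")
  } else {
    need <- c("mirna_expr", "mirna_annot", "mrna_expr", "mrna_annot",
              "targets", "overexpression_fc", "phase_counts")
    for (p in need)
      chk(!is.null(cfg$paths[[p]]), paste0("missing input path: ", p))
  }
  issues
}

#' Run the full pipeline
#'
#' @param cfg a [pipeline_config()]
#' @return (invisibly) the report list, also written as
#'   `report.json` in `cfg$out_dir` alongside every stage's TSV outputs
#' @export
run_pipeline <- function(cfg) {
  issues <- validate_config(cfg)
  if (length(issues))
    stop_domain("invalid config:\n  ", paste(issues, collapse = "\n  "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  truth <- NULL

  if (cfg$synthetic) {
    say("stage=synth generating inputs, seed=", cfg$synth$seed)
    mir <- gen_mirna_arrays(cfg$synth)
    tc <- gen_mrna_timecourse(cfg$synth)
    tp <- gen_target_predictions(cfg$synth, tc$truth)
    oe <- gen_overexpression_arrays(cfg$synth, tp$truth,
                                    names(tc$truth$gene_class))
    ph <- gen_phase_counts(cfg$synth)
    truth <- list(mirna = mir$truth, timecourse = tc$truth,
                  targets = tp$truth, overexpression = oe$truth,
                  phases = ph$truth)
    mirna_expr <- mir$expr; mirna_ann <- mir$annotations
    mrna_expr <- tc$expr; mrna_ann <- tc$annotations
    target_tab <- tp$table; fc <- oe$expr; phase_tab <- ph$counts
    write_expression_tsv(mirna_expr, out("mirna_expression.tsv"))
    write_annotation_tsv(mirna_ann, out("mirna_annotations.tsv"))
    write_expression_tsv(mrna_expr, out("mrna_timecourse.tsv"))
    write_annotation_tsv(mrna_ann, out("mrna_annotations.tsv"))
    write_target_table(target_tab, out("target_predictions.tsv"))
    write_expression_tsv(fc, out("overexpression_fc.tsv"))
    write_phase_counts(phase_tab, out("phase_counts.tsv"))
  } else {
    say("stage=input reading user files")
    mir <- read_expression_tsv(cfg$paths$mirna_expr, cfg$paths$mirna_annot)
    mirna_expr <- mir$expr; mirna_ann <- mir$annotations
    tc <- read_expression_tsv(cfg$paths$mrna_expr, cfg$paths$mrna_annot)
    mrna_expr <- tc$expr; mrna_ann <- tc$annotations
    target_tab <- read_target_table(cfg$paths$targets)
    fc <- read_expression_tsv(cfg$paths$overexpression_fc)$expr
    phase_tab <- read_phase_counts(cfg$paths$phase_counts)
  }

  say("stage=signature microRNA differential expression, FDR ",
      cfg$fdr_mirna)
  sig <- quiescence_signature(mirna_expr, mirna_ann, q = cfg$fdr_mirna,
                              n_permutations = cfg$n_permutations,
                              alpha_sva = cfg$alpha_sva,
                              seed = derive_seed(cfg$seed, 11L))
  utils::write.table(sig$table, out("mirna_signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("stage=eigengene SVD and proliferation index")
  complete <- filter_complete_genes(mrna_expr)
  dec <- compute_svd(complete)
  index <- proliferation_index(dec, complete)
  utils::write.table(
    data.frame(gene_id = names(index), proliferation_index = index),
    out("proliferation_index.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  clusters <- hierarchical_cluster(complete, 4L)
  utils::write.table(
    data.frame(gene_id = names(clusters), cluster = clusters),
    out("gene_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  say("stage=enrichment bootstrap over ", cfg$n_resamples, " resamples")
  volcano <- enrichment_volcano(target_tab, index,
                                n_resamples = cfg$n_resamples,
                                context_threshold = cfg$context_threshold,
                                seed = derive_seed(cfg$seed, 12L))
  utils::write.table(volcano, out("enrichment_volcano.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("stage=targets overexpression target calling, FDR ",
      cfg$fdr_targets)
  planted_family <- if (cfg$synthetic) cfg$synth$planted_family
                    else volcano$mirna_family[1]
  conserved <- well_conserved_targets(target_tab, planted_family,
                                      cfg$pct_threshold)
  calls <- call_targets(fc, conserved, fdr = cfg$fdr_targets,
                        fold_cutoff_log2 = cfg$fold_cutoff_log2)
  utils::write.table(calls, out("target_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("stage=phases Dirichlet LRT vs control '",
      cfg$control_transfection, "'")
  lrt <- phase_lrt_table(phase_tab, control = cfg$control_transfection)
  utils::write.table(lrt, out("phase_lrt.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- phase_summary(phase_tab)
  utils::write.table(summ, out("phase_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  recovery <- NULL
  if (cfg$synthetic) {
    planted <- names(truth$mirna$responsive_mirnas)
    called <- sig$table$feature_id[sig$table$significant]
    sens <- mean(planted %in% called)
    fdp <- if (length(called)) mean(!called %in% planted) else 0
    exp_targets <- calls$gene_id[calls$is_experimental_target]
    planted_rep <- intersect(truth$overexpression$repressed_genes,
                             conserved)
    recall <- if (length(planted_rep))
      mean(planted_rep %in% exp_targets) else NA_real_
    recovery <- list(
      signature_sensitivity = sens,
      signature_false_discovery_proportion = fdp,
      planted_family_rank = match(planted_family, volcano$mirna_family),
      eigengene_pattern_correlation =
        abs(stats::cor(dec$eigengenes[, 1], truth$timecourse$pattern)),
      target_recall = recall)
    say("recovery: sensitivity=", signif(sens, 3), " fdp=", signif(fdp, 3),
        " family_rank=", recovery$planted_family_rank,
        " target_recall=", signif(recall, 3))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("miRquiescence")),
    seed = cfg$seed,
    parameters = cfg[c("fdr_mirna", "fdr_targets", "fold_cutoff_log2",
                       "n_resamples", "context_threshold", "pct_threshold",
                       "n_permutations", "alpha_sva")],
    synthetic = cfg$synthetic,
    n_mirnas_tested = nrow(sig$table),
    n_mirnas_significant = sum(sig$table$significant),
    pearson_responses = sig$pearson,
    n_surrogates = sig$surrogates$n_significant,
    variance_explained_first_eigengene = variance_explained(dec, 1L),
    top_family = volcano$mirna_family[1],
    top_family_pvalue = volcano$pvalue[1],
    n_experimental_targets = sum(calls$is_experimental_target),
    phase_lrt = lrt,
    recovery = recovery,
    outputs = list.files(cfg$out_dir))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  writeLines(log_lines, out("run.log"))
  say("done: outputs in ", cfg$out_dir)
  invisible(report)
}
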