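# Published miR-29 target list shipped with the package.

#' Published experimentally determined miR-29 targets
#'
#' The 15 genes called as experimentally supported miR-29 targets in the
#' source study (repressed more than two-fold at 5% FDR upon miR-29
#' overexpression and carrying a predicted binding site), with their
#' reported mean log2 fold changes and functional annotations.  Function
#' labels `ECM` / `ECM?` mark (possible) extracellular-matrix genes.
#'
#' @return data.frame with columns `gene_id`, `log2_fc`, `annotation`
#' @export
mir29_experimental_targets <- function() {
  path <- system.file("extdata", "mir29_experimental_targets.tsv",
                      package = "miRquiescence", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(tab) <- c("gene_id", "log2_fc", "annotation")
  tab
}
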