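# Shared fixtures: small configurations and an independent Dirichlet
# sampler (kept separate from the package's internal one so simulation
# tests do not lean on the code under test).

small_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_mirnas = 100L, n_genes = 600L,
               target_set_sizes = rep(30L, 8L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

rdir_ref <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# tiny expression TSV on disk
write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

rand_expr <- function(nf, ns, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nf * ns), nf, ns,
              dimnames = list(sprintf("f%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  expression_matrix(m)
}
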