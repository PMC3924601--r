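# core_io: containers, TSV round trips, probe collapsing, stats utilities

test_that("expression TSV parsing flags missing cells and rejects bad headers", {
  p <- write_tsv_fixture(c("feature_id\ts1\ts2",
                           "f1\t1.5\tNA",
                           "f2\t2.25\t-3",
                           "f3\t0\t4"))
  got <- read_expression_tsv(p)
  expect_identical(dim(got$expr), c(3L, 2L))
  expect_identical(sum(is.na(got$expr)), 1L)
  expect_true(is.na(got$expr["f1", "s2"]))

  dup <- write_tsv_fixture(c("feature_id\ts1\ts1", "f1\t1\t2"))
  expect_error(read_expression_tsv(dup), "sample")
  dupf <- write_tsv_fixture(c("feature_id\ts1", "f1\t1", "f1\t2"))
  expect_error(read_expression_tsv(dupf), "feature")
})

test_that("write/read round trip is exact, and annotations align to columns", {
  set.seed(42)
  expr <- rand_expr(20, 5)
  expr[sample(length(expr), 7)] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(expr, path)
  back <- read_expression_tsv(path)$expr
  expect_identical(unclass(back), unclass(expr))

  ann <- data.frame(sample_id = rev(colnames(expr)),
                    condition = "proliferating", timepoint_h = NA_real_,
                    isolate = "iso1", replicate = 1L)
  apath <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, apath)
  got <- read_expression_tsv(path, apath)
  expect_identical(got$annotations$sample_id, colnames(expr))

  expect_error(read_expression_tsv(path, {
    bad <- ann[-1, ]
    bpath <- withr::local_tempfile(fileext = ".tsv")
    write_annotation_tsv(bad, bpath)
    bpath
  }), "missing samples")
})

test_that("target and phase-count tables round trip and validate", {
  tab <- data.frame(mirna_family = c("mir-a", "mir-a", "mir-b"),
                    gene_id = c("G1", "G2", "G1"),
                    pct = c(0.7, NA, 0.2),
                    context_score = c(-0.9, -0.3, -0.51))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_target_table(tab, path)
  back <- read_target_table(path)
  expect_equal(back$pct, tab$pct)
  expect_equal(back$context_score, tab$context_score)
  bad <- tab; bad$pct[1] <- 1.2
  expect_error(write_target_table(bad, path), "pct")
  expect_error(write_target_table(rbind(tab, tab[1, ]), path),
               "duplicated")

  cnt <- data.frame(timepoint_h = 20, transfection = "NC",
                    day_batch = c("d1", "d1"), replicate = 1:2,
                    g0g1 = c(50L, 60L), s = c(30L, 25L), g2m = c(20L, 15L))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_phase_counts(cnt, cpath)
  expect_equal(read_phase_counts(cpath), cnt)
  bad <- cnt; bad$s[1] <- -1L
  expect_error(write_phase_counts(bad, cpath), "non-negative")
})

test_that("probe collapsing averages per gene and applies the 80% detection rule", {
  vals <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3,
                 dimnames = list(c("p1", "p2", "p3"), c("a", "b")))
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("G", "G", "H"))
  out <- collapse_probes_to_genes(expression_matrix(vals), map, 0.5)
  expect_equal(out["G", "a"], 2)   # mean(1, 3)
  expect_equal(out["H", ], c(a = 5, b = 6))

  # probe seen in 7 of 10 arrays fails the >= 80% rule
  v <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("p1", "p2"), sprintf("s%d", 1:10)))
  v[1, 1:3] <- NA
  out <- collapse_probes_to_genes(
    expression_matrix(v),
    data.frame(probe_id = c("p1", "p2"), gene_id = c("A", "B")), 0.8)
  expect_identical(rownames(out), "B")
})

test_that("probe collapsing equals a brute-force group-by mean", {
  set.seed(7)
  for (rep in 1:5) {
    nf <- sample(5:20, 1)
    expr <- rand_expr(nf, 4, seed = rep)
    expr[sample(length(expr), round(length(expr) * 0.15))] <- NA
    genes <- sample(LETTERS[1:3], nf, replace = TRUE)
    map <- data.frame(probe_id = rownames(expr), gene_id = genes)
    out <- collapse_probes_to_genes(expr, map, 0.5)
    det <- rowMeans(!is.na(expr)) >= 0.5
    for (g in rownames(out)) {
      rows <- unclass(expr)[det & genes == g, , drop = FALSE]
      manual <- apply(rows, 2, function(x)
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
      expect_equal(unname(out[g, ]), unname(manual))
    }
  }
  expect_warning(
    empty <- collapse_probes_to_genes(rand_expr(2, 3),
                                      data.frame(probe_id = "zz",
                                                 gene_id = "G"),
                                      0.5),
    "no probes")
  expect_identical(nrow(empty), 0L)
})

test_that("one-sided t-test matches an independently coded t CDF", {
  expect_error(one_sided_t_test(c(-1, -1, -1)), "variance")
  expect_error(one_sided_t_test(2), "at least 2")

  r <- one_sided_t_test(c(-1, 1), "less")
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)

  x <- c(-2, -1, -3)
  r <- one_sided_t_test(x, "less")
  # oracle: t statistic from first principles + numeric integration of
  # the t density with nu = 2
  t_manual <- mean(x) / (sd(x) / sqrt(3))
  nu <- 2
  dens <- function(u) gamma((nu + 1) / 2) / (sqrt(nu * pi) * gamma(nu / 2)) *
    (1 + u^2 / nu)^(-(nu + 1) / 2)
  p_oracle <- integrate(dens, -Inf, t_manual, rel.tol = 1e-10)$value
  expect_equal(r$t, t_manual)
  expect_equal(r$p, p_oracle, tolerance = 1e-8)
  expect_equal(one_sided_t_test(x, "greater")$p, 1 - p_oracle,
               tolerance = 1e-8)
})

test_that("BH step-up matches the exhaustive rule and controls FDP", {
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  expect_false(any(bh_fdr(rep(1, 10), 0.5)$significant))
  expect_true(bh_fdr(0.004, 0.01)$significant)

  p <- c(0.01, 0.02, 0.03, 0.9)
  got <- bh_fdr(p, 0.05)
  # oracle: largest k with p_(k) <= q k/m, reject those
  o <- order(p); m <- length(p)
  ks <- which(p[o] <= 0.05 * seq_len(m) / m)
  k <- if (length(ks)) max(ks) else 0
  manual <- rep(FALSE, m); manual[o[seq_len(k)]] <- TRUE
  expect_identical(got$significant, manual)
  q_manual <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(got$qvalues, pmin(q_manual, 1))

  # discoveries monotone non-decreasing in q
  set.seed(3)
  pv <- runif(200)^2
  nd <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
               function(q) sum(bh_fdr(pv, q)$significant), numeric(1))
  expect_true(all(diff(nd) >= 0))

  # all-null FDP: mean realized FDP at q = 0.05 stays below 0.10
  set.seed(11)
  fdp <- replicate(100, {
    disc <- sum(bh_fdr(runif(1e4), 0.05)$significant)
    as.numeric(disc > 0)  # every discovery is false under the global null
  })
  expect_lt(mean(fdp), 0.10)
})

test_that("pearson_ci matches an independent Fisher-z computation", {
  x <- 1:10
  r <- pearson_ci(x, x)
  expect_equal(r$r, 1)
  expect_equal(r$lo, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)
  expect_error(pearson_ci(x, rep(2, 10)), "constant")

  set.seed(9)
  a <- rnorm(20); b <- 0.6 * a + rnorm(20)
  got <- pearson_ci(a, b, 0.95)
  r0 <- sum(scale(a) * scale(b)) / 19
  z <- 0.5 * log((1 + r0) / (1 - r0))
  half <- qnorm(0.975) / sqrt(17)
  expect_equal(got$r, r0)
  expect_equal(got$lo, tanh(z - half))
  expect_equal(got$hi, tanh(z + half))
})
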