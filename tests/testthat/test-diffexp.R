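# mirna_diffexp: normalization, design, OLS fit, F-test, surrogates,
# condition responses and the composed signature

test_that("total-intensity normalization scales to the mean column total", {
  raw <- matrix(c(10, 40, 50, 100, 50, 150), nrow = 3,
                dimnames = list(c("f1", "f2", "f3"), c("a", "b")))
  # totals (100, 300) -> scale factors (2, 2/3)
  out <- normalize_total_intensity(expression_matrix(raw))
  expect_equal(unclass(out), log2(raw %*% diag(c(2, 2 / 3))),
               ignore_attr = TRUE)
  expect_equal(colSums(2^unclass(out)), c(a = 200, b = 200))

  eq <- matrix(c(1, 3, 2, 2), 2, dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_equal(unclass(normalize_total_intensity(expression_matrix(eq))),
               log2(eq))
  one <- matrix(c(1, 7), 2, dimnames = list(c("f1", "f2"), "a"))
  expect_equal(unclass(normalize_total_intensity(expression_matrix(one))),
               log2(one))
  bad <- eq; bad[1, 1] <- -1
  expect_error(normalize_total_intensity(expression_matrix(bad)),
               "positive")
})

test_that("design matrix encodes quiescence, starvation and isolates", {
  g <- gen_mirna_arrays(small_cfg())
  X <- build_design(g$annotations)
  expect_identical(dim(X), c(9L, 5L))
  expect_identical(qr(X)$rank, 5L)
  ss <- g$annotations$condition == "serum_starved"
  ci <- g$annotations$condition == "contact_inhibited"
  expect_true(all(X[ss, "x_Q"] == 1) && all(X[ss, "x_S"] == 1))
  expect_true(all(X[ci, "x_Q"] == 1) && all(X[ci, "x_S"] == 0))
  expect_true(all(X[g$annotations$condition == "proliferating",
                    c("x_Q", "x_S")] == 0))
  ann <- g$annotations[g$annotations$condition != "serum_starved", ]
  expect_error(build_design(ann), "absent")
})

test_that("OLS equals the normal-equations oracle on random instances", {
  set.seed(21)
  for (case in 1:20) {
    n <- sample(7:12, 1)
    ann <- data.frame(
      sample_id = sprintf("s%02d", 1:n),
      condition = sample(c("proliferating", "serum_starved",
                           "contact_inhibited"), n, replace = TRUE),
      timepoint_h = NA_real_,
      isolate = sample(c("i1", "i2"), n, replace = TRUE),
      replicate = 1L)
    ok <- length(unique(ann$condition)) == 3 &&
      length(unique(ann$isolate)) == 2
    if (!ok) next
    X <- build_design(ann)
    if (qr(X)$rank < ncol(X) || n - ncol(X) < 1) next
    Y <- matrix(rnorm(50 * n), 50, n,
                dimnames = list(sprintf("f%02d", 1:50), ann$sample_id))
    fit <- fit_expression_model(expression_matrix(Y), X)
    oracle <- t(solve(t(X) %*% X, t(X) %*% t(Y)))
    expect_equal(unname(fit$coefficients), unname(oracle),
                 tolerance = 1e-10)
    # residuals orthogonal to every design column
    expect_lt(max(abs(fit$residuals %*% X)), 1e-8)
  }
})

test_that("constant features and missing values are handled", {
  g <- gen_mirna_arrays(small_cfg(n_mirnas = 10L))
  X <- build_design(g$annotations)
  Y <- unclass(g$expr)
  Y[1, ] <- 5
  Y[2, 3] <- NA
  expect_warning(fit <- fit_expression_model(expression_matrix(Y), X),
                 "skipped")
  expect_identical(fit$skipped, rownames(Y)[2])
  expect_equal(unname(fit$coefficients[rownames(Y)[1], -1]),
               rep(0, 4), tolerance = 1e-12)
})

test_that("F-test equals t^2 from lm() and the nested-RSS brute force", {
  g <- gen_mirna_arrays(small_cfg(seed = 31L, n_mirnas = 20L))
  X <- build_design(g$annotations)
  fit <- fit_expression_model(g$expr, X)
  ft <- quiescence_f_test(fit)
  for (i in c(1, 7, 20)) {
    y <- unclass(g$expr)[i, ]
    lmfit <- lm(y ~ X[, -1])
    tstat <- summary(lmfit)$coefficients["X[, -1]x_Q", "t value"]
    expect_equal(ft$F[i], tstat^2, tolerance = 1e-8)
    rss_full <- sum(residuals(lmfit)^2)
    rss_red <- sum(residuals(lm(y ~ X[, -c(1, 2)]))^2)
    expect_equal(ft$F[i],
                 (rss_red - rss_full) / (rss_full / fit$df),
                 tolerance = 1e-8)
  }
  # zero-residual feature is flagged with p = 0
  Y <- unclass(g$expr)
  Y[3, ] <- X %*% c(5, 2, 0, 0, 0)
  ft2 <- quiescence_f_test(fit_expression_model(expression_matrix(Y), X))
  expect_true(ft2$zero_residual[3])
  expect_identical(ft2$p[3], 0)
})

test_that("surrogate estimation recovers a planted batch and ignores noise", {
  cfg <- small_cfg(seed = 41L, surrogate_effect_sd = 2, noise_sd = 0.3)
  g <- gen_mirna_arrays(cfg)
  X <- build_design(g$annotations)
  sv <- estimate_surrogates(g$expr, X, n_permutations = 300, seed = 1)
  expect_identical(sv$n_significant, 1L)
  expect_gt(abs(cor(sv$vectors[, 1], g$truth$surrogate_vector)), 0.9)
  expect_equal(sum(sv$vectors[, 1]^2), 1)

  # no planted batch: most seeds report nothing
  nsig <- vapply(1:20, function(s) {
    h <- gen_mirna_arrays(small_cfg(seed = s, n_mirnas = 60L,
                                    surrogate_effect_sd = 0))
    estimate_surrogates(h$expr, X, n_permutations = 100,
                        seed = s)$n_significant
  }, integer(1))
  expect_gte(mean(nsig == 0L), 0.7)
})

test_that("condition responses reduce to coefficients without noise", {
  cfg <- small_cfg(seed = 51L, noise_sd = 1e-8, surrogate_effect_sd = 0)
  g <- gen_mirna_arrays(cfg)
  fit <- fit_expression_model(g$expr, build_design(g$annotations))
  resp <- condition_responses(fit, g$annotations)
  expect_equal(resp$ss_response,
               unname(g$truth$b_q + g$truth$b_s), tolerance = 1e-6)
  expect_equal(resp$ci_response, unname(g$truth$b_q), tolerance = 1e-6)

  # with noise: equals recomputation from the stored residuals
  g2 <- gen_mirna_arrays(small_cfg(seed = 52L))
  fit2 <- fit_expression_model(g2$expr, build_design(g2$annotations))
  resp2 <- condition_responses(fit2, g2$annotations)
  ss <- g2$annotations$condition == "serum_starved"
  manual <- fit2$coefficients[, "x_Q"] + fit2$coefficients[, "x_S"] +
    rowMeans(fit2$residuals[, ss])
  expect_equal(resp2$ss_response, unname(manual))
})

test_that("signature controls FDR, is concordant, and is powered at low noise", {
  # realized FDR stays below 2q across seeds at the stated parameters
  fdp <- numeric(0); concord <- numeric(0)
  for (s in 1:8) {
    cfg <- small_cfg(seed = s, frac_quiescence_responsive = 0.5,
                     effect_size_log2 = 1.5, noise_sd = 0.3)
    g <- gen_mirna_arrays(cfg)
    sig <- quiescence_signature(g$expr, g$annotations, q = 0.05,
                                n_permutations = 100, seed = s)
    called <- sig$table$feature_id[sig$table$significant]
    if (length(called))
      fdp <- c(fdp, mean(!called %in% names(g$truth$responsive_mirnas)))
  }
  expect_lt(mean(c(fdp, 0)), 0.10)

  # at array-replicate noise (sd 0.1) the signature recovers the planted set
  cfg <- small_cfg(seed = 71L, frac_quiescence_responsive = 0.5,
                   effect_size_log2 = 1.5, noise_sd = 0.1)
  g <- gen_mirna_arrays(cfg)
  sig <- quiescence_signature(g$expr, g$annotations, q = 0.01,
                              n_permutations = 200, seed = 2)
  planted <- names(g$truth$responsive_mirnas)
  called <- sig$table$feature_id[sig$table$significant]
  expect_gte(mean(planted %in% called), 0.9)
  # shared B_Q dominates both responses: SS and CI responses concordant
  expect_gt(sig$pearson$r, 0.9)
  expect_true(sig$pearson$lo < sig$pearson$r &&
                sig$pearson$r < sig$pearson$hi)
  # table ordered by |mean response|
  mm <- abs((sig$table$ss_response + sig$table$ci_response) / 2)
  expect_true(all(diff(mm) <= 1e-12))

  # extreme stringency yields (near) zero discoveries
  weak <- gen_mirna_arrays(small_cfg(seed = 72L, effect_size_log2 = 0.2,
                                     noise_sd = 0.3))
  strict <- quiescence_signature(weak$expr, weak$annotations, q = 1e-9,
                                 n_permutations = 50, seed = 3)
  expect_lte(sum(strict$table$significant), 1)
})
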