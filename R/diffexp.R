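# MicroRNA differential expression under quiescence.
#
# Per-feature linear model on log2 one-channel intensities:
#   Y = m + B_Q x_Q + B_S x_S + isolate offsets + B_SVA x_SVA + E
# x_Q marks both quiescence conditions (serum starvation and contact
# inhibition), x_S serum starvation only, so B_Q is the shared
# quiescence response and B_S the starvation-specific extra.  A
# surrogate variable estimated from the residuals absorbs hidden batch
# structure.  Differential expression is an F-test on the x_Q term,
# controlled at an FDR by Benjamini-Hochberg.

#' Total-intensity normalization
#'
#' Scales each array so its linear-scale total equals the mean of all
#' array totals, then log2-transforms.
#'
#' @param raw linear-scale intensity matrix, all entries > 0
#' @return log2 ExpressionMatrix
#' @export
normalize_total_intensity <- function(raw) {
  v <- unclass(raw)
  if (any(is.na(v)) || any(v <= 0))
    stop_domain("total-intensity normalization needs positive intensities")
  totals <- colSums(v)
  target <- mean(totals)
  expression_matrix(log2(sweep(v, 2, target / totals, `*`)))
}

#' Build the quiescence design matrix
#'
#' Columns: intercept, `x_Q` (1 for serum-starved and contact-inhibited
#' samples), `x_S` (1 for serum-starved only), and one indicator per
#' non-reference isolate (reference = lexicographically first isolate).
#'
#' @param annotations sample annotation data.frame (one row per array,
#'   in array order)
#' @return numeric design matrix with rownames = sample ids
#' @export
build_design <- function(annotations) {
  cond <- annotations$condition
  isolates <- sort(unique(annotations$isolate))
  if (length(isolates) < 2) stop_domain("need >= 2 isolates")
  for (cc in c("proliferating", "serum_starved", "contact_inhibited"))
    if (!any(cond == cc)) stop_domain("condition absent from design: ", cc)
  X <- cbind(intercept = 1,
             x_Q = as.numeric(cond %in% c("serum_starved",
                                          "contact_inhibited")),
             x_S = as.numeric(cond == "serum_starved"))
  for (iso in isolates[-1])
    X <- cbind(X, as.numeric(annotations$isolate == iso))
  colnames(X) <- c("intercept", "x_Q", "x_S",
                   paste0("x_", isolates[-1]))
  rownames(X) <- annotations$sample_id
  if (qr(X)$rank < ncol(X)) stop_domain("design matrix is rank deficient")
  X
}

#' Fit the per-feature expression model by ordinary least squares
#'
#' One QR decomposition of the design serves all features.  Features
#' containing missing values are skipped with a warning.
#'
#' @param expr log2 expression matrix (features x samples)
#' @param design design matrix from [build_design()], optionally
#'   augmented with surrogate columns
#' @return a `RegressionFit`: list with `coefficients` (features x
#'   terms), `residuals` (features x samples), `df` (residual degrees of
#'   freedom), `design`, and `skipped` feature ids
#' @export
fit_expression_model <- function(expr, design) {
  Y <- unclass(expr)
  if (qr(design)$rank < ncol(design))
    stop_domain("design matrix is rank deficient")
  n <- ncol(Y); p <- ncol(design)
  if (n - p <= 0) stop_domain("no residual degrees of freedom")
  complete <- rowSums(is.na(Y)) == 0L
  if (any(!complete))
    warning(sum(!complete), " features with missing values skipped")
  Yc <- Y[complete, , drop = FALSE]
  qrX <- qr(design)
  coefs <- t(qr.coef(qrX, t(Yc)))
  resid <- t(qr.resid(qrX, t(Yc)))
  colnames(coefs) <- colnames(design)
  structure(list(coefficients = coefs, residuals = resid,
                 df = n - p, design = design,
                 skipped = rownames(Y)[!complete]),
            class = "RegressionFit")
}

#' Estimate surrogate variables from model residuals
#'
#' Fits the primary model, decomposes the residual matrix by SVD, and
#' scores each residual eigenvector's variance fraction against a null
#' obtained by permuting residuals independently within each feature and
#' re-projecting out the design (parallel-analysis style).  Eigenvectors
#' forming a leading run with permutation p < `alpha` are returned as
#' unit-norm surrogate columns.
#'
#' @param expr log2 expression matrix (complete features are used)
#' @param design primary design matrix
#' @param n_permutations permutation rounds (default 1000)
#' @param alpha per-candidate significance level (default 0.05)
#' @param seed optional RNG seed for the permutations
#' @return list with `vectors` (samples x n_significant matrix),
#'   `permutation_pvalues`, `n_significant`
#' @export
estimate_surrogates <- function(expr, design, n_permutations = 1000,
                                alpha = 0.05, seed = NULL) {
  fit <- suppressWarnings(fit_expression_model(expr, design))
  R <- fit$residuals
  k <- min(dim(R)) - 0L
  n_cand <- ncol(R) - ncol(design)          # residual rank
  if (n_cand < 1)
    return(list(vectors = matrix(numeric(0), nrow = ncol(R), ncol = 0),
                permutation_pvalues = numeric(0), n_significant = 0L))
  frac_of <- function(M) { d2 <- svd(M, nu = 0, nv = 0)$d^2; d2 / sum(d2) }
  obs <- frac_of(R)[seq_len(n_cand)]
  qrX <- qr(design)
  with_seed(seed, {
    exceed <- integer(n_cand)
    for (b in seq_len(n_permutations)) {
      Rp <- t(apply(R, 1, sample))
      Rp <- t(qr.resid(qrX, t(Rp)))
      fp <- frac_of(Rp)[seq_len(n_cand)]
      exceed <- exceed + as.integer(fp >= obs)
    }
    pvals <- (exceed + 1) / (n_permutations + 1)
    sig <- pvals < alpha
    n_sig <- if (sig[1]) which.min(c(sig, FALSE)) - 1L else 0L
    v <- svd(R)$v[, seq_len(n_sig), drop = FALSE]
    rownames(v) <- colnames(R)
    if (n_sig > 0) colnames(v) <- paste0("x_SVA", seq_len(n_sig))
    list(vectors = v, permutation_pvalues = pvals, n_significant = n_sig)
  })
}

#' F-test for the quiescence term
#'
#' Nested-model F comparing the fitted model to the same model with
#' `x_Q` removed; p from F(1, residual df).  Features with (numerically)
#' zero residual variance are reported with p = 0 and flagged.
#'
#' @param fit a `RegressionFit`
#' @return data.frame with `feature_id`, `F`, `p`, `zero_residual`
#' @export
quiescence_f_test <- function(fit) {
  design <- fit$design
  if (!"x_Q" %in% colnames(design)) stop_domain("design lacks x_Q")
  reduced <- design[, colnames(design) != "x_Q", drop = FALSE]
  Y_hat_plus_E <- fit$coefficients %*% t(design) + fit$residuals
  qrR <- qr(reduced)
  rss_r <- rowSums(t(qr.resid(qrR, t(Y_hat_plus_E)))^2)
  rss_f <- rowSums(fit$residuals^2)
  zero <- rss_f < 1e-12 * pmax(rss_r, 1)
  Fstat <- (rss_r - rss_f) / (rss_f / fit$df)
  p <- stats::pf(Fstat, 1, fit$df, lower.tail = FALSE)
  Fstat[zero] <- Inf
  p[zero] <- 0
  data.frame(feature_id = rownames(fit$coefficients), F = Fstat, p = p,
             zero_residual = zero, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Reconstruct per-condition responses
#'
#' The overall biological response of each feature is the fitted
#' condition coefficient(s) plus the mean residual over that condition's
#' arrays: `ss_response = B_Q + B_S + mean(E | serum-starved)` and
#' `ci_response = B_Q + mean(E | contact-inhibited)`.
#'
#' @param fit a `RegressionFit`
#' @param annotations sample annotations aligned with the fitted arrays
#' @return data.frame with `feature_id`, `ss_response`, `ci_response`
#' @export
condition_responses <- function(fit, annotations) {
  stopifnot(identical(annotations$sample_id, colnames(fit$residuals)))
  ss <- annotations$condition == "serum_starved"
  ci <- annotations$condition == "contact_inhibited"
  bQ <- fit$coefficients[, "x_Q"]
  bS <- fit$coefficients[, "x_S"]
  data.frame(feature_id = rownames(fit$coefficients),
             ss_response = bQ + bS + rowMeans(fit$residuals[, ss,
                                                            drop = FALSE]),
             ci_response = bQ + rowMeans(fit$residuals[, ci, drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full microRNA quiescence signature
#'
#' Composes the stage: (optional total-intensity normalization) ->
#' design -> surrogate estimation -> per-feature OLS -> F-test on x_Q ->
#' BH at `q` -> condition responses -> Pearson CI between the
#' serum-starvation and contact-inhibition responses of the significant
#' features.  The table is ordered by decreasing |mean log2 change|.
#'
#' @param expr expression matrix; log2 by default, linear scale if
#'   `normalize = TRUE`
#' @param annotations sample annotation data.frame
#' @param q FDR level (default 0.01)
#' @param normalize apply [normalize_total_intensity()] first
#' @param n_permutations,alpha_sva surrogate-estimation controls
#' @param seed optional RNG seed for the surrogate permutations
#' @return list with `table` (feature, responses, F, p, qvalue,
#'   significant), `pearson` (r, lo, hi over the significant set, or
#'   NULL if < 4 significant), `surrogates`, `fit`
#' @export
quiescence_signature <- function(expr, annotations, q = 0.01,
                                 normalize = FALSE,
                                 n_permutations = 1000, alpha_sva = 0.05,
                                 seed = NULL) {
  if (normalize) expr <- normalize_total_intensity(expr)
  X <- build_design(annotations)
  sv <- estimate_surrogates(expr, X, n_permutations = n_permutations,
                            alpha = alpha_sva, seed = seed)
  Xa <- if (sv$n_significant > 0) cbind(X, sv$vectors) else X
  fit <- suppressWarnings(fit_expression_model(expr, Xa))
  ft <- quiescence_f_test(fit)
  fdr <- bh_fdr(ft$p, q)
  resp <- condition_responses(fit, annotations)
  tab <- data.frame(feature_id = ft$feature_id,
                    ss_response = resp$ss_response,
                    ci_response = resp$ci_response,
                    F = ft$F, p = ft$p, qvalue = fdr$qvalues,
                    significant = fdr$significant,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs((tab$ss_response + tab$ci_response) / 2)), ]
  rownames(tab) <- NULL
  pe <- NULL
  sig <- tab[tab$significant, ]
  if (nrow(sig) >= 4 &&
      stats::sd(sig$ss_response) > 0 && stats::sd(sig$ci_response) > 0)
    pe <- pearson_ci(sig$ss_response, sig$ci_response)
  list(table = tab, pearson = pe, surrogates = sv, fit = fit)
}
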