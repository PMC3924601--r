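# Dirichlet modelling of cell-cycle phase compositions.
#
# Replicate (G0/G1, S, G2/M) proportions are modelled as Dirichlet with
# concentration alpha = s * m (precision s > 0, mean m on the simplex).
# The MLE alternates exact coordinate maximisations: the mean step
# solves psi(s m_k) = log pbar_k + c on the simplex (c chosen so the
# m_k sum to one), the precision step is a Newton ascent in log s on the
# profile likelihood.  Both steps only ever increase the likelihood, so
# the recorded log-likelihood trace is non-decreasing.  Transfection
# groups are compared with a likelihood-ratio test on chi-square with 3
# degrees of freedom (the alternative fits two three-parameter
# Dirichlets instead of one).

#' Convert phase counts to open-simplex proportions
#'
#' `(count + pseudocount) / (total + 3 * pseudocount)` per replicate;
#' the default pseudocount 0.5 keeps zero counts off the simplex
#' boundary, where the Dirichlet density is undefined.
#'
#' @param counts phase count data.frame (see [read_phase_counts()])
#' @param pseudocount non-negative value added to each phase count
#' @return matrix of simplex triples (rows = replicates), with the key
#'   columns attached as attribute `key`
#' @export
counts_to_proportions <- function(counts, pseudocount = 0.5) {
  validate_phase_counts(counts)
  stopifnot(pseudocount >= 0)
  cnt <- as.matrix(counts[phase_labels])
  tot <- rowSums(cnt)
  if (any(tot == 0)) stop_domain("replicate with zero total count")
  props <- (cnt + pseudocount) / (tot + 3 * pseudocount)
  attr(props, "key") <- counts[c("timepoint_h", "transfection",
                                 "day_batch", "replicate")]
  props
}

#' Dirichlet log-likelihood
#'
#' Sum over replicates of
#' `log Gamma(sum a) - sum log Gamma(a_k) + sum (a_k - 1) log p_k`.
#'
#' @param alpha positive concentration vector
#' @param props matrix of simplex rows (or a single simplex vector)
#' @return total log density
#' @export
dirichlet_loglik <- function(alpha, props) {
  if (is.vector(props)) props <- matrix(props, nrow = 1)
  if (any(alpha <= 0)) stop_domain("alpha must be strictly positive")
  if (any(props <= 0) || any(props >= 1))
    stop_domain("proportions must lie in the open simplex")
  n <- nrow(props)
  n * (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum((alpha - 1) * colSums(log(props)))
}

# exact mean-coordinate maximisation at fixed precision s:
# find c with sum_k invpsi(log pbar_k + c) = s, return m
mean_step <- function(s, logpbar) {
  f <- function(c) sum(inv_digamma(logpbar + c)) - s
  lo <- digamma(s / length(logpbar)) - max(logpbar)   # f(lo) <= 0
  hi <- digamma(s) - min(logpbar)                     # f(hi) >= 0
  c <- stats::uniroot(f, c(lo - 1, hi + 1), tol = 1e-12)$root
  a <- inv_digamma(logpbar + c)
  a / sum(a)
}

# Newton ascent in log s on the profile likelihood at fixed mean m
precision_step <- function(s, m, logpbar, n) {
  ll <- function(s) n * (lgamma(s) - sum(lgamma(s * m))) +
    s * sum(m * logpbar) * n
  for (it in 1:100) {
    g <- n * (digamma(s) - sum(m * digamma(s * m)) + sum(m * logpbar))
    h <- n * (trigamma(s) - sum(m^2 * trigamma(s * m)))
    # Newton in log-space keeps s positive; g,h wrt log s:
    gl <- g * s
    hl <- h * s^2 + g * s
    step <- if (hl < 0) -gl / hl else sign(gl)
    base <- ll(s)
    while (abs(step) > 1e-14 && ll(s * exp(step)) < base) step <- step / 2
    s_new <- min(s * exp(step), 1e8)   # cap: near-degenerate data push s -> Inf
    if (abs(step) < 1e-12 || s_new >= 1e8) return(s_new)
    s <- s_new
  }
  s
}

#' Maximum-likelihood Dirichlet fit by alternating mean/precision steps
#'
#' Initialised by the method of moments, then alternates the exact mean
#' update (at fixed precision) and a Newton precision update (at fixed
#' mean) until the log-likelihood improves by less than `tol`.
#'
#' @param props matrix of open-simplex rows, >= 2 replicates
#' @param tol convergence tolerance on the log-likelihood (default 1e-10)
#' @param max_iter iteration cap (default 10000)
#' @return a `DirichletFit`: list with `alpha`, `mean`, `precision`,
#'   `loglik`, `loglik_trace`, `n_iterations`, `converged`
#' @export
dirichlet_mle <- function(props, tol = 1e-10, max_iter = 10000L) {
  if (is.vector(props)) props <- matrix(props, nrow = 1)
  if (nrow(props) < 2) stop_domain("need >= 2 replicates")
  if (any(props <= 0) || any(props >= 1))
    stop_domain("proportions must lie in the open simplex")
  n <- nrow(props)
  logpbar <- colMeans(log(props))

  # method-of-moments initialiser
  m <- colMeans(props)
  v <- apply(props, 2, stats::var)
  s_hat <- m * (1 - m) / pmax(v, 1e-12) - 1
  s <- max(mean(s_hat[is.finite(s_hat) & s_hat > 0]), 1e-3)
  if (!is.finite(s)) s <- 1

  ll <- dirichlet_loglik(s * m, props)
  trace <- ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    m_new <- mean_step(s, logpbar)
    ll_m <- dirichlet_loglik(s * m_new, props)
    if (ll_m >= ll) { m <- m_new; ll <- ll_m }      # ascent safeguard
    s_new <- precision_step(s, m, logpbar, n)
    ll_s <- dirichlet_loglik(s_new * m, props)
    if (ll_s >= ll) { s <- s_new; ll <- ll_s }
    trace <- c(trace, ll)
    if (ll - trace[length(trace) - 1L] < tol &&
        it > 1L) { converged <- TRUE; break }
  }
  alpha <- s * m
  names(alpha) <- colnames(props) %||% paste0("a", seq_along(alpha))
  structure(list(alpha = alpha, mean = m, precision = s, loglik = ll,
                 loglik_trace = trace, n_iterations = it,
                 converged = converged),
            class = "DirichletFit")
}

#' Likelihood-ratio test for two transfection groups
#'
#' Null: both groups share one Dirichlet (fit on the pooled
#' replicates).  Alternative: one Dirichlet per group.  The statistic
#' `D = -2 logL(H0) + 2 logL(Ha)` is referred to chi-square with 3
#' degrees of freedom (two three-parameter fits versus one).  Tiny
#' negative D from numerics is clipped to 0 and flagged.
#'
#' @param props_a,props_b matrices of open-simplex replicate rows
#'   (>= 2 rows each)
#' @return an `LrtResult`: list with `D`, `df`, `pvalue`, `fit_null`,
#'   `fit_a`, `fit_b`, `clipped`
#' @export
lrt_two_groups <- function(props_a, props_b) {
  if (is.vector(props_a)) props_a <- matrix(props_a, nrow = 1)
  if (is.vector(props_b)) props_b <- matrix(props_b, nrow = 1)
  if (nrow(props_a) < 2 || nrow(props_b) < 2)
    stop_domain("each group needs >= 2 replicates")
  fit0 <- dirichlet_mle(rbind(props_a, props_b))
  fita <- dirichlet_mle(props_a)
  fitb <- dirichlet_mle(props_b)
  D <- -2 * fit0$loglik + 2 * (fita$loglik + fitb$loglik)
  clipped <- D < 0
  if (clipped) {
    if (D < -1e-6) warning("negative LRT statistic beyond tolerance: ", D)
    D <- 0
  }
  structure(list(D = D, df = 3L,
                 pvalue = stats::pchisq(D, df = 3, lower.tail = FALSE),
                 fit_null = fit0, fit_a = fita, fit_b = fitb,
                 clipped = clipped),
            class = "LrtResult")
}

#' Run the LRT per timepoint against a control transfection
#'
#' @param counts phase count data.frame
#' @param control transfection label of the negative control
#' @param pseudocount passed to [counts_to_proportions()]
#' @return data.frame with one row per (timepoint, transfection) pair:
#'   `D`, `df`, `pvalue` and fitted alphas
#' @export
phase_lrt_table <- function(counts, control = "NC", pseudocount = 0.5) {
  props <- counts_to_proportions(counts, pseudocount)
  key <- attr(props, "key")
  if (!control %in% key$transfection)
    stop_domain("control transfection absent: ", control)
  others <- setdiff(unique(key$transfection), control)
  rows <- list()
  for (tp in sort(unique(key$timepoint_h))) {
    ctrl <- props[key$timepoint_h == tp & key$transfection == control, ,
                  drop = FALSE]
    for (tr in others) {
      grp <- props[key$timepoint_h == tp & key$transfection == tr, ,
                   drop = FALSE]
      if (nrow(grp) < 2 || nrow(ctrl) < 2) next
      res <- lrt_two_groups(ctrl, grp)
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint_h = tp, transfection = tr, D = res$D, df = res$df,
        pvalue = res$pvalue,
        alpha_control = paste(signif(res$fit_a$alpha, 6), collapse = ","),
        alpha_treated = paste(signif(res$fit_b$alpha, 6), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Phase percentage summary with the residual-sum-of-squares error rule
#'
#' Per (timepoint, transfection) and phase: the mean percentage over all
#' replicates, and a spread computed as the square root of the total sum
#' of squared residuals from each day's mean percentage (`se_method =
#' "rss"`, the default rule).  `se_method = "sem"` instead returns a
#' conventional standard error of the mean across all replicates.
#'
#' @param counts phase count data.frame
#' @param se_method `"rss"` or `"sem"`
#' @return data.frame with mean and se columns per phase
#' @export
phase_summary <- function(counts, se_method = c("rss", "sem")) {
  se_method <- match.arg(se_method)
  validate_phase_counts(counts)
  cnt <- as.matrix(counts[phase_labels])
  pct <- 100 * cnt / rowSums(cnt)
  groups <- split(seq_len(nrow(counts)),
                  list(counts$timepoint_h, counts$transfection),
                  drop = TRUE)
  rows <- lapply(groups, function(idx) {
    if (length(idx) == 1L)
      warning("single replicate in a group; se reported as 0")
    sub <- pct[idx, , drop = FALSE]
    days <- counts$day_batch[idx]
    se <- vapply(seq_along(phase_labels), function(k) {
      rss <- sum(unlist(lapply(split(sub[, k], days),
                               function(x) (x - mean(x))^2)))
      if (se_method == "rss") sqrt(rss)
      else sqrt(rss / max(1, length(idx) - length(unique(days)))) /
        sqrt(length(idx))
    }, numeric(1))
    out <- data.frame(timepoint_h = counts$timepoint_h[idx[1]],
                      transfection = counts$transfection[idx[1]],
                      stringsAsFactors = FALSE)
    for (k in seq_along(phase_labels)) {
      out[[paste0("mean_", phase_labels[k])]] <- mean(sub[, k])
      out[[paste0("se_", phase_labels[k])]] <- se[k]
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$timepoint_h, out$transfection), ]
  rownames(out) <- NULL
  out
}
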