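# Mini-bulk differential abundance: replicate-eligibility filtering,
# empirical-Bayes moderated two-sample t-statistics (variance shrinkage via
# moment matching of log sample variances), Storey q-values, significance
# calls, and the log10 PCA overview.

#' Replicate-eligibility filter for a two-group contrast
#'
#' A protein is eligible when it is detected (nonzero) in at least
#' `min_reps` runs of *both* groups; proteins detected in fewer replicates
#' in either condition are excluded from testing and from multiplicity
#' correction.
#'
#' @param matrix An [intensity_matrix] or `normalized_matrix`.
#' @param group_a,group_b Group labels (must exist in the run annotations).
#' @param min_reps Minimum detected replicates per group (default 2).
#' @return Named logical vector per protein.
#' @export
filter_by_replication <- function(matrix, group_a, group_b, min_reps = 2L) {
  g <- matrix$runs$group
  if (!group_a %in% g || !group_b %in% g)
    stop("group label(s) absent from run annotations: ",
         paste(setdiff(c(group_a, group_b), g), collapse = ", "))
  in_a <- matrix$values[, g == group_a, drop = FALSE] > 0
  in_b <- matrix$values[, g == group_b, drop = FALSE] > 0
  rowSums(in_a) >= min_reps & rowSums(in_b) >= min_reps
}

# Newton inversion of the trigamma function (solves trigamma(x) = y).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Moment-matched prior (d0, s0^2) for variance shrinkage: matches mean and
# variance of log(s^2) against the scaled-chi-square model via
# digamma/trigamma identities.
estimate_variance_prior <- function(s2, df) {
  ok <- df > 0 & is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    if (length(s2) >= 2 && all(s2[df > 0] == 0))
      return(list(d0 = Inf, s0_sq = 0))    # noiseless data: no variance at all
    stop("fewer than 2 proteins with residual variance; cannot estimate prior",
         " (consider an ordinary t-test)")
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df[ok] / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-protein two-sample comparison on log-transformed values with the
#' residual variance shrunk toward a moment-matched prior:
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`,
#' `t = (mean_a - mean_b) / (s_post * sqrt(1/n_a + 1/n_b))`, two-sided
#' p-values on `df + d0` degrees of freedom. Zeros (undetected) are treated
#' as missing: each protein is tested on its observed values with adjusted
#' degrees of freedom.
#'
#' @param matrix A `normalized_matrix` (or [intensity_matrix]).
#' @param group_a,group_b Group labels; positive `log_fc` means higher in
#'   `group_a`.
#' @param eligible Optional logical per-protein filter (e.g. from
#'   [filter_by_replication()]); ineligible proteins carry no statistics.
#' @param log_base Log transform applied to detected values before testing
#'   (default 2; use `NULL` when values are already log-scale).
#' @param d0 Force the prior degrees of freedom: `0` reproduces the ordinary
#'   pooled-variance t; `Inf` scales every protein by `s0`.
#' @return Data frame of class `differential_result`: `protein_id`,
#'   `log_fc`, `s2`, `df_resid`, `t_mod`, `df_total`, `p`, `q` (NA until
#'   [estimate_qvalues()] is applied via [call_significant()] or directly),
#'   `eligible`; the prior is attached as attribute `prior`.
#' @export
moderated_t_test <- function(matrix, group_a, group_b, eligible = NULL,
                             log_base = 2, d0 = NULL) {
  g <- matrix$runs$group
  if (!group_a %in% g || !group_b %in% g)
    stop("group label(s) absent: ",
         paste(setdiff(c(group_a, group_b), g), collapse = ", "))
  vals <- matrix$values
  if (is.null(eligible))
    eligible <- filter_by_replication(matrix, group_a, group_b)
  x <- vals
  x[x == 0] <- NA
  if (!is.null(log_base)) x <- log(x, base = log_base)
  a <- x[, g == group_a, drop = FALSE]
  b <- x[, g == group_b, drop = FALSE]
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  mean_a <- rowMeans(a, na.rm = TRUE); mean_b <- rowMeans(b, na.rm = TRUE)
  ssq <- function(m, mu) rowSums((m - mu)^2, na.rm = TRUE)
  df_resid <- na + nb - 2
  s2 <- (ssq(a, mean_a) + ssq(b, mean_b)) / pmax(df_resid, 1)
  use <- eligible & na >= 2 & nb >= 2
  prior <- if (is.null(d0)) {
    estimate_variance_prior(s2[use], df_resid[use])
  } else {
    s0 <- estimate_variance_prior(s2[use], df_resid[use])$s0_sq
    list(d0 = d0, s0_sq = s0)
  }
  log_fc <- mean_a - mean_b
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(s2))
             else (prior$d0 * prior$s0_sq + df_resid * s2) / (prior$d0 + df_resid)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log_fc / se,
                  ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
  df_total <- df_resid + prior$d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(protein_id = rownames(vals),
                    log_fc = log_fc, s2 = s2, df_resid = df_resid,
                    t_mod = t_mod, df_total = df_total, p = p,
                    q = NA_real_, eligible = use,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[!use, c("log_fc", "s2", "t_mod", "df_total", "p")] <- NA_real_
  attr(out, "prior") <- prior
  attr(out, "contrast") <- c(group_a, group_b)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Storey q-values
#'
#' `q_i = pi0 * min_{p_j >= p_i} (m * p_j / rank_j)`, with the null
#' proportion `pi0` estimated by the smoother method: `pi0(lambda) =
#' mean(p > lambda) / (1 - lambda)` over `lambda = 0.05 ... 0.95`, a natural
#' cubic smoothing spline evaluated at `lambda = 0.95`, floored at 0 and
#' capped at 1. For fewer than 100 p-values the estimate is unstable and
#' `pi0 = 1` is used (Benjamini-Hochberg). `method = "bh"` forces `pi0 = 1`.
#'
#' @param pvalues Numeric vector in [0, 1] (NA allowed, propagated).
#' @param method `"storey"` (default) or `"bh"`.
#' @param pi0 Optional override of the null proportion.
#' @return Numeric q-values, monotone non-decreasing in p, with attributes
#'   `pi0` and `method`.
#' @export
estimate_qvalues <- function(pvalues, method = c("storey", "bh"), pi0 = NULL) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (length(p) && (min(p) < 0 || max(p) > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) {
    if (method == "bh" || length(p) < 100) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = 0.95)$y
      pi0 <- min(max(pi0, 0), 1)
      if (pi0 <= 0) pi0 <- .Machine$double.eps
    }
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q_sorted <- cummin(m * p[o] / rank(p, ties.method = "max")[o])
  q <- numeric(m)
  q[o] <- pmin(pi0 * q_sorted, 1)
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  attr(out, "method") <- method
  out
}

#' Call significantly changed proteins
#'
#' Fills in q-values for the eligible proteins of a `differential_result`
#' and calls significance by strict inequality `q < q_cut` (default 0.05).
#'
#' @param result A `differential_result` from [moderated_t_test()].
#' @param q_cut Q-value cutoff.
#' @param method Passed to [estimate_qvalues()].
#' @return The result with `q` filled and a logical `significant` column.
#' @export
call_significant <- function(result, q_cut = 0.05, method = "storey") {
  result$q <- estimate_qvalues(result$p, method = method)
  result$significant <- !is.na(result$q) & result$q < q_cut
  result
}

#' PCA overview of a normalized matrix
#'
#' Restricts to proteins identified in all runs (complete cases), log10
#' transforms, centers each protein, and eigendecomposes exactly. Returns
#' per-run scores, explained-variance fractions and the top-k loading
#' proteins per component.
#'
#' @param normalized A `normalized_matrix`.
#' @param n_components Number of components to return (default 5, capped).
#' @param top_k Loading proteins reported per component (default 25).
#' @return List: `scores` (runs x components), `explained` (fractions),
#'   `loadings`, `top_loadings` (list of data frames), `proteins_used`.
#' @export
pca_overview <- function(normalized, n_components = 5L, top_k = 25L) {
  if (ncol(normalized$values) < 2) stop("need >= 2 runs for PCA")
  complete <- rowSums(normalized$values > 0) == ncol(normalized$values)
  if (sum(complete) < 2)
    stop("fewer than 2 proteins identified in all runs")
  x <- log10(normalized$values[complete, , drop = FALSE])
  x <- x - rowMeans(x)                       # per-protein centering
  n_components <- min(n_components, ncol(x) - 1L, nrow(x))
  # exact eigendecomposition of the run x run Gram matrix of the centered
  # data: scores = U * singular values, loadings = X U / singular values
  eig <- eigen(crossprod(x), symmetric = TRUE)
  pos <- pmax(eig$values, 0)
  total <- sum(pos)
  u <- eig$vectors[, seq_len(n_components), drop = FALSE]
  d <- sqrt(pos[seq_len(n_components)])
  scores <- u * rep(d, each = ncol(x))
  load <- x %*% u
  denom <- ifelse(d > 0, d, 1)
  load <- sweep(load, 2, denom, "/")
  dimnames(scores) <- list(colnames(normalized$values),
                           paste0("PC", seq_len(n_components)))
  colnames(load) <- colnames(scores)
  top <- lapply(seq_len(n_components), function(k) {
    o <- order(abs(load[, k]), decreasing = TRUE)[seq_len(min(top_k, nrow(load)))]
    data.frame(protein_id = rownames(load)[o], loading = load[o, k],
               stringsAsFactors = FALSE)
  })
  names(top) <- colnames(scores)
  list(scores = scores,
       explained = if (total > 0) pos / total else rep(0, length(pos)),
       loadings = load, top_loadings = top,
       proteins_used = rownames(normalized$values)[complete])
}
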