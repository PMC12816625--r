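# Single-cell pipeline: log normalization, variable-feature selection with a
# mean-variance trend, exact PCA with a batch-centering integration
# surrogate, shared-nearest-neighbour graph construction, Leiden community
# detection at fixed resolution, and logistic-regression marker tests.

#' Log-normalize a median-scaled single-cell matrix
#'
#' `v -> ln(1 + v * scale)`; zeros map exactly to 0. Expects riBAQ-like
#' values (per-run nonzero median 1).
#'
#' @param normalized A `normalized_matrix`.
#' @param scale Global scale factor applied before `log1p` (default 1).
#' @return Numeric matrix (proteins x cells) of log-normalized values.
#' @export
log_normalize_cells <- function(normalized, scale = 1) {
  v <- normalized$values
  if (any(v < 0)) stop("negative values violate the intensity invariant")
  log1p(v * scale)
}

#' Select highly variable protein features
#'
#' Standardized variance after a mean-variance trend fit: a local polynomial
#' (loess) of log10 variance on log10 mean over proteins' detected values
#' predicts each protein's expected variance; values are standardized by the
#' expected standard deviation, clipped at `sqrt(n_cells)`, and the variance
#' of the clipped standardized values across all cells ranks the features.
#' Ties break by protein id for determinism.
#'
#' @param log_matrix Proteins x cells matrix from [log_normalize_cells()].
#' @param n Number of features to select.
#' @param loess_span Span of the trend fit.
#' @return Character vector of selected protein ids (length <= n).
#' @export
select_variable_features <- function(log_matrix, n = 2000L, loess_span = 0.3) {
  if (n > nrow(log_matrix)) stop("n exceeds the number of proteins")
  n_cells <- ncol(log_matrix)
  det_mean <- apply(log_matrix, 1, function(v) mean(v[v > 0]))
  det_var <- apply(log_matrix, 1, function(v) {
    d <- v[v > 0]
    if (length(d) < 2) 0 else stats::var(d)
  })
  qualifying <- rowSums(log_matrix > 0) >= 2 & det_var > 0
  if (sum(qualifying) < n) {
    warning("only ", sum(qualifying), " proteins qualify for selection")
    n <- sum(qualifying)
  }
  std_var <- stats::setNames(rep(0, nrow(log_matrix)), rownames(log_matrix))
  if (any(qualifying)) {
    fit <- stats::loess(log10(det_var[qualifying]) ~ log10(det_mean[qualifying]),
                        span = loess_span, degree = 2)
    exp_sd <- sqrt(10^stats::fitted(fit))
    idx <- which(qualifying)
    clip <- sqrt(n_cells)
    for (k in seq_along(idx)) {
      i <- idx[k]
      z <- (log_matrix[i, ] - mean(log_matrix[i, ])) / exp_sd[k]
      z <- pmin(pmax(z, -clip), clip)
      std_var[i] <- stats::var(z)
    }
  }
  o <- order(-std_var, rownames(log_matrix))
  rownames(log_matrix)[o][seq_len(n)]
}

#' PCA embedding with batch-centering integration surrogate
#'
#' Selected features are centered across cells (optionally z-scored, clipped
#' at +/-10), technical covariates such as per-cell detection depth are
#' regressed out feature-wise, the data are reduced by exact PCA to `n_pcs`
#' components, and batch effects are attenuated by a per-batch centroid
#' subtraction in PC space with shrinkage toward the global centroid (weight
#' `n_batch / (n_batch + tau)`). This is a deliberately simple, fully
#' specified surrogate for iterative soft-clustering integration algorithms;
#' `integrate_fn` allows plugging in an external implementation with the
#' same signature.
#'
#' Centering without unit-variance scaling is the default: on
#' median-normalized log intensities the discriminating protein families are
#' the high-abundance ones, and unit-variance scaling hands equal weight to
#' low-abundance features whose variance is dominated by stochastic
#' detection. Set `scale_features = TRUE` for classic z-scoring.
#'
#' @param log_matrix Proteins x cells log-normalized matrix.
#' @param features Feature ids to use (e.g. from
#'   [select_variable_features()]).
#' @param n_pcs Number of principal components (>= 2).
#' @param batch_labels Named cell -> batch map (NULL skips integration).
#' @param tau Shrinkage strength of the surrogate (default 5; 0 = full
#'   centroid subtraction).
#' @param covariates Optional numeric matrix or vector (cells in rows /
#'   names) of technical covariates regressed out of each feature before
#'   PCA — typically the per-cell detected-protein count.
#' @param scale_features Divide each feature by its standard deviation
#'   (default FALSE, centering only).
#' @param integrate_fn Optional replacement `function(embedding,
#'   batch_labels)` returning a corrected embedding.
#' @return Cells x n_pcs embedding matrix.
#' @export
embed_and_integrate <- function(log_matrix, features, n_pcs = 35L,
                                batch_labels = NULL, tau = 5,
                                covariates = NULL, scale_features = FALSE,
                                integrate_fn = NULL) {
  if (n_pcs < 2) stop("n_pcs must be >= 2")
  x <- log_matrix[features, , drop = FALSE]
  n_cells <- ncol(x)
  if (n_pcs > min(n_cells, length(features)) - 1L)
    stop("n_pcs must be <= min(n_cells, n_features) - 1")
  mu <- rowMeans(x)
  if (scale_features) {
    sdv <- apply(x, 1, stats::sd)
    sdv[sdv == 0] <- 1
  } else sdv <- 1
  z <- (x - mu) / sdv
  z <- pmin(pmax(z, -10), 10)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n_cells) cv <- cv[colnames(x), , drop = FALSE]
    cv <- scale(cv, center = TRUE, scale = FALSE)
    # feature-wise least-squares residuals against the covariates
    beta <- (z %*% cv) %*% solve(crossprod(cv))
    z <- z - tcrossprod(beta, cv)
  }
  z <- z - rowMeans(z)                          # re-center after clip/regress
  eig <- eigen(crossprod(z), symmetric = TRUE)  # cell x cell Gram matrix
  d <- sqrt(pmax(eig$values[seq_len(n_pcs)], 0))
  emb <- eig$vectors[, seq_len(n_pcs), drop = FALSE] * rep(d, each = n_cells)
  dimnames(emb) <- list(colnames(x), paste0("PC", seq_len(n_pcs)))
  if (is.null(batch_labels)) return(emb)
  bl <- batch_labels[rownames(emb)]
  if (anyNA(bl)) stop("batch_labels must cover every cell")
  if (!is.null(integrate_fn)) return(integrate_fn(emb, bl))
  global <- colMeans(emb)
  for (b in unique(bl)) {
    rows <- which(bl == b)
    if (length(rows) < 2) {
      warning("batch ", b, " has a single cell; left uncentered")
      next
    }
    w <- length(rows) / (length(rows) + tau)
    shift <- w * (colMeans(emb[rows, , drop = FALSE]) - global)
    emb[rows, ] <- sweep(emb[rows, , drop = FALSE], 2, shift, "-")
  }
  emb
}

# Shared-nearest-neighbour graph: k nearest neighbours by Euclidean distance
# in the embedding, edges weighted by the Jaccard overlap of neighbourhoods
# (self included, the usual convention), pruned below `prune`.
snn_graph <- function(embedding, k = 20L, prune = 1 / 15) {
  n <- nrow(embedding)
  if (k <= 1) stop("invalid config: k must be > 1")
  if (k >= n) stop("invalid config: k must be < n_cells")
  d <- as.matrix(stats::dist(embedding))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k + 1L)]))  # incl. self
  nn_sets <- lapply(seq_len(n), function(i) nn[i, ])
  edges <- integer(0); weights <- numeric(0)
  seen <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    for (j in nn_sets[[i]]) {
      if (j == i) next
      a <- min(i, j); b <- max(i, j)
      key <- paste0(a, "_", b)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      ov <- length(intersect(nn_sets[[a]], nn_sets[[b]]))
      w <- ov / (2 * (k + 1L) - ov)
      if (w >= prune) {
        edges <- c(edges, a, b)
        weights <- c(weights, w)
      }
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::E(g)$weight <- weights
  g
}

#' Cluster cells on a shared-nearest-neighbour graph
#'
#' Builds the SNN graph (Euclidean kNN in PC space, Jaccard edge weights)
#' and partitions it by Leiden modularity optimization at the given
#' resolution with a fixed seed (`flavor = "louvain"` selects multi-level
#' Louvain instead). Singleton communities are merged into the cluster with
#' the nearest centroid.
#'
#' @param embedding Cells x components matrix.
#' @param k Neighbourhood size (default 20).
#' @param resolution Modularity resolution (default 1.45).
#' @param seed Integer seed (community detection is stochastic).
#' @param flavor `"leiden"` (default) or `"louvain"`.
#' @param prune SNN weight pruning threshold.
#' @return Named integer cluster labels (1-based, sorted by decreasing
#'   cluster size).
#' @export
cluster_cells <- function(embedding, k = 20L, resolution = 1.45, seed = 1L,
                          flavor = c("leiden", "louvain"), prune = 1 / 15) {
  flavor <- match.arg(flavor)
  if (is.null(rownames(embedding)))
    rownames(embedding) <- sprintf("cell%05d", seq_len(nrow(embedding)))
  input_order <- rownames(embedding)
  # canonical cell order makes the result invariant to input permutation
  embedding <- embedding[order(rownames(embedding)), , drop = FALSE]
  g <- snn_graph(embedding, k = k, prune = prune)
  set.seed(seed)
  comm <- if (flavor == "leiden") {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10)
  } else {
    igraph::cluster_louvain(g, resolution = resolution)
  }
  labels <- igraph::membership(comm)
  labels <- merge_singletons(labels, embedding)
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(labels)])
  names(out) <- rownames(embedding)
  out[input_order]
}

merge_singletons <- function(labels, embedding) {
  repeat {
    tab <- table(labels)
    singles <- names(tab)[tab == 1]
    if (!length(singles) || length(tab) == 1) return(labels)
    cl <- singles[1]
    i <- which(labels == cl)
    centroids <- vapply(setdiff(names(tab), cl), function(g)
      colMeans(embedding[labels == g, , drop = FALSE]), numeric(ncol(embedding)))
    dists <- colSums((centroids - embedding[i, ])^2)
    labels[i] <- names(dists)[which.min(dists)]
  }
}

#' Logistic-regression marker test for one cluster
#'
#' Proteins are pre-filtered by the absolute difference of mean
#' log-normalized expression in-cluster versus rest (natural-log fold
#' change, threshold 0.25 by default); each survivor is tested by a
#' likelihood-ratio test of logistic regression of cluster membership on the
#' protein's values against an intercept-only model, with Bonferroni
#' correction over the proteins tested.
#'
#' @param log_matrix Proteins x cells log-normalized matrix.
#' @param labels Named cell -> cluster labels.
#' @param cluster The cluster to contrast against all other cells.
#' @param logfc_threshold Pre-filter on |log fold change| (default 0.25).
#' @param alpha Significance level on the Bonferroni-adjusted p (strict).
#' @return Data frame: `protein_id`, `log_fc` (positive = higher in the
#'   cluster), `pct_in`, `pct_out`, `p`, `p_adj`, `significant`,
#'   `converged`.
#' @export
find_markers <- function(log_matrix, labels, cluster, logfc_threshold = 0.25,
                         alpha = 0.05) {
  labels <- labels[colnames(log_matrix)]
  inside <- labels == cluster
  if (sum(inside) < 3 || sum(!inside) < 3)
    stop("cluster and complement each need >= 3 cells")
  mean_in <- rowMeans(log_matrix[, inside, drop = FALSE])
  mean_out <- rowMeans(log_matrix[, !inside, drop = FALSE])
  log_fc <- mean_in - mean_out
  tested <- which(abs(log_fc) >= logfc_threshold)
  if (!length(tested))
    return(data.frame(protein_id = character(0), log_fc = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), converged = logical(0)))
  y <- as.integer(inside)
  res <- lapply(tested, function(i) {
    v <- log_matrix[i, ]
    fit <- suppressWarnings(stats::glm(y ~ v, family = stats::binomial(),
                                       control = list(maxit = 50)))
    null_dev <- fit$null.deviance
    data.frame(p = stats::pchisq(null_dev - fit$deviance, df = 1,
                                 lower.tail = FALSE),
               converged = fit$converged)
  })
  res <- do.call(rbind, res)
  p_adj <- pmin(1, res$p * length(tested))
  out <- data.frame(protein_id = rownames(log_matrix)[tested],
                    log_fc = log_fc[tested],
                    pct_in = rowMeans(log_matrix[tested, inside, drop = FALSE] > 0),
                    pct_out = rowMeans(log_matrix[tested, !inside, drop = FALSE] > 0),
                    p = res$p, p_adj = p_adj,
                    significant = p_adj < alpha,
                    converged = res$converged,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_adj, out$p, -abs(out$log_fc)), ]
}
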