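# Log normalization, variable features, embedding/integration, SNN/Leiden
# clustering and logistic-regression markers.

test_that("log normalization maps zero to zero and is monotone", {
  m <- toy_matrix(matrix(c(0, exp(1) - 1, 2, 5), ncol = 1), class = "single")
  norm <- compute_ribaq_minibulk(m, toy_catalog(rownames(m$values)))
  norm$values <- m$values        # raw values for the closed-form checks
  lg <- log_normalize_cells(norm)
  expect_identical(lg[1, 1], 0)
  expect_equal(lg[2, 1], 1, tolerance = 1e-12)
  expect_true(all(diff(lg[, 1]) > 0))
  norm$values[1, 1] <- -1
  expect_error(log_normalize_cells(norm), "negative")
})

test_that("constant proteins are never selected as variable features", {
  set.seed(20)
  v <- matrix(rlnorm(400, 2, 0.8), nrow = 20)
  v[1, ] <- 3                    # constant protein
  rownames(v) <- sprintf("P%02d", 1:20)
  lg <- log1p(v)
  feats <- select_variable_features(lg, 10)
  expect_false("P01" %in% feats)
  expect_identical(length(feats), 10L)
})

test_that("state-effect proteins concentrate in the variable feature set", {
  frac <- sapply(1:3, function(s) {
    cat <- generate_protein_catalog(3000, seed = 70 + s)
    e <- generate_scp_experiment(cat, scp_config(seed = 70 + s))
    keep <- filter_cells(e$matrix, 400)$matrix
    norm <- compute_ribaq_like_scp(keep, cat)
    feats <- select_variable_features(log_normalize_cells(norm), 2000)
    ft <- catalog_family_table(cat)
    eff <- ft$protein_id[ft$family %in% unique(default_state_effects()$family)]
    mean(eff %in% feats)
  })
  expect_gte(mean(frac), 0.70)
})

test_that("a single batch makes the integration surrogate the identity", {
  set.seed(21)
  lg <- matrix(abs(rnorm(400)), nrow = 20,
               dimnames = list(sprintf("P%02d", 1:20),
                               sprintf("c%02d", 1:20)))
  plain <- embed_and_integrate(lg, rownames(lg), n_pcs = 5)
  one_batch <- embed_and_integrate(lg, rownames(lg), n_pcs = 5,
                                   batch_labels = setNames(rep("b1", 20),
                                                           colnames(lg)))
  expect_equal(plain, one_batch, tolerance = 1e-9)
})

test_that("tau = 0 collapses identical offset batches onto one centroid", {
  set.seed(22)
  base <- matrix(rnorm(300), nrow = 10)
  lg <- cbind(base, base + 5)    # batch 2 offset by a constant vector
  lg <- lg - min(lg)
  dimnames(lg) <- list(sprintf("P%02d", 1:10), sprintf("c%02d", 1:60))
  batches <- setNames(rep(c("b1", "b2"), each = 30), colnames(lg))
  emb <- embed_and_integrate(lg, rownames(lg), n_pcs = 3,
                             batch_labels = batches, tau = 0)
  c1 <- colMeans(emb[batches == "b1", ])
  c2 <- colMeans(emb[batches == "b2", ])
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("batch integration improves cluster recovery under batch effects", {
  skip_if_no("mclust")
  gain <- sapply(1:3, function(s) {
    cat <- generate_protein_catalog(800, seed = 80 + s)
    cfg <- scp_config(n_cells = 150, n_blanks = 0, batch_sd = 0.6,
                      seed = 80 + s)
    e <- generate_scp_experiment(cat, cfg)
    norm <- compute_ribaq_like_scp(e$matrix, cat)
    lg <- log_normalize_cells(norm)
    feats <- select_variable_features(lg, 500)
    nd <- colSums(lg > 0)
    batches <- setNames(norm$runs$batch, norm$runs$run)
    st <- e$truth$cell_state
    ari <- function(emb) {
      lab <- cluster_cells(emb, k = 15, resolution = 1.45, seed = 80 + s)
      mclust::adjustedRandIndex(lab, st[names(lab)])
    }
    with_int <- ari(embed_and_integrate(lg, feats, 20, batches,
                                        covariates = cbind(nd, nd^2)))
    without <- ari(embed_and_integrate(lg, feats, 20,
                                       covariates = cbind(nd, nd^2)))
    with_int - without
  })
  expect_gt(mean(gain), 0)
})

test_that("well-separated blobs are recovered at any sane resolution", {
  set.seed(23)
  blob <- rbind(matrix(rnorm(40 * 5), ncol = 5),
                matrix(rnorm(40 * 5, mean = 10), ncol = 5))
  rownames(blob) <- sprintf("c%02d", 1:80)
  truth <- rep(1:2, each = 40)
  for (res in c(0.5, 1)) {
    lab <- cluster_cells(blob, k = 20, resolution = res, seed = 1)
    expect_identical(length(unique(lab)), 2L)
    expect_identical(length(unique(lab[truth == 1])), 1L)
  }
  # at higher resolutions modularity may shave a blob into pieces, but a
  # cluster never spans both blobs
  for (res in c(1.45, 2)) {
    lab2 <- cluster_cells(blob, k = 20, resolution = res, seed = 1)
    expect_identical(length(unique(paste(lab2, truth))),
                     length(unique(lab2)))
  }
  expect_error(cluster_cells(blob, k = 1), "invalid config")
  expect_error(cluster_cells(blob, k = 100), "invalid config")
})

test_that("clustering is deterministic and permutation invariant", {
  skip_if_no("mclust")
  set.seed(24)
  emb <- matrix(rnorm(120 * 10), nrow = 120,
                dimnames = list(sprintf("c%03d", 1:120), NULL))
  emb[1:60, 1] <- emb[1:60, 1] + 8
  l1 <- cluster_cells(emb, seed = 5)
  l2 <- cluster_cells(emb, seed = 5)
  expect_identical(l1, l2)
  perm <- sample(120)
  l3 <- cluster_cells(emb[perm, ], seed = 5)
  expect_equal(mclust::adjustedRandIndex(l1[rownames(emb)[perm]], l3), 1)
})

test_that("marker tests fold-filter, converge and correct by Bonferroni", {
  set.seed(25)
  n_in <- 30; n_out <- 200
  lg <- matrix(abs(rnorm((n_in + n_out) * 30, 1, 0.3)), nrow = 30,
               dimnames = list(sprintf("P%02d", 1:30),
                               sprintf("c%03d", seq_len(n_in + n_out))))
  lg[1, ] <- 1                                 # identical -> excluded
  lg[2, ] <- c(rep(2, n_in), rep(0, n_out))    # only inside the cluster
  labels <- setNames(rep(c(1, 2), c(n_in, n_out)), colnames(lg))
  mk <- find_markers(lg, labels, 1)
  expect_false("P01" %in% mk$protein_id)
  row2 <- mk[mk$protein_id == "P02", ]
  expect_true(row2$significant)
  expect_equal(row2$pct_in, 1)
  expect_equal(row2$pct_out, 0)
  expect_equal(mk$p_adj, pmin(1, mk$p * nrow(mk)))
  # independent two-model deviance oracle for the LRT statistic
  y <- as.integer(labels == 1)
  v <- lg[2, ]
  null_dev <- -2 * (sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y)))
  fit <- suppressWarnings(glm(y ~ v, family = binomial()))
  p_oracle <- pchisq(null_dev - fit$deviance, 1, lower.tail = FALSE)
  expect_equal(row2$p, p_oracle, tolerance = 1e-8)
  # swapping cluster and complement flips the fold change sign
  mk2 <- find_markers(lg, labels, 2)
  expect_equal(mk2[mk2$protein_id == "P02", "log_fc"], -row2$log_fc,
               tolerance = 1e-12)
})

test_that("marker p-values are calibrated under label permutation", {
  cat <- generate_protein_catalog(400, seed = 26)
  e <- generate_scp_experiment(cat, scp_config(n_cells = 150, n_blanks = 0,
                                               seed = 26))
  lg <- log_normalize_cells(compute_ribaq_like_scp(e$matrix, cat))
  lg <- lg[rowSums(lg > 0) >= 15, ]
  fr <- sapply(1:20, function(s) {
    set.seed(900 + s)
    perm <- setNames(sample(rep(c(1, 2), c(30, 120))), colnames(lg))
    mean(find_markers(lg, perm, 1, logfc_threshold = 0)$p < 0.05)
  })
  expect_lt(abs(mean(fr) - 0.05), 0.03)
})
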