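# Synthetic-data generator: catalog properties, detection model, ground-truth
# construction and calibration targets.

test_that("generated catalogs honour the configured MW median and layout", {
  cat <- generate_protein_catalog(5000, seed = 2)
  expect_lt(abs(median(cat$molecular_weight) - 47485) / 47485, 0.05)
  expect_gte(sum(cat$is_histone), 4)
  expect_true(all(cat$n_theoretical_peptides >= 1))
  expect_false(anyDuplicated(cat$protein_id) > 0)
  expect_error(generate_protein_catalog(10), "invalid config")
})

test_that("empty family spec leaves only mandatory histone flags", {
  cat <- generate_protein_catalog(50, family_spec = numeric(0), seed = 1)
  expect_gte(sum(cat$is_histone), 4)
  expect_identical(length(unlist(cat$families)), 0L)
})

test_that("the generator is bit-reproducible for a fixed seed", {
  c1 <- generate_protein_catalog(600, seed = 9)
  c2 <- generate_protein_catalog(600, seed = 9)
  expect_identical(c1, c2)
  e1 <- generate_scp_experiment(c1, scp_config(n_cells = 30, n_blanks = 3,
                                               seed = 9))
  e2 <- generate_scp_experiment(c2, scp_config(n_cells = 30, n_blanks = 3,
                                               seed = 9))
  expect_identical(e1$matrix$values, e2$matrix$values)
  expect_identical(e1$truth$cell_state, e2$truth$cell_state)
})

test_that("detection probability is monotone in abundance and midpoint", {
  mu <- 10^seq(2, 10, length.out = 50)
  p <- detection_probability(mu, midpoint = 8.9, slope = 0.45)
  expect_true(all(diff(p) >= 0))
  # marginal zero fraction decreases as the midpoint decreases
  cat <- generate_protein_catalog(400, seed = 4)
  zf <- sapply(c(10, 9, 8, 7), function(m) {
    e <- generate_scp_experiment(cat, scp_config(n_cells = 40, n_blanks = 0,
                                                 dropout_midpoint = m, seed = 4))
    mean(e$matrix$values == 0)
  })
  expect_true(all(diff(zf) < 0))
})

test_that("invalid generator configs are rejected", {
  expect_error(scp_config(state_proportions = c(a = 0.6, b = 0.6)),
               "sum to 1")
  bad_eff <- data.frame(state = "ghost", family = "histones", factor = 2)
  expect_error(scp_config(family_effects = bad_eff), "missing from")
  expect_error(scp_config(dropout_slope = 0), "dropout_slope")
  eff <- data.frame(state = "armed", family = "histones", factor = -1)
  expect_error(scp_config(family_effects = eff,
                          state_proportions = c(armed = 1)), "factor")
  expect_error(minibulk_config(n_subjects = 1), ">= 2 subjects")
})

test_that("noiseless family-sum ratios equal the configured factors exactly", {
  cat <- generate_protein_catalog(600, seed = 3)
  e <- generate_scp_experiment(cat, noiseless_scp_config(n_cells = 120, seed = 3))
  st <- e$truth$cell_state
  ft <- score_families(e$matrix, cat)
  ag_lytic <- mean(ft["azurophilic_granule", names(st)[st == "lytic_NETs"]])
  ag_armed <- mean(ft["azurophilic_granule", names(st)[st == "armed"]])
  expect_equal(ag_lytic / ag_armed, 0.20, tolerance = 1e-12)
  hist_ratio <- mean(ft["histones", names(st)[st == "lytic_NETs"]]) /
    mean(ft["histones", names(st)[st == "armed"]])
  expect_equal(hist_ratio, 0.17, tolerance = 1e-12)
})

test_that("noiseless mini-bulk carries the printed immature effects exactly", {
  cat <- generate_protein_catalog(600, seed = 5)
  cfg <- minibulk_config(batch_sd = 0, depth_cv = 0, group_depth_cv = NULL,
                         meas_sd = 0, dropout_midpoint = -Inf, seed = 5)
  e <- generate_minibulk_experiment(cat, cfg)
  sc <- score_families(e$matrix, cat)
  grp <- e$truth$cell_state
  imm <- names(grp)[grp == "G.LDN.CD10neg"]
  mat <- names(grp)[grp == "G.NDN.CD10pos"]
  expect_equal(mean(sc["ribosomal_40S", imm]) / mean(sc["ribosomal_40S", mat]),
               4.3, tolerance = 1e-12)
  expect_equal(mean(sc["electron_transport_chain", imm]) /
                 mean(sc["electron_transport_chain", mat]),
               2.65, tolerance = 1e-12)
})

test_that("zero noise with unit factors gives |t| = 0 between all groups", {
  cat <- generate_protein_catalog(600, seed = 6)
  eff <- default_minibulk_effects()
  eff$factor <- 1
  cfg <- minibulk_config(family_effects = eff, batch_sd = 0, depth_cv = 0,
                         group_depth_cv = NULL, meas_sd = 0,
                         dropout_midpoint = -Inf, seed = 6)
  e <- generate_minibulk_experiment(cat, cfg)
  res <- moderated_t_test(e$matrix, "TAN", "G.NDN.CD10pos")
  expect_true(all(abs(res$t_mod[res$eligible]) == 0))
})

test_that("single-cell preset hits the calibrated detection target", {
  cat <- generate_protein_catalog(3000, seed = 21)
  e <- generate_scp_experiment(cat, scp_config(seed = 21))
  cells <- e$matrix$runs$run[e$matrix$runs$class == "single"]
  med <- median(count_identifications(e$matrix)[cells])
  expect_lt(abs(med - 1100) / 1100, 0.15)
})

test_that("mini-bulk preset detects over 3000 proteins per sample", {
  cat <- generate_protein_catalog(3500, seed = 22)
  e <- generate_minibulk_experiment(cat, minibulk_config(seed = 22))
  expect_gte(median(count_identifications(e$matrix)), 3000)
})

test_that("with no state effects, cluster recovery sits at chance", {
  cat <- generate_protein_catalog(800, seed = 7)
  eff <- default_state_effects()
  eff$factor <- 1
  cfg <- scp_config(n_cells = 120, n_blanks = 0, batch_sd = 0,
                    family_effects = eff, seed = 7)
  e <- generate_scp_experiment(cat, cfg)
  norm <- compute_ribaq_like_scp(e$matrix, cat)
  logm <- log_normalize_cells(norm)
  feats <- select_variable_features(logm, 400)
  nd <- colSums(logm > 0)
  emb <- embed_and_integrate(logm, feats, 10, covariates = cbind(nd, nd^2))
  lab <- cluster_cells(emb, k = 10, resolution = 1.45, seed = 7)
  skip_if_no("mclust")
  ari <- mclust::adjustedRandIndex(lab, e$truth$cell_state[names(lab)])
  expect_lt(abs(ari), 0.1)
})

test_that("downstream differential recovers the ribosomal effect direction", {
  hits <- sapply(1:3, function(s) {
    cat <- generate_protein_catalog(1000, seed = 30 + s)
    e <- generate_minibulk_experiment(cat, minibulk_config(seed = 30 + s))
    norm <- compute_ribaq_minibulk(e$matrix, cat)
    res <- moderated_t_test(norm, "G.LDN.CD10neg", "G.NDN.CD10pos")
    ft <- catalog_family_table(cat)
    ribo <- ft$protein_id[ft$family %in% c("ribosomal_40S", "ribosomal_60S")]
    ok <- res$eligible & res$protein_id %in% ribo
    mean(res$log_fc[ok] > 0)
  })
  expect_gte(mean(hits), 0.95)
})
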