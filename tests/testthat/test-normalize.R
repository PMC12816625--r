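# riBAQ, riBAQ-like, proteomic-ruler and copy-number coverage.

test_that("riBAQ divides by peptide count then by the nonzero run median", {
  m <- toy_matrix(matrix(c(2, 4, 8), ncol = 1))
  cat <- toy_catalog(rownames(m$values), npep = 1)
  norm <- compute_ribaq_minibulk(m, cat)
  expect_equal(unname(norm$values[, 1]), c(0.5, 1, 2), tolerance = 1e-10)

  m2 <- toy_matrix(matrix(c(10, 0, 30), ncol = 1))
  cat2 <- toy_catalog(rownames(m2$values))
  cat2$n_theoretical_peptides <- c(5L, 1L, 3L)
  norm2 <- compute_ribaq_minibulk(m2, cat2)
  expect_equal(unname(norm2$values[, 1]), c(1 / 3, 0, 5 / 3),
               tolerance = 1e-10)
})

test_that("identical runs normalize identically and medians are recorded", {
  v <- matrix(rep(c(3, 6, 9), 3), ncol = 3)
  m <- toy_matrix(v)
  cat <- toy_catalog(rownames(m$values), npep = 2)
  norm <- compute_ribaq_minibulk(m, cat)
  expect_equal(norm$values[, 1], norm$values[, 2])
  expect_equal(unname(norm$per_run_median), rep(3, 3))
  # per-run nonzero median is 1 after normalization
  expect_equal(apply(norm$values, 2, function(x) median(x[x > 0])),
               setNames(rep(1, 3), colnames(norm$values)), tolerance = 1e-9)
})

test_that("riBAQ-like corrects by MW around the detected-set median", {
  v <- matrix(c(40000, 60000), ncol = 1)
  m <- toy_matrix(v)
  cat <- toy_catalog(rownames(m$values), mw = c(40000, 60000))
  norm <- compute_ribaq_like_scp(m, cat)
  expect_equal(norm$median_mw_used, 50000)
  expect_equal(unname(norm$values[, 1]), c(1, 1), tolerance = 1e-10)
  # a protein at exactly the median MW is unchanged before per-run scaling
  v2 <- matrix(c(5, 7, 11), ncol = 1)
  m2 <- toy_matrix(v2)
  v2 <- m2$values
  cat3 <- toy_catalog(rownames(v2), mw = c(30000, 50000, 70000))
  n2 <- compute_ribaq_like_scp(m2, cat3)
  expect_equal(n2$median_mw_used, 50000)
  corrected <- m2$values * (50000 / cat3$molecular_weight)
  expect_equal(corrected[2, 1], v2[2, 1])  # identity correction at the median
  expect_equal(unname(n2$values[, 1]),
               unname(corrected[, 1] / median(corrected[, 1])),
               tolerance = 1e-10)
  # the published constant can be forced for exact replication
  n3 <- compute_ribaq_like_scp(m2, cat3, median_mw_override = 47485)
  expect_equal(n3$median_mw_used, 47485)
})

test_that("normalizations are invariant to positive per-run rescaling", {
  set.seed(8)
  v <- matrix(rlnorm(30, 5, 1), ncol = 3)
  v[sample(30, 5)] <- 0
  m <- toy_matrix(v)
  cat <- toy_catalog(rownames(m$values), mw = runif(10, 2e4, 8e4),
                     npep = sample(1:30, 10, replace = TRUE))
  v2 <- m$values; v2[, 2] <- v2[, 2] * 37.5
  m2 <- intensity_matrix(v2, m$runs)
  expect_equal(compute_ribaq_minibulk(m, cat)$values,
               compute_ribaq_minibulk(m2, cat)$values, tolerance = 1e-12)
  expect_equal(compute_ribaq_like_scp(m, cat)$values,
               compute_ribaq_like_scp(m2, cat)$values, tolerance = 1e-12)
  # zeros are preserved exactly
  expect_identical(unname(compute_ribaq_like_scp(m, cat)$values == 0),
                   unname(v == 0))
})

test_that("all-zero runs are excluded with a warning, not a crash", {
  v <- matrix(c(1, 2, 0, 0), ncol = 2)
  m <- toy_matrix(v)
  cat <- toy_catalog(rownames(m$values))
  expect_warning(norm <- compute_ribaq_minibulk(m, cat), "no detected")
  expect_identical(colnames(norm$values), "r01")
  expect_identical(norm$excluded_runs, "r02")
})

test_that("proteomic ruler matches the one-histone closed form", {
  v <- matrix(12345, ncol = 1, dimnames = list("H1", "r1"))
  m <- toy_matrix(v)
  cat <- toy_catalog("H1", mw = 14000, is_histone = TRUE)
  cn <- proteomic_ruler(m, cat, dna_mass_pg = 6.5)
  closed_form <- 6.02214076e23 * 6.5e-12 / 14000
  expect_equal(unname(cn$copies["H1"]), closed_form, tolerance = 1e-12)
  expect_equal(closed_form, 2.80e8, tolerance = 0.005)
  # independent of the histone's intensity
  v2 <- v * 1000
  cn2 <- proteomic_ruler(intensity_matrix(v2, m$runs), cat)
  expect_equal(cn2$copies, cn$copies, tolerance = 1e-12)
})

test_that("ruler output is scale-invariant and linear in DNA mass", {
  set.seed(12)
  v <- matrix(rlnorm(40, 8, 1), ncol = 4)
  m <- toy_matrix(v, class = "bulk")
  cat <- toy_catalog(rownames(m$values), mw = runif(10, 1e4, 1e5),
                     is_histone = c(TRUE, TRUE, rep(FALSE, 8)))
  cn <- proteomic_ruler(m, cat)
  v2 <- m$values; v2[, 3] <- v2[, 3] * 2
  cn2 <- proteomic_ruler(intensity_matrix(v2, m$runs), cat)
  expect_equal(cn2$copies, cn$copies, tolerance = 1e-12)
  cn3 <- proteomic_ruler(m, cat, dna_mass_pg = 13)
  expect_equal(cn3$copies, 2 * cn$copies, tolerance = 1e-12)
  expect_error(proteomic_ruler(m, toy_catalog(rownames(m$values))),
               "ruler undefined")
})

test_that("copy-number coverage fractions follow the median definition", {
  copies <- structure(list(copies = setNames(c(1, 2, 3, 4, 5) * 1000,
                                             paste0("P", 1:5)),
                           dna_mass_per_cell = 6.5,
                           histone_signal_total = 1),
                      class = "copy_number_table")
  cov <- copy_number_coverage(copies, list(all = paste0("P", 1:5)),
                              threshold = 3000)
  expect_equal(cov$fraction_below, 0.4)
  expect_equal(cov$median_copies, 3000)
  cov2 <- copy_number_coverage(copies, list(top = c("P3", "P4", "P5")),
                               threshold = 3000)
  expect_equal(cov2$fraction_below, 0)
  expect_error(copy_number_coverage(copies, list(none = character(0))),
               "empty detected set")
})

test_that("fraction below the bulk median falls as dropout deepens", {
  ok <- sapply(1:3, function(s) {
    cat <- generate_protein_catalog(800, seed = 40 + s)
    bulk <- generate_scp_experiment(cat, scp_config(
      n_cells = 6, n_blanks = 0, dropout_midpoint = -Inf, seed = 40 + s))
    cn <- proteomic_ruler(bulk$matrix, cat)
    sets <- lapply(c(bulk = -Inf, minibulk = 7.06, scp = 8.95), function(mp) {
      e <- generate_scp_experiment(cat, scp_config(n_cells = 6, n_blanks = 0,
                                                   dropout_midpoint = mp,
                                                   seed = 40 + s))
      names(which(rowSums(e$matrix$values > 0) > 0))
    })
    cov <- copy_number_coverage(cn, sets)
    all(diff(cov$fraction_below) < 0)
  })
  expect_true(all(ok))
})
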