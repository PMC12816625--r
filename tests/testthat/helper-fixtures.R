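# Fixture builders shared across the suite. All fixtures are constructed in
# code; nothing is read from disk unless the test writes it first.

# Minimal annotation table for a set of runs.
run_annotations <- function(runs, group = "A", class = "minibulk",
                            subject = runs, batch = "b1") {
  data.frame(run = runs, subject = subject,
             group = rep_len(group, length(runs)),
             class = rep_len(class, length(runs)),
             batch = rep_len(batch, length(runs)),
             stringsAsFactors = FALSE)
}

# Intensity matrix from a plain numeric matrix (proteins x runs).
toy_matrix <- function(values, group = "A", class = "minibulk") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("r%02d", seq_len(ncol(values)))
  groups <- rep_len(group, ncol(values))
  intensity_matrix(values, run_annotations(colnames(values), groups, class))
}

# Catalog with given MWs / peptide counts (defaults neutral).
toy_catalog <- function(ids, mw = 50000, npep = 1, gene = ids,
                        families = rep("", length(ids)),
                        is_histone = FALSE) {
  protein_catalog(protein_id = ids, gene_symbol = gene,
                  molecular_weight = rep_len(mw, length(ids)),
                  n_theoretical_peptides = rep_len(npep, length(ids)),
                  families = families, is_histone = is_histone)
}

# Two-group intensity matrix with log-normal noise for differential tests.
two_group_matrix <- function(n = 200, na = 6, nb = 6, seed = 1,
                             meanlog = 10, sdlog = 1) {
  set.seed(seed)
  v <- matrix(2^stats::rnorm(n * (na + nb), meanlog, sdlog), nrow = n,
              dimnames = list(sprintf("P%03d", seq_len(n)),
                              c(sprintf("a%d", seq_len(na)),
                                sprintf("b%d", seq_len(nb)))))
  intensity_matrix(v, run_annotations(colnames(v),
                                      group = rep(c("A", "B"), c(na, nb))))
}

# Noiseless single-cell generator configuration (dropout disabled).
noiseless_scp_config <- function(...) {
  scp_config(batch_sd = 0, depth_cv = 0, meas_sd = 0,
             dropout_midpoint = -Inf, n_blanks = 0, ...)
}

skip_if_no <- function(pkg) testthat::skip_if_not_installed(pkg)
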