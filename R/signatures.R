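# Protein-family signature scoring, between-group family statistics,
# maturity-signature transfer from mini-bulk to single cells, and rule-based
# functional-state assignment for clusters.

#' Summed-intensity family scores
#'
#' Per run/cell, the plain sum of normalized intensities over a family's
#' member proteins (zeros contribute 0). Scores are additive over disjoint
#' families. When `registry` is `NULL`, the catalog's own family tags are
#' used; otherwise the registry's symbol lists are matched against the
#' catalog's gene symbols (empty families score 0 with a warning).
#'
#' @param normalized A `normalized_matrix` (or [intensity_matrix]).
#' @param catalog A [protein_catalog].
#' @param registry Named list family -> gene symbols (e.g.
#'   [neutrophil_family_registry()]), or `NULL` for catalog tags.
#' @return Families x runs numeric matrix with attribute
#'   `registry_version`.
#' @export
score_families <- function(normalized, catalog, registry = NULL) {
  version <- if (is.null(registry)) {
    registry <- catalog_registry(catalog)
    attr(registry, "version")
  } else attr(registry, "version") %||% "unversioned"
  if (!length(registry)) {
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(normalized$values),
                  dimnames = list(NULL, colnames(normalized$values)))
    attr(out, "registry_version") <- version
    return(out)
  }
  idx <- match(rownames(normalized$values), catalog$protein_id)
  symbols <- catalog$gene_symbol[idx]
  scores <- t(vapply(names(registry), function(fam) {
    rows <- which(symbols %in% registry[[fam]])
    if (!length(rows)) {
      warning("family ", fam, " resolves to no catalog protein; scored 0")
      return(rep(0, ncol(normalized$values)))
    }
    colSums(normalized$values[rows, , drop = FALSE])
  }, numeric(ncol(normalized$values))))
  dimnames(scores) <- list(names(registry), colnames(normalized$values))
  attr(scores, "registry_version") <- version
  scores
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare a family score between two groups
#'
#' Percent change of group B relative to group A
#' (`100 * (mean_b - mean_a) / mean_a`) and a two-sided Welch t-test with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param scores Family-score matrix from [score_families()].
#' @param family Family tag (a row of `scores`).
#' @param runs_a,runs_b Run/cell names of the two groups (>= 2 each).
#' @return List: `percent_change`, `welch_t`, `df`, `p`, `mean_a`,
#'   `mean_b`.
#' @export
compare_family <- function(scores, family, runs_a, runs_b) {
  if (!family %in% rownames(scores)) stop("unknown family: ", family)
  a <- scores[family, runs_a]; b <- scores[family, runs_b]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 members per group")
  # closed-form Welch statistic (tolerates zero-variance groups, which
  # stats::t.test refuses); equality with t.test on regular input is covered
  # by the tests
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  se <- sqrt(va + vb)
  delta <- mean(b) - mean(a)
  if (se > 0) {
    tt <- delta / se
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * stats::pt(-abs(tt), df)
  } else {
    tt <- if (delta == 0) 0 else sign(delta) * Inf
    df <- NA_real_
    p <- if (delta == 0) 1 else 0
  }
  pc <- if (mean(a) == 0) NA_real_ else 100 * delta / mean(a)
  list(percent_change = pc, welch_t = tt, df = df, p = p,
       mean_a = mean(a), mean_b = mean(b))
}

# Curated seed lists for the maturity-signature transfer.
.maturity_seed <- c("MMP8", "MMP9", "S100A8", "S100A9", "ITGAM", "ITGB2",
                    "FCGR3B")
.immaturity_seed_families <- c("ribosomal_40S", "ribosomal_60S",
                               "electron_transport_chain")
.immaturity_seed_extra <- c("PCNA", "CEBPE")

#' Derive the maturity signature from the mature-vs-immature contrast
#'
#' From a differential result of the mature (NDN CD10+) versus immature
#' (LDN CD10-) mini-bulk comparison (group A = mature), splits the
#' significant proteins by sign: `maturity_up` (higher in mature) and
#' `immaturity_up` (higher in immature). With `curated_only = TRUE` both
#' sets are intersected with curated seed lists (granule/adhesion maturity
#' markers; PCNA, CEBPE plus ribosomal and electron-transport families for
#' immaturity).
#'
#' @param result A `differential_result` with q-values
#'   (see [call_significant()]); positive `log_fc` = higher in group A
#'   (mature).
#' @param catalog A [protein_catalog] (for symbols and family membership).
#' @param q_cut Significance cutoff.
#' @param curated_only Restrict to the curated seed lists.
#' @return List of character vectors `maturity_up`, `immaturity_up` (gene
#'   symbols).
#' @export
derive_maturity_signature <- function(result, catalog, q_cut = 0.05,
                                      curated_only = TRUE) {
  if (!"significant" %in% names(result))
    result <- call_significant(result, q_cut)
  sig <- result[result$significant, ]
  sym <- catalog$gene_symbol[match(sig$protein_id, catalog$protein_id)]
  mat_up <- sym[sig$log_fc > 0]
  imm_up <- sym[sig$log_fc < 0]
  if (curated_only) {
    fam_tab <- catalog_family_table(catalog)
    imm_seed <- unique(c(.immaturity_seed_extra,
                         fam_tab$gene_symbol[fam_tab$family %in%
                                             .immaturity_seed_families]))
    mat_up <- intersect(mat_up, .maturity_seed)
    imm_up <- intersect(imm_up, imm_seed)
  }
  list(maturity_up = unique(mat_up), immaturity_up = unique(imm_up))
}

#' Default functional-state templates
#'
#' Signed family expectations for the seven neutrophil functional states,
#' derived from the shipped per-state effect table by z-scoring log effects
#' across states within each family. The sign structure encodes the
#' published evidence (e.g. lytic NETs: strong loss of azurophilic granules,
#' histones and nuclear membrane with elevated complement/coagulation;
#' vascular immature: ribosomal, mitochondrial, DNA-replication and
#' complement gain with maturity-marker loss).
#'
#' @param effects Effect table as from [default_state_effects()].
#' @return States x families numeric template matrix with attribute
#'   `template_version`.
#' @export
default_state_templates <- function(effects = default_state_effects()) {
  states <- unique(effects$state)
  fams <- unique(effects$family)
  f <- matrix(1, nrow = length(states), ncol = length(fams),
              dimnames = list(states, fams))
  for (j in seq_len(nrow(effects)))
    f[effects$state[j], effects$family[j]] <- effects$factor[j]
  lf <- log(f)
  tmpl <- scale(lf)            # z-score each family column across states
  tmpl[is.nan(tmpl)] <- 0
  tmpl <- matrix(tmpl, nrow = length(states), dimnames = dimnames(f))
  attr(tmpl, "template_version") <- "state-templates-v1"
  tmpl
}

#' Per-cluster family z-profiles
#'
#' Mean family score per cluster, z-scored across clusters within each
#' family — the evidence matrix consumed by [assign_states()].
#'
#' @param scores Family-score matrix (families x cells).
#' @param labels Named cell -> cluster labels.
#' @return Clusters x families z-profile matrix.
#' @export
cluster_family_profiles <- function(scores, labels) {
  labels <- labels[colnames(scores)]
  cls <- sort(unique(labels))
  m <- t(vapply(cls, function(cl)
    rowMeans(scores[, labels == cl, drop = FALSE]), numeric(nrow(scores))))
  rownames(m) <- as.character(cls)
  z <- scale(m)
  z[is.nan(z)] <- 0
  matrix(z, nrow = length(cls), dimnames = list(as.character(cls),
                                                rownames(scores)))
}

#' Assign functional states to clusters
#'
#' Similarity between each cluster's family z-profile and each state
#' template is the Spearman rank correlation over the template's families;
#' states are assigned to clusters by maximum-weight injective matching
#' (each state to at most one cluster), and clusters whose best acceptable
#' similarity falls below `threshold` remain `"unassigned"`.
#'
#' @param profiles Clusters x families z-profile matrix
#'   (see [cluster_family_profiles()]).
#' @param templates States x families template matrix
#'   (default [default_state_templates()]).
#' @param threshold Minimum similarity for an assignment (default 0.3).
#' @return List of class `state_assignment`: `assignment` (named cluster ->
#'   state, `"unassigned"` allowed), `similarity` (clusters x states),
#'   `evidence` (the profiles), `template_version`.
#' @export
assign_states <- function(profiles, templates = default_state_templates(),
                          threshold = 0.3) {
  fams <- intersect(colnames(templates), colnames(profiles))
  if (length(fams) < 3)
    stop("profiles and templates share fewer than 3 families")
  sim <- matrix(NA_real_, nrow = nrow(profiles), ncol = nrow(templates),
                dimnames = list(rownames(profiles), rownames(templates)))
  for (ci in seq_len(nrow(profiles)))
    for (si in seq_len(nrow(templates))) {
      tv <- templates[si, fams]
      use <- tv != 0              # families the template is indifferent to
      if (sum(use) < 3) use <- rep(TRUE, length(fams))
      sim[ci, si] <- suppressWarnings(
        stats::cor(profiles[ci, fams][use], tv[use], method = "spearman"))
    }
  sim[is.na(sim)] <- -1
  match_res <- best_injective_matching(sim, threshold)
  assignment <- rep("unassigned", nrow(profiles))
  names(assignment) <- rownames(profiles)
  for (k in seq_along(match_res))
    if (!is.na(match_res[k])) assignment[match_res[k]] <- names(match_res)[k]
  structure(list(assignment = assignment, similarity = sim,
                 evidence = profiles,
                 template_version = attr(templates, "template_version") %||%
                   "unversioned"),
            class = "state_assignment")
}

# Exact maximum-total-similarity injective matching of states to clusters:
# depth-first search over states with memoization on the used-cluster set.
# A state may stay unmatched (contributing 0) when no acceptable cluster
# remains; pairs below the threshold are never matched.
best_injective_matching <- function(sim, threshold) {
  states <- colnames(sim)
  clusters <- rownames(sim)
  memo <- new.env(hash = TRUE)
  solve <- function(si, used) {
    if (si > length(states)) return(list(value = 0, pick = integer(0)))
    key <- paste(si, paste(used, collapse = ","), sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- solve(si + 1L, used)                  # leave state unmatched
    best$pick <- c(NA_integer_, best$pick)
    for (ci in seq_along(clusters)) {
      if (used[ci] || sim[ci, si] < threshold) next
      used2 <- used; used2[ci] <- TRUE
      sub <- solve(si + 1L, used2)
      v <- sim[ci, si] + sub$value
      if (v > best$value) best <- list(value = v, pick = c(ci, sub$pick))
    }
    memo[[key]] <- best
    best
  }
  res <- solve(1L, rep(FALSE, length(clusters)))
  out <- ifelse(is.na(res$pick), NA_character_, clusters[res$pick])
  names(out) <- states
  out
}
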