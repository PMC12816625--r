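# End-to-end orchestration of the two analyses. Each stage's parameters are
# recorded in the bundle manifest so every emitted number is traceable.

#' Configuration for the end-to-end single-cell pipeline
#'
#' All stage parameters default to the published analysis settings: blank
#' fold 1.75 with granularity 50 and a 400-protein feature floor, 2000
#' variable features, 35 principal components, SNN k = 20, Leiden resolution
#' 1.45, marker fold-change threshold 0.25 with Bonferroni alpha 0.05.
#'
#' @param n_proteins Catalog size for the synthetic input.
#' @param generator An [scp_config()] (its `seed` is overridden by `seed`).
#' @param blank_fold,granularity,min_features Cell-QC parameters;
#'   `threshold_override` replaces the blank-derived threshold entirely.
#' @param n_features,n_pcs,k,resolution,tau Clustering parameters.
#' @param logfc_threshold,alpha Marker-test parameters.
#' @param compute_markers Run the (slower) marker stage.
#' @param seed Master seed for generation and clustering.
#' @return List of class `scp_pipeline_config`.
#' @export
scp_pipeline_config <- function(n_proteins = 3000L,
                                generator = scp_config(),
                                blank_fold = 1.75, granularity = 50L,
                                min_features = 400L,
                                threshold_override = NULL,
                                n_features = 2000L, n_pcs = 35L, k = 20L,
                                resolution = 1.45, tau = 5,
                                logfc_threshold = 0.25, alpha = 0.05,
                                compute_markers = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "scp_pipeline_config")
}

#' Run the single-cell pipeline end to end
#'
#' Stages: synthetic generation (or user input) -> blank-derived cell QC ->
#' molecular-weight-corrected riBAQ-like normalization -> log normalization
#' -> variable-feature selection -> PCA with batch integration -> SNN/Leiden
#' clustering -> (optional) logistic-regression markers -> family scoring ->
#' state assignment, with a cluster-proportion table.
#'
#' @param config An [scp_pipeline_config()].
#' @param input Optional list with `matrix` (an [intensity_matrix] including
#'   blank runs), `catalog` and optionally `truth`; when `NULL` a synthetic
#'   experiment is generated from `config`.
#' @return List of class `scp_bundle` with the artifacts of every stage and
#'   a `manifest` of stage parameters.
#' @export
run_scp_pipeline <- function(config = scp_pipeline_config(), input = NULL) {
  stopifnot(inherits(config, "scp_pipeline_config"))
  if (is.null(input)) {
    gen <- config$generator
    gen$seed <- config$seed
    catalog <- generate_protein_catalog(config$n_proteins, seed = config$seed)
    input <- generate_scp_experiment(catalog, gen)
    input$catalog <- catalog
  }
  catalog <- input$catalog
  counts <- count_identifications(input$matrix)
  blank_counts <- counts[input$matrix$runs$run[input$matrix$runs$class == "blank"]]
  threshold <- if (!is.null(config$threshold_override)) {
    config$threshold_override
  } else if (length(blank_counts)) {
    max(derive_blank_threshold(blank_counts, config$blank_fold,
                               config$granularity),
        config$min_features)
  } else config$min_features
  qc <- filter_cells(input$matrix, threshold)
  normalized <- compute_ribaq_like_scp(qc$matrix, catalog)
  logm <- log_normalize_cells(normalized)
  features <- select_variable_features(logm, min(config$n_features, nrow(logm)))
  batches <- stats::setNames(normalized$runs$batch, normalized$runs$run)
  n_pcs <- min(config$n_pcs, length(features) - 1L, ncol(logm) - 1L)
  depth <- colSums(logm > 0)
  embedding <- embed_and_integrate(logm, features, n_pcs, batches,
                                   tau = config$tau,
                                   covariates = cbind(depth, depth^2))
  labels <- cluster_cells(embedding, k = config$k,
                          resolution = config$resolution, seed = config$seed)
  markers <- if (isTRUE(config$compute_markers)) {
    out <- lapply(sort(unique(labels)), function(cl)
      find_markers(logm, labels, cl, config$logfc_threshold, config$alpha))
    names(out) <- as.character(sort(unique(labels)))
    out
  }
  scores <- score_families(normalized, catalog)
  profiles <- cluster_family_profiles(scores, labels)
  states <- assign_states(profiles)
  prop <- as.data.frame(table(cluster = labels), stringsAsFactors = FALSE)
  prop$state <- states$assignment[prop$cluster]
  prop$percent <- 100 * prop$Freq / sum(prop$Freq)
  names(prop)[names(prop) == "Freq"] <- "n_cells"
  manifest <- list(threshold = threshold, blank_max = qc$report$blank_max,
                   n_features = length(features), n_pcs = n_pcs,
                   k = config$k, resolution = config$resolution,
                   tau = config$tau, seed = config$seed,
                   registry_version = attr(scores, "registry_version"),
                   template_version = states$template_version,
                   median_mw_used = normalized$median_mw_used)
  structure(list(qc = qc$report, normalized = normalized,
                 features = features, embedding = embedding,
                 labels = labels, markers = markers,
                 family_scores = scores, profiles = profiles,
                 states = states, proportions = prop,
                 truth = input$truth, manifest = manifest),
            class = "scp_bundle")
}

#' Configuration for the end-to-end mini-bulk pipeline
#'
#' @param n_proteins Catalog size for the synthetic input.
#' @param generator A [minibulk_config()].
#' @param outlier_fold Identification-count outlier fold (default 10).
#' @param min_reps Replicate filter for differential testing.
#' @param q_cut Significance cutoff.
#' @param seed Master seed.
#' @return List of class `minibulk_pipeline_config`.
#' @export
minibulk_pipeline_config <- function(n_proteins = 3500L,
                                     generator = minibulk_config(),
                                     outlier_fold = 10, min_reps = 2L,
                                     q_cut = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "minibulk_pipeline_config")
}

#' Run the mini-bulk pipeline end to end
#'
#' Stages: synthetic generation (or user input) -> riBAQ normalization ->
#' identification-count outlier filtering -> PCA overview -> all pairwise
#' moderated-t contrasts with q-values -> family scoring -> maturity
#' signature from the mature-vs-immature contrast.
#'
#' @param config A [minibulk_pipeline_config()].
#' @param input Optional list with `matrix`, `catalog`, optionally `truth`.
#' @return List of class `minibulk_bundle`.
#' @export
run_minibulk_pipeline <- function(config = minibulk_pipeline_config(),
                                  input = NULL) {
  stopifnot(inherits(config, "minibulk_pipeline_config"))
  if (is.null(input)) {
    gen <- config$generator
    gen$seed <- config$seed
    catalog <- generate_protein_catalog(config$n_proteins, seed = config$seed)
    input <- generate_minibulk_experiment(catalog, gen)
    input$catalog <- catalog
  }
  catalog <- input$catalog
  counts <- count_identifications(input$matrix)
  groups <- stats::setNames(input$matrix$runs$group, input$matrix$runs$run)
  outliers <- detect_outlier_samples(counts, config$outlier_fold, groups)
  kept <- setdiff(names(counts), outliers)
  mat <- if (length(outliers)) subset_runs(input$matrix, kept) else input$matrix
  normalized <- compute_ribaq_minibulk(mat, catalog)
  pca <- pca_overview(normalized)
  group_levels <- unique(normalized$runs$group)
  pairs <- utils::combn(group_levels, 2, simplify = FALSE)
  contrasts <- lapply(pairs, function(pr) {
    res <- moderated_t_test(normalized, pr[1], pr[2],
                            eligible = filter_by_replication(normalized, pr[1],
                                                             pr[2],
                                                             config$min_reps))
    call_significant(res, config$q_cut)
  })
  names(contrasts) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  scores <- score_families(normalized, catalog)
  mature_vs_immature <- grep("NDN.CD10pos_vs_.*LDN.CD10neg|LDN.CD10neg_vs_.*NDN.CD10pos",
                             names(contrasts), value = TRUE)
  signature <- NULL
  key <- intersect(c("G.NDN.CD10pos_vs_G.LDN.CD10neg",
                     "G.LDN.CD10neg_vs_G.NDN.CD10pos"), names(contrasts))
  if (length(key)) {
    res <- contrasts[[key[1]]]
    if (key[1] == "G.LDN.CD10neg_vs_G.NDN.CD10pos") {
      res$log_fc <- -res$log_fc           # orient: positive = higher in mature
      res$t_mod <- -res$t_mod
    }
    signature <- derive_maturity_signature(res, catalog, config$q_cut)
  }
  manifest <- list(outlier_fold = config$outlier_fold,
                   min_reps = config$min_reps, q_cut = config$q_cut,
                   seed = config$seed, outliers = outliers,
                   registry_version = attr(scores, "registry_version"))
  structure(list(counts = counts, outliers = outliers,
                 normalized = normalized, pca = pca, contrasts = contrasts,
                 family_scores = scores, maturity_signature = signature,
                 truth = input$truth, manifest = manifest),
            class = "minibulk_bundle")
}

#' Write a JSON summary of a pipeline bundle
#'
#' @param bundle An `scp_bundle` or `minibulk_bundle`.
#' @param path Output JSON path.
#' @export
write_bundle_summary <- function(bundle, path) {
  summary <- if (inherits(bundle, "scp_bundle")) {
    list(kind = "scp", manifest = bundle$manifest,
         n_cells = length(bundle$labels),
         n_clusters = length(unique(bundle$labels)),
         proportions = bundle$proportions,
         states = as.list(bundle$states$assignment))
  } else {
    list(kind = "minibulk", manifest = bundle$manifest,
         n_runs = length(bundle$counts),
         n_contrasts = length(bundle$contrasts),
         n_significant = vapply(bundle$contrasts, function(cc)
           sum(cc$significant, na.rm = TRUE), numeric(1)))
  }
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
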