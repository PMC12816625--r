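# Intensity normalization (iBAQ/riBAQ and the molecular-weight-corrected
# single-cell variant) and histone-anchored proteomic-ruler copy numbers.

new_normalized_matrix <- function(values, runs, method, per_run_median,
                                  median_mw_used = NA_real_,
                                  excluded_runs = character(0)) {
  out <- intensity_matrix(values, runs)
  out$method <- method
  out$per_run_median <- per_run_median
  out$median_mw_used <- median_mw_used
  out$excluded_runs <- excluded_runs
  class(out) <- c("normalized_matrix", class(out))
  out
}

# Divide each run by the median of its nonzero values; zeros stay zero.
# Runs whose values are all zero are excluded (flagged, not an error).
scale_runs_to_unit_median <- function(values, runs, method, median_mw_used = NA_real_) {
  nonzero_median <- apply(values, 2, function(v) {
    v <- v[v > 0]
    if (!length(v)) NA_real_ else stats::median(v)
  })
  dead <- names(nonzero_median)[is.na(nonzero_median)]
  if (length(dead)) {
    warning("run(s) with no detected proteins excluded from normalization: ",
            paste(dead, collapse = ", "))
    keep <- setdiff(colnames(values), dead)
    values <- values[, keep, drop = FALSE]
    runs <- runs[runs$run %in% keep, , drop = FALSE]
    nonzero_median <- nonzero_median[keep]
  }
  if (!ncol(values)) stop("no runs with detected proteins")
  scaled <- sweep(values, 2, nonzero_median, "/")
  new_normalized_matrix(scaled, runs, method, nonzero_median, median_mw_used,
                        excluded_runs = dead)
}

#' riBAQ normalization for mini-bulk / bulk data
#'
#' iBAQ (intensity divided by the protein's theoretical tryptic peptide
#' count) followed by division of each run by the median of its nonzero iBAQ
#' values. After normalization every run's nonzero median equals 1; exact
#' zeros are preserved.
#'
#' @param matrix An [intensity_matrix].
#' @param catalog A [protein_catalog] resolving every matrix protein.
#' @return A `normalized_matrix` (method `"ribaq_minibulk"`).
#' @export
compute_ribaq_minibulk <- function(matrix, catalog) {
  idx <- match(rownames(matrix$values), catalog$protein_id)
  if (anyNA(idx))
    stop("protein(s) missing from catalog: ",
         paste(utils::head(rownames(matrix$values)[is.na(idx)]), collapse = ", "))
  ibaq <- matrix$values / catalog$n_theoretical_peptides[idx]
  scale_runs_to_unit_median(ibaq, matrix$runs, "ribaq_minibulk")
}

#' Molecular-weight-corrected riBAQ-like normalization for single cells
#'
#' Each intensity is multiplied by `median_MW / MW_protein`, where
#' `median_MW` is the median molecular weight over proteins detected
#' (nonzero in at least one run) in the input matrix — using the median
#' rather than the MW sum keeps the intensity scale in the original order of
#' magnitude. Each run is then divided by its nonzero median. The median MW
#' actually used is recorded (47,485 Da on the study's own detected
#' proteome); pass `median_mw_override` for exact replication against
#' published values.
#'
#' @param matrix An [intensity_matrix].
#' @param catalog A [protein_catalog] with molecular weights.
#' @param median_mw_override Optional fixed median MW (Da).
#' @return A `normalized_matrix` (method `"ribaq_like_scp"`) with
#'   `median_mw_used` recorded.
#' @export
compute_ribaq_like_scp <- function(matrix, catalog, median_mw_override = NULL) {
  idx <- match(rownames(matrix$values), catalog$protein_id)
  if (anyNA(idx))
    stop("protein(s) missing from catalog: ",
         paste(utils::head(rownames(matrix$values)[is.na(idx)]), collapse = ", "))
  mw <- catalog$molecular_weight[idx]
  detected <- rowSums(matrix$values > 0) > 0
  if (!any(detected)) stop("no detected proteins in matrix")
  med_mw <- if (is.null(median_mw_override)) stats::median(mw[detected])
            else median_mw_override
  corrected <- matrix$values * (med_mw / mw)
  scale_runs_to_unit_median(corrected, matrix$runs, "ribaq_like_scp", med_mw)
}

#' Histone proteomic-ruler copy numbers
#'
#' Anchors the summed histone MS signal to the DNA mass of a single cell:
#' `copies_i = intensity_i * N_A * m_DNA / (MW_i * sum(histone intensity))`
#' per run, with the per-protein copy number taken as the median across runs
#' (robust to a single outlier run). The default DNA mass is 6.5 pg, the
#' diploid human genome constant of the ruler method.
#'
#' @param bulk_matrix An [intensity_matrix] of bulk runs.
#' @param catalog A [protein_catalog] with histone flags and MWs.
#' @param dna_mass_pg DNA mass per cell in picograms (> 0).
#' @return List of class `copy_number_table`: `copies` (named per-protein
#'   copies/cell), `dna_mass_per_cell` (pg), `histone_signal_total` (summed
#'   histone intensity per run).
#' @export
proteomic_ruler <- function(bulk_matrix, catalog, dna_mass_pg = 6.5) {
  if (dna_mass_pg <= 0) stop("dna_mass_pg must be > 0")
  idx <- match(rownames(bulk_matrix$values), catalog$protein_id)
  if (anyNA(idx)) stop("protein(s) missing from catalog")
  mw <- catalog$molecular_weight[idx]
  hist_rows <- catalog$is_histone[idx]
  if (!any(hist_rows & rowSums(bulk_matrix$values > 0) > 0))
    stop("ruler undefined: no detected histone-flagged protein")
  avogadro <- 6.02214076e23
  hist_total <- colSums(bulk_matrix$values[hist_rows, , drop = FALSE])
  if (any(hist_total <= 0))
    stop("ruler undefined: run(s) with zero total histone signal: ",
         paste(colnames(bulk_matrix$values)[hist_total <= 0], collapse = ", "))
  dna_g <- dna_mass_pg * 1e-12
  per_run <- sweep(bulk_matrix$values, 2, hist_total, "/") *
    (avogadro * dna_g) / mw
  copies <- apply(per_run, 1, stats::median)
  structure(list(copies = copies, dna_mass_per_cell = dna_mass_pg,
                 histone_signal_total = hist_total),
            class = "copy_number_table")
}

#' Detection-sensitivity stratification by copy number
#'
#' For each workflow's detected protein set, the fraction of proteins whose
#' bulk-estimated copy number lies below a threshold, and the median copy
#' number of the detected set. The default threshold is the median copy
#' number over the bulk-detected set (~5500 copies in the study).
#'
#' @param copies A `copy_number_table` from [proteomic_ruler()].
#' @param detected_sets Named list: workflow -> character vector of detected
#'   protein ids (must be present in `copies`).
#' @param threshold Copy-number threshold; default the median over
#'   `detected_sets[["bulk"]]` if present, otherwise over all proteins.
#' @return Data frame with `workflow`, `fraction_below`, `median_copies`,
#'   `n_detected`, plus the `threshold` as an attribute.
#' @export
copy_number_coverage <- function(copies, detected_sets, threshold = NULL) {
  cn <- copies$copies
  for (w in names(detected_sets)) {
    if (!length(detected_sets[[w]]))
      stop("undefined fraction: empty detected set for workflow ", w)
    missing_p <- setdiff(detected_sets[[w]], names(cn))
    if (length(missing_p))
      stop("detected set for ", w, " contains proteins without copy estimates")
  }
  if (is.null(threshold)) {
    ref <- if ("bulk" %in% names(detected_sets))
      cn[detected_sets[["bulk"]]] else cn
    threshold <- stats::median(ref)
  }
  out <- do.call(rbind, lapply(names(detected_sets), function(w) {
    v <- cn[detected_sets[[w]]]
    data.frame(workflow = w, fraction_below = mean(v < threshold),
               median_copies = stats::median(v), n_detected = length(v),
               stringsAsFactors = FALSE)
  }))
  attr(out, "threshold") <- threshold
  out
}
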