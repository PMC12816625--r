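# Quality control: identification counting, blank-derived cell filtering,
# mini-bulk outlier detection and coefficient-of-variation profiling.

#' Count protein identifications per run
#'
#' An identification is a nonzero intensity.
#'
#' @param matrix An [intensity_matrix] (or `normalized_matrix`).
#' @return Named integer vector, run -> count.
#' @export
count_identifications <- function(matrix) {
  colSums(matrix$values > 0)
}

#' Derive the cell-QC threshold from blank (0-cell) runs
#'
#' `threshold = ceiling(fold * max(blank_counts) / granularity) * granularity`.
#' With the defaults (fold 1.75, granularity 50) a blank maximum of 228
#' identifications gives 1.75 x 228 = 399, rounded up to 400 — the study's
#' worked example. The rounding granularity is a documented convention (the
#' source states only "rounded up"); pass `granularity = 1` for plain
#' ceiling.
#'
#' @param blank_counts Identification counts of the blank runs (>= 1 value).
#' @param fold Fold factor over the blank maximum (> 1).
#' @param granularity Rounding granularity in proteins.
#' @return The threshold count.
#' @export
derive_blank_threshold <- function(blank_counts, fold = 1.75, granularity = 50L) {
  if (!length(blank_counts))
    stop("no blank counts supplied; set an explicit threshold instead")
  if (fold <= 1) stop("fold must be > 1")
  ceiling(fold * max(blank_counts) / granularity) * granularity
}

#' Filter cells by identification count
#'
#' Retains non-blank runs with at least `threshold` identified proteins
#' (cells with fewer are filtered out; a count exactly at the threshold is
#' kept). Blank runs are always excluded from the analysis set.
#'
#' @param matrix An [intensity_matrix].
#' @param threshold Minimum identification count (>= 0).
#' @return List: `matrix` (retained runs) and `report` (a `qc_report` with
#'   per-run counts, the threshold, and retained/excluded lists with
#'   reasons).
#' @export
filter_cells <- function(matrix, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  counts <- count_identifications(matrix)
  is_blank <- matrix$runs$class == "blank"
  names(is_blank) <- matrix$runs$run
  keep <- !is_blank[names(counts)] & counts >= threshold
  excluded <- data.frame(run = names(counts)[!keep],
                         reason = ifelse(is_blank[names(counts)][!keep],
                                         "blank run",
                                         sprintf("below threshold (%d < %d)",
                                                 counts[!keep], threshold)),
                         stringsAsFactors = FALSE)
  if (!any(keep))
    stop("all cells filtered at threshold ", threshold, "; count range ",
         paste(range(counts[!is_blank[names(counts)]]), collapse = "-"))
  report <- structure(list(per_run_protein_count = counts,
                           blank_max = if (any(is_blank))
                             max(counts[is_blank[names(counts)]]) else NA_integer_,
                           derived_threshold = threshold,
                           retained_runs = names(counts)[keep],
                           excluded_runs = excluded),
                      class = "qc_report")
  list(matrix = subset_runs(matrix, names(counts)[keep]), report = report)
}

#' Detect outlier samples by identification count
#'
#' A run is excluded when `count * fold < median(count of its group)` — with
#' the default fold of 10, a sample with 10-fold fewer identifications than
#' its group median is a clear outlier.
#'
#' @param counts Named run -> count vector (>= 3 runs).
#' @param fold Fold factor (default 10).
#' @param groups Optional named run -> group map; default one common group.
#' @return Character vector of excluded run names (possibly empty).
#' @export
detect_outlier_samples <- function(counts, fold = 10, groups = NULL) {
  if (length(counts) < 3) stop("need >= 3 runs for outlier detection")
  if (is.null(groups))
    groups <- stats::setNames(rep("all", length(counts)), names(counts))
  med <- tapply(counts, groups[names(counts)], stats::median)
  names(counts)[counts * fold < med[groups[names(counts)]]]
}

#' Per-protein coefficient of variation by population
#'
#' CV% = 100 * sd / mean over each protein's values within a population's
#' runs, computed on normalized intensities with zeros included (all
#' proteins enter the calculation; nothing is filtered). Sample (n-1)
#' standard deviation is used. Proteins with zero mean in a population are
#' reported as `NaN`, not dropped. Populations with a single run are omitted
#' with a warning.
#'
#' @param normalized A `normalized_matrix`.
#' @param populations Named run -> group map covering the matrix runs.
#' @return Numeric matrix proteins x populations of CV percentages.
#' @export
compute_cv <- function(normalized, populations) {
  runs <- colnames(normalized$values)
  pops <- populations[runs]
  if (anyNA(pops)) stop("populations must cover every run")
  tab <- table(pops)
  singletons <- names(tab)[tab < 2]
  if (length(singletons))
    warning("population(s) with a single run omitted: ",
            paste(singletons, collapse = ", "))
  use <- setdiff(names(tab), singletons)
  out <- vapply(use, function(g) {
    v <- normalized$values[, pops == g, drop = FALSE]
    100 * apply(v, 1, stats::sd) / rowMeans(v)
  }, numeric(nrow(normalized$values)))
  matrix(out, nrow = nrow(normalized$values),
         dimnames = list(rownames(normalized$values), use))
}
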