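#' Intensity matrix container
#'
#' A protein-by-run matrix of nonnegative intensities in arbitrary units,
#' where an exact zero means "not detected", together with one annotation
#' record per run (subject, group, run class and batch).
#'
#' @param values Numeric matrix, proteins in rows, runs in columns. Row names
#'   are protein identifiers, column names are run names.
#' @param runs Data frame with columns `run`, `subject`, `group`, `class`
#'   (one of `"bulk"`, `"minibulk"`, `"single"`, `"blank"`) and `batch`.
#'   Exactly one row per column of `values`.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` and `runs`.
#' @export
intensity_matrix <- function(values, runs) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values) || any(values < 0))
    stop("intensities must be nonnegative with 0 (not NA) meaning undetected")
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  needed <- c("run", "subject", "group", "class", "batch")
  missing_cols <- setdiff(needed, names(runs))
  if (length(missing_cols))
    stop("run annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(colnames(values)))
    stop("`values` must carry run names as column names")
  if (!setequal(colnames(values), runs$run) || ncol(values) != nrow(runs))
    stop("every run must have exactly one annotation record; unannotated: ",
         paste(setdiff(colnames(values), runs$run), collapse = ", "))
  runs <- runs[match(colnames(values), runs$run), , drop = FALSE]
  rownames(runs) <- NULL
  bad_class <- setdiff(unique(runs$class), c("bulk", "minibulk", "single", "blank"))
  if (length(bad_class))
    stop("unknown run class: ", paste(bad_class, collapse = ", "))
  structure(list(values = values, runs = runs), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d runs (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$runs$class)),
                            as.integer(table(x$runs$class))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

# Subset an intensity matrix by run names (annotations follow).
subset_runs <- function(x, run_names) {
  intensity_matrix(x$values[, run_names, drop = FALSE],
                   x$runs[x$runs$run %in% run_names, , drop = FALSE])
}

#' Construct a protein catalog
#'
#' Per-protein identity and physico-chemical metadata used throughout the
#' pipeline: molecular weight (average mass), theoretical tryptic peptide
#' count (the iBAQ denominator), protein-family tags and histone/contaminant
#' flags.
#'
#' @param protein_id Character vector of unique accessions.
#' @param gene_symbol Character vector of gene symbols.
#' @param molecular_weight Positive numeric, Daltons.
#' @param n_theoretical_peptides Integer counts, at least 1.
#' @param families List of character vectors of family tags (one per protein),
#'   or a character vector for single-family membership ("" = none).
#' @param is_histone,is_contaminant Logical flags.
#' @return A data frame of class `protein_catalog` with a list-column
#'   `families`.
#' @export
protein_catalog <- function(protein_id, gene_symbol, molecular_weight,
                            n_theoretical_peptides,
                            families = vector("list", length(protein_id)),
                            is_histone = FALSE, is_contaminant = FALSE) {
  if (anyDuplicated(protein_id))
    stop("duplicate protein_id in catalog: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  if (any(!is.finite(molecular_weight)) || any(molecular_weight <= 0))
    stop("molecular_weight must be positive and finite")
  if (any(n_theoretical_peptides < 1))
    stop("n_theoretical_peptides must be >= 1")
  if (is.character(families))
    families <- lapply(families, function(f) f[nzchar(f)])
  out <- data.frame(protein_id = as.character(protein_id),
                    gene_symbol = as.character(gene_symbol),
                    molecular_weight = as.numeric(molecular_weight),
                    n_theoretical_peptides = as.integer(n_theoretical_peptides),
                    is_histone = rep_len(as.logical(is_histone), length(protein_id)),
                    is_contaminant = rep_len(as.logical(is_contaminant), length(protein_id)),
                    stringsAsFactors = FALSE)
  out$families <- families
  class(out) <- c("protein_catalog", "data.frame")
  out
}

#' @export
print.protein_catalog <- function(x, ...) {
  cat(sprintf("<protein_catalog> %d proteins, %d histone(s), %d contaminant(s)\n",
              nrow(x), sum(x$is_histone), sum(x$is_contaminant)))
  invisible(x)
}

#' Family membership of a catalog as a long table
#'
#' @param catalog A [protein_catalog].
#' @return Data frame with columns `gene_symbol`, `protein_id`, `family`
#'   (one row per membership).
#' @export
catalog_family_table <- function(catalog) {
  n <- lengths(catalog$families)
  data.frame(gene_symbol = rep(catalog$gene_symbol, n),
             protein_id = rep(catalog$protein_id, n),
             family = unlist(catalog$families, use.names = FALSE),
             stringsAsFactors = FALSE)
}
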