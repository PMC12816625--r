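# Reading the standard formats: FASTA -> protein catalog (molecular weights,
# theoretical tryptic peptide counts), search-engine protein-group pivot
# reports -> intensity matrices, and two-column family annotation tables.

# ExPASy average residue masses (Da); a peptide bond has already condensed
# out one water per residue, so chain mass = sum(residues) + one water.
.aa_average_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01528

#' Average-mass molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water. Non-canonical residues are
#' handled by convention: B averages N/D, Z averages E/Q, X (and U) contribute
#' the mean canonical residue mass.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Numeric vector of molecular weights in Daltons.
#' @export
protein_mw <- function(sequence) {
  lookup <- c(.aa_average_mass,
              B = mean(.aa_average_mass[c("N", "D")]),
              Z = mean(.aa_average_mass[c("E", "Q")]),
              X = mean(.aa_average_mass),
              U = mean(.aa_average_mass))
  vapply(sequence, function(s) {
    if (!nzchar(s)) stop("empty sequence")
    aa <- strsplit(toupper(s), "")[[1]]
    m <- lookup[aa]
    if (anyNA(m))
      stop("unknown residue(s): ", paste(unique(aa[is.na(m)]), collapse = ", "))
    sum(m) + .water_mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count theoretical tryptic peptides of a sequence
#'
#' In-silico digestion with the Trypsin/P rule (cleave after every K or R,
#' including before proline), zero missed cleavages, retaining peptides whose
#' length falls inside `length_range`. This is the iBAQ denominator.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param length_range Length-2 integer vector, inclusive peptide length
#'   window (default 7--30, the common iBAQ convention).
#' @return Integer vector of peptide counts.
#' @export
digest_peptide_count <- function(sequence, length_range = c(7L, 30L)) {
  vapply(sequence, function(s) {
    pep <- tryptic_peptides(s)
    n <- nchar(pep)
    sum(n >= length_range[1] & n <= length_range[2])
  }, integer(1), USE.NAMES = FALSE)
}

# All fully-cleaved Trypsin/P peptides of a sequence (no length filter).
tryptic_peptides <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  cut_after <- which(aa %in% c("K", "R"))
  bounds <- unique(c(0L, cut_after, length(aa)))
  starts <- utils::head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  substring(sequence, starts, ends)
}

#' Build a protein catalog from a FASTA database
#'
#' Reads a (optionally gzipped) protein FASTA, computes average-mass molecular
#' weights and theoretical tryptic peptide counts, and flags contaminant
#' records by a header prefix. UniProt-style headers
#' (`db|ACCESSION|NAME GN=SYMBOL`) are understood; otherwise the first
#' whitespace-delimited token is the accession.
#'
#' @param fasta_source Path to a FASTA file (gzip accepted).
#' @param length_range Peptide-length window for theoretical counting.
#' @param contaminant_prefix Header prefix flagging contaminant records
#'   (default `"CON__"`).
#' @return A [protein_catalog].
#' @export
read_fasta_catalog <- function(fasta_source, length_range = c(7L, 30L),
                               contaminant_prefix = "CON__") {
  seqs <- Biostrings::readAAStringSet(fasta_source)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", fasta_source)
  headers <- names(seqs)
  sequence <- as.character(seqs)
  if (any(!nzchar(sequence))) stop("FASTA record with empty sequence")
  first_tok <- sub("\\s.*$", "", headers)
  is_contam <- startsWith(first_tok, contaminant_prefix)
  stripped <- sub(paste0("^", contaminant_prefix), "", first_tok)
  acc <- ifelse(grepl("\\|", stripped),
                vapply(strsplit(stripped, "\\|"), function(p)
                  if (length(p) >= 2) p[2] else p[1], character(1)),
                stripped)
  gene <- ifelse(grepl("GN=", headers),
                 sub("^.*GN=([^ ]+).*$", "\\1", headers), acc)
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  protein_catalog(protein_id = acc, gene_symbol = gene,
                  molecular_weight = protein_mw(sequence),
                  n_theoretical_peptides = pmax(1L, digest_peptide_count(sequence, length_range)),
                  is_histone = grepl("^(H1-|H2A|H2B|H3|H4|HIST)", gene),
                  is_contaminant = is_contam)
}

#' Read a wide protein-group report into an intensity matrix
#'
#' Ingests the tab-separated pivot report of a DIA search engine: one protein
#' identifier column plus one quantity column per run. Non-numeric or absent
#' quantities become 0 (not detected); row order is preserved; run annotations
#' are joined by run name.
#'
#' @param table_source Path to a tab-separated report (gzip accepted).
#' @param annotations Data frame with columns `run`, `subject`, `group`,
#'   `class`, `batch` covering every quantity column.
#' @param id_column Name of the protein-identifier column (default the first
#'   column).
#' @param catalog Optional [protein_catalog]; when given together with
#'   `drop_contaminants = TRUE`, contaminant-flagged rows are removed.
#' @param drop_contaminants Drop rows flagged as contaminants in `catalog`.
#' @return An [intensity_matrix].
#' @export
read_protein_report <- function(table_source, annotations, id_column = NULL,
                                catalog = NULL, drop_contaminants = FALSE) {
  tab <- utils::read.delim(table_source, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("report needs an identifier column and >=1 quantity column")
  if (is.null(id_column)) id_column <- names(tab)[1]
  if (!id_column %in% names(tab)) stop("identifier column not found: ", id_column)
  ids <- as.character(tab[[id_column]])
  qcols <- setdiff(names(tab), id_column)
  vals <- vapply(qcols, function(cn) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    v[is.na(v)] <- 0
    v
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, qcols))
  if (any(vals < 0)) stop("negative quantity in report")
  unannotated <- setdiff(qcols, annotations$run)
  if (length(unannotated))
    stop("no annotation for run(s): ", paste(unannotated, collapse = ", "))
  if (drop_contaminants && !is.null(catalog)) {
    bad <- catalog$protein_id[catalog$is_contaminant]
    vals <- vals[!rownames(vals) %in% bad, , drop = FALSE]
  }
  intensity_matrix(vals, annotations[annotations$run %in% qcols, , drop = FALSE])
}

#' Write an intensity matrix as a wide tab-separated report
#'
#' Inverse of [read_protein_report()]: rows are protein groups, columns runs.
#' The run annotation table is written alongside as `<path>.annotations.tsv`
#' unless `annotations_path = NULL`.
#'
#' @param x An [intensity_matrix].
#' @param path Output path for the wide table.
#' @param annotations_path Output path for the annotation table (default
#'   derived from `path`; `NULL` skips it).
#' @export
write_intensity_matrix <- function(x, path,
                                   annotations_path = paste0(path, ".annotations.tsv")) {
  df <- data.frame(protein_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotations_path))
    utils::write.table(x$runs, annotations_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a two-column protein-family annotation table
#'
#' Tab-separated, two columns per line: gene symbol, family tag. A symbol may
#' appear under several families; symbols unknown to any catalog are retained
#' and matched lazily at scoring time.
#'
#' @param table_source Path (gzip accepted).
#' @return Named list mapping family tag to a character vector of symbols.
#' @export
read_family_table <- function(table_source) {
  lines <- readLines(table_source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed family table line ", bad[1], ": ", lines[bad[1]])
  sym <- vapply(parts, `[`, character(1), 1L)
  fam <- vapply(parts, `[`, character(1), 2L)
  if (sym[1] %in% c("gene_symbol", "symbol", "gene")) { # header row
    sym <- sym[-1]; fam <- fam[-1]
  }
  split(sym, fam)
}
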