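# Synthetic-data generator: protein catalogs plus single-cell, mini-bulk and
# blank (0-cell) intensity matrices with known ground truth. The generative
# model is multiplicative on the intensity scale:
#
#   mu[protein, run] = baseline * state/group family factor * batch factor
#                      * per-(batch, protein) minor factor * run depth factor
#
# with detection sampled from a logistic curve in log10(mu) (two parameters:
# midpoint and slope), observed intensities log-normal around mu, and exact
# zeros for undetected entries. Blanks are low-count background runs drawn
# from the most abundant proteins.

# Fig-legend cluster sizes of the seven functional states (n = 279).
.state_counts <- c(armed = 76, engaged = 46, vital_NETs = 33, exhausted = 47,
                   lytic_NETs = 32, immunosuppressive_angiogenic = 23,
                   vascular_immature = 22)

#' Default per-state protein-family effect table (single cell)
#'
#' Multiplicative factors applied to family members' expected intensities in
#' each functional state, relative to the armed/baseline proteome. Factors
#' printed as percentages in the source figures are carried exactly
#' (`source = "printed"`): azurophilic granules x0.20, histones x0.17 and
#' nuclear membrane x0.15 in lytic NETs (80/83/85% reductions). All other
#' directions are only shown qualitatively in dot plots, and are encoded as
#' +/-50% by default (`source = "qualitative"`).
#'
#' @return Data frame with columns `state`, `family`, `factor`, `source`.
#' @export
default_state_effects <- function() {
  eff <- function(state, family, factor, source = "qualitative")
    data.frame(state = state, family = family, factor = factor,
               source = source, stringsAsFactors = FALSE)
  rbind(
    eff("armed", "cytoskeleton", 1.5),
    eff("engaged", "azurophilic_granule", 0.5),
    eff("engaged", "specific_granule", 0.5),
    eff("engaged", "ficolin_granule", 0.6),
    eff("engaged", "secretory_vesicle", 0.6),
    eff("vital_NETs", "azurophilic_granule", 0.35),
    eff("vital_NETs", "specific_granule", 0.35),
    eff("vital_NETs", "ficolin_granule", 0.35),
    eff("vital_NETs", "secretory_vesicle", 0.35),
    eff("vital_NETs", "histones", 0.4),
    eff("vital_NETs", "nuclear_membrane", 0.5),
    eff("vital_NETs", "cell_membrane", 0.5),
    eff("exhausted", "azurophilic_granule", 0.5),
    eff("exhausted", "specific_granule", 0.5),
    eff("exhausted", "ficolin_granule", 0.5),
    eff("exhausted", "secretory_vesicle", 0.5),
    eff("exhausted", "glycolysis_glycogenolysis_ppp", 0.35),
    eff("lytic_NETs", "azurophilic_granule", 0.20, "printed"),
    eff("lytic_NETs", "histones", 0.17, "printed"),
    eff("lytic_NETs", "nuclear_membrane", 0.15, "printed"),
    eff("lytic_NETs", "specific_granule", 0.2),
    eff("lytic_NETs", "ficolin_granule", 0.2),
    eff("lytic_NETs", "secretory_vesicle", 0.2),
    eff("lytic_NETs", "cell_membrane", 0.5),
    eff("lytic_NETs", "glycolysis_glycogenolysis_ppp", 0.5),
    eff("lytic_NETs", "complement_coagulation", 1.5),
    eff("immunosuppressive_angiogenic", "ia_markers", 2.0),
    eff("immunosuppressive_angiogenic", "lysosome", 1.5),
    eff("immunosuppressive_angiogenic", "proteasome_20S", 1.5),
    eff("immunosuppressive_angiogenic", "immunoglobulins", 1.5),
    eff("immunosuppressive_angiogenic", "desmosome", 1.5),
    eff("immunosuppressive_angiogenic", "maturity_markers", 0.5),
    eff("vascular_immature", "ribosomal_40S", 1.5),
    eff("vascular_immature", "ribosomal_60S", 1.5),
    eff("vascular_immature", "electron_transport_chain", 1.5),
    eff("vascular_immature", "mitochondrial_membrane", 1.5),
    eff("vascular_immature", "mitochondrial_metabolism", 1.5),
    eff("vascular_immature", "dna_replication", 2.0),
    eff("vascular_immature", "complement_coagulation", 1.5),
    eff("vascular_immature", "maturity_markers", 0.5)
  )
}

#' Default per-group family effect table (mini-bulk)
#'
#' The immature LDN CD10- group carries the printed ribosome (+330%, factor
#' 4.3) and electron-transport-chain (+165%, factor 2.65) increases relative
#' to the mature groups; TANs carry a qualitative intermediate mitochondrial
#' increase.
#'
#' @return Data frame with columns `group`, `family`, `factor`, `source`.
#' @export
default_minibulk_effects <- function() {
  eff <- function(group, family, factor, source = "qualitative")
    data.frame(group = group, family = family, factor = factor,
               source = source, stringsAsFactors = FALSE)
  rbind(
    eff("G.LDN.CD10neg", "ribosomal_40S", 4.3, "printed"),
    eff("G.LDN.CD10neg", "ribosomal_60S", 4.3, "printed"),
    eff("G.LDN.CD10neg", "electron_transport_chain", 2.65, "printed"),
    eff("G.LDN.CD10neg", "dna_replication", 2.0),
    eff("G.LDN.CD10neg", "maturity_markers", 0.5),
    eff("TAN", "mitochondrial_membrane", 1.5),
    eff("TAN", "mitochondrial_metabolism", 1.5)
  )
}

# Default family composition of a generated catalog (fractions of proteins).
.default_family_fractions <- c(
  azurophilic_granule = 0.020, specific_granule = 0.015,
  ficolin_granule = 0.010, secretory_vesicle = 0.015, histones = 0.0033,
  nuclear_membrane = 0.015, cell_membrane = 0.030, ribosomal_40S = 0.011,
  ribosomal_60S = 0.013, electron_transport_chain = 0.020,
  mitochondrial_membrane = 0.015, mitochondrial_metabolism = 0.020,
  complement_coagulation = 0.015, lysosome = 0.015, proteasome_20S = 0.0047,
  immunoglobulins = 0.010, desmosome = 0.005, cytoskeleton = 0.030,
  glycolysis_glycogenolysis_ppp = 0.015, dna_replication = 0.010,
  maturity_markers = 0.0023, ia_markers = 0.0013)

# Baseline-abundance boosts: granule proteins and histones sit far above the
# proteome median in neutrophils; everything unlisted is x1.
.family_abundance_boost <- c(
  histones = 60, azurophilic_granule = 8, specific_granule = 8,
  ficolin_granule = 6, secretory_vesicle = 6, maturity_markers = 20,
  cytoskeleton = 6, glycolysis_glycogenolysis_ppp = 4, ribosomal_40S = 3,
  ribosomal_60S = 3, electron_transport_chain = 2,
  mitochondrial_membrane = 2, mitochondrial_metabolism = 2,
  complement_coagulation = 2, lysosome = 2, proteasome_20S = 2,
  ia_markers = 2)

#' Generate a synthetic protein catalog
#'
#' Draws molecular weights log-normally around a configurable median (default
#' 47,485 Da, the median MW of the detected neutrophil proteome), theoretical
#' peptide counts roughly proportional to size, and baseline abundances
#' log-normal over copies per cell (median 5500 copies before family boosts,
#' spanning roughly 10^3--10^7). Family members receive real marker gene
#' symbols from the shipped registry first, then systematic synthetic
#' symbols. At least four proteins are always flagged as histones.
#'
#' @param n_proteins Number of proteins (>= 20).
#' @param family_spec Named numeric of per-family fractions in [0,1], summing
#'   to at most 1; remainder is unassigned. Defaults to the registry families
#'   at realistic neutrophil proportions.
#' @param seed Integer seed; same seed gives a byte-identical catalog.
#' @param median_mw Median molecular weight in Da.
#' @param mw_sdlog Log-scale SD of the MW distribution.
#' @param median_copies Median baseline copies per cell (before boosts).
#' @param copies_sdlog10 SD of log10 baseline copies.
#' @return A [protein_catalog] with an extra generator column
#'   `baseline_copies` (expected copies per cell).
#' @export
generate_protein_catalog <- function(n_proteins,
                                     family_spec = .default_family_fractions,
                                     seed = 1L,
                                     median_mw = 47485,
                                     mw_sdlog = 0.35,
                                     median_copies = 5500,
                                     copies_sdlog10 = 0.9) {
  if (n_proteins < 20)
    stop("invalid config: n_proteins must be >= 20 to place all mandatory families")
  if (any(family_spec < 0) || any(family_spec > 1) || sum(family_spec) > 1)
    stop("invalid config: family fractions must lie in [0,1] and sum to <= 1")
  set.seed(seed)
  counts <- round(family_spec * n_proteins)
  counts <- counts[counts > 0]
  n_hist <- max(4L, if ("histones" %in% names(counts)) counts[["histones"]] else 0L)
  if (sum(counts[names(counts) != "histones"]) + n_hist > n_proteins)
    stop("invalid config: family fractions leave no room for mandatory histones")
  if ("histones" %in% names(counts)) counts[["histones"]] <- n_hist

  fam_assign <- rep("", n_proteins)
  pos <- 1L
  for (fam in names(counts)) {
    fam_assign[pos:(pos + counts[[fam]] - 1L)] <- fam
    pos <- pos + counts[[fam]]
  }
  is_histone <- rep(FALSE, n_proteins)
  if (!"histones" %in% names(counts)) {
    # mandatory histone flags without a family tag (empty family_spec case)
    is_histone[pos:(pos + n_hist - 1L)] <- TRUE
    hist_rows <- which(is_histone)
  } else {
    is_histone[fam_assign == "histones"] <- TRUE
    hist_rows <- which(is_histone)
  }

  seeds <- .family_seed_symbols
  gene_symbol <- character(n_proteins)
  for (fam in unique(fam_assign[nzchar(fam_assign)])) {
    rows <- which(fam_assign == fam)
    pool <- if (!is.null(seeds[[fam]])) seeds[[fam]] else character(0)
    k <- min(length(pool), length(rows))
    syms <- c(pool[seq_len(k)],
              if (length(rows) > k)
                sprintf("%s.%03d", toupper(fam), seq_len(length(rows) - k) + k))
    gene_symbol[rows] <- syms
  }
  free <- which(!nzchar(gene_symbol))
  gene_symbol[free] <- sprintf("PROT%04d", seq_along(free))
  if (!"histones" %in% names(counts))
    gene_symbol[hist_rows] <- .family_seed_symbols$histones[seq_len(n_hist)]

  mw <- stats::rlnorm(n_proteins, meanlog = log(median_mw), sdlog = mw_sdlog)
  npep <- pmax(1L, stats::rpois(n_proteins, lambda = mw / 1800))
  boost <- ifelse(nzchar(fam_assign) & fam_assign %in% names(.family_abundance_boost),
                  .family_abundance_boost[fam_assign], 1)
  boost[is.na(boost)] <- 1
  copies <- 10^stats::rnorm(n_proteins, mean = log10(median_copies),
                            sd = copies_sdlog10) * boost

  cat <- protein_catalog(protein_id = sprintf("SYN%05d", seq_len(n_proteins)),
                         gene_symbol = gene_symbol,
                         molecular_weight = mw,
                         n_theoretical_peptides = npep,
                         families = fam_assign,
                         is_histone = is_histone)
  cat$baseline_copies <- copies
  cat
}

# ---- generator configs -----------------------------------------------------

validate_generator_config <- function(config, effects_col, group_col) {
  eff <- config$family_effects
  if (any(eff$factor <= 0)) stop("invalid config: all family factors must be > 0")
  if (config$dropout_slope <= 0) stop("invalid config: dropout_slope must be > 0")
  invisible(config)
}

#' Configuration for the single-cell generator
#'
#' Defaults reproduce the study conditions: 300 tumour-associated
#' neutrophils across 6 patients with 12 blank (0-cell) runs, seven
#' functional states at the published cluster proportions, the printed family
#' effects of [default_state_effects()], and a dropout curve calibrated so a
#' 3000-protein catalog yields a median of about 1100 detected proteins per
#' cell. `dropout_midpoint = -Inf` disables dropout entirely.
#'
#' @param n_cells,n_blanks,n_patients Experiment layout.
#' @param state_proportions Named fractions summing to 1 (within 1e-9).
#' @param family_effects Data frame `state`, `family`, `factor`.
#' @param batch_sd Log-scale SD of the shared per-patient factor (a minor
#'   per-(patient, protein) term uses `batch_sd / 4`).
#' @param dropout_midpoint log10 expected intensity at 50% detection.
#' @param dropout_slope Logistic scale (log10 units), > 0.
#' @param depth_cv Coefficient of variation of the per-run depth factor.
#' @param meas_sd Log-scale SD of measurement noise around mu.
#' @param blank_max_count Identification ceiling of the blank background;
#'   the default 228 makes the blank-derived QC threshold round to 400.
#' @param seed Integer seed.
#' @return A list of class `scp_config`.
#' @export
scp_config <- function(n_cells = 300L, n_blanks = 12L, n_patients = 6L,
                       state_proportions = .state_counts / sum(.state_counts),
                       family_effects = default_state_effects(),
                       batch_sd = 0.2,
                       dropout_midpoint = SCP_DROPOUT_MIDPOINT,
                       dropout_slope = 0.45,
                       depth_cv = 0.3,
                       meas_sd = 0.35,
                       blank_max_count = 228L,
                       seed = 1L) {
  if (abs(sum(state_proportions) - 1) > 1e-9)
    stop("invalid config: state_proportions must sum to 1")
  missing_states <- setdiff(unique(family_effects$state), names(state_proportions))
  if (length(missing_states))
    stop("invalid config: family_effects states missing from state_proportions: ",
         paste(missing_states, collapse = ", "))
  config <- structure(list(n_cells = n_cells, n_blanks = n_blanks,
                           n_patients = n_patients,
                           state_proportions = state_proportions,
                           family_effects = family_effects,
                           batch_sd = batch_sd,
                           dropout_midpoint = dropout_midpoint,
                           dropout_slope = dropout_slope,
                           depth_cv = depth_cv, meas_sd = meas_sd,
                           blank_max_count = blank_max_count,
                           seed = seed),
                      class = "scp_config")
  validate_generator_config(config)
}

#' Configuration for the mini-bulk generator
#'
#' Defaults: the five-group design (healthy-control NDN CD10+, patient NDN
#' CD10+, LDN CD10+, LDN CD10-, TAN) with 6 subjects per group, weak dropout
#' (median detected >= 3000 proteins per sample on the default catalog), the
#' printed immature-group effects, and a larger depth CV for the TAN group
#' (higher within-population variation).
#'
#' @param groups Group labels (must contain `contrast` groups used later).
#' @param n_subjects Subjects per group (>= 2 each).
#' @param family_effects Data frame `group`, `family`, `factor`.
#' @param group_depth_cv Named per-group depth CV override.
#' @inheritParams scp_config
#' @return A list of class `minibulk_config`.
#' @export
minibulk_config <- function(groups = c("C.NDN.CD10pos", "G.NDN.CD10pos",
                                       "G.LDN.CD10pos", "G.LDN.CD10neg", "TAN"),
                            n_subjects = 6L,
                            family_effects = default_minibulk_effects(),
                            batch_sd = 0.15,
                            dropout_midpoint = MINIBULK_DROPOUT_MIDPOINT,
                            dropout_slope = 0.45,
                            depth_cv = 0.2,
                            group_depth_cv = c(TAN = 0.5),
                            meas_sd = 0.2,
                            seed = 1L) {
  n_subjects <- rep_len(as.integer(n_subjects), length(groups))
  names(n_subjects) <- groups
  if (any(n_subjects < 2))
    stop("invalid config: every group needs >= 2 subjects (replicates)")
  missing_groups <- setdiff(unique(family_effects$group), groups)
  if (length(missing_groups))
    stop("invalid config: family_effects groups not in design: ",
         paste(missing_groups, collapse = ", "))
  config <- structure(list(groups = groups, n_subjects = n_subjects,
                           family_effects = family_effects,
                           batch_sd = batch_sd,
                           dropout_midpoint = dropout_midpoint,
                           dropout_slope = dropout_slope,
                           depth_cv = depth_cv,
                           group_depth_cv = group_depth_cv,
                           meas_sd = meas_sd, seed = seed),
                      class = "minibulk_config")
  validate_generator_config(config)
}

# ---- shared machinery ------------------------------------------------------

# Per-protein multiplicative factor matrix (proteins x conditions) from a
# long effect table; factor 1 wherever no effect is declared. Proteins in
# several affected families multiply their factors.
effect_factor_matrix <- function(catalog, effects, condition_col, conditions) {
  f <- matrix(1, nrow = nrow(catalog), ncol = length(conditions),
              dimnames = list(catalog$protein_id, conditions))
  fam_of <- catalog$families
  for (j in seq_len(nrow(effects))) {
    cond <- effects[[condition_col]][j]
    if (!cond %in% conditions) next
    hit <- vapply(fam_of, function(ff) effects$family[j] %in% ff, logical(1))
    f[hit, cond] <- f[hit, cond] * effects$factor[j]
  }
  f
}

# Detection probability: logistic in log10 expected intensity. Monotone
# non-decreasing in mu by construction.
detection_probability <- function(mu, midpoint, slope) {
  if (identical(midpoint, -Inf)) return(ifelse(mu > 0, 1, 0))
  stats::plogis((log10(pmax(mu, .Machine$double.xmin)) - midpoint) / slope)
}

lognormal_depth <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# Baseline expected intensity: copies x molecular weight (arbitrary units;
# downstream normalization is scale-invariant so the absolute scale is moot).
baseline_intensity <- function(catalog) {
  if (is.null(catalog$baseline_copies))
    stop("catalog lacks generator baseline abundances; use generate_protein_catalog()")
  catalog$baseline_copies * catalog$molecular_weight
}

sample_observed <- function(mu, p_detect, meas_sd) {
  detected <- stats::runif(length(mu)) < p_detect
  noise <- if (meas_sd > 0)
    stats::rlnorm(length(mu), meanlog = -meas_sd^2 / 2, sdlog = meas_sd)
  else 1
  ifelse(detected, mu * noise, 0)
}

# ---- experiment generators -------------------------------------------------

#' Generate a synthetic single-cell experiment with blanks
#'
#' @param catalog A generated [protein_catalog] (with `baseline_copies`).
#' @param config An [scp_config()].
#' @return List with elements `matrix` (an [intensity_matrix] of single-cell
#'   and blank runs) and `truth` (cell states, cell patients, the configured
#'   family effects, and baseline abundances).
#' @export
generate_scp_experiment <- function(catalog, config = scp_config()) {
  stopifnot(inherits(config, "scp_config"))
  known_fams <- unique(unlist(catalog$families))
  missing_f <- setdiff(unique(config$family_effects$family), known_fams)
  if (length(missing_f))
    stop("catalog does not cover family_effects families: ",
         paste(missing_f, collapse = ", "))
  set.seed(config$seed)
  n <- nrow(catalog)
  states <- names(config$state_proportions)
  cell_state <- sample(states, config$n_cells, replace = TRUE,
                       prob = config$state_proportions)
  patients <- paste0("P", seq_len(config$n_patients))
  cell_patient <- sample(rep_len(patients, config$n_cells))
  base <- baseline_intensity(catalog)
  sf <- effect_factor_matrix(catalog, config$family_effects, "state", states)
  batch_major <- stats::rlnorm(config$n_patients, 0, config$batch_sd)
  names(batch_major) <- patients
  batch_minor <- matrix(stats::rlnorm(n * config$n_patients, 0, config$batch_sd / 4),
                        nrow = n, dimnames = list(catalog$protein_id, patients))
  depth <- lognormal_depth(config$n_cells, config$depth_cv)

  cells <- sprintf("cell%03d", seq_len(config$n_cells))
  vals <- matrix(0, nrow = n, ncol = config$n_cells,
                 dimnames = list(catalog$protein_id, cells))
  for (c_i in seq_len(config$n_cells)) {
    mu <- base * sf[, cell_state[c_i]] *
      batch_major[cell_patient[c_i]] * batch_minor[, cell_patient[c_i]] *
      depth[c_i]
    p <- detection_probability(mu, config$dropout_midpoint, config$dropout_slope)
    vals[, c_i] <- sample_observed(mu, p, config$meas_sd)
  }

  runs <- data.frame(run = cells, subject = cell_patient, group = "TAN",
                     class = "single", batch = cell_patient,
                     stringsAsFactors = FALSE)

  if (config$n_blanks > 0) {
    blanks <- sprintf("blank%02d", seq_len(config$n_blanks))
    bcounts <- c(config$blank_max_count,
                 if (config$n_blanks > 1)
                   pmin(stats::rbinom(config$n_blanks - 1L,
                                      config$blank_max_count, 0.8),
                        config$blank_max_count))
    bvals <- matrix(0, nrow = n, ncol = config$n_blanks,
                    dimnames = list(catalog$protein_id, blanks))
    w <- base / sum(base)
    for (b_i in seq_len(config$n_blanks)) {
      picked <- sample.int(n, bcounts[b_i], prob = w)
      bvals[picked, b_i] <- base[picked] * 0.01 *
        stats::rlnorm(length(picked), 0, 0.3)
    }
    vals <- cbind(vals, bvals)
    runs <- rbind(runs, data.frame(run = blanks, subject = "none",
                                   group = "blank", class = "blank",
                                   batch = "blank", stringsAsFactors = FALSE))
  }

  names(cell_state) <- names(cell_patient) <- cells
  baseline <- stats::setNames(catalog$baseline_copies, catalog$protein_id)
  list(matrix = intensity_matrix(vals, runs),
       truth = structure(list(cell_state = cell_state,
                              cell_patient = cell_patient,
                              true_family_effects = config$family_effects,
                              baseline_abundance = baseline),
                         class = "synthetic_truth"))
}

#' Generate a synthetic mini-bulk experiment
#'
#' @param catalog A generated [protein_catalog].
#' @param config A [minibulk_config()].
#' @return List with `matrix` (an [intensity_matrix] of mini-bulk runs) and
#'   `truth` (run group/subject maps, configured effects, baselines).
#' @export
generate_minibulk_experiment <- function(catalog, config = minibulk_config()) {
  stopifnot(inherits(config, "minibulk_config"))
  known_fams <- unique(unlist(catalog$families))
  missing_f <- setdiff(unique(config$family_effects$family), known_fams)
  if (length(missing_f))
    stop("catalog does not cover family_effects families: ",
         paste(missing_f, collapse = ", "))
  set.seed(config$seed)
  n <- nrow(catalog)
  base <- baseline_intensity(catalog)
  gf <- effect_factor_matrix(catalog, config$family_effects, "group",
                             config$groups)
  run_group <- rep(config$groups, config$n_subjects)
  run_subject <- unlist(lapply(config$groups, function(g) {
    prefix <- if (startsWith(g, "C.")) "H" else "G"
    paste0(prefix, seq_len(config$n_subjects[[g]]))
  }))
  run_names <- paste(run_group, run_subject, sep = "_")
  subj_all <- unique(run_subject)
  subj_factor <- stats::setNames(stats::rlnorm(length(subj_all), 0, config$batch_sd),
                                 subj_all)
  minor <- matrix(stats::rlnorm(n * length(subj_all), 0, config$batch_sd / 4),
                  nrow = n, dimnames = list(catalog$protein_id, subj_all))
  vals <- matrix(0, nrow = n, ncol = length(run_names),
                 dimnames = list(catalog$protein_id, run_names))
  for (r in seq_along(run_names)) {
    cv <- config$depth_cv
    if (run_group[r] %in% names(config$group_depth_cv))
      cv <- config$group_depth_cv[[run_group[r]]]
    mu <- base * gf[, run_group[r]] * subj_factor[run_subject[r]] *
      minor[, run_subject[r]] * lognormal_depth(1, cv)
    p <- detection_probability(mu, config$dropout_midpoint, config$dropout_slope)
    vals[, r] <- sample_observed(mu, p, config$meas_sd)
  }
  runs <- data.frame(run = run_names, subject = run_subject,
                     group = run_group, class = "minibulk",
                     batch = run_subject, stringsAsFactors = FALSE)
  run_group_named <- stats::setNames(run_group, run_names)
  run_subject_named <- stats::setNames(run_subject, run_names)
  baseline <- stats::setNames(catalog$baseline_copies, catalog$protein_id)
  list(matrix = intensity_matrix(vals, runs),
       truth = structure(list(cell_state = run_group_named,
                              cell_patient = run_subject_named,
                              true_family_effects = config$family_effects,
                              baseline_abundance = baseline),
                         class = "synthetic_truth"))
}

#' Expected number of detected proteins under the dropout curve
#'
#' Closed-form expectation (sum of per-protein logistic detection
#' probabilities at baseline expected intensity); used to calibrate the
#' dropout midpoint by bisection.
#'
#' @param catalog A generated [protein_catalog].
#' @param midpoint,slope Dropout curve parameters.
#' @return Expected detected-protein count for one run at unit depth.
#' @export
expected_detected_count <- function(catalog, midpoint, slope) {
  sum(detection_probability(baseline_intensity(catalog), midpoint, slope))
}

#' Calibrate the dropout midpoint for a target detection count
#'
#' Bisection on [expected_detected_count()].
#'
#' @param catalog A generated [protein_catalog].
#' @param target Target expected detected-protein count.
#' @param slope Dropout slope.
#' @param lower,upper Bisection bracket in log10 intensity.
#' @return The calibrated midpoint (log10 intensity units).
#' @export
calibrate_dropout_midpoint <- function(catalog, target, slope = 0.45,
                                       lower = 0, upper = 20) {
  f <- function(m) expected_detected_count(catalog, m, slope) - target
  if (f(lower) < 0 || f(upper) > 0) stop("target outside bracket")
  for (i in 1:60) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}
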