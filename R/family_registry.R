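# Curated protein-family registry. The published analysis scores families of
# functionally related proteins (granule compartments, histones, ribosomal
# subunits, electron transport chain, ...) by summed intensity, but no full
# member lists are printed anywhere; this registry is a reconstruction
# assembled from standard annotations plus the marker proteins named in the
# study's figures. It is versioned, and every scoring operation records the
# version it used.

REGISTRY_VERSION <- "neutrophil-families-v1"

# Real marker symbols per family. The synthetic generator pads each family to
# its target size with systematic synthetic symbols (e.g. AZUG008), which are
# added to catalog-derived registries but never to the shipped curated one.
.family_seed_symbols <- list(
  azurophilic_granule = c("MPO", "ELANE", "CTSG", "PRTN3", "AZU1", "BPI",
                          "DEFA1", "DEFA4", "CTSC", "RNASE3"),
  specific_granule = c("LTF", "LCN2", "CAMP", "MMP25", "CYBB", "OLFM4",
                       "HP", "PGLYRP1"),
  ficolin_granule = c("FCN1", "CHI3L1", "GSN", "B2M"),
  secretory_vesicle = c("ALPL", "CD177", "MGAM", "CR1", "CEACAM8"),
  histones = c("H2AC1", "H2BC1", "H3C1", "H4C1", "H2AC4", "H2BC14",
               "H3C2", "H4C2", "H1-2", "H1-4"),
  nuclear_membrane = c("LMNB1", "LMNB2", "LBR", "NUP62", "NUP98", "RANBP2"),
  cell_membrane = c("SELL", "CD44", "CD55", "SLC44A2", "CEACAM1", "ICAM3"),
  ribosomal_40S = paste0("RPS", c(2:21, 23:25)),
  ribosomal_60S = c("RPL4", "RPL7", "RPL15", paste0("RPL", c(3, 5, 6, 8:14))),
  electron_transport_chain = c("NDUFA2", "NDUFB4", "NDUFS1", "SDHA", "SDHB",
                               "UQCRC1", "UQCRC2", "COX4I1", "COX5A",
                               "ATP5F1A", "ATP5F1B"),
  mitochondrial_membrane = c("TOMM5", "IMMT", "TOMM20", "TOMM22", "TIMM23",
                             "VDAC1", "VDAC2"),
  mitochondrial_metabolism = c("PDHB", "IDH3A", "ACAT1", "CS", "FH", "MDH2",
                               "SUCLA2", "OGDH"),
  complement_coagulation = c("C3", "C5", "CFB", "FGA", "FGB", "FGG", "F2",
                             "F9", "PLG", "CLU", "SERPINC1"),
  lysosome = c("CTSD", "LAMP1", "LAMP2", "SCARB2", "HEXB", "GUSB", "GLB1"),
  proteasome_20S = c(paste0("PSMA", 1:7), paste0("PSMB", 1:7)),
  immunoglobulins = c("IGHG1", "IGHG3", "IGHA1", "IGKC", "IGLC2"),
  desmosome = c("DSP", "DSG1", "DSC1", "JUP", "PKP1"),
  cytoskeleton = c("ACTB", "ACTN1", "VIM", "TUBB", "CORO1A", "MSN", "EZR",
                   "TLN1", "FLNA"),
  glycolysis_glycogenolysis_ppp = c("PYGL", "SLC2A3", "PFKL", "PKM", "GAPDH",
                                    "ALDOA", "ENO1", "G6PD", "PGD", "TALDO1"),
  dna_replication = c("PCNA", "CEBPE", paste0("MCM", 2:7), "POLA1", "LIG1",
                      "RFC1"),
  maturity_markers = c("MMP8", "MMP9", "S100A8", "S100A9", "ITGAM", "ITGB2",
                       "FCGR3B"),
  ia_markers = c("ARG1", "S100A7", "ECM1", "S100A10")
)

#' The shipped neutrophil protein-family registry
#'
#' A curated gene-symbol-to-family map covering the protein families used for
#' signature scoring: granule compartments (azurophilic, specific, ficolin,
#' secretory vesicles), histones, nuclear and cell membrane, 40S/60S ribosome,
#' electron transport chain, mitochondrial membrane and metabolism, complement
#' and coagulation, lysosome, 20S proteasome, immunoglobulins, desmosome,
#' cytoskeleton, glycolysis/glycogenolysis/PPP, DNA replication, and two
#' marker panels (maturity, immunosuppressive/angiogenic). The lists are a
#' reconstruction from standard annotations, not a published table.
#'
#' @return Named list: family tag -> character vector of gene symbols, with a
#'   `version` attribute.
#' @export
neutrophil_family_registry <- function() {
  structure(.family_seed_symbols, version = REGISTRY_VERSION)
}

#' Family registry derived from a catalog's own family tags
#'
#' For synthetic catalogs (whose padded members are not in the curated
#' registry) scoring uses the catalog's family annotations directly.
#'
#' @param catalog A [protein_catalog].
#' @return Named list as in [neutrophil_family_registry()].
#' @export
catalog_registry <- function(catalog) {
  ft <- catalog_family_table(catalog)
  structure(split(ft$gene_symbol, ft$family),
            version = paste0("catalog-derived/", REGISTRY_VERSION))
}

#' Write the shipped registry as a versioned two-column table
#'
#' @param path Output path (tab-separated: gene_symbol, family).
#' @export
write_family_registry <- function(path) {
  reg <- neutrophil_family_registry()
  df <- data.frame(gene_symbol = unlist(reg, use.names = FALSE),
                   family = rep(names(reg), lengths(reg)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
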