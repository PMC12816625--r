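# scpstates

Analysis pipeline for ultra-low-input proteomics of human neutrophils:
from a search engine's protein-group intensity matrix (bulk, 500-cell
"mini-bulk", or single sorted cells) to normalized abundances, copy-number
context, quality-controlled cells, differential abundance, graph-based
cell clusters, and protein-family signatures that label clusters with
neutrophil functional states — armed, engaged, vital NETs, exhausted,
lytic NETs, immunosuppressive & angiogenic, and vascular immature.

It is aimed at proteomics practitioners analysing sorted-population or
single-cell DIA data of neutrophils (or other granulocytes) who want the
published analysis conventions as tested, reusable functions.

## What it computes

* **riBAQ normalization** — iBAQ (intensity / count of theoretical
  tryptic peptides, Trypsin/P digestion, peptide length 7–30) scaled so
  each run's nonzero median is 1; plus the single-cell **riBAQ-like**
  variant that corrects by `median_MW / MW` over detected proteins before
  median scaling.
* **Proteomic-ruler copy numbers** — `copies_i = I_i · N_A · m_DNA /
  (MW_i · Σ histone intensity)` with `m_DNA = 6.5 pg`, and
  detection-sensitivity statistics (fraction of detected proteins under a
  copy threshold per workflow).
* **Blank-derived QC** — cell threshold `ceil(1.75 · max(blank counts) /
  50) · 50` (a blank maximum of 228 identifications gives 400), strict
  "fewer than threshold" filtering, and 10-fold identification-count
  outlier detection for mini-bulk runs.
* **Moderated differential abundance** — empirical-Bayes moderated t
  (`s̃²_g = (d₀s₀² + d_g s²_g)/(d₀+d_g)`, prior by digamma/trigamma moment
  matching), replicate-eligibility filtering (detected in ≥2 replicates of
  both conditions), Storey q-values, strict `q < 0.05` calls, and a
  complete-case log10 PCA overview.
* **Single-cell clustering** — log normalization, 2000 variable features
  against a mean–variance trend, 35-component PCA with detection-depth
  regression and a per-batch centroid-shrinkage integration surrogate,
  SNN/Leiden communities at resolution 1.45, and logistic-regression
  marker tests (fold-change 0.25, Bonferroni).
* **Family signatures and states** — summed-intensity family scores over
  a versioned curated registry, Welch comparisons with percent change,
  maturity-signature transfer from mini-bulk to single cells, and
  template-based assignment of the seven functional states by Spearman
  similarity with injective matching.
* **Synthetic study emulation** — a generator producing protein catalogs
  (median MW 47,485 Da, log-normal copies with median 5500) and
  single-cell / mini-bulk / blank matrices with known ground truth,
  encoding the printed effect sizes (azurophilic granules ×0.20, histones
  ×0.17, nuclear membrane ×0.15 in lytic NETs; ribosomes ×4.3 and electron
  transport chain ×2.65 in immature cells) with dropout calibrated to
  ~1100 detected proteins per single cell.

## Worked example

```r
library(scpstates)

catalog    <- generate_protein_catalog(3000, seed = 1)
experiment <- generate_scp_experiment(catalog, scp_config(seed = 1))

counts <- count_identifications(experiment$matrix)
blanks <- experiment$matrix$runs$run[experiment$matrix$runs$class == "blank"]
derive_blank_threshold(counts[blanks])
#> blank max: 228 -> threshold: 400

bundle <- run_scp_pipeline(scp_pipeline_config(seed = 1, compute_markers = FALSE))
bundle$manifest$median_mw_used   # 47178 Da (median MW of detected proteins)
bundle$proportions
#>   cluster n_cells                        state   percent
#> 1       1      86                        armed 28.666667
#> 2       2      53                    exhausted 17.666667
#> 3       3      52                      engaged 17.333333
#> 4       4      46 immunosuppressive_angiogenic 15.333333
#> 5       5      35                   vital_NETs 11.666667
#> 6       6      28                   lytic_NETs  9.333333

truth <- bundle$truth$cell_state
compare_family(bundle$family_scores, "azurophilic_granule",
               names(truth)[truth == "armed"],
               names(truth)[truth == "lytic_NETs"])
#> azurophilic granules, lytic NETs vs armed: -78.5% (Welch p = 7.5e-49)
```

The median identification count here is ~1000 proteins per cell; all 300
cells clear the blank-derived 400-protein threshold; the lytic-NETs cells
show the configured ~80% loss of azurophilic-granule signal. Six
communities emerge at resolution 1.45 on this seed (the two states that
differ only by weak qualitative effects merge; the family evidence still
identifies them — see the vignette's limitations section).

`run_minibulk_pipeline()` is the mini-bulk counterpart: riBAQ,
identification-count outlier removal, PCA, all 10 pairwise moderated-t
contrasts with q-values, family scores and the maturity signature.

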