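# crcsig

Derivation and scoring of epithelial gene-expression signatures in
colorectal cancer (CRC).

Right-sided, serrated-pathway CRCs driven by BRAF^V600E with disabled
TGF-β signalling carry a Wnt-low, foetal-like epithelial expression
program that is hard to read out from bulk tumour profiles, because bulk
expression mixes epithelium with stroma and immune cells. `crcsig`
implements the full pipeline for building two complementary,
epithelium-restricted signatures from mouse model data and applying them
to annotated human cohorts:

- **BA signature** — genes differentially expressed in mouse
  BRAF-mutant/TGF-β-receptor-null epithelium, mapped to human orthologs
  and filtered to epithelial-specific genes. A sample's score is
  `mean(z(up genes)) − mean(z(down genes))`, where `z(·)` standardizes
  each gene across the cohort.
- **WA signature** — a Wnt-activation module: the AXIN2-anchored cluster
  of epithelial up-genes under hierarchical clustering on correlation
  distance (1 − Pearson r) with complete linkage. An 8-gene default
  (MACC1, KRT23, FGFR4, RPS6KA6, PROX1, ASCL2, AXIN2, RASSF10) ships
  with the package. The score is the mean of the standardized module
  genes.

The stages, each usable on its own:

1. **Differential expression** (`fit_de`, `filter_de`,
   `combine_contrasts`): per-gene negative-binomial GLM with batch +
   condition covariates and TMM-corrected library offsets
   (edgeR backend); the derivation filter keeps genes with
   |log2FC| > 2 at unadjusted p < 1e−5; two contrasts merge under a
   union-consistent policy.
2. **Ortholog mapping** (`map_orthologs`): only unambiguous,
   high-confidence mouse→human pairs survive; everything else is dropped
   with a reason.
3. **Cell-type specificity** (`aggregate_pseudobulk`,
   `classify_specificity`): single-cell counts are summed per
   (sample, cell type); a gene is specific to a type when its mean raw
   pseudobulk count beats every other type by ≥ 1 count and every
   pairwise Welch test on log2-CPM is significant at p < 0.01.
4. **Signature construction and scoring** (`build_ba_signature`,
   `build_wa_signature`, `score_signature`).
5. **Cohort associations** (`compare_groups`, `compare_multi`,
   `correlate_signatures`, `survival_stratify`,
   `cox_score_association`): Welch t-tests, one-way ANOVA, Pearson
   correlation, and median-split survival ("high" = strictly above the
   median score) with Kaplan–Meier curves, univariable Cox (Efron ties,
   Wald p) and the log-rank test.
6. **Synthetic data** (`simulate_mouse_counts`, `simulate_cell_counts`,
   `simulate_cohort`, `simulate_study`): generators with planted DE
   genes, planted cell-type-specific genes, a planted AXIN2-anchored
   gene block anticorrelated with a BA-like program, label links and
   score-dependent hazards — so every stage is testable against known
   truth without any download.

## Worked example

Derive both signatures from a coordinated synthetic study and score the
cohort:

```r
library(crcsig)

study <- simulate_study(sim_config(seed = 7, n_genes = 1000,
                                   cells_per_sample_per_type = 100,
                                   cohort_n = 300))
res <- derive_signatures(
  contrasts    = list(study$contrasts$a$matrix, study$contrasts$b$matrix),
  ortholog_map = study$ortholog_map,
  cell_data    = study$cell_data,
  cohort       = study$cohort
)
print(res$ba)
#> signature 'BA': 41 up / 41 down genes (zscore scale)
print(res$wa)
#> signature 'WA': 8 up / 0 down genes (zscore scale)

report <- run_score(study$cohort, list(BA = res$ba, WA = res$wa))
```

The association battery reproduces the planted structure:

```
BA score, BRAF MUT vs WT: 0.96 vs -0.60 (Welch p = 2.3e-18)
BA-WA Pearson r = -0.551 (p = 3.2e-25, n = 300)
Median-split survival: HR = 2.88 (Wald p = 4.2e-12, log-rank p = 6.9e-13)
```

BRAF-mutant samples score markedly higher on the BA signature; the BA
and WA scores are negatively correlated (Wnt-low character of the BA
program); and BA-high patients relapse faster than BA-low patients.

A thin command-line wrapper around the same functions ships at
`inst/cli/crcsig.R` with verbs `simulate`, `derive` and `score`, driven
by a YAML pipeline configuration (`pipeline_config`,
`write_pipeline_config`).

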