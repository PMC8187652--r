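---
title: "Deriving and scoring epithelial CRC signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and scoring epithelial CRC signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcsig)
```

This vignette is the package's account of what each stage computes, which
assumptions it leans on, where the design was genuinely open and what we
chose, and what the synthetic-data generators do and do not emulate.

## The problem

Serrated-pathway colorectal cancers initiated by BRAF^V600E with disrupted
TGF-β signalling express a Wnt-low, foetal-like epithelial program. Reading
that program out of bulk tumour expression requires (i) finding the genes
that move in the mouse model, (ii) translating them to human, (iii)
restricting to genes whose bulk signal actually comes from the epithelium,
and (iv) a scoring rule that is comparable across platforms. The package
implements that chain plus the downstream cohort statistics.

## Stage 1: differential expression

Counts for each gene are modelled as negative binomial with a log link,

$$\log \mu_{gj} = \beta_{0g} + \beta_{b g}\,\mathrm{batch}_j +
  \beta_{c g}\,\mathrm{condition}_j + \log \tilde N_j,$$

where $\tilde N_j$ is the TMM-scaled effective library size. The condition
coefficient, reported on the log2 scale, is the quantity of interest; its
p-value comes from a likelihood-ratio test. Fitting uses edgeR's GLM
machinery with a dispersion we supply (below). The derivation filter keeps
genes with |log2FC| > 2 **and** unadjusted p < 1e−5, both strict, exactly
as a signature-derivation screen should: no shrinkage of the fold change
(the filter presupposes raw coefficients) and no multiple-testing
correction (the extreme p threshold does that work).

Two numerical choices deserve a note, both made after the plain variants
failed on simulated data with known truth:

- **TMM offsets, not raw library sizes.** With a strongly asymmetric
  planted effect (many genes up four log2 units), case libraries grow by
  roughly one log2 unit, and plain per-library CPM normalization absorbs
  that growth into every fold change — a moment estimator and the GLM both
  recovered ≈3.2 where 4 was planted. TMM factors (which assume the
  majority of genes are null; here 90% are) restore the planted value; we
  cross-checked with an independent DESeq-style median-of-ratios scaling.
- **Moderated method-of-moments dispersion.** Per-gene dispersions are
  estimated by moments within each batch × condition cell, averaged,
  squeezed halfway toward the across-gene median, and floored at 1e−4.
  With 2–3 replicates per cell the raw per-gene estimate is noisy enough
  that treating it as known makes the likelihood-ratio test
  anticonservative at the extreme tail the filter uses; the half-weight
  squeeze (the same idea as empirical-Bayes dispersion moderation)
  restores tail calibration without costing recovery of a 4-log2-unit
  planted effect.

Genes with fewer than 10 total counts (configurable) are excluded from
testing and reported as untested: GLM fits on all-zero rows are
degenerate, and such genes could never pass the filter anyway.

Two mouse contrasts (e.g. an early-timepoint and an endpoint dataset) are
merged with a **union-consistent** policy: a gene is up if it is up in
either contrast and down in neither. How the original derivation merged
its two datasets is not documented; union-consistent is the permissive
choice that still refuses direction conflicts, and an `intersection`
policy is available for stricter use. Conflicting calls *within* one
contrast are impossible by construction and treated as an upstream bug.

## Stage 2: ortholog mapping

Only high-confidence mouse→human records are used, and only when they are
one-to-one in both directions: a mouse gene with two high-confidence human
hits is ambiguous, and two mouse genes hitting one human gene collide;
both are dropped and reported with reasons rather than guessed at. This
mirrors "most confident orthologue" practice and keeps the signature free
of paralog noise at the cost of some coverage.

## Stage 3: cell-type specificity from pseudobulk

Cell-level counts are summed per (sample, cell type) — pseudobulk — which
converts single-cell noise into a small number of replicate-level
observations and makes ordinary two-sample tests valid. Aggregation
conserves the grand total exactly, which the suite asserts on every run.

A gene is called specific to type $T$ when, against **every** other type
$U$: (a) its mean raw pseudobulk count in $T$ exceeds the mean in $U$ by
at least `margin_counts` (default 1), and (b) a two-sided Welch t-test on
per-sample log2-CPM pseudobulk values rejects at `alpha` (default 0.01).
With a positive margin at most one type can qualify, so labels are unique
by construction. Open points we had to fix by convention:

- The "1 raw count" margin is applied to **per-sample means** of
  pseudobulk counts (replicate-aware), not to summed totals or normalized
  values; the margin is configurable.
- The significance test is a **Welch t-test on per-sample values** — the
  smallest-assumption replicate-level test consistent with pseudobulk
  practice; a pooled cell-level test would overstate the effective n.
- The margin is tested on raw counts (as stated by the rule) but the
  t-test runs on log2-CPM, so library-size differences between units do
  not masquerade as specificity.

With only two samples per type the Welch test is underpowered; the
classifier then loses sensitivity but not correctness (calls drift to
"non-specific" rather than to wrong types), which the suite checks.
Tightening either knob can only shrink the specific sets (monotonicity,
also under test).

## Stage 4: signatures and scores

**BA.** Up and down DE sets are intersected with the epithelial-specific
set; both components are retained. An empty up-intersection is an error
that advises revisiting thresholds rather than silently emitting an
unusable signature.

**WA.** The epithelial up-genes are clustered on the derivation cohort
with correlation distance $d(g,h) = 1 - r_{gh}$ and complete linkage.
The tree is cut at the $k \in [2, 15]$ maximizing mean silhouette width,
and the cluster containing the anchor gene (AXIN2) becomes the
signature. "Most significant cluster" has no canonical definition; the
silhouette-optimal cut plus the anchor constraint is our declared
convention, validated against exhaustive enumeration of all partitions on
small inputs. Genes are sorted lexicographically before clustering so
merge ties break deterministically; if all candidates are perfectly
correlated the whole input is returned as one cluster (silhouettes are
undefined there). A packaged 8-gene default (MACC1, KRT23, FGFR4,
RPS6KA6, PROX1, ASCL2, AXIN2, RASSF10) is used whenever no derivation
cohort is supplied.

**Scoring.** Each gene is standardized across the cohort (z-score), then
`score = mean(z up) − mean(z down)`. Whether to standardize before the
difference of means is underdetermined by the verbal rule "difference in
mean expression"; we standardize by default because it makes the score
invariant to per-gene affine transforms — i.e. comparable across
platforms with gene-specific dynamic ranges — and we expose
`scoring_scale = "log-expression"` for the literal reading. Zero-variance
genes contribute 0 rather than NaN; genes missing from the matrix are
skipped and counted, with a warning below 80% coverage.

## Stage 5: cohort associations

- Two-group comparisons are Welch t-tests (two-sided): the variance-equal
  variant is never safer and the original analyses do not specify one.
- The CMS comparison reports both CMS1-vs-rest (Welch) and the one-way
  ANOVA across subtypes, since either reading of "across subtypes" is
  defensible.
- T stage is compared as T1–2 vs T3–4.
- Correlation is Pearson on the sample intersection, p from the t
  distribution.
- Survival: "high" is **strictly above** the median score, ties at the
  median go to "low" (literal reading of "above the median", and
  deterministic); Kaplan–Meier curves per group; univariable Cox on the
  indicator with Efron tie handling and a two-sided Wald p; log-rank p
  reported alongside. A degenerate split (everything on one side) and
  groups with fewer than two events are errors, not silent output.
  `cox_score_association` supplements the split with a per-SD continuous
  Cox coefficient, the scale on which the generator plants its hazard.

## The synthetic-data generators

`simulate_mouse_counts` draws NB counts ($\phi = 0.1$ by default) with
per-gene baselines uniform on $[2^3, 2^9]$, two conditions × five
samples, two batches balanced across conditions with per-gene batch
offsets (SD 0.5 log2), and 10% DE genes at ±4 log2 units. These defaults
are the study conditions of the whole suite: a planted effect well above
the |log2FC| > 2 filter, replicate counts typical of mouse RNA-seq, and a
batch effect large enough to matter if unmodelled.

`simulate_cell_counts` plants 10% of genes as specific to one of five
types (epithelial, stroma, myeloid, lymphocytes, endothelial) at an
8-fold expected bump, with 4 samples × 200 cells per (sample, type) and
mild per-sample library factors. `simulate_cohort` draws two latent
per-sample programs (BA-like, WA-like) with correlation −0.6, loads the
AXIN2-anchored block (8 genes, pairwise r ≈ 0.9) on WA and disjoint
up/down sets on ±BA, links BRAF/side/CMS1/stage labels to BA and lesion
morphology to WA through logistic models, and draws exponential relapse
times with log hazard 0.7 per SD of BA, independently censored at 30%.
The exponential baseline gives a closed-form truth for Cox recovery
checks. `simulate_study` wires all of this into one coherent study
(shared planted genes, identity-style ortholog map with planted
low-confidence/ambiguous/collision entries) so the pipeline can run end
to end against known truth.

What the generators deliberately do **not** emulate: mean–variance trends
across genes (dispersion is constant; the DE stage assumes none),
gene–gene correlation beyond the planted blocks, ambient RNA and doublets
in the cell data, platform-specific intensity distributions in the
cohort, and informative censoring. Passing the suite therefore
demonstrates that the algorithms recover the structure they claim to
recover under their own assumptions — not that those assumptions hold in
any particular real dataset.

## Problem sizes and determinism

Unit tests run on reduced sizes (hundreds of genes, tens of cells per
unit) chosen so the full suite completes in well under a minute of
compute; whole-pipeline checks use the default study conditions (2000
genes, 10 bulk samples, ~4000 cells, cohorts of 400–500) where the
statistical claims need them. Every generator reseeds from its
configuration, so a fixed `SimConfig` reproduces its output bit for bit,
and the file-level pipeline is byte-identical under a fixed seed — which
the suite verifies by hashing outputs of two independent runs.

## Known limitations

- The DE stage estimates one dispersion per gene without a trend;
  datasets with strong mean–variance structure would deserve edgeR's own
  trended/tagwise machinery.
- The specificity rule's raw-count margin is scale-dependent: very deep
  pseudobulk libraries make a 1-count margin weak, shallow ones make it
  harsh. It is configurable for that reason.
- The silhouette-optimal cut can split very elongated modules; the anchor
  constraint bounds the damage for the WA use case.
- Ortholog handling discards ambiguous many-to-many families wholesale;
  no attempt is made to pick a best pair.
- The association battery is univariable throughout; no multivariable
  adjustment is offered.
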