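# myosig

Myogenic cell-type gene signatures for bulk and single-cell
transcriptomics.

Satellite cells — the resident stem cells of skeletal muscle — and their
myoblast/myocyte progeny make up only a few percent of the cells in a
muscle biopsy, so their activity is nearly invisible in bulk RNA-seq
unless you track genes expressed *only* by them. `myosig` implements the
machinery for building and using such cell-type-restricted signatures:

* **derivation** — from a clustered single-cell count matrix, select
  genes with a > *f*-fold increase in the target population that are
  detected in < *g* of all other cells and < *k* of cells in any other
  single cluster (detection = nonzero raw count), over a grid of
  27 threshold combinations (*f* ∈ {1.5, 1.75, 2}, *g* ∈ {5, 10, 15}%,
  *k* ∈ {20, 30, 40}%); lists under 10 genes are discarded and the
  survivor with the best ROC AUC on an independent validation dataset
  wins;
* **scoring** — per sample, the sum of log-normalized counts over
  signature genes (median-of-ratios size factors + log2 for bulk,
  per-10k + ln(1+x) for cells), reported as the difference from the
  control-group average;
* **evaluation** — the score as a binary classifier of cell identity:
  ROC curve and tie-aware AUC (= Mann–Whitney U / n₁n₀);
* **association** — Spearman correlation of scores with external
  measurements (e.g. PAX7⁺ cells per fiber) tested against 1000
  size-matched random gene sets, with empirical p = (1 + #{ρ_null ≥
  ρ_obs}) / 1001, plus the standard group comparisons (Wilcoxon,
  ANOVA + Tukey, Kruskal–Wallis + Dunn);
* **simulation** — a negative-binomial generator for clustered
  single-cell counts with analytically calibrated planted markers, bulk
  cohorts as cell-type mixtures with paired pseudo-histology, and a
  post-injury time course, so the whole pipeline runs and is tested
  without any external data.

The three published human signatures ship with the package:
`muscle_signatures()` returns the satellite-cell (10 genes, including
*PAX7* and *MYF5*), myoblast/myocyte (25 genes) and myonuclear (66 genes)
sets, with `map_orthologs()` for table-driven cross-species translation.

It is aimed at people analyzing muscle transcriptomes — muscular
dystrophy cohorts, regeneration time courses, exercise studies — who
want a small, auditable alternative to full deconvolution.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (simulate → derive → validate → score → associate). In code:

```r
library(myosig)
res <- run_pipeline(seed = 1, outdir = "results/demo")
```

which derives a signature on a simulated 4-cluster × 500-cell atlas with
12 planted satellite-like markers, validates it on an independent
simulation, scores a 3-group bulk cohort, and tests the score–histology
association. Running the scripts prints, among other things:

```
Derived signature: 12 genes; winning thresholds FC > 1.50, global < 5%, cluster < 20%; validation AUC 1.000
Planted-marker recovery: 12/12 recovered, 0 false positives
ROC on 1000 validation cells (250 target): AUC = 1.0000
       control   disease_mild disease_severe
          0.00           6.08           9.17
Satellite score vs histology: Spearman rho = 0.926 (p = 8.8e-11, n = 24)
Resampling null: ... 0 draws matched or beat the signature; empirical p = 0.000999
```

Reading: the grid search recovered exactly the planted markers; the score
separates target cells perfectly in validation; centered scores rise with
the simulated disease severity (controls centered at 0 by construction);
and no random 10-gene set correlates with the pseudo-histology as well as
the signature (p < 0.001 by the resampling convention).

See `vignettes/myogenic-signatures.Rmd` for the model, parameter and
edge-case documentation.

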