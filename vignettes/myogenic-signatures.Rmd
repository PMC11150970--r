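---
title: "Deriving and scoring myogenic cell-type gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and scoring myogenic cell-type gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myosig)
```

## The problem

Satellite cells — the resident stem cells of skeletal muscle — and their
myoblast/myocyte progeny are a small fraction of the cells in a muscle
biopsy, so their activity is hard to read out of bulk RNA-seq: most genes
that change during myogenesis are also expressed by fibroblasts, immune
cells, endothelium or the myofibers themselves. The remedy implemented
here is to derive *cluster-restricted* signatures from clustered
single-cell data — genes strongly enriched in one myogenic population and
nearly silent everywhere else — and then to track those small gene sets in
bulk transcriptomes. `myosig` implements the full machinery: derivation,
scoring, classifier-style validation, and a resampling null for
score–phenotype associations, together with a synthetic-data generator so
every stage can be exercised and tested without external downloads. The
package also ships the three published human signatures (satellite cell,
10 genes; myoblast/myocyte, 25; myonuclear, 66) via `muscle_signatures()`.

## Derivation model

For a target population $T$ (a designated set of clusters) against all
other cells $R$, each gene receives:

* **fold change** $(\bar{x}_T + c)/(\bar{x}_R + c)$ on mean *linear*
  library-size-normalized expression (counts scaled per cell to 10,000),
  with pseudocount $c = 0.01$ guarding rare genes;
* **detection fractions**: share of cells with a nonzero raw count, in
  $T$, in $R$ pooled, and within each individual non-target cluster
  (the maximum of which is the per-cluster statistic). Pooled detection is
  a cell-count-weighted mean of the per-cluster fractions, so it always
  lies between their extremes;
* **a differential-expression q-value**: two-sided Wilcoxon rank-sum of
  $T$ vs $R$ on normalized expression, Benjamini–Hochberg adjusted.

A gene passes thresholds $(f, g, k)$ when fold change $> f$, pooled
other-cell detection $< g$, every-other-cluster detection $< k$, and
q-value $< 0.05$. All inequalities are strict. The default grid crosses
$f \in \{1.5, 1.75, 2\}$, $g \in \{5\%, 10\%, 15\%\}$ and
$k \in \{20\%, 30\%, 40\%\}$ — 27 candidate lists. Lists with fewer than
10 genes are discarded (small lists are fragile to coverage differences
across platforms), and the survivor with the highest ROC AUC on an
*independent* validation dataset — scoring its cells and classifying
target-cluster membership — wins. Ties break toward the smaller list, then
lexicographic gene order, so reruns are reproducible. A
`fixed_thresholds` mode applies one threshold combination without grid
search, for signatures that inherit thresholds optimized on another cell
type.

Two derivation details are deliberate choices. First, the DE prefilter
only tests genes detected in at least 10% of the target population or of
the pooled other cells (`min_detect`, settable to 0). A gene detected in
3% of its own population cannot serve as a marker, and at a few hundred
cells its fold-change estimate is sampling noise; without the screen such
genes occasionally slip through all three filters jointly. This is also
the standard single-cell marker-testing convention, so candidate lists
match what a typical upstream DE run would feed in. Second, the rank-sum
p-values use the tie-corrected normal approximation with continuity
correction (equivalent to `wilcox.test(exact = FALSE, correct = TRUE)`),
computed vectorized across genes; at thousands of genes times thousands
of cells, per-gene exact tests would dominate runtime without changing
any decision made at $\alpha = 0.05$.

## Scoring model

The signature score of a sample (or cell) is the **plain sum** of its
log-normalized expression over the signature genes present in the matrix.
Sums, not means: signature size therefore sets the scale, which is why
scores are only compared within a dataset and are reported after
subtracting the control-group average (`center_scores()`; controls then
average exactly zero). Genes absent from a dataset are dropped from the
signature for that analysis; the retained fraction is recorded as
*coverage*, and a warning fires below 75% coverage rather than an error —
an analysis with 3/10 genes may still be informative, but the reader
should know.

Two normalization conventions are provided (`log_normalize()`):

* **bulk**: median-of-ratios size factors, then $\log_2(x/s_j + 1)$. The
  reference profile for sample $j$ is the geometric mean of the *other*
  samples' counts (leave-one-out). With the classical all-sample
  reference, multiplying one sample's counts by $k$ multiplies its size
  factor by $k^{(n-1)/n}$ — the pseudo-reference absorbs $k^{1/n}$ — so
  normalized values drift under per-sample rescaling. The leave-one-out
  reference makes the covariance exact: the scaled sample's size factor
  scales by exactly $k$ and its normalized values are exactly unchanged.
  The two estimators agree up to finite-cohort jitter (the test suite
  cross-checks against `DESeq2::estimateSizeFactorsForMatrix`). The log
  base is a convention, exposed as a parameter; scores are compared
  within a dataset, never across bases.
* **single-cell**: per-cell scaling to 10,000 counts, then $\ln(1+x)$ —
  the common single-cell convention, matching the provenance of typical
  clustered atlases.

The authors' exact log base and pseudocount are not stated in the source
material for either convention; the defaults above are recorded in output
metadata and all downstream statistics (ranks, ROC, Spearman) are
invariant to monotone transforms of the score.

## Evaluation and association

`roc_curve()`/`auc()` treat higher score as evidence for the positive
class, with **no automatic direction flip** — a signature that scores its
own cell type lower has failed and should be seen to fail. Tied scores
collapse to one threshold, making the trapezoidal AUC exactly the
tie-aware Mann–Whitney statistic $U/(n_1 n_0)$ (verified against an
$O(n^2)$ pairwise oracle to 1e-12 in the tests).

`resampling_null()` asks whether a curated signature's Spearman
correlation with an external measurement (e.g. PAX7$^+$ cells per fiber)
out-performs size-matched random gene sets: each of $n$ resamples draws
the same number of genes uniformly without replacement from the gene
universe (default: genes with nonzero count in at least one sample — a
constant all-zero score has no rank correlation), scores them, and
records the correlation. The empirical p is $(1 + \#\{\rho_{null} \ge
\rho_{obs}\})/(1 + n)$ — never zero, and exactly $1/(n+1)$ when the
signature beats every draw, so 1000 resamples with no exceedance reads
"p < 0.001". "Out-performed" is one-sided on $\rho$ by default, since the
claim under test is a positive association; a two-sided $|\rho|$ option
exists. Spearman p-values use the t approximation for $n > 10$, full
permutation enumeration for $n \le 7$, and a seeded Monte-Carlo estimate
for $8 \le n \le 10$.

`group_compare()` wraps the standard comparisons — Wilcoxon rank-sum /
signed-rank for two groups (unpaired/paired), one-way ANOVA with Tukey's
HSD for three or more when per-group Shapiro–Wilk at $\alpha = 0.05$
does not object, otherwise Kruskal–Wallis with Dunn's tie-corrected
post-hoc z tests — and reports significance stars at the conventional
0.05/0.01/0.001/0.0001 cutpoints.

## The synthetic-data generator

`generate_single_cell()` draws negative-binomial counts (dispersion
`size = 0.5` by default — strongly overdispersed, zero-rich at low means,
the standard generative baseline for UMI data) with per-gene lognormal
baseline means shared across clusters. Planted markers are calibrated
*analytically*: the NB zero probability $P[X=0] = (r/(r+\mu))^r$ is
inverted to find the background mean matching the requested background
detection fraction and the target-cluster mean matching the target
detection fraction; the planted fold change acts as a floor on the
target/background mean ratio. At the default regime (fold change 4,
detection 0.8 vs 0.02) the detection calibration implies a mean ratio far
above 4, so realized fold changes comfortably exceed the floor. Requesting
target detection at or below background detection is an error — no NB
mean assignment can produce it.

`generate_bulk_cohort()` forms bulk samples as proportion-weighted
mixtures of cell-type expression profiles scaled to a library size, read
out with NB noise (`nb_size = 20`: a few percent extra-Poisson variation,
typical of bulk replicates). Disease groups carry elevated
satellite/myoblast fractions (defaults 1.5% satellite in controls rising
to 4.5% in severe disease — the few-percent range expected of muscle);
a paired pseudo-histology readout is a linear function of the true
satellite fraction plus Gaussian noise, floored at zero. A time-course
mode emits one group per timepoint over hours 0–48 with the satellite
fraction dipping by 8 h, the myoblast fraction rising from 16 h and the
myonuclear fraction dipping around 20 h and recovering by 48 h — the
qualitative post-injury pattern. `satellite_gradient()` builds a 24-sample
design spanning satellite fractions 0.5–10% for monotonicity checks.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, varying capture efficiency, compositional interactions between cell
types, or the scale of a third-of-a-million-cell atlas. Passing tests
demonstrate that the machinery is correct and well-calibrated under a
clean NB world at desk scale (4 clusters × 500 cells × 2,000 genes for
derivation; 24-sample bulk cohorts) — not that any particular real
dataset will yield a signature of any particular quality.

## Worked example

```{r pipeline, eval = FALSE}
res <- run_pipeline(seed = 1, outdir = "results/demo")
length(res$signature$genes)   # planted markers recovered
res$roc$auc                   # validation AUC
res$association$empirical_p   # resampling null vs pseudo-histology
```

The numbered scripts under `analysis/` run the same stages as a readable
workflow (simulate → derive → validate → score/compare → associate),
writing tables under `results/`.

## Numerical and edge-case policy

* Strict inequalities at all selection thresholds; a gene at exactly the
  fold-change cutoff is excluded.
* Selected gene lists are ordered by descending fold change, ties by gene
  id; `select_signature()` ties break to smaller lists, then lexicographic
  gene order.
* Empty candidate lists are valid; only the minimum-size rule errors, and
  it names the remedy (relax the grid or lower `min_size`).
* Samples with zero total counts, single-class labels, constant vectors
  in correlation, missing control ids, and incomplete pairs in paired
  designs are all hard errors naming the offending units.
* All simulation randomness flows through per-call seeds; `run_pipeline()`
  derives per-stage child seeds deterministically from one global seed,
  and reruns are bit-identical.
* Gene identifiers are opaque and case-sensitive; ortholog translation is
  table-driven (one-to-one; collisions keep the first occurrence with a
  warning, unmapped symbols are returned in a `dropped` list that exactly
  complements the mapped one).

## Known limitations

Scores are unweighted sums, so a single highly expressed signature gene
can dominate; the coverage warning, centering, and the resampling null
are the guardrails, not a cure. The DE prefilter's detection screen means
a marker expressed in under 10% of its own population cannot be found
with default settings (lower `min_detect` deliberately if that is the
regime of interest). The normality gate for multi-group designs uses
Shapiro–Wilk per group, which is itself noisy at very small group sizes.
And derivation quality is bounded by the input clustering: mislabeled
clusters propagate directly into the signature, as the package treats
cluster labels as ground truth.
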