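---
title: "Methods: velocity driver genes, regulon activity and driver regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: velocity driver genes, regulon activity and driver regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velodrive)
```

## The biological setting and the pipeline

Embryonic muscle anlagen that lack neural-crest mesenchyme contain bipotent
`Myf5`-expressing progenitors that split into a myogenic fate
(Pdgfa⁺, Myf5/Myod/Myog⁺) and a non-myogenic connective-tissue fate
(Pdgfra⁺). `velodrive` implements the computational side of that finding as
five composable stages: QC and preprocessing, RNA-velocity driver-gene
ranking, signature/coexpression transition calling, regulon (AUC) activity,
and driver-regulator network recurrence, plus a ligand–receptor
complementarity score. This vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

## Splicing kinetics and the velocity model

Transcription, splicing and degradation of each gene follow

$$\frac{du}{dt} = \alpha - \beta u, \qquad \frac{ds}{dt} = \beta u - \gamma s,$$

with transcription rate $\alpha$ (molecules/unit time), splicing rate
$\beta$ and degradation rate $\gamma$ (both 1/unit time). For a segment of
constant $\alpha$ the system has the closed form implemented in
`kinetics_closed_form()`; the degenerate case $\beta = \gamma$ uses the
analytic limit (switched on when $|\beta-\gamma| < 10^{-8}\max(\beta,\gamma)$
to avoid catastrophic cancellation). The test suite checks the closed form
against an independent stiff ODE integration (`deSolve::lsoda`,
rtol $10^{-10}$) to $10^{-6}$ over random parameter draws.

At steady state $u^\* = \alpha/\beta$, $s^\* = \alpha/\gamma$, so cells at
rest lie on the line $u = (\gamma/\beta)\,s$. `fit_gamma()` estimates that
slope per gene by zero-intercept least squares on the cells in the lower and
upper `extreme_quantile` (default 0.05 per tail) of spliced abundance — the
cells most likely to be near the extremes of the phase portrait. Velocity is
the residual $v = u - \hat\gamma s$ on kNN-smoothed, per-layer
depth-normalised abundances (`smooth_knn()`, first-order averaging over the
cell and its k = 30 neighbours). We deliberately re-implement the
steady-state estimator rather than the EM-based dynamical model of upstream
tools: it is transparent, deterministic, and sufficient for planted-truth
recovery; equivalence with any specific upstream likelihood is not claimed.

Mitochondrial (`mt-`) genes are excluded from kinetics fitting by default:
mitochondrial transcripts do not undergo nuclear splicing, and their
per-cell load variation otherwise masquerades as dynamics.

## The driver-gene score

A "driver" is a gene whose phase-portrait dynamics best explain a cluster's
velocity flow. Within the chosen cluster, each gene gets

$$\text{score} = R^2_{\text{piecewise}} \times
  \frac{\Delta_{\log}}{\max_g \Delta_{\log}} \times
  \frac{|\bar v|}{\mathrm{sd}(v)}$$

* $R^2_{\text{piecewise}}$: coefficient of determination of a two-segment
  linear fit of $u$ on $s$, with cells assigned to the induction or
  repression segment by the sign of $v$. Genes tracing a genuine loop fit
  both segments well.
* $\Delta_{\log}$: spread between the 5% and 95% quantiles of
  $\log(1+s)$ in the cluster. The log scale makes strongly and weakly
  transcribed genes compete on relative spread; on the raw scale a few
  highly expressed genes crowd out genuine low-expression drivers.
* $|\bar v|/\mathrm{sd}(v)$ (directionality): a consistent displacement off
  the steady-state line. This term is the package's main refinement of the
  naive $R^2 \times$ range score: co-regulated gene modules whose expression
  fluctuates *along* the steady-state line (shared TF activity) have high
  $R^2$ and high range but near-zero mean velocity, and without this factor
  they pollute the top of the list.

Constant genes score 0 and rank last; the returned list is truncated to
`top_n` (default 100, the length of the published per-stage driver lists).
For the driver-regulator step the cluster is additionally restricted to the
"start of the trajectory", operationalised as the cluster cells in the
lowest tercile of the non-myogenic signature fraction — the published
methods name the concept but not a definition, so this is configurable.

## Signatures, coexpression and transition cells

Compartment scores are sums of normalised log expression over the top 10
markers of each compartment ("total expression" is read as the normalised
log scale, with a raw-count option out of scope); each is divided by their
sum, giving fractions $s_m + s_n = 1$. The coexpression score
$c = s_m s_n \le 1/4$ flags *transition* cells at $c > 0.20$ (strict: the
boundary fraction solves $f(1-f) = 0.2$, $f \approx 0.2764$, and a cell at
exactly 0.20 is not flagged). Cells whose two signature sums are both zero
are excluded from transition calling rather than set to $0.5/0.5$, which
would fabricate maximal coexpression from silence. Cells are ordered by
increasing $s_n$ with a stable tie-break on the cell identifier.

Markers come from a two-sided Wilcoxon rank-sum test (group vs rest, exact
null on small untied samples, normal approximation otherwise), keeping
positively enriched genes, ranked by p-value then fold change. One numerical
choice matters at benchmark scale: with thousands of cells the approximation
yields p-values like $10^{-300}$ whose ordering is noise, so values below
`p_saturation` ($10^{-250}$, about a rank-sum z of 34) are treated as tied
and the fold change decides. Marker groups are the cluster-derived
compartments; the per-cell presence/absence annotation rule
(`annotate_compartments()`: ligand⁺ or myogenic-gene⁺ ⇒ myogenic) is
implemented exactly as stated but is noisy at realistic depth, as any
"expressing" rule on raw counts is.

## Regulon activity and driver regulators

Regulons (a TF plus its target gene set, consumed as GMT; discovery itself
is out of scope) are scored per cell by recovery-curve AUC: genes are ranked
by decreasing expression, ties broken deterministically by gene identifier,
and the cumulative count of targets within the top
`ceil(top_fraction × n_genes)` ranks (default 5%) is integrated and
normalised by the best achievable area. The statistic is rank-based, hence
invariant to any monotone transform of a cell's expression vector; the test
suite checks it against a brute-force step-curve integration on exhaustive
small cases. "Most active" regulons in a cluster are ranked by difference of
mean AUC (a rank-sum z is reported alongside but does not drive the
ranking; the source methods name no statistic).

A TF is a *driver regulator* of a dataset when its regulon contains at
least `min_driver_targets` (default 1) of the dataset's driver genes.
Per-dataset TF sets are combined into a presence/absence matrix whose row
sums are the recurrence frequencies; on the bundled published matrix the
maximum frequency 4 is attained exactly by Foxp2, Hmga2, Meis1, Meox2 and
Tcf7l2.

## Ligand–receptor complementarity

The imaging-based quantification (per-probe Area% ratio of myogenic to
non-myogenic signal, receptor ratio subtracted from ligand ratio) is
re-expressed on expression data as
$\log_2\frac{\bar x_{\text{myo}} + \varepsilon}{\bar x_{\text{non}} + \varepsilon}$
per gene ($\varepsilon = 0.01$), with score = ligand ratio − receptor
ratio. The log scale makes the subtraction exactly antisymmetric under
swapping the compartment labels. Only the signs are asserted against the
planted truth (Pdgf-like positive; Bmp- and Eph-like negative).

## What the synthetic benchmark emulates — and what it does not

`build_benchmark_dataset()` plants, under a single seed: a bifurcating
topology (cells uniform on $[0, 20]$, branch switch at $t = 8$, post-switch
cells split 50/50); 100 non-myogenic driver genes (4-fold transcription
switches, half up, half down, solved in closed form so trajectories are
continuous at the switch); 50 myogenic-branch switch genes so both branches
carry velocity flow away from the bifurcation; 10 regulons of 20 targets
coupled to their TF by a shared lognormal per-cell activity factor
(sd 0.3), the last regulon being the non-myogenic module whose targets are
drivers; 10 + 10 signature genes and the marker/ligand/receptor genes as
sharp on/off programmes (off-state transcription `base/signature_fold²`);
mitochondrial genes scaled to per-cell Beta(2, 18) fractions with a 5%
planted subpopulation above the 0.20 QC threshold; and negative-binomial
counts (gamma per-cell capture, dispersion 0.15, ~5,000 spliced UMI per
cell, unspliced depth 15% of spliced — mimicking intronic capture). Cells
start at the progenitor steady state, so pre-switch cells sit on the
steady-state line.

Scale defaults (3,000 cells × 1,500 genes) are desk-scale choices: the real
datasets are larger and sparser (4,000–13,000 cells loaded, ~4,000 genes
detected per cell), and no sequencing-depth fitting to the deposited data is
attempted. The generator also omits batch effects, doublets, an
ambiguous-read layer, cell-cycle structure (the pipeline accepts any numeric
per-cell covariates for regression; a pseudo score can be passed), and
UMAP/clustering (cluster labels are inputs). Passing recovery tests on this
benchmark therefore demonstrates correctness of the machinery under a known
generative model — not performance on any particular real dataset.

## Numerical and interface choices

* "More than 20% mitochondrial fraction" is a strict inequality: a cell at
  exactly 0.20 is retained. Filtering is idempotent.
* Normalisation: per-cell scaling to the median depth, then `log1p`;
  covariate regression is per-gene OLS with the intercept restored, so gene
  means are preserved and residuals are orthogonal to the covariates;
  collinear covariates are an error naming the columns.
* kNN graphs are exact (full Euclidean distances on 30 PCs, k = 30,
  deterministic); duplicated cells resolve to each other.
* All ranking tie-breaks are deterministic (gene or cell identifier), so
  reruns under one seed are byte-identical; every result TSV carries the
  config hash and seed in a comment header.
* Genes detected in fewer than 10 cells are flagged unfit and excluded from
  velocity; zero-velocity cells get cosine scores of 0; isolated cells get
  missing confidence.
* Matrix layers are addressed by gene/cell identifier, never by position;
  readers reject shape- or barcode-inconsistent inputs instead of coercing.

## Problem sizes used in the checks

The unit suite runs on a 600-cell × 300-gene benchmark; the acceptance
checks run five full 3,000 × 1,500 benchmarks (driver precision, transition
calling, ligand–receptor signs) and four of those for cross-simulation
recurrence, plus 100-draw kinetics and 50-draw γ-recovery oracles. These
sizes were chosen so the whole suite completes in minutes on a single CPU
while keeping the benchmark at its default conditions.

## Known limitations

* The driver score is a designed statistic, not the upstream tool's EM
  likelihood; only planted-truth recovery is claimed. Differential-kinetics
  correction for outlier genes is not implemented.
* The per-cell annotation rule degrades with sequencing depth (any count
  threshold does); compartment-level analyses use cluster labels where
  available.
* Regulon discovery from data is out of scope; `coexpression_regulons()`
  exists only to fabricate test regulons and does no motif pruning.
* The recurrence analysis treats datasets symmetrically and unweighted; a
  TF present with one edge counts as much as one with fifty (tunable via
  `min_driver_targets`).
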