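---
title: "Methods: linking cell morphology to transcription, networks and outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking cell morphology to transcription, networks and outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapegenet)
```

## The analysis in one paragraph

`shapegenet` implements an image-omics pipeline for breast cancer cell lines
(BCLs). Single-cell morphology is summarized per line (mean and SD of ten
shape features), every gene's expression is screened for Spearman correlation
against those 20 statistics, and the resulting shape-correlated genes are
joined with protein-protein interactions and a panel of preselected EMT and
stemness transcription factors (TFs) into a shape-gene network. Unweighted
shortest and near-shortest paths from each feature statistic to SMAD3, RELA
(NF-kB) and YAP1 define a mechanotransduction subnetwork, whose members are
classified from a gene-knockdown expression panel as regulators of TF
expression, regulators of TF activation (activators vs inhibitors), or TF
effectors. Morphological metagenes — sparse linear models of a feature
statistic in gene expression — are fitted by forward sequential selection and
scored on patient cohorts, where they are tested for ordinal association with
tumor grade (Jonckheere-Terpstra) and for survival stratification
(quantile-optimized dichotomization, Kaplan-Meier/log-rank, Cox). A
synthetic-data generator plants all of these signals so the full pipeline is
testable with no external downloads.

## The correlation screen

Per-line feature statistics are the mean and sample SD (n-1 denominator) of
ten features: cell elongation (width/length, derived per cell before
aggregation), cell area, nucleus width/length/area, nucleus/cell area ratio,
nucleus-center offset, neighbor fraction, protrusion area and ruffliness.
Genes with more than one probe are averaged first; genes whose cross-line SD
is at or below `sd_cutoff = 0.3` are removed (the low-variability mode of
the SD distribution). Spearman's rho uses average ranks for ties, with the
two-sided p from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
n-2 degrees of freedom; a perfect |rho| = 1 is reported at the smallest
positive double rather than zero. At the screen's threshold (|rho| > 0.7,
n = 18) this p is 0.0012, which is why the rho cutoff, not the q-value,
defines the significant set. FDR is Benjamini-Hochberg by default; Storey's
plug-in q-value (lambda = 0.5) is available via `fdr_method = "storey"`.
Because the screen thresholds on rho, the FDR choice does not alter the gene
set — it only annotates it.

## Network construction and centralities

Interaction tables use the STRING download dialect (two identifier columns
plus a combined score, either 0-1000 integers or 0-1 floats; anything larger
is rejected as an unknown scale). Scores are normalized to [0, 1], edges
below `string_min_score = 0.4` dropped (>= keeps the boundary), duplicates
merged keeping the maximum. The network holds three node types — genes, the
twelve preselected TFs (kept even when isolated), and feature statistics
(the mean and SD of one feature are distinct nodes) — and two edge types,
which count identically in all analyses.

Centralities are computed on the unweighted graph: degree; stress (the
number of shortest paths over all unordered node pairs passing through the
node, each path counted once); fractional betweenness; and closeness in the
Wasserman-Faust form `(r/(n-1)) * (r/sum of distances)` over the `r` nodes
reachable from the node, which equals classical closeness on a connected
graph and deterministically penalizes small components on a disconnected
one. All four are verified in the test suite against a brute-force
enumeration oracle on random graphs.

Feature-to-TF paths are enumerated on the graph with all *other* feature
nodes and all *other* preselected TFs deleted, so no path detours through a
second phenotype or TF. "Suboptimal" means up to `path_slack = 1` hop longer
than the shortest path; the slack is configurable because the original
plugin's notion is not published. The subnetwork is the induced subgraph on
the union of path nodes: all parent edges among those nodes are kept, not
just the traversed ones.

## Knockdown-panel classification

A raw panel (measured genes x perturbations, roughly z-scaled) is
consolidated: a perturbation is valid only if it drives its targeted gene
below `kd_valid_z = -0.4`; valid columns per gene are averaged; the matrix
is then re-z-scored per gene across all knockdowns. For a TF, targets are
the genes with |z| strictly above `target_z = 1.5` in its column, with their
signs. A gene is then called, per TF:

* **expression regulator** — its knockdown moves the TF's own z past the
  threshold (direction up/down);
* **activation regulator** — its knockdown perturbs at least
  `ceiling(coverage_frac * K)` of the TF's K targets and the overlap k is
  enriched by the upper-tail hypergeometric test `P(X >= k) < 0.05` in the
  universe of measured genes excluding the TF and the knocked-down gene
  (the universe convention is recorded in every call, since the source
  analysis does not state it); direction is activator when the majority of
  overlapping targets move with the same sign as under TF knockdown,
  inhibitor for the opposite, ambiguous at exactly half;
* **TF effector** — the TF's knockdown moves the gene past the threshold.

One-sided enrichment is used because only overlap excess is meaningful; a
saturated overlap (k = K = n = N) correctly yields P = 1 and no call.
Interaction-edge directionality is annotated whenever one endpoint's
knockdown significantly changes the other.

## Subtype clustering and differential networks

Cell lines are clustered on the z-scored (per gene, across lines) expression
of the subnetwork genes with Euclidean distance and complete linkage, cut at
exactly k = 2 (the analysis uses only the two main clusters). Genes whose
cluster-mean z values differ by more than `dz_cutoff = 0.5` are
differential; non-differential genes are retained in a cluster's network
only while that cluster's mean raw expression reaches `expr_floor = 7.0` on
the log scale. The floor is applied per cluster — each derived network keeps
its own expressed genes — because the two published networks differ in
exactly this way; a global-mean reading was the alternative. The |dz| value
is exported as the node-sizing attribute, and the dendrogram is written as a
Newick string.

## Metagenes

`forward_select_fit` is plain greedy forward selection under ordinary least
squares: at each step the candidate minimizing the residual sum of squares
joins the model, ties broken by input order. "Sum of the residuals" in the
source description is read as the residual sum of squares, since raw OLS
residuals with an intercept sum to zero. Selection always reaches
`min_genes = 4`, then continues while R-squared < `r2_stop = 0.9` up to
`max_genes = 10`; the two published stopping sentences are combined in that
order. Candidates are z-scored across samples by default (`standardize =
TRUE`) so the fitted coefficients transfer to cohorts, which are scored as
`intercept + sum(coef * z-expression)` with per-cohort standardization
bridging platforms; whether the original coefficients were fitted on raw or
z-scored expression is not stated, so both are supported. The NF-kB response
is the natural log (base recorded in the output) of the mean
nuclear/cytoplasmic RELA ratio with TNF over without; its candidate pool is
the genes called regulators of RELA expression or activation. The random
control metagene draws a standard-normal response and 20 random candidate
genes, then runs the identical fit.

## Clinical association

Survival analyses administratively censor at 120 months (10-year
disease-specific survival) and code covariates as: lymph node = 1 if at
least one positive node; tumor size = 1 if strictly greater than 2 cm (a
2.0 cm tumor codes 0). The Jonckheere-Terpstra statistic sums Mann-Whitney
counts over ordered group pairs (ties half-weighted); p uses the
tie-corrected normal approximation with a 1/2 continuity correction — the
uncorrected approximation misses the exact tail by up to ~0.09 at n = 9,
while the corrected one stays within ~0.01 — and full-enumeration exact p
when n <= 12. Dichotomization scans the candidate quantiles {0.2..0.8},
keeps the split with the smallest discovery log-rank p (ties resolved toward
the median; splits leaving a group without events skipped), and transfers
the chosen cutoff *value* — not the quantile — to the validation cohort,
which is what applying a trained rule means. Kaplan-Meier and Cox fits
(Efron ties, Wald tests, univariate and multivariate with size + grade +
node) are delegated to the survival package behind the module's interface;
the log-rank observed-minus-expected table and the product-limit curve are
nonetheless verified against hand-computed examples in the tests.

## The synthetic stated world

The generator emulates the five real inputs at desk scale with planted,
recoverable ground truth:

* **Cells**: per-line latent feature means drawn around plausible adherent
  breast-line scales (e.g. cell area ~N(2500, 700^2) px^2, elongation
  ~N(0.65, 0.1^2)), cells Gaussian around their line's latent mean with a
  line-specific SD. Elongation is generated as the latent per-cell feature
  and raw width derived from it, so the width/length derivation is exact.
  Values are not truncated; realism of marginals is explicitly out of scope.
* **Expression**: log-scale i.i.d. N(8, 1.5) background so the 7.0
  expression floor is exercised on both sides; 41 planted shape genes as
  linear (hence monotone) transforms of their statistic with
  signal-to-noise 4 — chosen once, by simulation, to give high but imperfect
  recovery — 30% of background genes below the SD cutoff, 10% of genes as
  duplicate probes.
* **Interactions**: one high-confidence edge per planted regulator-TF pair
  (placing each regulator on a two-hop feature-to-TF route) plus random
  edges above and below the score floor, written in the 0-1000 dialect.
* **Knockdowns**: on-target depth -3 (or -0.2 for planted invalid columns),
  trans effects +-2.5 before per-gene re-z-scoring; three TF regulons
  (20/20/10 signed targets), activation regulators covering 60% of their
  TF's regulon, expression regulators moving only the TF.
* **Cohort**: i.i.d. patient expression; the latent metagene is the planted
  linear combination; grade is a noisy tertile cut of the latent; survival
  is exponential with log-hazard either linear in the standardized latent
  (hazard_beta = 0.7; used for Cox parameter recovery) or a step at the
  latent's 0.6 quantile (used for cutoff recovery); censoring is an
  independent exponential competing time.

What a green test does **not** establish: recovery under realistic
expression covariance (background genes are independent), under batch or
platform effects, or at full scale. Two desk-scale artifacts are handled
explicitly and documented here rather than hidden: (i) with 400 genes the
|rho| > 0.7 screen admits a handful of chance background genes — the same
multiple-testing phenomenon as the original FDR < 23% — so screen
*precision* reflects the background test count, not implementation quality;
(ii) the random-control metagene draws its pool from genes excluding the
planted metagene genes, because at 20-of-400 the draw would contain a
clinically active gene often enough to contaminate the null being
calibrated, whereas at the original 20-of-11,314 scale that probability is
negligible.

## Numerical conventions

Sample SD (n-1) throughout; BH over all tested pairs; zero-variance feature
statistics are excluded from testing and logged; rank-deficient candidates
are dropped from forward selection with a message; a flat gene row in the
knockdown panel re-z-score is left at zero rather than NaN; hypergeometric
tails use `phyper(k-1, ..., lower.tail = FALSE)`; all path and centrality
computations are on unweighted hop counts, with STRING scores used only as
an inclusion filter. Every stage reads thresholds from the validated
`pipeline_config` object, which serializes to JSON alongside every run.

```{r example, eval = FALSE}
cfg <- pipeline_config()
run_pipeline("all", cfg, out_dir = "demo_run", seed = 1)
```
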