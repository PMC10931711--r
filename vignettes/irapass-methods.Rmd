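---
title: "Methods: differential APA, the IRAPAss score, and network prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential APA, the IRAPAss score, and network prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`irapass` implements an analysis pipeline for alternative polyadenylation
(APA) in tumor immunotherapy cohorts. The pipeline begins at PDUI tables
(Percentage of Distal polyA site Usage Index, the DaPars2 statistic: the
fraction of a gene's transcripts using the distal polyA site, so low PDUI
means a shortened 3'-UTR). Read alignment, APA quantification,
immune-deconvolution scoring and single-cell processing are upstream of this
package and enter only as tables.

The pipeline has four analysis stages, each exercisable on synthetic cohorts
with planted ground truth:

1. differential 3'-UTR usage calling between responders (PRCR) and
   non-responders (PDSD);
2. an APA-factor regulatory network ranked by twelve topology algorithms;
3. the IRAPAss scoring system (correlation scores, preranked GSEA,
   pathAPAscore screening, Cox/LASSO selection, a linear scorer);
4. personalized-PageRank extraction of a feature-based module from a
   protein-interaction network.

# Differential APA calling

For two groups A (responders) and B (non-responders), each event's group
means are averaged over non-missing samples and

$$\Delta PDUI = \overline{PDUI}_A - \overline{PDUI}_B .$$

Positive values mean lower distal usage — a shortened 3'-UTR — in
non-responders. Significance comes from a two-sided label-permutation test:
labels are permuted jointly across events (preserving between-event
correlation) and

$$p = \frac{1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\}}{B + 1},$$

the add-one estimator, so p is never zero and the test is slightly
conservative. An event is called when $|\Delta PDUI| \ge 0.1$ (inclusive)
and $p < 0.05$ (exclusive); BH-adjusted q-values are always reported
alongside, and `use_fdr = TRUE` switches the significance criterion to q.
We default to raw p because the calling rule is stated in terms of p with
the permutation scheme itself controlling the FDR; the choice is exposed
rather than hidden. Events with fewer than 3 non-missing values in either
group are excluded rather than imputed — PDUI tables are sparse and
imputation would fabricate 3'-UTR signal.

Small cohorts can request `method = "exhaustive"`, which enumerates every
assignment of the group-A label set; the tests verify that this equals an
independently written enumeration oracle.

Subgroup utilities follow the same machinery: one-vs-rest contrasts over the
TA/TS/TN T-cell subgroups (activation / suppression / naive, assigned by the
largest summed population fraction with the fixed tie priority TA > TS > TN),
and gradient events whose three subgroup means are strictly monotone with a
range of at least the calling threshold.

# The ATF network and master factors

APA-factor regulation is screened by Spearman correlation between each
factor's expression and each differential event's PDUI (pairwise-complete
observations; p from the t-approximation). An edge requires `p < 0.05` and
`|rho| >= 0.3`; the magnitude cutoff is not part of the published method
description, so it is a configurable default chosen to keep the network
sparse (`rho_threshold = 0` recovers a p-only screen). Protein-interaction
edges between factors and event parental genes are overlaid, with parallel
evidence collapsed onto a single edge.

Node importance uses the twelve cytoHubba-family algorithms (Degree,
Betweenness, Stress, harmonic Closeness, 1/eccentricity, Radiality, local
clustering coefficient, MNC, DMNC with $\varepsilon = 1.7$, MCC over maximal
cliques, BottleNeck with subtree threshold $n/4$ and parent ties broken by
smallest node id, and Monte-Carlo edge-percolation EPC with 1000 samples at
retention 0.5, seeded). Analysis is restricted to the largest connected
component; nodes outside it rank last. How twelve rankings were reduced to a
master-factor list is not specified in the published description; we use
Borda aggregation (sum of per-algorithm ranks over factor nodes, ties broken
by Degree then lexicographically) because it is deterministic, order-invariant
and transparent, with `intersection-topN` available as an alternative.

# The IRAPAss scoring system

Within one sample group, the correlation score between gene $x$ and event
$y$ is

$$CS_{xy} = -\log_{10}(P_{xy} + 10^{-20})\,\mathrm{sign}(Cor_{xy}),$$

with $Cor$ the Pearson correlation and $P$ its two-sided p-value; the
pseudocount caps $|CS|$ at 20. Each event's CS vector over all genes is the
ranking statistic for preranked GSEA: hits advance the running sum by
$|CS|^{w}$ (normalized, $w = 1$ by default; $w = 0$ is the classic KS
statistic), misses retreat by $1/(N - N_h)$, and ES is the maximum signed
deviation. The null is gene-label permutation — the ranked list is a vector
of per-event correlation scores, so phenotype permutation is unavailable —
with the permutation count and seed recorded; p is two-sided with the
add-one estimator, NES divides ES by the mean |null ES| of matching sign,
and FDR is BH across pathways. The defaults $w = 1$, 1000 permutations are
package choices; the published description names only the GSEA method.

The association statistic is

$$pathAPAscore = \begin{cases} 1 - 2p & ES > 0 \\ 2p - 1 & ES < 0, \end{cases}$$

zero at $ES = 0$ by continuity. Screening keeps event-pathway pairs with
$|pathAPAscore| > 0.995$ and FDR $< 0.05$ in at least one response group,
then requires opposite NES signs between responders and non-responders, then
requires the pair to replicate in both cohorts with the same orientation.
Note $p < 0.0025$ is only attainable when the permutation count is at least
799; at the default 1000 permutations the minimal score is $1 - 2/1001
\approx 0.998$.

Surviving events enter a univariate Cox screen (features standardized,
$p < 0.05$) and LASSO Cox selection (penalty by cross-validated partial
likelihood at the 1-SE rule, falling back to the CV minimum when 1-SE selects
nothing) on the discovery cohort, matching the published stage-to-cohort
assignment; the stage cohort is configurable. The final scorer trains on the
pooled samples with a random 70/30 split. Although the original description
names a multilayer perceptron, the published formula is a plain linear
combination of ten raw PDUI features, so the canonical architecture here is a
single linear layer (logistic link against responder status) whose
coefficients multiply raw PDUI exactly as the printed formula does; an `mlp`
option (one hidden layer plus skip connections) is provided, with an
equivalent-linear export valid when the hidden layer carries negligible
weight. The published ten-event model ships in
`inst/extdata/irapass_published_model.tsv` and loads via
`published_irapass_model()`; its coefficients are the ground truth for the
scoring contract.

Evaluation reports the response ROC/AUC (responders as cases), an optimal
cutoff (Youden index by default; a median split is available), Kaplan-Meier
curves with the log-rank p for the high/low score groups, and a multivariate
proportional-hazards model of the score group plus supplied covariates. The
published description says "optimal cutoff" without naming a method; Youden
on the response ROC is the default because response is the score's training
target.

# Feature-based module extraction

The protein-interaction network (STRING-style combined scores, strict
`> 700` filter, undirected de-duplication keeping the maximum score) is
reduced to its largest connected component (size ties broken toward the
component containing the lexicographically smallest node id). Personalized
PageRank is power iteration with damping 0.85, teleport mass uniform over
the seed genes — the parental genes of the model features — L1 tolerance
1e-10, and dangling-node mass redistributed to the teleport vector. The top
200 genes by impact score form the module; whether the seeds themselves
belong to the module is unstated in the source description, so they are
included and flagged with `is_seed`.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis assumes,
not any real expression program:

* **PDUI** values are Beta draws with per-event baseline means uniform on
  (0.25, 0.75) and concentration 20 (within-group SD ~0.1, a realistic
  DaPars2 spread); PDUI is a bounded proportion, hence the Beta family.
* **Planted differential events** (default 50 of 2000) shift the
  non-responder mean by ±0.2 (negative = 3'-UTR shortening), clipped away
  from the boundaries.
* **Factor regulation** couples an event's PDUI to its regulator's
  expression through a Gaussian copula; the copula correlation is
  $2\sin(\pi\rho_s/6)$ so the realized Spearman correlation matches the
  target (default 0.6). One designated hub factor additionally regulates 30
  of the planted differential events, making it the ground-truth master
  regulator.
* **Immune coupling**: each of the 20 immune-coupled events drives its own
  disjoint block of one immune pathway's genes, shifting their
  log2-expression by ±1.2 per standardized PDUI unit with opposite sign in
  responders and non-responders — exactly the opposite-orientation structure
  the screen looks for. Blocks are disjoint by design: coupling every set
  gene to the same mixture of events makes set genes nearly collinear, and
  gene-permutation GSEA is then anti-conservative for *any* statistic, which
  is a property of that screen worth knowing about, not a useful test bed.
* **Survival** is exponential with log-hazard $\beta \cdot$ latent score
  (default $\beta = -1$; the latent score is 1 + noise in responders, 0 +
  noise otherwise, so high scores are protective). A sample is censored with
  probability `censor_rate` (default 0.3) at a time uniform on (0, its event
  time).
* **Missingness** is completely at random (default 5%).
* Structure (which events, factors, pathways are planted) is driven by
  `structure_seed`, noise by `seed`, each table from its own sub-stream —
  so replicate cohorts share planted truth, and adding an output never
  perturbs earlier draws. Cohort sizes default to 23/82 with a 14/13
  companion cohort, the two melanoma anti-PD-1 designs.

What the generator does **not** emulate: batch effects, library-size or
GC biases, correlated missingness (DaPars2 missingness tracks coverage),
transcript-level structure, overlapping regulatory programs, and real
pathway co-expression beyond the planted couplings. Passing recovery tests
therefore demonstrates that the implementation detects the structure it is
designed to detect at realistic sizes and noise — not that the biological
claims transfer to any real cohort.

# Numerical choices and degenerate inputs

* Permutation and GSEA p-values use add-one estimators, never zero.
* Correlation p-values use the t-approximation (both Pearson and Spearman);
  perfect correlations are clamped so downstream `-log10` and BH stay finite.
* Constant vectors: a constant event yields $\Delta = 0$, $p = 1$; a
  constant gene yields missing CS; a constant survival feature is skipped
  with a warning.
* A gene set spanning the whole universe leaves no misses; its degenerate ES
  is reported with a warning.
* Ties: subgroup assignment uses the fixed priority TA > TS > TN; module and
  master-factor orderings break score ties lexicographically; BottleNeck
  parent selection takes the smallest node id.
* The scorer's split indices, seeds and Monte-Carlo settings are stored in
  model metadata; writers stamp a version/parameter comment line.

# Problem sizes used in the test suite

Module tests run on instances small enough for exhaustive oracles (graphs of
at most 12 nodes, permutation tests over at most $\binom{8}{4}$ label
splits, GSEA universes of at most 15 genes). The recovery experiments run at
the study design itself — 2000 events, 3000 genes, 23 vs 82 plus 14 vs 13
samples, 1000 permutations, ten seeds — which we consider the smallest scale
at which sensitivity, FDR and AUC claims about the pipeline are meaningful.

# Known limitations

* The permutation scheme assumes exchangeable samples within cohorts; no
  covariate adjustment is offered.
* Gene-permutation GSEA understates the null variance for internally
  correlated gene sets (see the generator discussion above).
* MCC requires exact maximal-clique enumeration and refuses components
  beyond a configurable bound rather than silently approximating.
* The LASSO stage inherits the instability of cross-validated penalty
  selection at small event counts; the selection trail (univariate table,
  CV fit) is kept in the output for inspection.
* The published ten-event model is shipped as data; this package can
  reproduce its *form* and scoring contract on synthetic cohorts but not its
  coefficients, which require the original patient cohorts.
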