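---
title: "Two-state co-expression networks: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state co-expression networks: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

saltnet turns a two-condition time-course count matrix into co-expression
modules, module–trait relationships, and a list of "key genes" whose
network importance rises under stress. This vignette explains the model
behind each stage, the parameters that matter and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices a maintainer should know about.

## Pipeline model

**Preprocessing.** Genes with a zero count in more than 80% of libraries
(`zero_fraction = 0.8`) are unreliable at typical 3′-tag sequencing
depths and are removed. Size factors follow the median-of-ratios rule:
for sample $s$, $\hat{s}_s = \mathrm{median}_g\, c_{gs}/(\prod_t
c_{gt})^{1/n}$ over reference genes $g$ with all-positive counts. Note
the median is taken on the *ratio* scale, exactly as the formula reads;
the exp-of-median-of-log variant differs whenever the reference set has
even size. A consequence worth knowing: scaling one library by $c$
multiplies every *ratio* of factors involving that library by $c$, but
each individual factor also absorbs a common $c^{-1/n}$ through the
geometric means — size factors are meaningful up to a shared scale.

**DE screen.** Each gene is fitted with a negative-binomial GLM of the
raw counts on the condition label, with log size factors as offsets.
The dispersion is a per-gene method-of-moments estimate on normalized
counts, $\hat\alpha = \max((v - m)/m^2, 10^{-8})$; the Wald statistic is
the condition coefficient over its standard error, with a two-sided
normal p-value, and genes are kept at raw $p < 0.05$ (no multiplicity
correction — this stage is a screen that feeds the network, not an
inference endpoint). Two implementation details matter. First, the
covariance must be taken at dispersion 1 (`summary(fit, dispersion =
1)`): the NB variance is already carried by $\theta = 1/\hat\alpha$, and
letting `summary.glm` rescale by the Pearson statistic (its default for
non-standard families) turns the test into a quasi-likelihood one and
breaks the degenerate all-constant case. Second, all-zero genes get
$p = 1$ by convention. Calibration is verified by simulation: on 2,000
matched-mean null NB genes the empirical type-I error is ≈ 0.05 and the
p-values are near-uniform (Kolmogorov–Smirnov distance ≈ 0.01).

**Networks.** Correlations are Pearson on $\log_2(\text{normalized} +
1)$ (the transform is a package choice; a pseudo-count of 1 avoids
$-\infty$ and is standard for count data). The unsigned power adjacency
$a_{ij} = |r_{ij}|^\beta$ treats strong negative co-expression as
connectivity, deliberately: repressed and induced members of one
regulatory program belong together. The soft threshold is the smallest
scanned power whose scale-free fit reaches $R^2 \ge 0.90$ **with a
negative slope** — a positive-slope log–log fit is not scale-free
topology no matter its $R^2$, which is why the slope condition is part
of the rule (the signed-$R^2$ convention). Small or strongly modular
networks often never reach 0.90; `pick_power()` then falls back on the
standard sample-size rule of thumb for unsigned networks (< 20 samples:
9; 20–30: 8; 30–40: 7; > 40: 6). Edges are kept at weight ≥ 0.1,
inclusive; nodes isolated after thresholding are dropped from the graph
but retained in the adjacency. The global network uses all samples of
the DE genes; the normal-state and salinity-state networks use the same
genes restricted to control or stress samples, with the power chosen on
the global network so the three are comparable.

**Modules.** $\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$ is computed on the full weighted
adjacency (pre-thresholding). Average-linkage clustering runs on
$1 - \mathrm{TOM}$; tied dissimilarities can leave `hclust` heights
non-monotone within floating-point noise, so heights pass through
`cummax` before cutting. Branches come from a **static cut** at
dissimilarity `cut_height = 0.85`. A static cut was chosen over a
merge-height quantile because of how the two behave on structureless
input: for independent genes all merge heights crowd into a narrow band
near 1, so any quantile cut yields large meaningless clusters, whereas a
fixed cut below the band leaves every noise gene a singleton → grey.
The default 0.85 sits well above genuine within-module merge heights
(≲ 0.7 on the reference simulation) and well below both the noise band
(≈ 1) and the heights at which chance-correlated module pairs merge
(≈ 0.93–0.95 with 18 samples per state; correlation estimates at that
sample size have a standard error around 0.24, so occasional strong
spurious module–module correlation is expected and the cut must not
reach it). Clusters below `min_module_size = 30` go grey; modules whose
eigengenes correlate above $1 - \texttt{merge\_cut} = 0.75$ are merged
iteratively; and grey genes whose best absolute module membership (kME,
correlation with an eigengene) reaches `kme_rescue = 0.50` are assigned
to that module — the rescue matters for stress-rewired genes, whose
global-network topological overlap is diluted by their inactivity in
half the samples. Labels are size-ordered color names; grey is reserved
for unassigned genes.

**Module–trait relationships.** One indicator trait per time point
(1 for stress samples at that time, 0 elsewhere; controls are included
as 0 by default and can be excluded with
`include_controls_in_traits = FALSE` — both encodings are supported
because published analyses rarely state which was used). Pearson $r$
per eigengene × trait with the exact $t$ test on $n - 2$ degrees of
freedom; a pair is significant at $|r| > 0.50$ and $p < 0.05$.

**Centralities and key genes.** The four measures run on the
thresholded, unweighted graph. Betweenness is normalized by
$(N-1)(N-2)/2$ with $N$ the size of the node's connected component;
closeness is the inverse mean distance to reachable nodes (0 for
isolates); the clustering coefficient is 0 below degree 2. Percentile
ranks are ascending-by-value with average-rank ties, so ties compress
toward the middle — a deliberate property: in a saturated subgraph where
many nodes tie, none of them can occupy the "top decile". Key genes are
flagged per module and measure when the salinity percentile is
≥ 0.90 (`salinity_top_fraction = 0.10`) and the normal percentile is
≤ 0.50 (`normal_max_percentile = 0.50`); genes absent from a state's
graph count as percentile 0 there. The quantification of "low in
normal, high in salinity" is the package's declared operationalization —
the qualitative rule it implements does not fix numbers — and both
thresholds are configurable and recorded in the outputs. Flags are
unioned over measures, with a multi-measure annotation, matching the
convention of highlighting genes detected by more than one centrality.

## The synthetic-data generator

`generate_dataset()` emulates the 36-library design: 2 conditions × time
points 0, 3, 6, 12, 24, 48 h × 3 replicates. Counts are negative
binomial with mean $s_s \exp(b_g + \lambda_g f_{m(g),s} + \delta_g)$:
log-uniform baselines $b_g \in \ln[100, 3000]$, per-sample size factors
with log-sd 0.25, dispersion 0.05, and a condition main effect
$\delta_g$ of ±1.5 log2 units for ordinary planted genes. Six modules of
50 genes ride on per-module latent factors whose mean follows the
activity profile — flat in control, a single-time-point bump of
amplitude 2.5 (natural-log units) under stress, at a different time
point and sign per module. The control-state factor noise is inflated so
the per-state factor variance (and covariance, below) matches the stress
state: ordinary co-expression strength is condition-independent by
construction, so only the planted key genes rewire between states.

Key genes are the part that needed real design care. Modules come in
pairs whose factor noise components correlate at `factor_cor = 0.6` —
too weak to connect ordinary genes across the pair (their cross
correlations stay safely below the edge threshold
$0.1^{1/\beta} \approx 0.72$ at $\beta = 7$), but enough for the six key
genes per module, which load on **both** factors of their pair (1.15 :
0.85 in favor of the home module, at $0.9/\sqrt2$ each), to correlate
highly with both. The loading is active in stress samples only. The
result is the intended two-state signature: in the normal network key
genes are absent; in the salinity network they bridge the pair and hold
the top degree, closeness and betweenness ranks of both modules. A
flat-loading design cannot produce this: at 18 samples per state and
$\beta = 7$, a gene's correlations to two independent blocks are bounded
by $r_{\text{own}}^2 + r_{\text{partner}}^2 < 1$, which cannot clear the
edge threshold twice — correlated pair factors are the escape hatch.
Two further deliberate choices: there are *more* key genes per module
(6/50) than the 10% flag window, so the true keys saturate the top
decile and ordinary genes cannot enter it for the hub-type measures; and
keys carry a larger condition effect (3.5 vs 1.5 log2) because their
stress-only factor loading inflates the within-stress variance that the
pooled Wald screen must overcome — without it a substantial fraction of
keys never pass the DE screen and cannot appear in any network.

What the generator does **not** emulate: batch effects, library-prep
artifacts, read-level noise, zero inflation beyond the NB, annotation
structure, and — most importantly — the messy, partially overlapping
module structure of real transcriptomes. Passing the recovery tests
therefore shows the pipeline is correct and well-calibrated on data that
satisfies its assumptions; it does not promise comparable precision and
recall on real tissue data, where "truth" is unknown and module
boundaries are soft.

## Validation design and reference problem sizes

The test-suite checks fall into four families, run at sizes chosen to
keep the default suite fast while leaving no stage untested:

* **Oracle equivalence** — centralities against hand-rolled BFS
  path-counting on 100 random graphs (n ≤ 15), exact for degree and
  clustering coefficient and within $10^{-9}$ for betweenness and
  closeness; TOM against a triple-loop evaluation on 20 random weighted
  adjacencies (n = 15) within $10^{-10}$; size factors against the
  literal ratio-matrix median; the hypergeometric tail against the
  explicit binomial-coefficient sum and base R's one-sided Fisher test.
* **Closed forms** — stars, paths, cycles, cliques for the centralities;
  the doubled-column size-factor case $(1/\sqrt2, \sqrt2)$; the
  $(0.01, 0.02, 0.03) \to (0.03, 0.03, 0.03)$ BH step-up example; the
  published three-network summary panel re-derived from its own node and
  edge counts ($2E/N$, $E/N$).
* **Recovery** — on the default simulation, three fixed seeds: adjusted
  Rand index ≥ 0.8 between detected and planted modules, and key-gene
  precision and recall ≥ 0.7 at the default thresholds, with a
  no-rewiring control whose flagged fraction must stay under the
  threshold-geometry union bound (4 × 0.10 × 0.50).
* **Calibration** — Wald type-I error within [0.03, 0.07] on 2,000 null
  genes; Fisher-enrichment null rejection within the same band over
  1,000 random query sets (universe 2,000, term size 100, query 200 —
  sizes at which the discrete hypergeometric p is close enough to
  uniform for the band to be meaningful).

Two textual invariants were corrected to their mathematically true
forms during development: size-factor equivariance holds for factor
*ratios* (not individual factors), and adding unannotated genes to the
enrichment universe can only *decrease* an over-representation p-value
(dilution makes the same overlap more surprising).

## Known limitations

* The DE screen pools all time points into a condition main effect;
  genes with transient, sign-balanced responses can escape it.
* The static tree cut plus kME rescue approximates dynamic tree cut; it
  was tuned for well-separated planted modules and may fragment or
  over-merge real data with nested module structure.
* With 18 samples per state, correlation noise (sd ≈ 0.24 per pair) is
  irreducible: occasional chance merges of unrelated modules and
  near-threshold edge flips are properties of the design, not bugs.
* MTR significance of a planted module at $|r| > 0.50$ sits near the
  boundary under the default effect sizes, so the number of significant
  modules varies by seed; key-gene recovery is therefore evaluated over
  all detected modules rather than the MTR-selected subset.
* The scale-free fit $R^2$ of small modular networks is intrinsically
  low; the reported panel includes it for comparability, not as a
  goodness criterion.
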