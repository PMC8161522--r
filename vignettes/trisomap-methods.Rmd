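---
title: "Methods: rank-based dosage analysis of trisomy model panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based dosage analysis of trisomy model panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisomap)
```

# The analysis problem

Segmental-duplication mouse panels carry three copies of nested or
overlapping chromosomal intervals, so that comparing lines localizes which
interval drives a molecular or behavioural phenotype. Two quantities
organize the transcriptome side: the *dosage effect* — a three-copy gene is
expected at a 3:2 = 1.5 linear expression ratio — and *dosage
compensation* — the fraction of three-copy expressed genes that nonetheless
show no differential expression. Around these sit genome-wide *trans*
effects, their correlation between models sharing duplicated intervals,
pathway-level readouts, and the protein-interaction neighbourhood of the
affected (synaptic) genes.

`trisomap` implements this chain end to end: a rank-based differential
expression statistic, per-model gene bookkeeping, a directional gene-set
test aggregated into meta-pathways, seed-network construction and
decomposition, the standard quantification formulas for qPCR, western
blots, MRI volumetry and behavioural batteries, and a synthetic-data
generator that makes every stage testable in isolation.

# Differential expression by fold-change rank ordering

For group sizes $n_c$ (control) and $n_t$ (trisomic), all
$k = n_c n_t$ test/control sample pairs are formed (deterministic
control-major order). This all-pairs choice keeps the statistic exact and
reproducible; the method family is defined for "$k$ pairs" without fixing a
subset, and all pairs is the natural deterministic default. Within each
pair, per-gene log2 fold changes are ranked increasingly, with ties
averaged so that degenerate simulated inputs are stable; ranks are divided
by the gene count $m$, giving values in $(0, 1]$. The per-gene mean
normalized rank $\bar r$ over the $k$ pairs is standardized to
$z = (\bar r - \mu)/\sigma$ and mapped to an f-value $f = \Phi(z)$.

Two standardizations are exposed:

* **empirical** (default): $\mu, \sigma$ are the mean and SD of the
  observed $\bar r$ values. This is robust to an asymmetric burden of
  differential expression and is what the package's calibration tests
  exercise.
* **theoretical**: $\mu = 1/2$, $\sigma = \sqrt{1/(12k)}$, the null
  moments of a mean of $k$ independent uniform normalized ranks. Slightly
  anti-conservative at small $m$ and when pairs correlate, but useful as a
  reference.

Genes with $f < \alpha_\mathrm{low}$ or $f > \alpha_\mathrm{high}$
(defaults 0.025 / 0.975, a 5% two-sided window) are called down- or
up-regulated. The reported per-gene effect is the **median** pairwise log2
fold change — a robust estimator chosen because the pairwise FC
distribution has no natural mean interpretation under outlying samples.
Under a complete null the window flags close to 5% of genes; the test suite
checks $5\% \pm 1$ percentage point at $m = 20{,}000$ over 10 seeds.

The window is applied to raw f-values. An optional Benjamini–Hochberg
filter on the two-sided f-derived p-values ($2\min(f, 1-f)$) can be added
in `call_degs(adjust = TRUE)` but is off by default: the two published
descriptions of the calling rule (an $\alpha$ window on f; a "5% FDR") are
not mutually consistent, and the window is the one that is exactly
specified. Degenerate inputs where every gene ties in every pair yield a
warning, $f = 0.5$ everywhere and zero calls.

**Expressed genes.** Intensity arrays lack a universal detection call; a
gene is treated as expressed when its mean log2 intensity exceeds the
matrix-wide 10th percentile of gene means (configurable, including an
absolute threshold). This choice only gates bookkeeping denominators, not
DE calling.

# Trisomy bookkeeping

A gene is *in* a duplicated interval iff its start coordinate lies within
the closed interval (1-based, inclusive) — one rule used consistently by
the generator, the classifier and the tests, so cis-gene counts always
reconcile. Per model: TEG = expressed gene inside the duplicated intervals;
differential TEG = TEG also called DE;
$\mathrm{pct\_differential} = \mathrm{round}(100\,\cdot\,$ differential
TEGs / TEGs$)$ with halves rounded away from zero (the convention that
reproduces published panel tables, e.g. 54/127 → 43%), and
pct_compensated is its complement. "TEG" deliberately follows the
table-style usage (any expressed cis gene); the narrower text-style usage
(cis DEG) is carried as the `differential_teg` flag.

Cross-model effect correlation is $100 \times r$ (Pearson by default,
Spearman available) of median log2 FC vectors over a stated universe —
either the union of all models' DEGs or a cis-region gene list; both modes
are exposed because both summaries are in common use. DEG overlaps are
reported as complete Venn partitions. Sample structure is visualized by PCA
or by a spectral neighbour embedding (Laplacian eigenmaps on a
k-nearest-neighbour sample graph with a fixed eigenvector sign convention,
hence deterministic), scored by the mean silhouette width between genotype
groups.

# Gene sets and meta-pathways

Per sample pair, the set members' log2 fold changes are compared with all
other measured genes by Welch's t-test, one-sided in each direction. The
$k$ per-pair p-values are combined by a Stouffer sum. Because all pairs
sharing a control or a test sample are positively correlated, the naive
$\sqrt k$ denominator is badly anti-conservative; the combination instead
divides by $\sqrt{\sum_{ij} \rho_{ij}}$ with
$\rho_{ij} = (\mathbb 1[\text{same control}] + \mathbb 1[\text{same
test}])/2$, the correlation implied by equal per-sample noise
contributions. With the full $n_c \times n_t$ design this equals
$\sqrt{k(n_c + n_t)/2}$. The pair design is attached to the fold-change
matrix by `pairwise_fold_changes()`; a plain matrix with genuinely
independent columns is combined with $\sqrt k$. The test suite verifies
both calibrations (uniform null p-values for independent columns; a null
discovery fraction at $q < 0.1$ below 10% over 500 random sets on
simulated 5v5 data, 10 seeds).

Across a collection, the two-sided $p = 2\min(p_{up}, p_{down})$ is
BH-adjusted; sets with $q < 0.1$ get the direction of the smaller one-sided
p. Significant sets are aggregated into ten keyword-defined meta-pathways
(synaptic; myelin & SNARE; transcription & epigenomics; ribosome;
mitochondria; cell structure & organelles; phospho-kinases; interferon;
stemness & differentiation; enzyme activity) as separate up and down
counts. The keyword map is a shipped, editable best-effort reconstruction —
the canonical ten-group membership has never been fully enumerated — with
deterministic first-match precedence and explicit reporting of unmapped
significant sets. Inter-model connectivity counts, per meta-pathway, the
genes that are *core members* (measured members whose median FC has the
set's direction and magnitude above the set median — an invented but
documented rule) of significant sets in both models of a pair.

# Seed networks

Edge tables are confidence-filtered at CS ≥ 0.4 (inclusive; 0–1000 scores
auto-rescaled, duplicate undirected edges collapsed keeping the maximum).
The minimum connected seed network starts from the subgraph induced on the
seeds and repeatedly joins the two closest components by the globally
shortest path in the full filtered graph, marking interior nodes as
connectors; ties break by (path length, summed $1 -$ confidence,
lexicographic node ids). Exact Steiner trees are NP-hard and unnecessary at
these sizes; the greedy merge is then **pruned**: any connector whose
removal leaves all seeds mutually reachable is deleted (deterministic
order), so the output satisfies, by construction, the property that every
connector is load-bearing — verified by exhaustive single-deletion in the
tests. Seeds absent from the edge universe or in unreachable components
are reported, never silently dropped. Paths are unweighted by default
(confidences kept as attributes; $1-$confidence weighting available).

Hubs are ranked by exact normalized betweenness (checked against an
exhaustive path-enumeration oracle on small graphs), with 2-step control
percentages computed on the *induced* 2-neighbourhood (edges among level-2
nodes included; whether the published convention meant the BFS tree is
unknowable, and the induced reading is the more conservative
neighbourhood). Percentages exclude the hub itself from numerator and
denominator.

Null significance uses degree-preserving double-edge-swap randomization
(`igraph::keeping_degseq`, $10|E|$ rewiring trials per replicate, no loops
or multi-edges), with empirical $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(N + 1)$ — never exactly 0; a published asymptotic
"p < 2e-16" corresponds here to saturation at $1/(N+1)$. The tested
statistic ("such connectivity") is not canonically defined, so three
metrics are implemented — seed-internal edge count (default), global
clustering, mean seed distance — and the chosen metric is always part of
the output. The default replicate count is 100,000, matching published
practice; tests and the demo pipeline scale down to 10,000 and below
purely as a problem-size choice. Small-world sigma is
$(C/C_\mathrm{rand})/(L/L_\mathrm{rand})$ against the same null, with a
dense-graph caveat flag; the degree tail is fitted by maximum-likelihood
power law (`igraph::fit_power_law`).

The published connector-relevance machine-learning score is out of scope
(external trained model); where a composite relevance is needed, the hub
report's betweenness and neighbourhood coverage serve as a transparent
stand-in.

# Phenotype quantification

* **Comparative Ct**: quantity $= E^{Ct_{\min}(g) - Ct(s,g)}$ with
  amplification factor $E \in (1, 2]$ (default 2), so the most expressed
  sample of each gene is 1.
* **geNorm**: stability $M_j$ = mean over partners of
  $\mathrm{sd}_s\,\log_2(q_j/q_k)$; iterative removal of the highest-M
  candidate until 2 remain (count configurable; the published procedure
  keeps "the more stable" genes without a count) or all $M < 0.5$;
  normalization factor = per-sample geometric mean of kept references.
* **Fold induction**: normalized quantity divided by the genotype's mean
  dark-housed quantity, so dark-housed groups average exactly 1.
* **Western blot**: (signal / loading control) normalized by the wild-type
  mean ratio; scale invariant.
* **MRI**: structure volumes normalized by whole-brain volume, per-structure
  Student's t with BH adjustment (the published correction names only
  "FDR"; BH is used everywhere in the package).
* **Behaviour**: Shapiro–Wilk (per group) and Brown–Forsythe (ANOVA on
  absolute deviations from group medians) gates at $\alpha = 0.05$ choose
  one-way ANOVA vs Kruskal–Wallis; Fisher's LSD (pooled-MSE pairwise t, no
  multiplicity adjustment) runs only behind a significant omnibus; groups
  under $n = 3$ take the non-parametric path with a note. The novel-object
  chance test is a two-sided one-sample t against 50% — two-sided because
  preferences for the familiar object are real outcomes. Repeated-measures
  designs are reduced to per-session comparisons; mixed models are out of
  scope.

# The synthetic-data generator

The generator is first-class, tested code. It emulates: a genome of
non-overlapping genes on a few chromosomes; a panel of one full-span model
containing proximal/middle/distal sub-spans, a compound model (union of two
disjoint sub-spans), a single-gene transgenic line, and a compound line
with an extra non-syntenic duplicated segment; and per-model expression
with cis genes shifted by $\log_2(\text{dosage ratio})$ unless compensated,
a genome-wide trans program, and i.i.d. Gaussian log2 noise (additive on
log2 = multiplicative log-normal on the linear scale, matching ratio-based
analysis).

Defaults, chosen once as the study conditions the generator emulates:
5 vs 5 animals per group; dosage ratio 1.5 (three copies vs two); dosage
compensation probability 0.5 (the reported per-model range is roughly
38–57%); noise SD 0.15 log2 units — the source arrays' noise magnitude is
not published, and 0.15 gives realistic (near-saturating) power for a
0.585 log2 shift at $n = 5$; baseline intensities N(8, 1.5²) log2; trans
program of 300 genes with effects N(0, 0.4²) log2 — about 1.5% of a
20,000-gene genome, matching the few-percent DEG rates typical of these
panels. Cross-model sharing reuses a deterministic (gene, effect) pool
drawn from the design seed, in proportion
`shared_program_fraction × interval-overlap weight`, which makes
cross-model FC correlation a monotone, controllable generator parameter.
All randomness in every generator flows from one explicit seed, and truth
labels (`cis`, `cis_compensated`, `trans`, `null`) partition the genome.

What the generator does **not** emulate: probe-level array artifacts,
normalization residuals, correlated (co-expression) noise, batch effects,
and realistic pathway structure in the trans program. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to real-array pathology.

The interaction simulator grows a preferential-attachment graph
(heavy-tailed degrees), assigns confidence scores, and can plant a fully
connected seed clique — the planted structure the null-model tests must
recover. Phenotype simulators produce behaviour, qPCR-Ct and morphometry
tables with configurable group effects, including exact nulls.

# Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → DE → bookkeeping → gene sets → network →
phenotype statistics from one validated configuration; every
ambiguity-resolving parameter (standardization mode, null metric,
correlation universe, geNorm count, q cutoff, CS threshold, seeds) appears
explicitly in the output manifest together with per-file checksums, and
identical configurations produce identical checksums. Stage failures abort
with the stage name; partial outputs are retained. The package's interface
is R functions plus this configuration runner; no shell entry point is
shipped.

Problem sizes used by the test suite, chosen as the smallest sizes at which
each property is meaningful: DE calibration and dosage recovery at
$m = 20{,}000$ genes (10 seeds / 1 seed); set-level FDR at 500 random sets
× 10 seeds; betweenness oracle over all labeled graphs on ≤ 5 nodes plus
fixed random 6–7-node graphs; null-model detection of a planted 10-seed
clique in a 300-node graph at 10,000 replicates; connector minimality on
≤ 200-node fixtures by exhaustive deletion.

# Known limitations

* The empirical standardization assumes differential genes are a minority;
  with very large effect fractions (tens of percent of the genome) the
  window miscalibrates — visible in the generator at implausibly dense
  trans programs.
* The Stouffer dependence correction uses the equal-variance pair
  correlation model; strongly heteroscedastic groups would need a
  permutation reference instead.
* The greedy component-merge is a heuristic; it guarantees connectivity and
  connector minimality (post-pruning), not global Steiner optimality.
* Published headline percentages that depend on a specific external
  interactome/annotation snapshot (hub control percentages, pathway term
  counts) are qualitative references; the package reproduces the
  *procedures*, and its quantitative guarantees are stated on synthetic
  data with known truth.
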