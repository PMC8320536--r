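---
title: "Differential partial correlation networks: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential partial correlation networks: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Complex diseases such as hepatocellular carcinoma rarely reduce to the
expression change of single genes; much of the signal sits in *rewired
regulation* — gene–gene dependencies that exist in tumor tissue but not in
normal tissue, or vice versa. `dpcnet` identifies a candidate disease
module by asking, for every protein–protein interaction, whether the
statistical dependence between the two genes differs between tumor and
normal samples at both the expression and the DNA-methylation level, and
then ranking the hubs of that differential structure by how often they are
somatically mutated.

## The model

### From correlation to first-order partial correlation

A Pearson correlation between genes *i* and *j* cannot distinguish a direct
dependence from one induced by a shared neighbor *k* (a chain
*i–k–j* makes *i* and *j* marginally correlated). The first-order partial
correlation removes the linear effect of one conditioning gene:

$$ r_{ij(k)} \;=\; \frac{r_{ij} - r_{ik}\,r_{jk}}
  {\sqrt{1 - r_{ik}^2}\,\sqrt{1 - r_{jk}^2}} $$

and is tested with

$$ t \;=\; \frac{r_{ij(k)}\sqrt{N - q - 2}}{\sqrt{1 - r_{ij(k)}^2}} $$

on Student's *t* with \(N - q - 2\) degrees of freedom, where \(N\) is the
group's sample size and \(q\) the order (1 when conditioned on a gene, 0
otherwise). First order is a deliberate compromise: full-order partial
correlations require estimating and inverting a genome-scale covariance
matrix, while first-order sweeps cost \(O(n^3)\) at worst and far less on
the sparse networks that PPI-constrained analysis produces.

### The network cascade

Per group (tumor, normal), restricted to a background of PPI edges with
STRING confidence strictly above 500 between expressed genes:

1. **PCCN** — keep background edges whose Pearson correlation is
   significant after Benjamini–Hochberg adjustment over all background
   edges of the group, adjusted *p* < 0.01 (strict). The permissive BH step
   keeps the tumor and normal network sizes comparable despite the
   imbalanced group sizes.
2. **PCORN** — for each PCCN edge, condition on common neighbors and keep
   the edge only if it survives the partial-correlation test after
   Bonferroni adjustment over all PCCN edges of the group, adjusted
   *p* < 0.05 (strict). The strict Bonferroni step minimises surviving
   indirect edges, which matters because the gene ranking downstream is
   degree-based.
3. **Diff-PCORN** — the symmetric difference of the two PCORNs, each edge
   tagged `tumor_only` or `normal_only`.
4. **Diff-MN** — for every Diff-PCORN edge whose genes both carry mapped
   CpG sites, compute the Pearson correlation of every cross-gene site
   pair within each group; the edge score is the maximum over site pairs of
   \(|r_{tumor} - r_{normal}|\), and edges with score strictly above 0.7
   are kept. Beta values are used directly (no M-value transform), and
   absolute differences are used, both following the method's definition.
5. **Ranking** — candidate set 1 = genes with Diff-PCORN degree strictly
   above 30; candidate set 2 = genes with Diff-MN degree strictly above
   15; their overlap is ordered by *descending* somatic variation frequency
   (fraction of variant-called samples in which the gene carries at least
   one mutation), ties broken by descending Diff-PCORN degree, remaining
   ties lexicographically for determinism. The top 15 genes are the module
   biomarkers. A bundled kidney-cancer profile relaxes the Diff-MN hub
   threshold to 10.

### Conditioning-set rule

Which gene conditions each edge is a genuinely open design point. `dpcnet`
lets *k* range over the **PCCN common neighbors** of the edge and tests the
candidate minimising \(|r_{ij(k)}|\): an edge survives only when *no*
single network neighbor can explain it away. This is the most conservative
single-conditioner rule, it matches the sparse-network cost argument for
first-order analysis, and it is deterministic (ties in the minimisation
break lexicographically on the conditioning gene's symbol). An
`exhaustive_k` flag conditions on every other gene instead for users who
want network-independence of the conditioning set. Edges without a common
neighbor fall back to the zero-order test (\(q = 0\)); edges whose every
candidate is degenerate (\(|r_{ik}| = 1\)) do too, with a warning.

### Multiple-testing universes

The adjustment procedures are applied jointly per group: BH over all
background edges (PCCN step) and Bonferroni over all PCCN edges (PCORN
step). Pooling both groups into one family would couple the two networks'
sizes; per-group universes keep each network a self-contained inference.

## Validation statistics

* **Enrichment** of the selected module in a reference gene list uses the
  exact hypergeometric upper tail
  \(P(X \ge x) = 1 - \sum_{k=0}^{x-1} \binom{M}{k}\binom{N-M}{n-k} / \binom{N}{n}\),
  with each term computed in log space. The complement-sum form resolves
  tails down to about \(10^{-16}\) (double precision); smaller values are
  reported as 0. The universe \(N\) defaults to the number of genes in the
  processed expression matrix and is configurable, since enrichment
  p-values are sensitive to it.
* **Classification**: stratified five-fold cross-validation of a
  linear-kernel SVM on the module genes' expression. The minority class is
  randomly oversampled to balance *inside each training fold only*, so no
  test sample influences training. The ROC/AUC is computed from the pooled
  out-of-fold decision scores — deterministic given the seed and using
  every sample exactly once; per-fold AUC averaging is the main
  alternative and gives noisier estimates at these sample sizes.
* **Clustering**: agglomerative single-linkage clustering with cityblock
  (L1) distance over samples, cut at two clusters. The cluster holding the
  majority of the true normal samples is called the normal cluster, and
  recall is the fraction of normal samples inside it.
* **Per-gene Welch t-tests** report differential expression of the module
  genes.

## The synthetic generator

`simulate_omics()` emulates the statistical structure the method assumes,
with known ground truth, so the whole pipeline is testable without any
download.

**Expression.** Each group's latent expression is drawn from a Gaussian
graphical model with unit-diagonal precision matrix; an entry \(-s\) at a
planted edge makes its full-order partial correlation exactly \(s\).
Planted structure is laid out in vertex-disjoint components so positive
definiteness is controllable:

* a *backbone matching* (disjoint gene pairs) and *chains* *i–k–j* present
  in both groups at `direct_edge_strength` (default 0.5);
* each chain also contributes a PPI *shortcut* edge *i–j* with no direct
  dependence — the planted indirect edges the partial-correlation step
  must remove;
* each disease gene (default 10) gains `disease_edges_per_gene` (default
  5) *tumor-only* edges to otherwise-unconnected partner genes. A star of
  degree \(d\) with uniform strength is positive definite only for
  \(s < 1/\sqrt{d}\), so star strengths are capped at \(0.9/\sqrt{d}\)
  (0.402 at the defaults). Positive definiteness of the assembled
  precision matrix is verified numerically; violations are an error, not a
  silent rescale.

The latent Gaussian is scaled (`expression_sd` 0.4), shifted by a gene
mean, shifted again by `disease_expression_shift` (default 1) for disease
genes in tumor samples, and exponentiated to an FPKM-like non-negative
scale. The exponentiation is a deliberate monotone stressor — Pearson
correlations attenuate under it — and can be disabled
(`fpkm_transform = FALSE`), which the consistency tests use to compare
recovered partial correlations against the planted strengths. Ten decoy
genes expressed in under half the samples exercise the expression filter.

**Methylation.** Every gene gets 1–3 CpG sites whose latents share a gene
factor (within-gene correlation 0.5); Beta values are a logistic squash of
the latents. For each planted disease edge, the partner gene's first site
tracks the disease gene's first site with correlation 0.8 in tumor and
-0.4 in normal (default `diff_meth_effect` 1.2 — chosen so the planted
difference clears the 0.7 score threshold with margin at the default
normal-group size of 40, where the sampling noise of a correlation is
about 0.16). Decoy sites with multi-gene annotations or missing values
exercise the site filter.

**Mutations.** Bernoulli per gene per tumor sample: rate 0.4 for disease
genes, 0.02 otherwise — a strong but realistic contrast between driver-like
and passenger-like frequencies.

**Sample sizes.** Defaults are 120 tumor / 40 normal, mirroring the
imbalanced cohorts this method targets. At \(n = 40\) the Bonferroni-level
partial test has little power at strength 0.5, so many shared edges are
detected only in the tumor group and leak into Diff-PCORN as
`tumor_only` noise — deliberately so: the methylation filter and the
mutation ranking are what rescue specificity, exactly the integration
argument the method makes. The balanced configuration
(`n_tumor = n_normal = 200`) is used for the indirect-removal and
retention checks, where per-edge power is the quantity under test.

**What the generator does not emulate**: real marginal FPKM distributions,
batch effects, CpG density, copy-number confounding, or sample pairing.
Passing tests show the inference machinery recovers the structure it
assumes; they are not evidence about any particular cohort.

## Scaled study conditions

The degree thresholds 30/15 and top-15 selection are calibrated to a
genome-scale network (~16k nodes, ~580k edges). The synthetic universe has
200 genes and 5 planted edges per disease gene, so `recover_truth()`
defaults to Diff-PCORN degree > 3, Diff-MN degree > 2 and top 10 — fixed
once from the generator's design (a disease gene passes when most of its 5
planted edges survive), not fitted to test outcomes. Tests and the
acceptance script use 200 genes, 10–20 replicates where rates are
estimated, and n = 2000 for the consistency check; these sizes are the
package's chosen study conditions.

## Numerical choices and degenerate inputs

* Partial correlations are clamped to \([-1, 1]\) against floating-point
  overshoot; \(|r| = 1\) maps to \(p = 0\).
* Constant genes/sites make a correlation undefined: such pairs get
  \(p = 1\) (never significant) with a warning rather than an error, so a
  single flat feature cannot abort a run.
* Degenerate conditioning (\(|r_{ik}| = 1\)) skips that candidate; if all
  candidates are degenerate the edge falls back to order 0 with a warning.
* Edge lists are kept in canonical form (lexicographically sorted pairs,
  sorted rows), making outputs byte-reproducible and membership queries
  order-invariant.
* Duplicate expression rows keep the highest-mean row; reciprocal PPI
  duplicates keep the maximum confidence.
* All "greater than" thresholds are strict, following their definitions.

## Known limitations

* Only first-order conditioning: a dependence explained jointly by two or
  more genes, but by no single one, survives into PCORN.
* Pearson correlations on FPKM-scale data are sensitive to monotone
  nonlinearity; the generator quantifies but does not remove this.
* The Diff-MN score is a difference of correlations without a significance
  test; with few samples per group its sampling noise is substantial
  (~0.18 at 40 normals), which is why the 0.7 threshold is high.
* Enrichment p-values below ~1e-16 are reported as 0 (complement-sum
  resolution).
* The variation-frequency ranking ignores mutation type and recurrence
  position; every variant counts equally.

## A worked synthetic run

```{r, eval = FALSE}
library(dpcnet)
sim <- simulate_omics(synthetic_config(seed = 1))
rec <- recover_truth(sim)
rec$fit          # stage counts and the selected module
rec$metrics      # recall, indirect-edge removal, direct-edge retention
```
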