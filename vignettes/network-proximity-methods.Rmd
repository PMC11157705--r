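---
title: "Predicting herb-disease associations with weighted network proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting herb-disease associations with weighted network proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbprox)
```

## The problem and the model

Natural herbs act through many compounds, each of which may bind many
protein targets — the multi-compound multi-target (MCMT) principle. A
single-compound, single-target view therefore misses most of a herb's
pharmacology. `herbprox` takes a network-medicine view instead: a herb is
represented by the set of genes its compounds target, a disease by its set
of associated genes, and the strength of a putative herb-disease
association is read off from how close these two gene sets lie in the human
protein interactome.

For herb $i$ with gene set $H_i = \{h_{i1},\dots,h_{iN}\}$ and disease $k$
with gene set $D_k = \{d_{k1},\dots,d_{kM}\}$, writing
$\mathrm{spl}(\cdot,\cdot)$ for the unweighted shortest-path length in the
interactome, the package computes three measures (lower = stronger
predicted association):

$$\mathrm{ASP}(H_i, D_k) =
  \frac{\sum_{n=1}^{N}\sum_{m=1}^{M}\mathrm{spl}(h_{in}, d_{km})}{N \cdot M}$$

$$\mathrm{ACP}(H_i, D_k) =
  \frac{\sum_{n=1}^{N}\min_{m}\ \mathrm{spl}(h_{in}, d_{km})}{N}$$

$$\mathrm{WACP}(H_i, D_k) =
  \frac{\sum_{n=1}^{N}\frac{1}{w_{in}}\cdot\min_{m}\ \mathrm{spl}(h_{in}, d_{km})}{N}$$

ASP is the classical all-pairs average; ACP recognizes that a herb gene
need only be close to *some* disease gene; WACP additionally weights each
herb gene by its compound multiplicity $w_{in}$ — the number of compounds
in the herb that target it — on the hypothesis that a gene perturbed by
many compounds contributes more to the herb's effect. The inverse weight
keeps the orientation of the distance scale (smaller = stronger). Two
identities follow directly and are enforced by the test suite:
$\mathrm{WACP} \le \mathrm{ACP} \le \mathrm{ASP}$ always, with
$\mathrm{WACP} = \mathrm{ACP}$ when every weight is 1. The closest-path
measures vanish whenever $H \subseteq D$; the all-pairs average does not
(off-diagonal distances remain), which is why ASP is both the weakest
predictor and the one most sensitive to large, diffuse herb gene sets.

### Assumptions

* Disease genes form a reasonably localized neighbourhood (a "disease
  module") in the interactome; proximity is only meaningful under this
  assumption.
* The interactome is undirected and unweighted; interaction direction,
  sign (activation/inhibition) and tissue specificity are ignored. The
  package therefore predicts *association*, not agonism or antagonism.
* Compound multiplicity is a usable proxy for perturbation strength; dose,
  affinity and bioavailability are not modelled.

## The pipeline and its parameters

1. **Evidence filtering** (`filter_by_evidence`). Every association record
   (disease-gene, herb-compound, compound-gene) carries the set of source
   databases reporting it; only records present in at least `min_sources`
   databases (default **2**) are kept. Distinct database labels are
   counted, not mentions — a record cited three times by one database has
   evidence 1. All label types are counted uniformly. The gold standard is
   *not* filtered: it is the answer key, not an evidence table.
2. **Profiles** (`build_disease_profiles`, `build_herb_profiles`). A herb's
   gene set is the union of its compounds' targets; $w_{in}$ counts the
   compounds targeting each gene, so $1 \le w_{in} \le$ (number of
   compounds). Herbs whose compounds target nothing are dropped with a
   warning rather than an error, mirroring the restriction of any such
   pipeline to herbs with usable annotation.
3. **Interactome** (`build_graph`, `largest_connected_component`).
   Self-loops are removed, duplicate and reversed edges collapsed, and all
   scoring happens on the largest connected component (LCC) so that every
   distance is finite. Component-size ties break towards the
   lexicographically smallest member, making the result deterministic.
   Distances are exact breadth-first values served by a `distance_oracle`
   that caches one row per queried source gene; all-pairs storage is never
   materialized.
4. **Scoring** (`score_all_pairs`). Genes absent from the LCC are dropped
   from $H_i$ and $D_k$ *before* applying the formulas, and $N$, $M$ are
   the restricted counts — the standard network-medicine convention, since
   no finite distance exists for absent genes. Pairs whose restricted set
   is empty get `NA` and are excluded (and counted in a message) rather
   than imputed.
5. **Evaluation** (`evaluate_predictions`, `per_entity_auroc`). Pairs are
   ranked by score (ascending); gold-standard pairs are the positives.
   AUROC uses the rank/midrank (Mann-Whitney) formulation, identical to
   trapezoidal ROC integration; AUPRC uses step-wise rectangular
   integration (the average-precision convention, avoiding optimistic
   interpolation), reported with its chance baseline positives/total.
   Per-entity AUROCs require at least one positive *and* one negative in
   the entity's defined cells — the metric is otherwise ill-defined — and
   the Pearson correlation between per-entity AUROC and gold-partner count
   (`auroc_vs_count_correlation`) diagnoses annotation-richness bias.
6. **Thresholding and discovery**. `threshold_at_fpr` returns the largest
   score threshold whose achieved false-positive rate stays at or below the
   target (default **5%**) — conservative by construction, never
   exceeding the target. `select_reliable_herbs` keeps herbs with per-herb
   AUROC above **0.9**, at least **3** known diseases, and all known
   associations below that threshold; `discover_novel` then proposes
   non-gold diseases scoring below the mean of a herb's known associations
   whose own per-disease AUROC exceeds the run's mean per-disease AUROC.
   That reference AUROC is recomputed from the current run each time, never
   hard-coded: any fixed number would be a dataset-specific realization.
7. **Rank-sum case comparison** (`rank_sum_compare`). Known versus other
   disease scores are compared with the two-sided Wilcoxon rank-sum test:
   exact null distribution when both samples have at most 8 observations
   and no ties, tie-corrected normal approximation (midranks, no continuity
   correction) otherwise.

## What the synthetic generator emulates

Real inputs of this kind come from integrated repositories that are not
redistributable, so `synth_generate` produces datasets with their
statistical shape, at desk scale:

* a preferential-attachment interactome (default 500 nodes, 2 edges per
  new node) whose heavy-tailed degree distribution mimics real
  interactomes, with an Erdős–Rényi fallback; the LCC is extracted exactly
  as in the real pipeline;
* disease modules sampled as connected neighbourhoods (balls of radius
  1–2 around a seed node), sizes drawn from a shifted geometric with mean
  ≈ 6 genes (range clipped to 2–74) — proximity signal presupposes module
  locality, so scattering module genes uniformly would destroy the very
  structure the method detects;
* herbs with a long-tailed number of compounds (mean ≈ 34.5, range 1–80)
  and compounds with several targets each, so herb gene sets are large;
* per-record evidence labels drawn as 1 + Binomial(databases − 1,
  0.35) database memberships, so roughly 80% of records survive the
  two-database filter and the filter is genuinely exercised;
* a sparse gold standard: a configurable fraction of herbs (default 10%)
  is assigned 1–2 diseases each.

The planted signal has two components, matching the two hypotheses the
measures encode. With probability `module_locality` (default 0.8) a
positive herb's compound draws its targets from the ball of radius
`module_radius` (default 1) around its disease module — this proximity
component is visible to ACP and WACP alike. Independently,
`multiplicity_boost` (default 3) extra compounds per positive herb target
the module's radius-1 *shell* (neighbours of module genes, excluding the
module itself). The shell choice is deliberate: weights on distance-0
genes cannot change WACP relative to ACP (anything times zero is zero), so
concentrating multiplicity at distance 1 is what encodes signal
specifically into the weights. With both dials at zero the gold standard
is statistically indistinguishable from the negatives and AUROC sits at
0.5 within sampling error — the null calibration the test suite checks
over 20 seeds.

What passing these tests does *not* show: real annotation databases have
correlated errors, study bias towards well-known genes, shared compounds
across herbs, and hub-concentrated disease genes; the generator models
none of these, so benchmark AUROCs here say the *method and code* work,
not that any particular real-world AUROC will be attained.

## Numerical choices and degenerate inputs

* Generation is integer-seeded and restores the caller's RNG state;
  identical config + seed reproduces outputs byte-for-byte, and the
  pipeline writes MD5-checksummed manifests so reruns can be verified
  bit-for-bit.
* Duplicate association rows merge their evidence sets on load, so row
  order never matters; profile and score computations are likewise
  invariant to gene iteration order.
* Empty tables after filtering yield empty profile lists; a pipeline run
  aborts with a stage-tagged error if no usable profiles remain.
* `threshold_at_fpr` accepts targets in (0, 1]; at target 1 everything is
  called positive and the maximum score is returned.
* Problem sizes used in the bundled tests and the acceptance script —
  25–50-node graphs for oracle equivalence, 500-node interactomes with 60
  herbs × 12 diseases for signal recovery, 10–20 replicate seeds — were
  chosen as the smallest scales at which the distributional targets above
  are meaningful; all run on a single CPU in minutes.

## Known limitations

* No degree-preserving randomization z-scores: raw proximity is compared
  across pairs, not against a rewired-network null.
* Identifier vocabularies are opaque strings; no gene-symbol/accession
  mapping is attempted, so inputs must share one identifier space.
* Unscored pairs are excluded from evaluation rather than worst-ranked;
  with very incomplete interactomes this can flatter the metrics, and the
  excluded counts are always reported.
* The discovery rules inherit the biases of the gold standard; on real
  data, candidate lists skew towards densely annotated disease areas.
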