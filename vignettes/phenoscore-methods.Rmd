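---
title: "Scoring disease causality of gene perturbations from phenotype ontology annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring disease causality of gene perturbations from phenotype ontology annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies locate disease-associated SNPs, but the gene
responsible for an association signal is rarely the nearest one, and
association alone never demonstrates causality. The definitive evidence that
perturbing a gene causes a disease is the appearance of disease-like
phenotypes in a genetic model. Mouse mutant databases record exactly this:
for thousands of genes, the phenotypes observed when the gene is knocked out
or otherwise perturbed, coded as terms of a phenotype ontology (a DAG in
which an edge means is_a generalization, e.g. *hyperglycemia* is_a *abnormal
glucose homeostasis*).

`phenoscore` turns those annotations into a quantitative, per-gene score: the
likelihood that perturbing the gene produces the phenotypes of a complex
disease, where the disease is defined by a curated list of ontology terms
(e.g. hyperglycemia, obesity, impaired glucose tolerance, ... for type 2
diabetes). Because complex diseases present several co-occurring traits, a
gene whose mutant shows *some* of them is likely to share the others — the
model exploits these phenotype co-occurrences.

## The model

### Annotation expansion and the attribute vocabulary

Annotating a gene with a term implies all of the term's ancestors, so direct
annotations are first expanded upward through the DAG
(`expand_annotations()`). The classifier vocabulary is then the set of
**testable phenotypes** (`testable_phenotypes()`): the lowest-level terms
annotated to at least `min_genes` genes (default 10), formalized as terms
meeting the threshold with no descendant that also meets it. The threshold
guarantees enough training cases per term; taking the *lowest* qualifying
terms keeps the attributes maximally specific. Gene counts are taken on the
expanded annotations, since expansion precedes filtering in the scoring
flow.

For a target phenotype $PT_t$, the usable attributes are all testable
phenotypes except $PT_t$ and *every* descendant of $PT_t$
(`attribute_set()`). Descendants — not only direct children — must go,
because upward expansion makes any descendant annotation imply the target:
keeping one would leak the label.

### Per-phenotype decision-tree ensembles

Each target phenotype gets a binary classifier built from C4.5-style
decision trees (`phenotree()`). Genes carrying the target (after expansion)
are the gold-standard positives (GSP); each tree draws a fresh
gold-standard-negative set (GSN) of `neg_ratio` (default 5) times as many
genes, uniformly *without* replacement from the genes lacking the target.
Training repeats over `n_trees` (default 100) independent GSN draws and the
final probability is the arithmetic mean over trees
(`train_phenotype_classifier()`): resampling the negatives averages out the
arbitrariness of any one negative draw.

A tree grows greedily: each node is split by the presence/absence of the
attribute with maximal information gain, where the node entropy is
$H = -p\log_2 p - (1-p)\log_2(1-p)$ with $p$ the GSP fraction at the node.
The default gain is the standard size-weighted form
$H(N) - \frac{|N_0|}{|N|}H(N_0) - \frac{|N_1|}{|N|}H(N_1)$; the unweighted
difference $H(N) - H(N_0) - H(N_1)$ is retained as `gain_mode = "literal"`
for fidelity experiments, but it is not the default because it is not the
quantity the C4.5 family maximizes and can reward uninformative splits.
Splitting stops when the node is pure, no attribute has positive gain, the
node is smaller than `2 * min_leaf`, or a child would fall below `min_leaf`
(default 2, preventing singleton leaves with degenerate probabilities 0/1).
No pruning is applied; the positive-gain rule already bounds depth in
practice. A leaf stores its training counts, and predicts
$n_{pos}/(n_{pos}+n_{neg})$ — the probability that a gene routed to that
leaf shows the target phenotype. At prediction time an attribute absent
from a gene's annotations is treated as phenotype-absent, mirroring the
annotation databases' implicit negatives.

### From phenotype probabilities to a disease score

Common phenotypes say little; rare ones say a lot. Each phenotype is
weighted by $w_t = -\log_{10}(f_t)$, where $f_t$ is the fraction of the
annotated gene universe carrying the term (`phenotype_weight()`); $w_t = 0$
exactly when every gene carries the term. A gene's disease score is the
weighted sum of its per-phenotype ensemble probabilities, normalized by its
maximal attainable value,

$$S(g) \;=\; \frac{\sum_t w_t \, P_t(g)}{\sum_t w_t} \;\in\; [0,1],$$

summing over the disease's phenotype terms that could actually be trained
(`weighted_disease_score()`, `phenoscore()`). Phenotypes with too few
positives (or too few eligible negatives) are *skipped and renormalized
over*, never imputed at probability zero: absence of training data is not
evidence of phenotype absence. The skip list is reported in the fitted
object and in the pipeline manifest.

## Evaluation machinery

* **ROC / AUC** (`roc_curve()`): genes are rank-ordered by score; all genes
  sharing a score enter at a single threshold, so the trapezoid AUC equals
  the tie-corrected Mann–Whitney rank statistic (a property the test suite
  asserts to 1e-12). "Coverage" and "sensitivity" are the same quantity
  against different positive universes.
* **Cross-validation** (`kfold_phenotype_cv()`): stratified k-fold (default
  10) over the GSP plus a single 5× GSN pool drawn once and folded jointly;
  per fold an ensemble is trained on the other folds and the held-out genes
  scored; the ROC pools all folds. Drawing the GSN once avoids any held-out
  gene appearing among another fold's training negatives.
* **Specificity cutoff** (`specificity_cutoff()`): the smallest threshold
  at which at most `1 - level` (default 5%) of the gold-standard negatives
  score at or above it; used to call high-confidence predictions.
* **Fold enrichment** (`fold_enrichment()`): $(m/n)/(M/N)$.
* **Interaction-count Monte Carlo** (`empirical_p_links()`): the empirical
  P of the observed number of network links between two gene sets is the
  frequency with which equal-size uniformly resampled sets achieve at least
  as many. Null sampling is uniform over network nodes to match the
  "randomly selected genes" convention; a degree-stratified null is
  available for sensitivity analysis. A zero exceedance count is reported
  as the bound `< 1/iterations`, never as 0. Edges inside the overlap of
  the two sets count once.
* **Degree comparison** (`degree_stats()`): one-sided Wilcoxon rank-sum
  (normal approximation, tie correction, no continuity correction so that
  the degenerate self-comparison sits at exactly 0.5) of a set's degrees
  against all network nodes.
* **SNP proximity** (`distance_profile()`, `max_score_vs_or()`): gene–SNP
  distance is 0 inside the 1-based inclusive gene span, else the distance
  to the nearest boundary, infinite across chromosomes. The profile bins
  genes by their minimum distance over all disease SNPs; the OR analysis
  takes, per SNP, the maximal score within ±`window_mbp` (default 1 Mbp)
  and reports the Pearson correlation with the SNPs' odds ratios plus the
  regression-slope P value. Windows are symmetric and per-SNP maxima are
  monotone in the window size.

## What the synthetic generator emulates

`synthetic_config()` fixes the study conditions; all generation is a pure
function of it. The defaults are a 300-term DAG (each non-root term drawing
1–2 parents from earlier terms), 2000 annotated genes, 50 planted disease
genes, 8 disease phenotypes drawn from ontology leaves, a planted
co-occurrence probability of 0.6 against a background annotation rate of
0.05 per gene-term pair, a 500-node/1000-edge interaction network with 50
planted cross-links, and 20 SNPs whose odds ratios follow
$1 + 0.5\,m + \varepsilon$, $\varepsilon \sim N(0, 0.05^2)$, with $m$ the
windowed maximal score. Disease terms are drawn from leaves deliberately,
so the testable-phenotype filter's lowest-level rule is exercised. Draws
whose disease phenotypes end with fewer than `min_genes` positives are
regenerated with a warning, at most 10 times, then fail loudly.

The background rate and co-occurrence were chosen once as plausible for
curated mutant-phenotype data: a typical gene carries ~15 of 300 terms, and
a planted disease gene shows most but not all disease traits. Under these
conditions the planted genes are recovered with ranking AUC well above
0.85 (asserted by the test suite at `n_trees = 25`).

What the generator does **not** emulate: realistic term names or ontology
shape (the MP ontology is deeper and broader), correlated background
annotations (real phenotypes co-occur even outside disease modules),
curation bias toward well-studied genes, ortholog mapping noise, or linkage
disequilibrium among SNPs. Passing the recovery tests therefore shows the
pipeline is correct and well-calibrated on its stated generative model, not
that real-data AUCs will be as high. One visible consequence: the
cross-validated AUC of a single synthetic phenotype classifier is modest
(~0.6), because under independent background annotations most carriers of
any one term are unrelated to the planted module — real annotation data,
with its strong phenotype correlations, is much more learnable per
phenotype.

## Numerical choices

* Gains are computed in bits (log base 2); the argmax is base-invariant.
* Ties in gain are broken toward the lexicographically smallest term id,
  and "tie" means within 1e-12 bits: a strict floating-point argmax can
  flip between mathematically equal splits computed in different orders,
  and the tolerance makes fits reproducible across platforms and
  comparable with reference implementations.
* Randomness: one master seed; the per-(target, repeat) RNG streams are
  derived deterministically from a hash of the target term id and the
  repeat index, so per-phenotype results do not depend on the order in
  which phenotypes are trained, and the full score table is bit-identical
  across runs (asserted on the written files).
* `specificity_cutoff()` returns the smallest *observed* score satisfying
  the specificity constraint; when even the maximum fails it (e.g. all
  negatives tied at the top value), it returns the next representable
  double above the maximum, so the realized specificity is always at least
  the requested level.
* Degenerate inputs are reported as missing, never silently zeroed: empty
  distance bins, zero-variance OR correlations, untrainable phenotypes and
  score-less genes all surface as `NA`/skip flags with reasons.

## Design decisions that were genuinely open

* *"Lowest-level phenotypes with ≥ 10 genes"* is formalized as: meets the
  threshold and no descendant does. Plain ontology leaves would make the
  threshold unusable exactly where annotations are sparse.
* Only is_a relations build the DAG; part_of and other relationship types
  are ignored (mouse phenotype ontologies are predominantly is_a, and
  mixed-relation closure would weaken the leakage argument).
* The gene universe for frequencies and negatives is the set of genes with
  at least one annotation — "all the genes" in the untyped sense would make
  every frequency depend on an arbitrary genome size.
* Genes are opaque identifiers: any mouse-to-human ortholog mapping is
  applied upstream of the annotation table.
* The interaction null is uniform node sampling, not degree-preserving
  rewiring; the score's hub bias is itself a finding one wants to see, not
  normalize away (the stratified option exists to check sensitivity).
* Problem sizes in the test suite (ensembles of 3–25 trees, 200-replicate
  calibration at 500 permutation iterations, 80-gene sets for the
  uniformity check) were chosen so the full suite completes in about a
  minute while keeping each statistical check's discreteness well below
  its test's critical value; the 80-gene choice in particular keeps the
  permutation p-value's atom masses (~0.06) far under the
  Kolmogorov–Smirnov critical D at n = 200 (~0.115).

## Known limitations

* Annotation bias: heavily studied genes carry more terms, which inflates
  both their attribute vectors and their chance of qualifying as training
  positives; the method inherits whatever curation bias the input table
  has.
* Probabilities are leaf frequencies without smoothing; with `min_leaf = 2`
  a leaf probability of exactly 0 or 1 is still common, and downstream
  consumers should treat scores as rankings rather than calibrated
  probabilities.
* Skipped phenotypes change the normalizer: scores are comparable within a
  disease run, not across runs that trained different phenotype subsets.
* The untrainable-phenotype rule (≥ `min_genes` positives, ≥ 5× eligible
  negatives) means very small or very pervasive phenotypes silently drop
  out of the score; the manifest lists them, and diseases whose *every*
  phenotype drops out are a hard error.
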