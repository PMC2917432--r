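# phenoscore

Quantifying the probability that perturbing a gene causes the phenotypes of
a complex disease, from ontology-structured phenotype annotations of mutant
model organisms.

GWAS finds disease-associated SNPs, not disease-causal genes: the gene
behind an association signal is often not the nearest one, and association
is not causality. Mutant mouse databases record, for thousands of genes,
the phenotypes produced when the gene is perturbed — coded as terms of a
phenotype ontology (a DAG of is_a relations). `phenoscore` learns from
these annotations how a disease's phenotypes co-occur, and scores every
annotated gene for how likely its perturbation is to produce the disease's
phenotype spectrum. The scores can benchmark disease-gene collections and
rank candidate causal genes around GWAS SNPs.

It is aimed at statistical/computational geneticists working with
phenotype-annotation resources (MGI-style gene→term tables), disease gene
lists, interaction networks and GWAS summary tables.

## Method

For each phenotype term $PT_t$ of a disease:

* **GSP** = genes annotated (after upward expansion through the DAG) with
  $PT_t$; each of `n_trees` (default 100) C4.5-style decision trees is
  trained on the GSP plus a fresh **GSN** of `neg_ratio` (default 5) times
  as many genes drawn from the rest of the annotated universe.
* Tree attributes are the *testable phenotypes* — lowest-level terms with
  ≥ 10 annotated genes — minus $PT_t$ and all its descendants (which would
  leak the label). Splits maximize information gain
  $H(N) - \frac{|N_0|}{|N|}H(N_0) - \frac{|N_1|}{|N|}H(N_1)$ and stop when
  no split has positive gain. A leaf predicts $n_{pos}/(n_{pos}+n_{neg})$.
* $P_t(g)$ = mean leaf probability over the ensemble.

Per-gene disease score, with $f_t$ the annotation frequency of $PT_t$ and
$w_t = -\log_{10} f_t$:

$$S(g) = \frac{\sum_t w_t P_t(g)}{\sum_t w_t} \in [0, 1].$$

Evaluation utilities include pooled k-fold cross-validation ROCs,
rank-statistic-exact AUCs, specificity cutoffs, fold enrichment,
Monte-Carlo tests for interaction counts between gene sets,
degree comparisons, and SNP-proximity analyses (score-vs-distance profiles,
windowed max-score vs odds-ratio correlation). A seeded synthetic-data
module generates ontologies, annotations with a planted disease module,
networks with planted cross-links and score-coupled SNP tables, so the
whole pipeline is testable offline. See `vignettes/phenoscore-methods.Rmd`
for the model, assumptions and design choices.

## Worked example

```r
library(phenoscore)

cfg <- synthetic_config(n_terms = 100, n_genes = 500, n_disease_genes = 25,
                        disease_term_count = 5, seed = 7)
ont <- generate_ontology(cfg)
syn <- generate_annotations(cfg, ont)

fit <- phenoscore(syn$disease, syn$annotations, ont, n_trees = 25, seed = 7)
print(fit)
#> Disease phenotype score model: synthetic_disease
#>   499 genes scored over 5/5 phenotypes (25 trees each, 5x negatives, seed 7)
#>   top genes: G00005 (0.995), G00015 (0.902), G00023 (0.900), G00001 (0.830), G00004 (0.816)

roc <- roc_curve(fit$scores,
                 gold_standard(syn$planted_genes,
                               setdiff(names(fit$scores), syn$planted_genes),
                               label = "planted"))
print(roc)
#> ROC (planted) - 25 positives vs 474 negatives; AUC = 0.9673

cutoff <- specificity_cutoff(fit$scores,
                             setdiff(names(fit$scores), syn$planted_genes),
                             level = 0.95)
sum(fit$scores >= cutoff)
#> [1] 44
```

The fitted model reports, per gene, the per-phenotype ensemble
probabilities, the raw weighted sum and the normalized score; `summary(fit)`
lists each disease phenotype's positive count, trainability and weight. Of
the 25 planted disease genes, the score ranks nearly all above the 474
background genes (AUC 0.967); at the 95% specificity cutoff 44 genes are
called, dominated by planted ones.

For file-based runs, `run_score(config)` / `run_evaluate(config)` read a
YAML config naming the OBO ontology, annotation TSV, disease-definition TSV
and optional gold standards / edge lists / SNP and locus tables, and write
score TSVs, an `evaluation.json` report and a manifest. A thin CLI with
`score`, `evaluate`, `cv`, `network-test`, `gwas` and `simulate`
subcommands is installed at `inst/scripts/phenoscore`.

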