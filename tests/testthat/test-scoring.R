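# shared small synthetic world for ensemble tests
syn_world <- local({
  cfg <- synthetic_config(n_terms = 60, n_genes = 300, n_disease_genes = 20,
                          disease_term_count = 4, seed = 5)
  ont <- generate_ontology(cfg)
  syn <- generate_annotations(cfg, ont)
  list(cfg = cfg, ont = ont, ann = syn$annotations, disease = syn$disease,
       planted = syn$planted_genes)
})

test_that("phenotype weights follow -log10 of annotation frequency", {
  ont <- chain_ontology()
  direct <- c(replicate(25, "C", simplify = FALSE),
              replicate(75, "A", simplify = FALSE))
  names(direct) <- sprintf("g%03d", 1:100)
  ann <- expand_annotations(annotation_set(direct), ont)
  w <- phenotype_weight(ann, c("A", "C"))
  expect_equal(unname(w["A"]), 0)               # f = 1 -> weight 0
  expect_equal(unname(w["C"]), -log10(0.25))    # 25 of 100 genes
  expect_error(phenotype_weight(ann, "B_missing"), "unannotated|undefined")
  # rarer phenotypes always weigh more
  expect_true(w["C"] > w["A"])
})

test_that("weighted disease score follows the stated algebra", {
  expect_equal(weighted_disease_score(c(1, 0), c(1, 2)), 1 / 3)
  expect_equal(weighted_disease_score(c(1, 1, 1), c(0.3, 1, 2)), 1)
  expect_equal(weighted_disease_score(c(0, 0, 0), c(0.3, 1, 2)), 0)
  m <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(weighted_disease_score(m, c(1, 2)), c(1 / 3, 0.5))
  expect_error(weighted_disease_score(c(1, 0), c(0, 0)), "positive")
})

test_that("ensembles use 5x resampled negatives and are seed-deterministic", {
  target <- syn_world$disease$phenotype_terms[1]
  clf <- train_phenotype_classifier(target, syn_world$ann, syn_world$ont,
                                    n_trees = 8, seed = 9)
  expect_true(clf$trainable)
  expect_length(clf$trees, 8)
  n_pos <- length(clf$gsp)
  for (tr in clf$trees) {
    expect_equal(tr$n_pos, n_pos)
    expect_equal(tr$n_neg, 5 * n_pos)           # training set is 6x positives
  }
  # attributes never include the target or its descendants
  leak <- intersect(clf$attributes,
                    c(target, term_descendants(syn_world$ont, target)))
  expect_length(leak, 0)
  clf2 <- train_phenotype_classifier(target, syn_world$ann, syn_world$ont,
                                     n_trees = 8, seed = 9)
  expect_identical(clf, clf2)
  clf3 <- train_phenotype_classifier(target, syn_world$ann, syn_world$ont,
                                     n_trees = 8, seed = 10)
  expect_false(identical(lapply(clf$trees, tree_shape),
                         lapply(clf3$trees, tree_shape)))
})

test_that("too few positives or negatives marks the classifier untrainable", {
  ont <- chain_ontology()
  direct <- c(replicate(4, "C", simplify = FALSE),
              replicate(40, "A", simplify = FALSE))
  names(direct) <- sprintf("g%03d", seq_along(direct))
  ann <- expand_annotations(annotation_set(direct), ont)
  clf <- train_phenotype_classifier("C", ann, ont, min_genes = 10)
  expect_false(clf$trainable)
  expect_match(clf$reason, "positives")
  expect_error(predict(clf, matrix(FALSE, 1, 0)), "untrainable")
  expect_error(phenotype_probability(clf, "g001", ann), "untrainable")
  # plenty of positives but nearly no negatives left
  clf2 <- train_phenotype_classifier("A", ann, ont, min_genes = 10)
  expect_false(clf2$trainable)
  expect_match(clf2$reason, "negatives|attribute")
})

test_that("ensemble probability is the mean over trees", {
  target <- syn_world$disease$phenotype_terms[2]
  clf <- train_phenotype_classifier(target, syn_world$ann, syn_world$ont,
                                    n_trees = 6, seed = 2)
  genes <- sample(syn_world$ann$genes, 20)
  m <- annotation_matrix(syn_world$ann, terms = clf$attributes, genes = genes)
  per_tree <- sapply(clf$trees, function(tr) predict(tr, m))
  expect_equal(predict(clf, m), rowMeans(per_tree))
  expect_equal(unname(phenotype_probability(clf, genes, syn_world$ann)),
               rowMeans(per_tree))
  # an unannotated gene follows every tree's all-absent path
  p_empty <- phenotype_probability(clf, "not_a_gene", syn_world$ann)
  spine <- mean(sapply(clf$trees, function(tr)
    oracle_predict(tree_shape(tr), logical(0))))
  expect_equal(unname(p_empty), spine)
})

test_that("a perfectly co-occurring attribute is every tree's root split", {
  # two leaves under a root; all carriers of T1 carry T2 and vice versa
  ont <- phenotype_ontology(list(R = character(0), T1 = "R", T2 = "R",
                                 X = "R"))
  direct <- c(lapply(1:15, function(i) c("T1", "T2")),
              lapply(1:90, function(i) "X"))
  names(direct) <- sprintf("g%03d", seq_along(direct))
  ann <- expand_annotations(annotation_set(direct), ont)
  clf <- train_phenotype_classifier("T1", ann, ont, n_trees = 10, seed = 4,
                                    min_genes = 10)
  expect_true(clf$trainable)
  for (tr in clf$trees) expect_equal(tr$root$term, "T2")
})

test_that("the fitted model renormalizes over trainable phenotypes only", {
  fit <- phenoscore(syn_world$disease, syn_world$ann, syn_world$ont,
                    n_trees = 5, seed = 3)
  scored <- names(fit$weights)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  expect_equal(fit$scores,
               fit$raw / sum(fit$weights))
  # recompute one gene by hand from the probability matrix
  g <- names(fit$scores)[7]
  expect_equal(unname(fit$scores[g]),
               sum(fit$prob[g, scored] * fit$weights) / sum(fit$weights))
  # a disease with an untrainable phenotype: skipped, not imputed at zero
  rare <- disease_definition("rare", c(scored[1], "PT:0001"))
  ont2 <- syn_world$ont
  fit2 <- suppressWarnings(
    phenoscore(rare, syn_world$ann, ont2, n_trees = 5, seed = 3))
  if (length(fit2$skipped) > 0) {
    expect_named(fit2$weights, setdiff(rare$phenotype_terms,
                                       names(fit2$skipped)))
    expect_true(all(fit2$scores <= 1))
  }
})

test_that("model fits are reproducible from the master seed", {
  fit1 <- phenoscore(syn_world$disease, syn_world$ann, syn_world$ont,
                     n_trees = 4, seed = 11)
  fit2 <- phenoscore(syn_world$disease, syn_world$ann, syn_world$ont,
                     n_trees = 4, seed = 11)
  expect_identical(fit1$scores, fit2$scores)
  expect_identical(fit1$prob, fit2$prob)
})

test_that("predict on the training annotations reproduces fitted scores", {
  fit <- phenoscore(syn_world$disease, syn_world$ann, syn_world$ont,
                    n_trees = 4, seed = 2)
  some <- sample(names(fit$scores), 15)
  again <- predict(fit, syn_world$ann, genes = some)
  expect_equal(again, fit$scores[some])
})
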