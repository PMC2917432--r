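test_that("ROC handles separation, ties and the rank-statistic identity", {
  scores <- c(a = .9, b = .8, c = .7, d = .3, e = .2)
  gold <- gold_standard(c("a", "b"), c("c", "d", "e"))
  roc <- roc_curve(scores, gold)
  expect_equal(roc$auc, 1)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)

  # all genes tied: one non-trivial vertex, AUC 0.5
  tied <- setNames(rep(0.4, 6), letters[1:6])
  roc2 <- roc_curve(tied, gold_standard(letters[1:2], letters[3:6]))
  expect_equal(nrow(roc2$points), 2)
  expect_equal(roc2$auc, 0.5)

  expect_error(roc_curve(scores, gold_standard("zzz", "d")),
               "positive")
  expect_error(gold_standard(c("a", "b"), c("b", "c")), "disjoint")

  # trapezoid AUC equals the Mann-Whitney identity on random tied data
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(20:500, 1)
    s <- setNames(sample(seq(0, 1, by = 0.05), n, replace = TRUE),
                  sprintf("g%04d", 1:n))
    lab <- runif(n) < 0.3
    if (!any(lab) || all(lab)) next
    roc <- roc_curve(s, gold_standard(names(s)[lab], names(s)[!lab]))
    expect_equal(roc$auc, oracle_auc(s, lab), tolerance = 1e-12)
  }
})

test_that("ROC coverage and FPR are nondecreasing along the sweep", {
  set.seed(29)
  s <- setNames(runif(200), sprintf("g%03d", 1:200))
  lab <- runif(200) < 0.4
  roc <- roc_curve(s, gold_standard(names(s)[lab], names(s)[!lab]))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_true(all(diff(roc$points$fpr) >= 0))
})

test_that("specificity cutoff achieves the requested specificity", {
  set.seed(37)
  neg <- setNames(runif(10000), sprintf("n%05d", 1:10000))
  cut <- specificity_cutoff(neg, names(neg), level = 0.95)
  expect_equal(cut, unname(quantile(neg, 0.95)), tolerance = 0.01)
  expect_gte(mean(neg < cut), 0.95)            # realized specificity

  # degenerate: every negative scored zero -> smallest increment above zero
  zeros <- setNames(rep(0, 50), sprintf("n%02d", 1:50))
  cut0 <- specificity_cutoff(zeros, names(zeros), 0.95)
  expect_gt(cut0, 0)
  expect_equal(cut0, .Machine$double.xmin)

  # level close to 1 with a unique maximum -> just above the maximum
  s <- setNames(c(runif(99), 2), sprintf("n%03d", 1:100))
  cut1 <- specificity_cutoff(s, names(s), 0.995)
  expect_gt(cut1, 2)

  expect_error(specificity_cutoff(neg, names(neg), level = 1), "between")
  expect_error(specificity_cutoff(neg, names(neg), level = 0), "between")

  # property: realized specificity >= level across random inputs
  for (level in c(0.5, 0.9, 0.99)) {
    sc <- setNames(sample(seq(0, 1, 0.1), 500, TRUE), sprintf("x%03d", 1:500))
    ct <- specificity_cutoff(sc, names(sc), level)
    expect_gte(mean(sc < ct), level)
  }
})

test_that("fold enrichment follows (m/n)/(M/N) and is scale invariant", {
  expect_equal(fold_enrichment(5, 10, 100, 1000), 5)
  expect_equal(fold_enrichment(30, 300, 100, 1000), 1)
  expect_equal(fold_enrichment(0, 10, 100, 1000), 0)
  expect_equal(fold_enrichment(5, 10, 100, 1000),
               fold_enrichment(35, 70, 700, 7000))
  expect_error(fold_enrichment(1, 0, 10, 100), "positive")
})

test_that("disease similarity is the double sum over gene diseases x reference", {
  dis <- c("d1", "d2", "d3", "r1", "r2")
  sim <- matrix(runif(25), 5, 5, dimnames = list(dis, dis))
  gd <- list(gA = c("d1", "d2", "d3", "r1"), gB = "r1", gC = "d9")
  R <- c("r1", "r2")
  want <- sum(sapply(c("d1", "d2", "d3"), function(i)
    sum(sapply(R, function(j) sim[i, j]))))
  expect_equal(disease_similarity_score("gA", gd, R, sim), want)
  expect_equal(disease_similarity_score("gB", gd, R, sim), 0)
  expect_warning(got <- disease_similarity_score("gC", gd, R, sim),
                 "missing")
  expect_equal(got, 0)
  expect_error(disease_similarity_score("gC", gd, R, sim,
                                        missing = "error"), "missing")
  one <- matrix(0.7, 1, 1, dimnames = list("i1", "j1"))
  expect_equal(disease_similarity_score("g", list(g = "i1"), "j1", one), 0.7)
})

test_that("cross-validation separates a real signal and rejects tiny GSPs", {
  cfg <- synthetic_config(n_terms = 60, n_genes = 400, n_disease_genes = 25,
                          disease_term_count = 4, cooccurrence_prob = 0.9,
                          background_rate = 0.04, seed = 13)
  ont <- generate_ontology(cfg)
  syn <- generate_annotations(cfg, ont)
  target <- syn$disease$phenotype_terms[1]
  cv <- kfold_phenotype_cv(target, syn$annotations, ont, k = 5,
                           n_trees = 5, seed = 3)
  expect_gt(cv$roc$auc, 0.7)                   # strong planted co-occurrence
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  expect_error(kfold_phenotype_cv(target, syn$annotations, ont, k = 1e4),
               "at least")
})

test_that("leave-one-out runs on a 12-positive toy set", {
  ont <- phenotype_ontology(list(R = character(0), T1 = "R", T2 = "R",
                                 X = "R"))
  direct <- c(lapply(1:12, function(i) c("T1", "T2")),
              lapply(1:80, function(i) "X"))
  names(direct) <- sprintf("g%03d", seq_along(direct))
  ann <- expand_annotations(annotation_set(direct), ont)
  cv <- kfold_phenotype_cv("T1", ann, ont, k = 12, n_trees = 3, seed = 1,
                           min_genes = 10)
  expect_equal(cv$k, 12)
  expect_equal(cv$roc$auc, 1)                  # T2 separates perfectly
})

test_that("shuffled labels give a chance-level cross-validated AUC", {
  # break the gene/phenotype coupling by permuting which genes are "positive":
  # score a phenotype whose carriers are random background annotations only
  cfg <- synthetic_config(n_terms = 40, n_genes = 1500, n_disease_genes = 2,
                          disease_term_count = 2, cooccurrence_prob = 0,
                          background_rate = 0.15, seed = 21)
  ont <- generate_ontology(cfg)
  syn <- suppressWarnings(generate_annotations(cfg, ont))
  target <- syn$disease$phenotype_terms[1]
  cv <- kfold_phenotype_cv(target, syn$annotations, ont, k = 10,
                           n_trees = 5, seed = 7)
  expect_gt(length(cv$scores), 1000)           # held-out pool size
  expect_lt(abs(cv$roc$auc - 0.5), 0.05)
})
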