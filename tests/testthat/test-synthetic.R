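test_that("generated ontologies are DAGs, trees when max_parents is 1", {
  cfg1 <- synthetic_config(n_terms = 80, max_parents = 1, seed = 3)
  tree <- generate_ontology(cfg1)
  n_par <- vapply(tree$parents, length, integer(1))
  expect_equal(unname(n_par[tree$terms[1]]), 0L)
  expect_true(all(n_par[-1] == 1L))            # every non-root: one parent

  cfg2 <- synthetic_config(n_terms = 120, max_parents = 3, seed = 4)
  dag <- generate_ontology(cfg2)               # constructor validates acyclicity
  expect_s3_class(dag, "phenotype_ontology")
  expect_true(all(vapply(dag$parents[-1], length, integer(1)) >= 1))
  expect_identical(generate_ontology(cfg2)$parents, dag$parents)
})

test_that("planted genes carry the disease phenotypes above background", {
  cfg <- synthetic_config(n_terms = 100, n_genes = 600, n_disease_genes = 100,
                          disease_term_count = 5, cooccurrence_prob = 0.6,
                          background_rate = 0.05, seed = 8)
  ont <- generate_ontology(cfg)
  syn <- generate_annotations(cfg, ont)
  expect_length(syn$disease$phenotype_terms, 5)
  expect_true(all(syn$disease$phenotype_terms %in% ont$leaves))
  expect_length(syn$planted_genes, 100)

  # observed planted co-occurrence within 3 binomial SDs of the configured rate
  p_hat <- mean(syn$planted_counts) / cfg$n_disease_genes
  se3 <- 3 * sqrt(0.6 * 0.4 / cfg$n_disease_genes)
  expect_lt(abs(p_hat - 0.6), se3)

  # planted genes carry more disease-term annotations than background genes
  dt <- syn$disease$phenotype_terms
  carry <- function(g) sum(dt %in% syn$annotations$direct[[g]])
  planted_mean <- mean(vapply(syn$planted_genes, carry, numeric(1)))
  bg <- setdiff(syn$annotations$genes, syn$planted_genes)
  bg_mean <- mean(vapply(bg, carry, numeric(1)))
  expect_gt(planted_mean, bg_mean)

  expect_identical(generate_annotations(cfg, ont)$annotations$direct,
                   syn$annotations$direct)
})

test_that("degenerate extremes produce exactly the planted pattern", {
  cfg <- synthetic_config(n_terms = 30, n_genes = 40, n_disease_genes = 15,
                          disease_term_count = 3, cooccurrence_prob = 1,
                          background_rate = 0, min_genes = 3, seed = 12)
  ont <- generate_ontology(cfg)
  syn <- generate_annotations(cfg, ont)
  dt <- sort(syn$disease$phenotype_terms)
  for (g in syn$planted_genes)
    expect_equal(sort(syn$annotations$direct[[g]]), dt)
  expect_setequal(syn$annotations$genes, syn$planted_genes)  # others empty
})

test_that("impossible disease draws fail loudly after bounded retries", {
  cfg <- synthetic_config(n_terms = 30, n_genes = 20, n_disease_genes = 2,
                          disease_term_count = 2, cooccurrence_prob = 0,
                          background_rate = 0, min_genes = 10, seed = 9)
  ont <- generate_ontology(cfg)
  expect_error(suppressWarnings(generate_annotations(cfg, ont)), "retries")
  w <- capture_warnings(try(generate_annotations(cfg, ont), silent = TRUE))
  expect_true(any(grepl("regenerating", w)))
})

test_that("generated networks respect the requested sizes and planted links", {
  cfg <- synthetic_config(n_network_nodes = 200, n_edges = 400,
                          planted_links = 0, seed = 14)
  A <- syn_gene_ids_for_test(1:20); B <- syn_gene_ids_for_test(21:40)
  net <- generate_network(cfg, A, B)
  expect_lte(nrow(net$edges), 400)             # dedup only removes
  expect_true(all(net$edges$from != net$edges$to))
  cfg2 <- synthetic_config(n_network_nodes = 200, n_edges = 400,
                           planted_links = 120, seed = 14)
  net2 <- generate_network(cfg2, A, B)
  expect_gt(links_between(A, B, net2), links_between(A, B, net))
})

test_that("planted network enrichment is detected by the permutation test", {
  cfg <- synthetic_config(n_network_nodes = 500, n_edges = 1000,
                          planted_links = 50, seed = 16)
  A <- syn_gene_ids_for_test(1:30); B <- syn_gene_ids_for_test(31:60)
  net <- generate_network(cfg, A, B)
  res <- empirical_p_links(A, B, net, iterations = 1000, seed = 2)
  expect_lt(res$empirical_p, 0.05)
})

test_that("synthetic GWAS couples odds ratios to windowed scores", {
  cfg <- synthetic_config(n_genes = 150, n_snps = 25, coupling_slope = 0.6,
                          noise_sd = 0, seed = 18)
  genes <- syn_gene_ids_for_test(1:150)
  set.seed(180)
  scores <- setNames(runif(150), genes)
  loci <- generate_loci(cfg, genes)
  snps <- generate_gwas(cfg, scores, loci)
  expect_equal(nrow(snps), 25)
  expect_true(all(snps$odds_ratio > 0))
  res <- suppressWarnings(          # summary.lm warns on the perfect fit
    max_score_vs_or(scores, loci, snps, window_mbp = cfg$window_mbp))
  expect_equal(res$r, 1)                       # noise-free coupling
  expect_identical(generate_gwas(cfg, scores, loci), snps)

  # zero slope: correlation within null sampling spread
  cfg0 <- synthetic_config(n_genes = 150, n_snps = 25, coupling_slope = 0,
                           noise_sd = 0.05, seed = 19)
  snps0 <- generate_gwas(cfg0, scores, loci)
  res0 <- max_score_vs_or(scores, loci, snps0, window_mbp = cfg0$window_mbp)
  expect_lt(abs(res0$r), 2 / sqrt(res0$n))
})

test_that("synthetic fixtures round-trip through writers and readers", {
  cfg <- synthetic_config(n_terms = 40, n_genes = 60, n_disease_genes = 10,
                          disease_term_count = 3, min_genes = 3, seed = 22)
  ont <- generate_ontology(cfg)
  syn <- generate_annotations(cfg, ont)
  dir <- withr::local_tempdir()

  op <- file.path(dir, "ont.obo")
  write_obo(ont, op)
  ont2 <- parse_obo(op)
  expect_setequal(ont2$terms, ont$terms)
  expect_identical(lapply(ont2$parents[ont$terms], sort),
                   lapply(ont$parents, sort))

  ap <- file.path(dir, "ann.tsv")
  write_annotations(syn$annotations, ap)
  ann2 <- expand_annotations(read_annotations(ap), ont)
  expect_identical(lapply(ann2$expanded[syn$annotations$genes], sort),
                   lapply(syn$annotations$expanded, sort))

  dp <- file.path(dir, "disease.tsv")
  write_disease_definitions(syn$disease, dp)
  d2 <- read_disease_definitions(dp)[[1]]
  expect_equal(d2$phenotype_terms, syn$disease$phenotype_terms)

  np <- file.path(dir, "net.tsv")
  net <- generate_network(cfg, syn$planted_genes[1:5], syn$planted_genes[6:10],
                          nodes = syn_gene_ids_for_test(1:60))
  write_edge_list(net, np)
  net2 <- read_edge_list(np)
  expect_identical(net2$edges, net$edges)
})
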