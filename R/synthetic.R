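#' Configuration for the synthetic data generator
#'
#' The generator emulates the structure of the real inputs — a DAG phenotype
#' ontology, gene annotations with a planted set of disease genes whose
#' disease-phenotype co-occurrence exceeds background, an interaction network
#' with enriched links between two planted sets, and GWAS SNPs whose odds
#' ratios are coupled to nearby gene scores — so every pipeline stage is
#' testable without external downloads. Generation is a pure function of the
#' configuration.
#'
#' @param seed master seed (default 42).
#' @param n_terms ontology size (default 300).
#' @param max_parents maximum parents per non-root term (default 2).
#' @param n_genes gene universe size (default 2000).
#' @param n_disease_genes planted disease genes (default 50).
#' @param disease_term_count disease phenotype terms, drawn from ontology
#'   leaves (default 8).
#' @param cooccurrence_prob probability that a planted gene carries each
#'   disease phenotype (default 0.6).
#' @param background_rate per-gene-per-term background annotation probability
#'   (default 0.05).
#' @param min_genes minimum expanded positives per disease phenotype; draws
#'   violating it are regenerated (default 10).
#' @param n_network_nodes,n_edges,planted_links interaction-network size and
#'   planted A-B link excess (defaults 500, 1000, 50).
#' @param n_snps,coupling_slope,noise_sd,window_mbp GWAS table size, linear
#'   OR-vs-score coupling, Gaussian noise SD, and scoring window in Mbp
#'   (defaults 20, 0.5, 0.05, 1).
#' @param n_chrom,chrom_length genome layout for synthetic loci (defaults
#'   20 chromosomes of 100 Mbp).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L, n_terms = 300L, max_parents = 2L,
                             n_genes = 2000L, n_disease_genes = 50L,
                             disease_term_count = 8L,
                             cooccurrence_prob = 0.6, background_rate = 0.05,
                             min_genes = 10L,
                             n_network_nodes = 500L, n_edges = 1000L,
                             planted_links = 50L,
                             n_snps = 20L, coupling_slope = 0.5,
                             noise_sd = 0.05, window_mbp = 1,
                             n_chrom = 20L, chrom_length = 1e8) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              max_parents = as.integer(max_parents),
              n_genes = as.integer(n_genes),
              n_disease_genes = as.integer(n_disease_genes),
              disease_term_count = as.integer(disease_term_count),
              cooccurrence_prob = cooccurrence_prob,
              background_rate = background_rate,
              min_genes = as.integer(min_genes),
              n_network_nodes = as.integer(n_network_nodes),
              n_edges = as.integer(n_edges),
              planted_links = as.integer(planted_links),
              n_snps = as.integer(n_snps),
              coupling_slope = coupling_slope, noise_sd = noise_sd,
              window_mbp = window_mbp,
              n_chrom = as.integer(n_chrom), chrom_length = chrom_length)
  probs <- c(cfg$cooccurrence_prob, cfg$background_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_terms, cfg$n_genes, cfg$n_disease_genes,
              cfg$disease_term_count, cfg$n_network_nodes)
  if (any(counts <= 0L)) stop("counts must be positive")
  if (cfg$n_terms < 2L) stop("n_terms must be >= 2")
  structure(cfg, class = "synthetic_config")
}

syn_gene_ids <- function(n) sprintf("G%05d", seq_len(n))
syn_term_ids <- function(n) sprintf("PT:%04d", seq_len(n))

#' Generate a random DAG phenotype ontology
#'
#' Terms are added in order; each non-root term draws between 1 and
#' `max_parents` parents uniformly from the earlier terms, so the graph is
#' acyclic by construction (a tree when `max_parents = 1`).
#'
#' @param cfg a [synthetic_config()].
#' @return A [phenotype_ontology()].
#' @export
generate_ontology <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "syn-ontology", 0L))
  ids <- syn_term_ids(cfg$n_terms)
  parents <- vector("list", cfg$n_terms)
  names(parents) <- ids
  parents[[1L]] <- character(0)
  for (i in 2:cfg$n_terms) {
    k <- sample.int(min(cfg$max_parents, i - 1L), 1L)
    parents[[i]] <- ids[sample.int(i - 1L, k)]
  }
  phenotype_ontology(parents)
}

#' Generate annotations with a planted disease module
#'
#' Draws `disease_term_count` disease phenotypes from the ontology's leaves.
#' Planted genes carry each disease term independently with
#' `cooccurrence_prob`, on top of background annotations in which every gene
#' carries every term with `background_rate`; background genes carry only
#' background annotations. Draws in which some disease phenotype ends up with
#' fewer than `min_genes` expanded positives are regenerated (with a warning,
#' at most 10 retries).
#'
#' @param cfg a [synthetic_config()].
#' @param ontology a [phenotype_ontology()], typically from
#'   [generate_ontology()].
#' @return List: `annotations` (expanded [annotation_set()]), `planted_genes`,
#'   `disease` (a [disease_definition()]), `planted_counts` (planted carriers
#'   per disease term).
#' @export
generate_annotations <- function(cfg, ontology) {
  if (cfg$disease_term_count > length(ontology$leaves))
    stop("disease_term_count exceeds the number of leaf terms")
  genes <- syn_gene_ids(cfg$n_genes)
  planted <- genes[seq_len(cfg$n_disease_genes)]
  terms <- ontology$terms

  for (attempt in 0:10) {
    if (attempt == 10L)
      stop("failed to draw disease phenotypes with >= ", cfg$min_genes,
           " positives after 10 retries")
    set.seed(derive_seed(cfg$seed, "syn-annotations", attempt))
    disease_terms <- sort(sample(ontology$leaves, cfg$disease_term_count),
                          method = "radix")
    # background: every gene x term flip
    bg <- matrix(stats::runif(cfg$n_genes * length(terms)) < cfg$background_rate,
                 nrow = cfg$n_genes, dimnames = list(genes, terms))
    # planted co-occurrence on top
    pl <- matrix(stats::runif(cfg$n_disease_genes * length(disease_terms)) <
                   cfg$cooccurrence_prob,
                 nrow = cfg$n_disease_genes,
                 dimnames = list(planted, disease_terms))
    bg[planted, disease_terms] <- bg[planted, disease_terms] | pl
    direct <- apply(bg, 1L, function(row) terms[row], simplify = FALSE)
    direct <- direct[vapply(direct, length, integer(1)) > 0L]
    ann <- expand_annotations(annotation_set(direct), ontology)
    counts <- term_gene_counts(ann)
    pos <- vapply(disease_terms, function(t)
      if (t %in% names(counts)) counts[[t]] else 0L, integer(1))
    if (all(pos >= cfg$min_genes)) break
    warning("disease phenotype with < ", cfg$min_genes,
            " positives; regenerating (attempt ", attempt + 1L, ")")
  }
  planted_counts <- colSums(pl)
  list(annotations = ann, planted_genes = planted,
       disease = disease_definition("synthetic_disease", disease_terms),
       planted_counts = planted_counts)
}

#' Generate an interaction network with planted cross-links
#'
#' Background edges are uniform random node pairs; `planted_links` additional
#' uniform A-B pairs are overlaid, then self-loops dropped and duplicates
#' collapsed (so the realized edge count is at most the requested one).
#'
#' @param cfg a [synthetic_config()].
#' @param setA,setB character vectors of gene ids to enrich links between.
#' @param nodes node universe (default: `n_network_nodes` synthetic gene ids,
#'   unioned with `setA` and `setB`).
#' @return An [interaction_network()].
#' @export
generate_network <- function(cfg, setA, setB, nodes = NULL) {
  if (is.null(nodes)) nodes <- syn_gene_ids(cfg$n_network_nodes)
  nodes <- unique(c(nodes, setA, setB))
  set.seed(derive_seed(cfg$seed, "syn-network", 0L))
  a <- sample(nodes, cfg$n_edges, replace = TRUE)
  b <- sample(nodes, cfg$n_edges, replace = TRUE)
  if (cfg$planted_links > 0L) {
    pa <- sample(setA, cfg$planted_links, replace = TRUE)
    pb <- sample(setB, cfg$planted_links, replace = TRUE)
    a <- c(a, pa); b <- c(b, pb)
  }
  interaction_network(data.frame(a, b, stringsAsFactors = FALSE),
                      nodes = nodes)
}

#' Generate synthetic gene loci
#'
#' Places each gene on a uniformly chosen chromosome at a uniform start with
#' span 10-100 kb; coordinates are 1-based inclusive.
#'
#' @param cfg a [synthetic_config()].
#' @param genes gene ids to place (default: the configured gene universe).
#' @return Loci data.frame (`gene`, `chrom`, `start`, `end`).
#' @export
generate_loci <- function(cfg, genes = NULL) {
  if (is.null(genes)) genes <- syn_gene_ids(cfg$n_genes)
  set.seed(derive_seed(cfg$seed, "syn-loci", 0L))
  n <- length(genes)
  chrom <- paste0("chr", sample.int(cfg$n_chrom, n, replace = TRUE))
  len <- as.integer(round(stats::runif(n, 1e4, 1e5)))
  start <- as.integer(floor(stats::runif(n, 1, cfg$chrom_length - max(len))))
  data.frame(gene = genes, chrom = chrom, start = start,
             end = start + len, stringsAsFactors = FALSE)
}

#' Generate GWAS SNPs with score-coupled odds ratios
#'
#' SNPs are placed near randomly chosen genes (within 50 kb of the gene
#' span); each SNP's odds ratio is `1 + coupling_slope * m + noise`, where
#' `m` is the maximal gene score within `window_mbp` of the SNP and the
#' Gaussian noise has SD `noise_sd`, truncated to stay positive.
#'
#' @param cfg a [synthetic_config()].
#' @param scores named numeric vector of gene scores (or a [phenoscore()]
#'   fit).
#' @param loci loci data.frame covering the scored genes.
#' @return SNP data.frame (`snp_id`, `chrom`, `pos`, `assoc_p`, `odds_ratio`).
#' @export
generate_gwas <- function(cfg, scores, loci) {
  if (inherits(scores, "phenoscore")) scores <- scores$scores
  loci <- loci[loci$gene %in% names(scores), , drop = FALSE]
  set.seed(derive_seed(cfg$seed, "syn-gwas", 0L))
  gi <- sample.int(nrow(loci), cfg$n_snps, replace = TRUE)
  offset <- as.integer(round(stats::runif(cfg$n_snps, -5e4, 5e4)))
  pos <- pmax(1L, loci$start[gi] + offset)
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(cfg$n_snps)),
                     chrom = loci$chrom[gi], pos = pos,
                     assoc_p = 10^(-stats::runif(cfg$n_snps, 4, 8)),
                     odds_ratio = NA_real_, stringsAsFactors = FALSE)
  m <- snp_max_scores(scores, loci, snps, cfg$window_mbp * 1e6)
  m[is.na(m)] <- 0
  or <- 1 + cfg$coupling_slope * m +
    stats::rnorm(cfg$n_snps, 0, cfg$noise_sd)
  snps$odds_ratio <- pmax(or, 1e-3)
  snps
}

# ---- plain-text writers (round-trip with the pipeline's readers) ----------

#' Serialize synthetic objects to the pipeline's plain-text formats
#'
#' `write_obo` emits minimal OBO 1.2 `[Term]` stanzas; the other writers emit
#' the tab-separated formats the corresponding readers expect, so generated
#' fixtures round-trip through [parse_obo()], [read_annotations()],
#' [read_edge_list()], [read_snp_table()], [read_gene_loci()] and
#' [read_disease_definitions()].
#'
#' @param ontology,annotations,net,snps,loci,diseases objects to serialize.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ontology$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    nm <- ontology$term_names[[t]]
    if (!is.null(nm) && !is.na(nm)) writeLines(paste0("name: ", nm), con)
    for (p in ontology$parents[[t]]) writeLines(paste0("is_a: ", p), con)
    if (t %in% ontology$obsolete) writeLines("is_obsolete: true", con)
  }
  invisible(path)
}

#' @rdname write_obo
#' @export
write_annotations <- function(annotations, path) {
  genes <- rep(annotations$genes,
               vapply(annotations$direct, length, integer(1)))
  df <- data.frame(gene = genes,
                   term_id = unlist(annotations$direct, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_obo
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("geneA", "geneB"))
  invisible(path)
}

#' @rdname write_obo
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_obo
#' @export
write_gene_loci <- function(loci, path) {
  utils::write.table(loci[c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_obo
#' @param diseases a [disease_definition()] or list of them.
#' @export
write_disease_definitions <- function(diseases, path) {
  if (inherits(diseases, "disease_definition")) diseases <- list(diseases)
  df <- do.call(rbind, lapply(diseases, function(d)
    data.frame(disease_id = d$disease_id, term_id = d$phenotype_terms)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
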