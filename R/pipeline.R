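#' Read disease definitions from TSV
#'
#' Two tab-separated columns `disease_id` and `term_id` (header required),
#' one phenotype term per row.
#'
#' @param path path to the disease-definition TSV.
#' @return Named list of [disease_definition()] objects.
#' @export
read_disease_definitions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", colClasses = "character")
  if (!all(c("disease_id", "term_id") %in% names(df)))
    stop("disease file must have columns 'disease_id' and 'term_id'")
  by_disease <- split(df$term_id, df$disease_id)
  lapply(stats::setNames(names(by_disease), names(by_disease)),
         function(d) disease_definition(d, by_disease[[d]]))
}

read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

# fingerprint a run: parameters, seed and the *content* of the input files
# (not their locations), so identical runs hash identically anywhere
config_hash <- function(config) {
  paths <- config$paths
  inputs <- list()
  for (p in sort(names(paths))) {
    if (is.character(paths[[p]]) && length(paths[[p]]) == 1L &&
        file.exists(paths[[p]]) && !dir.exists(paths[[p]]))
      inputs[[p]] <- unname(tools::md5sum(paths[[p]]))
  }
  canon <- list(params = config$params[sort(names(config$params))],
                seed = config$seed, inputs = inputs)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(min_genes = 10L, neg_ratio = 5L, n_trees = 100L,
                   k_folds = 10L, specificity_level = 0.95,
                   iterations = 1000L, window_mbp = 1)
  config$params <- utils::modifyList(defaults,
                                     as.list(config$params %||% list()))
  if (is.null(config$seed)) config$seed <- 1L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end scoring pipeline
#'
#' Reads the ontology, annotations and disease definitions named in the
#' configuration, fits the [phenoscore()] model for every disease, and writes
#' per-disease score tables plus a JSON manifest recording the configuration
#' hash, seed, package version and skipped phenotypes. Reruns with an
#' identical configuration and seed produce byte-identical outputs.
#'
#' @param config run configuration: a list, or the path to a YAML file, with
#'   entries `paths` (`ontology`, `annotations`, `diseases`, `output`),
#'   `params` (`min_genes`, `neg_ratio`, `n_trees`, ... — defaults are the
#'   published constants) and `seed`.
#' @return Invisibly, a list with the fitted models (`fits`), output file
#'   paths (`score_files`, `manifest_file`) and the manifest list.
#' @export
run_score <- function(config) {
  config <- load_run_config(config)
  paths <- config$paths
  for (p in c("ontology", "annotations", "diseases"))
    if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
      stop("config paths$", p, " is missing or does not exist")
  out_dir <- paths$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ontology <- parse_obo(paths$ontology)
  annotations <- expand_annotations(read_annotations(paths$annotations),
                                    ontology)
  diseases <- read_disease_definitions(paths$diseases)
  prm <- config$params

  fits <- list()
  score_files <- character(0)
  skipped <- list()
  for (d in names(diseases)) {
    fit <- phenoscore(diseases[[d]], annotations, ontology,
                      min_genes = prm$min_genes, neg_ratio = prm$neg_ratio,
                      n_trees = prm$n_trees, seed = config$seed)
    fits[[d]] <- fit
    skipped[[d]] <- as.list(fit$skipped)
    genes <- names(fit$scores)
    tab <- data.frame(gene = genes, check.names = FALSE)
    for (t in colnames(fit$prob)) tab[[paste0("p_", t)]] <- fit$prob[genes, t]
    tab$raw_sum <- fit$raw
    tab$score <- fit$scores
    tab$n_phenotypes_scored <- length(fit$weights)
    f <- file.path(out_dir, paste0("scores_", d, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    score_files[d] <- f
  }
  manifest <- list(tool = "phenoscore",
                   version = as.character(utils::packageVersion("phenoscore")),
                   config_hash = config_hash(config),
                   seed = config$seed, params = config$params,
                   diseases = names(diseases),
                   skipped_phenotypes = skipped,
                   n_genes = length(annotations$genes),
                   n_testable_phenotypes =
                     length(testable_phenotypes(ontology, annotations,
                                                prm$min_genes)))
  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(fits = fits, score_files = score_files,
                 manifest_file = manifest_file, manifest = manifest))
}

read_score_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  stats::setNames(df$score, df$gene)
}

#' Evaluate fitted scores against gold standards and optional side data
#'
#' For each configured gold-standard gene set: mean score with standard
#' error, ROC with AUC, the specificity cutoff at the configured level and
#' the genes at or above it. A control ROC in which the positives are
#' replaced by an equal-size random sample of scored genes is included. When
#' an interaction network (plus a second gene set) or SNP/locus tables are
#' configured, the Monte-Carlo link test, degree comparison, distance profile
#' and OR correlation are run as well. Results are written as a JSON report.
#'
#' @param config run configuration (see [run_score()]); evaluation reads
#'   `paths$gold_standards` (list of `label` / `positives` / optional
#'   `negatives` gene-list files), and optionally `paths$network`,
#'   `paths$network_set_b`, `paths$snps`, `paths$loci`.
#' @param scores named numeric vector of gene scores, a [phenoscore()] fit,
#'   or `NULL` to read the first score table written by [run_score()].
#' @return Invisibly, the report list (also written to
#'   `paths$output`/evaluation.json).
#' @export
run_evaluate <- function(config, scores = NULL) {
  config <- load_run_config(config)
  paths <- config$paths
  prm <- config$params
  out_dir <- paths$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scores)) {
    sf <- list.files(out_dir, pattern = "^scores_.*\\.tsv$",
                     full.names = TRUE)
    if (length(sf) == 0L) stop("no score table found; run run_score first")
    scores <- read_score_table(sf[[1L]])
  }
  if (inherits(scores, "phenoscore")) scores <- scores$scores

  report <- list(n_genes_scored = length(scores))
  set.seed(config$seed)

  gs_results <- list()
  for (gs in paths$gold_standards %||% list()) {
    pos <- intersect(read_gene_list(gs$positives), names(scores))
    neg <- if (!is.null(gs$negatives))
      intersect(read_gene_list(gs$negatives), names(scores))
    else setdiff(names(scores), pos)
    gold <- gold_standard(pos, neg, label = gs$label %||% "gold_standard")
    roc <- roc_curve(scores, gold)
    cutoff <- specificity_cutoff(scores, neg, prm$specificity_level)
    high <- names(scores)[scores >= cutoff]
    ctrl_pos <- sample(names(scores), length(pos))
    ctrl <- roc_curve(scores, gold_standard(ctrl_pos,
                                            setdiff(names(scores), ctrl_pos),
                                            label = "random control"))
    s <- scores[pos]
    gs_results[[gold$label]] <- list(
      n_positives = length(pos), n_negatives = length(neg),
      mean_score = mean(s),
      se_score = stats::sd(s) / sqrt(length(s)),
      auc = roc$auc, control_auc = ctrl$auc,
      specificity_cutoff = cutoff,
      n_predicted = length(high),
      predicted_genes = sort(intersect(high, union(pos, neg)),
                             method = "radix"))
  }
  report$gold_standards <- gs_results

  if (!is.null(paths$network)) {
    net <- read_edge_list(paths$network)
    cutoff <- if (length(gs_results) > 0L)
      gs_results[[1L]]$specificity_cutoff
    else stats::quantile(scores, prm$specificity_level)
    setA <- names(scores)[scores >= cutoff]
    report$network <- list(degree = degree_stats(setA, net))
    if (!is.null(paths$network_set_b)) {
      setB <- read_gene_list(paths$network_set_b)
      pr <- empirical_p_links(setA, setB, net,
                              iterations = prm$iterations,
                              seed = config$seed)
      report$network$links <- list(observed = pr$observed,
                                   empirical_p = pr$empirical_p,
                                   p_label = pr$p_label,
                                   null_mean = mean(pr$null_counts))
    }
  }

  if (!is.null(paths$snps) && !is.null(paths$loci)) {
    snps <- read_snp_table(paths$snps)
    loci <- read_gene_loci(paths$loci)
    cutoff <- if (length(gs_results) > 0L)
      gs_results[[1L]]$specificity_cutoff
    else stats::quantile(scores, prm$specificity_level)
    edges <- c(0, 10^(4:7) * 5, Inf)
    report$gwas <- list(
      distance_profile = distance_profile(scores, loci, snps, edges, cutoff),
      or_correlation = max_score_vs_or(scores, loci, snps,
                                       window_mbp = prm$window_mbp)[
                                         c("r", "slope_p", "n")])
  }

  report_file <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(report)
}
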