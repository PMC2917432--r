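#' Disease definition
#'
#' A disease is represented by its curated list of phenotype ontology terms
#' (the clinical traits mapped to ontology accessions).
#'
#' @param disease_id label for the disease.
#' @param phenotype_terms character vector of phenotype term ids; must be
#'   nonempty and unique.
#' @return An object of class `disease_definition`.
#' @export
disease_definition <- function(disease_id, phenotype_terms) {
  phenotype_terms <- as.character(phenotype_terms)
  if (length(phenotype_terms) == 0L) stop("phenotype_terms must be nonempty")
  if (anyDuplicated(phenotype_terms)) stop("phenotype_terms must be unique")
  structure(list(disease_id = disease_id, phenotype_terms = phenotype_terms),
            class = "disease_definition")
}

#' @export
print.disease_definition <- function(x, ...) {
  cat("Disease", x$disease_id, "-", length(x$phenotype_terms),
      "phenotype terms\n")
  invisible(x)
}

# deterministic per-(target, repeat) RNG stream derived from the master seed;
# order-independent across targets, always < 2^31
derive_seed <- function(seed, target, r) {
  u <- utf8ToInt(target)
  h <- sum(u * seq_along(u)) %% 100000
  as.integer((as.numeric(seed) + 1000003 * h + 104729 * r) %% 2147483629)
}

#' Train a per-phenotype classifier ensemble
#'
#' For a target phenotype, the gold-standard positives (GSP) are the genes
#' annotated (after expansion) with the target; each of `n_trees` trees is
#' trained on the GSP plus a fresh gold-standard-negative (GSN) set of
#' `neg_ratio` times as many genes, drawn uniformly without replacement from
#' the genes lacking the target. Attributes are the leakage-safe
#' [attribute_set()] of the target.
#'
#' A target with fewer than `min_genes` positives, no attributes, or too few
#' eligible negatives is marked untrainable and skipped downstream rather
#' than imputed.
#'
#' @param target term id of the target phenotype.
#' @param annotations an expanded [annotation_set()].
#' @param ontology a [phenotype_ontology()].
#' @param testable testable phenotype set (computed if `NULL`).
#' @param n_trees ensemble size (default 100).
#' @param neg_ratio negatives per positive (default 5).
#' @param min_genes minimum GSP size (default 10).
#' @param seed master seed; per-repeat streams are derived deterministically.
#' @param config a [tree_config()].
#' @param attr_matrix optional precomputed [annotation_matrix()] over the gene
#'   universe whose columns include the attribute set (avoids rebuilding when
#'   training many targets).
#' @return An object of class `phenotype_classifier` with components `target`,
#'   `trainable`, `trees`, `attributes`, `gsp`, `n_trees`, `neg_ratio`,
#'   `seed` and, when untrainable, `reason`.
#' @export
train_phenotype_classifier <- function(target, annotations, ontology,
                                       testable = NULL,
                                       n_trees = 100L, neg_ratio = 5L,
                                       min_genes = 10L, seed = 1L,
                                       config = tree_config(),
                                       attr_matrix = NULL) {
  if (is.null(annotations$expanded))
    stop("annotations must be expanded first (see expand_annotations)")
  if (!target %in% ontology$terms)
    stop("target term not in ontology: ", target)
  if (is.null(testable))
    testable <- testable_phenotypes(ontology, annotations, min_genes)
  attrs <- attribute_set(target, testable, ontology)
  universe <- annotations$genes
  gsp <- universe[vapply(annotations$expanded,
                         function(ts) target %in% ts, logical(1))]
  eligible <- setdiff(universe, gsp)

  untrainable <- function(reason) {
    structure(list(target = target, trainable = FALSE, reason = reason,
                   gsp = gsp, attributes = attrs,
                   n_trees = n_trees, neg_ratio = neg_ratio, seed = seed),
              class = "phenotype_classifier")
  }
  if (length(gsp) < min_genes)
    return(untrainable(sprintf("only %d positives (< %d)",
                               length(gsp), min_genes)))
  if (length(attrs) == 0L)
    return(untrainable("empty attribute set"))
  n_neg <- neg_ratio * length(gsp)
  if (length(eligible) < n_neg)
    return(untrainable(sprintf("only %d eligible negatives (< %d)",
                               length(eligible), n_neg)))

  if (is.null(attr_matrix))
    attr_matrix <- annotation_matrix(annotations, terms = attrs)
  x_pos <- attr_matrix[gsp, attrs, drop = FALSE]
  trees <- vector("list", n_trees)
  for (r in seq_len(n_trees)) {
    set.seed(derive_seed(seed, target, r))
    gsn <- sample(eligible, n_neg, replace = FALSE)
    x <- rbind(x_pos, attr_matrix[gsn, attrs, drop = FALSE])
    y <- rep(c(TRUE, FALSE), c(length(gsp), n_neg))
    trees[[r]] <- phenotree(x, y, config)
  }
  structure(list(target = target, trainable = TRUE, trees = trees,
                 gsp = gsp, attributes = attrs,
                 n_trees = n_trees, neg_ratio = neg_ratio, seed = seed),
            class = "phenotype_classifier")
}

#' @export
print.phenotype_classifier <- function(x, ...) {
  cat("Phenotype classifier for", x$target, "- ")
  if (x$trainable)
    cat(x$n_trees, "trees,", length(x$gsp), "positives,",
        length(x$attributes), "attributes\n")
  else
    cat("untrainable (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Ensemble phenotype probability
#'
#' The final probability that a gene shows the target phenotype is the
#' arithmetic mean of the leaf probabilities over the ensemble's trees.
#'
#' @param object a trainable [train_phenotype_classifier()] result.
#' @param newdata logical attribute matrix (genes x terms); columns missing a
#'   split term are treated as phenotype-absent.
#' @param ... unused.
#' @return Numeric vector of probabilities, one per row of `newdata`.
#' @export
predict.phenotype_classifier <- function(object, newdata, ...) {
  if (!object$trainable)
    stop("classifier for ", object$target, " is untrainable: ", object$reason)
  preds <- vapply(object$trees, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  if (nrow(newdata) == 1L) mean(preds) else rowMeans(preds)
}

#' @describeIn predict.phenotype_classifier convenience wrapper computing the
#'   attribute matrix for named genes from an expanded annotation set.
#' @param clf a [train_phenotype_classifier()] result.
#' @param genes gene ids to score.
#' @param annotations an expanded [annotation_set()]; genes absent from it are
#'   scored with all attributes absent.
#' @export
phenotype_probability <- function(clf, genes, annotations) {
  if (!clf$trainable)
    stop("classifier for ", clf$target, " is untrainable: ", clf$reason)
  m <- matrix(FALSE, nrow = length(genes), ncol = length(clf$attributes),
              dimnames = list(genes, clf$attributes))
  known <- intersect(genes, annotations$genes)
  if (length(known) > 0L)
    m[known, ] <- annotation_matrix(annotations, terms = clf$attributes,
                                    genes = known)
  predict(clf, m)
}

#' Phenotype frequency weight
#'
#' The weight of a phenotype is `-log10(f)` where `f` is the fraction of the
#' gene universe annotated (after expansion) with the term. Common phenotypes
#' carry little information and are down-weighted; a phenotype annotated to
#' every gene gets weight 0.
#'
#' @param annotations an expanded [annotation_set()].
#' @param terms character vector of term ids; each must be annotated to at
#'   least one gene.
#' @return Named numeric vector of weights.
#' @export
phenotype_weight <- function(annotations, terms) {
  if (is.null(annotations$expanded))
    stop("annotations must be expanded first (see expand_annotations)")
  counts <- term_gene_counts(annotations)
  n <- vapply(terms, function(t)
    if (t %in% names(counts)) counts[[t]] else 0L, integer(1))
  if (any(n == 0L))
    stop("weight undefined for unannotated term(s): ",
         paste(terms[n == 0L], collapse = ", "))
  w <- -log10(n / length(annotations$genes))
  names(w) <- terms
  w
}

#' Weighted, normalized disease score
#'
#' Aggregates per-phenotype probabilities into a disease score:
#' `sum(w * p) / sum(w)`, i.e. the weighted probability sum normalized by its
#' maximal attainable value, so scores lie in \[0, 1\] and equal 1 only for a
#' gene with probability 1 for every scored phenotype.
#'
#' @param probabilities numeric vector (or genes x phenotypes matrix) of
#'   per-phenotype probabilities.
#' @param weights numeric vector of phenotype weights, aligned with the
#'   probabilities.
#' @return Numeric score(s) in \[0, 1\].
#' @export
weighted_disease_score <- function(probabilities, weights) {
  if (sum(weights) <= 0) stop("total phenotype weight must be positive")
  if (is.matrix(probabilities)) {
    stopifnot(ncol(probabilities) == length(weights))
    as.numeric(probabilities %*% weights) / sum(weights)
  } else {
    stopifnot(length(probabilities) == length(weights))
    sum(probabilities * weights) / sum(weights)
  }
}

#' Fit the disease-causality scoring model
#'
#' The central estimator: for each phenotype of a disease, a decision-tree
#' ensemble with resampled negative gene sets estimates every gene's
#' probability of showing that phenotype when perturbed; the probabilities are
#' combined with `-log10` frequency weights and normalized, yielding a
#' per-gene disease score in \[0, 1\] interpreted as the likelihood that
#' perturbing the gene produces the disease's phenotypes.
#'
#' Phenotypes whose classifiers are untrainable (too few positives or
#' negatives) are skipped and the score renormalized over the phenotypes
#' actually scored; they are reported in the fitted object, never imputed as
#' probability zero.
#'
#' @param disease a [disease_definition()].
#' @param annotations an [annotation_set()] (expanded automatically if not
#'   already).
#' @param ontology a [phenotype_ontology()].
#' @param min_genes testable-phenotype and GSP-size threshold (default 10).
#' @param neg_ratio negatives per positive in each training set (default 5).
#' @param n_trees trees per phenotype ensemble (default 100).
#' @param seed master seed; all negative-set draws derive from it.
#' @param config a [tree_config()].
#' @return An object of class `phenoscore` with components `scores` (named,
#'   normalized, sorted by gene id), `raw` (weighted sums), `prob` (gene x
#'   phenotype probability matrix), `weights`, `skipped` (named reasons),
#'   `classifiers`, `disease`, `params`, and the inputs needed by
#'   [predict.phenoscore()].
#' @export
phenoscore <- function(disease, annotations, ontology,
                       min_genes = 10L, neg_ratio = 5L, n_trees = 100L,
                       seed = 1L, config = tree_config()) {
  stopifnot(inherits(disease, "disease_definition"))
  if (is.null(annotations$expanded))
    annotations <- expand_annotations(annotations, ontology)
  bad <- setdiff(disease$phenotype_terms, ontology$terms)
  if (length(bad) > 0L)
    stop("disease phenotype term(s) not in ontology: ",
         paste(bad, collapse = ", "))

  testable <- testable_phenotypes(ontology, annotations, min_genes)
  genes <- sort(annotations$genes, method = "radix")
  full_matrix <- annotation_matrix(annotations, terms = testable,
                                   genes = genes)

  terms <- disease$phenotype_terms
  classifiers <- vector("list", length(terms))
  names(classifiers) <- terms
  prob <- matrix(NA_real_, nrow = length(genes), ncol = length(terms),
                 dimnames = list(genes, terms))
  skipped <- character(0)
  for (t in terms) {
    clf <- train_phenotype_classifier(
      t, annotations, ontology, testable = testable,
      n_trees = n_trees, neg_ratio = neg_ratio, min_genes = min_genes,
      seed = seed, config = config, attr_matrix = full_matrix)
    classifiers[[t]] <- clf
    if (clf$trainable) {
      prob[, t] <- predict(clf, full_matrix[, clf$attributes, drop = FALSE])
    } else {
      skipped[t] <- clf$reason
    }
  }
  scored <- setdiff(terms, names(skipped))
  if (length(scored) == 0L)
    stop("no trainable phenotype for disease ", disease$disease_id, ": ",
         paste(sprintf("%s (%s)", names(skipped), skipped), collapse = "; "))
  weights <- phenotype_weight(annotations, scored)
  raw <- as.numeric(prob[, scored, drop = FALSE] %*% weights)
  names(raw) <- genes
  scores <- raw / sum(weights)

  structure(list(scores = scores, raw = raw, prob = prob, weights = weights,
                 skipped = skipped, classifiers = classifiers,
                 disease = disease, ontology = ontology,
                 params = list(min_genes = min_genes, neg_ratio = neg_ratio,
                               n_trees = n_trees, seed = seed,
                               config = config),
                 testable = testable),
            class = "phenoscore")
}

#' @export
print.phenoscore <- function(x, ...) {
  cat("Disease phenotype score model:", x$disease$disease_id, "\n")
  cat("  ", length(x$scores), " genes scored over ",
      length(x$weights), "/", length(x$disease$phenotype_terms),
      " phenotypes (", x$params$n_trees, " trees each, ",
      x$params$neg_ratio, "x negatives, seed ", x$params$seed, ")\n", sep = "")
  if (length(x$skipped) > 0L)
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  top <- utils::head(sort(x$scores, decreasing = TRUE), 5L)
  cat("  top genes:",
      paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.phenoscore <- function(object, ...) {
  terms <- object$disease$phenotype_terms
  tab <- data.frame(
    term      = terms,
    n_pos     = vapply(object$classifiers,
                       function(c) length(c$gsp), integer(1)),
    trainable = vapply(object$classifiers,
                       function(c) isTRUE(c$trainable), logical(1)),
    weight    = ifelse(terms %in% names(object$weights),
                       object$weights[terms], NA_real_),
    row.names = NULL)
  out <- list(disease = object$disease$disease_id, phenotypes = tab,
              score_quantiles = stats::quantile(object$scores,
                                                c(0, .25, .5, .75, .95, 1)))
  class(out) <- "summary.phenoscore"
  out
}

#' @export
print.summary.phenoscore <- function(x, ...) {
  cat("Disease:", x$disease, "\n\nPhenotypes:\n")
  print(x$phenotypes, row.names = FALSE)
  cat("\nScore quantiles:\n")
  print(signif(x$score_quantiles, 4))
  invisible(x)
}

#' Score new genes with a fitted model
#'
#' @param object a fitted [phenoscore()] model.
#' @param newdata an [annotation_set()] of the genes to score (expanded
#'   against the model's ontology if not already); genes without annotations
#'   may be included by name in `genes` and are scored down the all-absent
#'   paths.
#' @param genes gene ids to score (default: `newdata`'s gene universe).
#' @param ... unused.
#' @return Named numeric vector of normalized disease scores.
#' @export
predict.phenoscore <- function(object, newdata, genes = NULL, ...) {
  if (is.null(newdata$expanded))
    newdata <- expand_annotations(newdata, object$ontology)
  if (is.null(genes)) genes <- newdata$genes
  scored <- names(object$weights)
  p <- matrix(NA_real_, length(genes), length(scored),
              dimnames = list(genes, scored))
  for (t in scored)
    p[, t] <- phenotype_probability(object$classifiers[[t]], genes, newdata)
  out <- weighted_disease_score(p, object$weights)
  names(out) <- genes
  out
}

#' @export
plot.phenoscore <- function(x, ...) {
  s <- sort(x$scores, decreasing = TRUE)
  graphics::plot(seq_along(s), s, type = "l", log = "x",
                 xlab = "gene rank", ylab = "normalized disease score",
                 main = paste("Disease score profile:", x$disease$disease_id),
                 ...)
  invisible(x)
}
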