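#' Gold standard gene sets
#'
#' @param positives,negatives disjoint character vectors of gene ids.
#' @param label provenance label for reports.
#' @return An object of class `gold_standard`.
#' @export
gold_standard <- function(positives, negatives, label = "") {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(intersect(positives, negatives)) > 0L)
    stop("positives and negatives must be disjoint")
  structure(list(positives = positives, negatives = negatives, label = label),
            class = "gold_standard")
}

#' ROC curve of gene scores against a gold standard
#'
#' Genes are rank-ordered by score; thresholds sweep the distinct score
#' values in descending order, with all genes sharing a score entering at one
#' threshold (one ROC vertex). Coverage (sensitivity) is `TP / |GSP|` and the
#' false positive rate is `FP / (FP + TN)`; the area under the curve is the
#' trapezoid area over the vertices, which under this tie convention equals
#' the tie-corrected Mann-Whitney rank statistic.
#'
#' @param scores named numeric vector of gene scores.
#' @param gold a [gold_standard()]; genes absent from `scores` are ignored.
#' @return An object of class `roc_curve`: `points` (data.frame with columns
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, gold) {
  pos <- intersect(gold$positives, names(scores))
  neg <- intersect(gold$negatives, names(scores))
  if (length(pos) == 0L || length(neg) == 0L)
    stop("need at least one scored positive and one scored negative")
  s <- scores[c(pos, neg)]
  y <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- rev(!duplicated(rev(s)))          # last index of each tied block
  tpr <- c(0, tp[last] / length(pos))
  fpr <- c(0, fp[last] / length(neg))
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = length(pos), n_neg = length(neg),
                 label = gold$label),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC", if (nzchar(x$label)) paste0("(", x$label, ")"), "-",
      x$n_pos, "positives vs", x$n_neg, "negatives; AUC =",
      signif(x$auc, 4), "\n")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate (1 - specificity)",
                 ylab = "coverage (sensitivity)",
                 main = sprintf("ROC %s (AUC = %.3f)", x$label, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Cross-validated phenotype classifier ROC
#'
#' Evaluates a target phenotype's ensemble classifier by stratified k-fold
#' cross-validation. The positives are the genes carrying the target; a
#' single negative pool of `neg_ratio` times as many genes is drawn once and
#' folded jointly with the positives. Per fold, an ensemble is trained on the
#' other folds (each tree drawing its negatives from the training folds'
#' negative pool) and the held-out genes are scored; the ROC is pooled over
#' folds.
#'
#' @inheritParams train_phenotype_classifier
#' @param k number of folds (default 10); `k = |GSP|` gives leave-one-out.
#' @return List of class `phenotype_cv`: `roc` (a [roc_curve()]), pooled
#'   `scores` and `labels`, `k`, `target`.
#' @export
kfold_phenotype_cv <- function(target, annotations, ontology, k = 10L,
                               n_trees = 25L, neg_ratio = 5L, min_genes = 10L,
                               seed = 1L, config = tree_config(),
                               testable = NULL) {
  if (is.null(annotations$expanded))
    annotations <- expand_annotations(annotations, ontology)
  if (is.null(testable))
    testable <- testable_phenotypes(ontology, annotations, min_genes)
  attrs <- attribute_set(target, testable, ontology)
  universe <- annotations$genes
  gsp <- universe[vapply(annotations$expanded,
                         function(ts) target %in% ts, logical(1))]
  if (length(gsp) < k)
    stop("cross-validation needs at least k = ", k, " positives; ",
         target, " has ", length(gsp))
  eligible <- setdiff(universe, gsp)
  n_neg <- min(neg_ratio * length(gsp), length(eligible))
  set.seed(derive_seed(seed, target, 0L))
  gsn <- sample(eligible, n_neg, replace = FALSE)

  m <- annotation_matrix(annotations, terms = attrs, genes = c(gsp, gsn))
  fold_pos <- sample(rep_len(seq_len(k), length(gsp)))
  fold_neg <- sample(rep_len(seq_len(k), length(gsn)))

  all_scores <- numeric(0); all_labels <- logical(0); all_genes <- character(0)
  for (f in seq_len(k)) {
    tr_pos <- gsp[fold_pos != f]; te_pos <- gsp[fold_pos == f]
    tr_neg <- gsn[fold_neg != f]; te_neg <- gsn[fold_neg == f]
    n_draw <- min(neg_ratio * length(tr_pos), length(tr_neg))
    preds <- matrix(NA_real_, length(te_pos) + length(te_neg), n_trees)
    te_m <- m[c(te_pos, te_neg), , drop = FALSE]
    for (r in seq_len(n_trees)) {
      set.seed(derive_seed(seed, target, 1000L * f + r))
      neg_r <- sample(tr_neg, n_draw, replace = FALSE)
      x <- m[c(tr_pos, neg_r), , drop = FALSE]
      y <- rep(c(TRUE, FALSE), c(length(tr_pos), n_draw))
      preds[, r] <- predict(phenotree(x, y, config), te_m)
    }
    all_scores <- c(all_scores, rowMeans(preds))
    all_labels <- c(all_labels, rep(c(TRUE, FALSE),
                                    c(length(te_pos), length(te_neg))))
    all_genes <- c(all_genes, te_pos, te_neg)
  }
  names(all_scores) <- all_genes
  roc <- roc_curve(all_scores,
                   gold_standard(all_genes[all_labels], all_genes[!all_labels],
                                 label = paste0(k, "-fold CV: ", target)))
  structure(list(roc = roc, scores = all_scores, labels = all_labels,
                 k = k, target = target),
            class = "phenotype_cv")
}

#' @export
print.phenotype_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation of ", x$target, ": AUC = ",
      signif(x$roc$auc, 4), " (", sum(x$labels), " positives, ",
      sum(!x$labels), " negatives held out)\n", sep = "")
  invisible(x)
}

# smallest double strictly greater than x (x >= 0)
next_up <- function(x) {
  if (x == 0) .Machine$double.xmin else x * (1 + .Machine$double.eps)
}

#' Score threshold at a given specificity
#'
#' The smallest threshold such that the fraction of gold-standard negatives
#' scoring at or above it is at most `1 - level`; genes at or above the
#' returned threshold are the high-confidence predictions.
#'
#' @param scores named numeric vector of gene scores.
#' @param negatives character vector of gold-standard-negative gene ids (must
#'   be scored).
#' @param level required specificity, in (0, 1) (default 0.95).
#' @return Numeric threshold; the realized specificity on `negatives` is
#'   guaranteed to be at least `level`.
#' @export
specificity_cutoff <- function(scores, negatives, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1")
  neg <- scores[intersect(negatives, names(scores))]
  if (length(neg) == 0L) stop("no scored negatives")
  cand <- sort(unique(neg))
  n <- length(neg)
  for (t in cand) {
    if (sum(neg >= t) / n <= 1 - level) return(t)
  }
  next_up(max(neg))
}

#' Fold enrichment over background
#'
#' `(m/n) / (M/N)`: within a subset of `n` genes of which `m` are disease
#' related, the enrichment relative to a background of `N` genes of which `M`
#' are disease related.
#'
#' @param m,n,M,N nonnegative counts; `n`, `M`, `N` must be positive.
#' @return The enrichment ratio (scale-invariant in the counts).
#' @export
fold_enrichment <- function(m, n, M, N) {
  if (n <= 0 || N <= 0 || M <= 0) stop("n, M and N must be positive")
  (m / n) / (M / N)
}

#' Disease phenotype similarity of a gene to a reference disease set
#'
#' For a gene `a` with known disease associations, the similarity to a
#' reference set `R` is the double sum of pairwise disease similarities
#' `S(a) = sum_i sum_j s_ij` over diseases `i` associated with `a` but not in
#' `R`, and diseases `j` in `R`.
#'
#' @param gene gene id.
#' @param gene_diseases named list mapping gene -> character vector of disease
#'   ids.
#' @param reference character vector: the reference disease set `R`.
#' @param sim numeric matrix of pairwise disease similarities with disease ids
#'   as dimnames.
#' @param missing how to treat absent similarity entries: `"zero"` (default;
#'   counted as 0 with a warning) or `"error"`.
#' @return Numeric similarity score (0 if the gene has no diseases outside
#'   `R`).
#' @export
disease_similarity_score <- function(gene, gene_diseases, reference, sim,
                                     missing = c("zero", "error")) {
  missing <- match.arg(missing)
  di <- setdiff(gene_diseases[[gene]], reference)
  if (length(di) == 0L || length(reference) == 0L) return(0)
  total <- 0
  n_missing <- 0L
  for (i in di) for (j in reference) {
    if (i %in% rownames(sim) && j %in% colnames(sim) && !is.na(sim[i, j])) {
      total <- total + sim[i, j]
    } else {
      if (missing == "error")
        stop("missing similarity entry for (", i, ", ", j, ")")
      n_missing <- n_missing + 1L
    }
  }
  if (n_missing > 0L)
    warning(n_missing, " missing similarity entr",
            if (n_missing == 1L) "y" else "ies", " treated as 0")
  total
}
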