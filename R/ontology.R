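#' Construct a phenotype ontology from child -> parent edges
#'
#' A phenotype ontology is a directed acyclic graph of controlled phenotype
#' terms in which edges denote is_a generalization: annotating a gene with a
#' term implies all of its ancestors.
#'
#' @param parents named list; one entry per term, each a character vector of
#'   parent term ids (character(0) for roots).
#' @param names optional named character vector of human-readable term names.
#' @param obsolete optional character vector of term ids flagged obsolete.
#' @return An object of class `phenotype_ontology` with components `terms`
#'   (term ids), `parents` and `children` (adjacency lists), `ancestors` and
#'   `descendants` (precomputed transitive closures), `roots`, `leaves`,
#'   `obsolete` and `term_names`. Obsolete terms are retained but excluded
#'   from the leaf set.
#' @export
phenotype_ontology <- function(parents, names = NULL, obsolete = character()) {
  term_ids <- base::names(parents)
  if (is.null(term_ids) || anyDuplicated(term_ids))
    stop("terms must have unique ids")
  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, term_ids)
  if (length(missing) > 0L)
    stop("parent term(s) not defined: ", paste(missing, collapse = ", "))

  children <- lapply(term_ids, function(t) character(0))
  base::names(children) <- term_ids
  for (t in term_ids) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }

  ord <- topological_order(parents, term_ids)   # errors on cycles

  # transitive closures in topological order (parents before children)
  ancestors <- vector("list", length(term_ids))
  base::names(ancestors) <- term_ids
  for (t in ord) {
    ps <- parents[[t]]
    ancestors[[t]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
  }
  descendants <- lapply(term_ids, function(t) character(0))
  base::names(descendants) <- term_ids
  for (t in rev(ord)) {
    ch <- children[[t]]
    descendants[[t]] <- unique(c(ch, unlist(descendants[ch], use.names = FALSE)))
  }

  is_leaf <- vapply(children, function(ch) length(ch) == 0L, logical(1))
  structure(list(
    terms       = term_ids,
    parents     = parents,
    children    = children,
    ancestors   = ancestors,
    descendants = descendants,
    roots       = term_ids[vapply(parents, length, 1L) == 0L],
    leaves      = setdiff(term_ids[is_leaf], obsolete),
    obsolete    = obsolete,
    term_names  = names
  ), class = "phenotype_ontology")
}

# Kahn topological sort over child->parent edges; hard error naming a cycle
# member, as required for malformed ontology files.
topological_order <- function(parents, term_ids) {
  indeg <- vapply(parents, length, integer(1))  # number of unprocessed parents
  children <- new.env(parent = emptyenv())
  for (t in term_ids) {
    for (p in parents[[t]]) {
      assign(p, c(get0(p, envir = children, ifnotfound = character(0)), t),
             envir = children)
    }
  }
  queue <- term_ids[indeg == 0L]
  ord <- character(0)
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, t)
    for (ch in get0(t, envir = children, ifnotfound = character(0))) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != length(term_ids)) {
    cyc <- setdiff(term_ids, ord)
    stop("cycle detected in ontology involving term ", cyc[[1L]])
  }
  ord
}

#' Parse a phenotype ontology from an OBO file
#'
#' Reads `[Term]` stanzas (OBO 1.2/1.4), using `id`, `name`, `is_a` and
#' `is_obsolete` tags. Only is_a relations build the DAG; other relationship
#' types are ignored. Obsolete terms are loaded but flagged and excluded from
#' the leaf set.
#'
#' @param path path to an OBO file.
#' @return A [phenotype_ontology()].
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)           # trailing comments
  lines <- trimws(lines)

  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0), obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[.*\\]$", ln)) {          # [Typedef] etc.
      terms <- flush(cur, terms)
      cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || ln == "") next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) next
    tag <- m[[2L]]; val <- trimws(m[[3L]])
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "is_a") cur$parents <- c(cur$parents, strsplit(val, "\\s+")[[1L]][1L])
    else if (tag == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0L) stop("no [Term] stanzas found in ", path)

  parents <- lapply(terms, function(t) if (t$obsolete) character(0) else t$parents)
  nm <- vapply(terms, function(t) if (is.null(t$name)) NA_character_ else t$name,
               character(1))
  obsolete <- names(terms)[vapply(terms, `[[`, logical(1), "obsolete")]
  phenotype_ontology(parents, names = nm, obsolete = obsolete)
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  cat("Phenotype ontology:", length(x$terms), "terms,",
      length(x$roots), "root(s),", length(x$leaves), "leaves")
  if (length(x$obsolete) > 0L) cat(",", length(x$obsolete), "obsolete")
  cat("\n")
  invisible(x)
}

#' Ancestors / descendants of ontology terms
#'
#' @param ontology a [phenotype_ontology()].
#' @param terms character vector of term ids.
#' @return Character vector: the union of the (strict) ancestors, respectively
#'   descendants, of `terms`.
#' @export
term_ancestors <- function(ontology, terms) {
  unknown <- setdiff(terms, ontology$terms)
  if (length(unknown) > 0L)
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  unique(unlist(ontology$ancestors[terms], use.names = FALSE))
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(ontology, terms) {
  unknown <- setdiff(terms, ontology$terms)
  if (length(unknown) > 0L)
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  unique(unlist(ontology$descendants[terms], use.names = FALSE))
}

#' Gene -> phenotype annotation sets
#'
#' Holds direct annotations (as curated) and, after [expand_annotations()],
#' their upward closure under the ontology's is_a relation. The gene universe
#' is the set of genes with at least one annotation.
#'
#' @param direct named list mapping gene id to a character vector of term ids.
#' @return An object of class `annotation_set` with components `direct`,
#'   `expanded` (NULL until expanded) and `genes`.
#' @export
annotation_set <- function(direct) {
  if (is.null(names(direct)) || anyDuplicated(names(direct)))
    stop("genes must have unique ids")
  direct <- lapply(direct, function(ts) unique(as.character(ts)))
  keep <- vapply(direct, length, integer(1)) > 0L
  direct <- direct[keep]
  structure(list(direct = direct, expanded = NULL,
                 genes = names(direct)),
            class = "annotation_set")
}

#' Read gene annotations from a TSV file
#'
#' Expects two tab-separated columns `gene` and `term_id` (header required),
#' one gene/term pair per row; lines starting with `#` are comments.
#'
#' @param path path to the annotation TSV.
#' @return An [annotation_set()] (not yet expanded).
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", colClasses = "character")
  if (!all(c("gene", "term_id") %in% names(df)))
    stop("annotation file must have columns 'gene' and 'term_id'")
  annotation_set(split(df$term_id, df$gene))
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set:", length(x$genes), "genes,",
      length(unique(unlist(x$direct, use.names = FALSE))), "distinct terms",
      if (is.null(x$expanded)) "(direct only)" else "(expanded)", "\n")
  invisible(x)
}

#' Expand annotations upward through the ontology
#'
#' For each gene, adds every ancestor of each directly annotated term, so that
#' annotation with a term implies annotation with all of its generalizations.
#' Direct annotations are left untouched. Expansion is idempotent.
#'
#' @param annotations an [annotation_set()].
#' @param ontology a [phenotype_ontology()].
#' @param unknown how to treat annotated term ids absent from the ontology:
#'   `"skip"` (default; dropped with a warning — real annotation dumps contain
#'   retired ids) or `"error"`.
#' @return The annotation set with its `expanded` component filled in. Genes
#'   whose annotations are all unknown are dropped from the gene universe.
#' @export
expand_annotations <- function(annotations, ontology,
                               unknown = c("skip", "error")) {
  unknown <- match.arg(unknown)
  all_terms <- unique(unlist(annotations$direct, use.names = FALSE))
  bad <- setdiff(all_terms, ontology$terms)
  if (length(bad) > 0L) {
    if (unknown == "error")
      stop("unknown annotation term(s): ", paste(bad, collapse = ", "))
    warning("skipping ", length(bad), " unknown annotation term(s): ",
            paste(utils::head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ...")
  }
  obs <- intersect(all_terms, ontology$obsolete)
  drop <- union(bad, obs)   # obsolete terms carry no annotations after loading
  direct <- lapply(annotations$direct, function(ts) setdiff(ts, drop))
  keep <- vapply(direct, length, integer(1)) > 0L
  direct <- direct[keep]
  anc <- ontology$ancestors
  expanded <- lapply(direct, function(ts)
    unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  structure(list(direct = direct, expanded = expanded, genes = names(direct)),
            class = "annotation_set")
}

#' Gene x term annotation incidence matrix
#'
#' @param annotations an expanded [annotation_set()].
#' @param terms term ids to use as columns (default: all annotated terms).
#' @param genes gene ids to use as rows (default: the gene universe).
#' @return Logical matrix, `TRUE` where the gene's expanded annotations
#'   contain the term.
#' @export
annotation_matrix <- function(annotations, terms = NULL, genes = NULL) {
  if (is.null(annotations$expanded))
    stop("annotations must be expanded first (see expand_annotations)")
  if (is.null(genes)) genes <- annotations$genes
  if (is.null(terms))
    terms <- sort(unique(unlist(annotations$expanded, use.names = FALSE)))
  m <- matrix(FALSE, nrow = length(genes), ncol = length(terms),
              dimnames = list(genes, terms))
  exp_ann <- annotations$expanded
  for (i in seq_along(genes)) {
    ts <- intersect(exp_ann[[genes[[i]]]], terms)
    if (length(ts) > 0L) m[i, ts] <- TRUE
  }
  m
}

#' Select testable phenotypes
#'
#' A testable phenotype is a lowest-level term annotated (after expansion) to
#' at least `min_genes` genes: it meets the gene-count threshold and no
#' descendant of it does. These terms form the classifiers' attribute
#' vocabulary and the set of scorable target phenotypes.
#'
#' @param ontology a [phenotype_ontology()].
#' @param annotations an expanded [annotation_set()].
#' @param min_genes minimum number of annotated genes (default 10).
#' @return Character vector of term ids, sorted.
#' @export
testable_phenotypes <- function(ontology, annotations, min_genes = 10) {
  if (is.null(annotations$expanded))
    stop("annotations must be expanded first (see expand_annotations)")
  counts <- term_gene_counts(annotations)
  qualifying <- names(counts)[counts >= min_genes]
  qualifying <- intersect(qualifying, ontology$terms)
  keep <- vapply(qualifying, function(t) {
    !any(ontology$descendants[[t]] %in% qualifying)
  }, logical(1))
  sort(qualifying[keep], method = "radix")
}

# number of genes carrying each term in expanded annotations
term_gene_counts <- function(annotations) {
  tab <- table(unlist(annotations$expanded, use.names = FALSE))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Leakage-safe attribute set for a target phenotype
#'
#' Attributes available to a target phenotype's classifier: all testable
#' phenotypes except the target itself and any of its descendants. Because
#' annotations are expanded upward, any descendant of the target would leak
#' the label, so the whole descendant subtree is excluded.
#'
#' @param target a term id present in the ontology.
#' @param testable character vector of testable phenotype term ids.
#' @param ontology a [phenotype_ontology()].
#' @return Character vector of attribute term ids, sorted.
#' @export
attribute_set <- function(target, testable, ontology) {
  if (!target %in% ontology$terms)
    stop("target term not in ontology: ", target)
  excluded <- c(target, ontology$descendants[[target]])
  sort(setdiff(testable, excluded), method = "radix")
}
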