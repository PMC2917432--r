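# Independent reference implementations used only as test oracles.
# Deliberately written in a different style (exhaustive enumeration, plain
# loops) from the package code they check.

# -- reachability on a child->parent adjacency list, by fixpoint iteration --
oracle_ancestors <- function(parents, term) {
  reached <- parents[[term]]
  repeat {
    nxt <- unique(c(reached, unlist(parents[reached], use.names = FALSE)))
    if (length(nxt) == length(reached)) return(sort(nxt))
    reached <- nxt
  }
}

oracle_descendants <- function(parents, term) {
  ids <- names(parents)
  sort(ids[vapply(ids, function(t) term %in% oracle_ancestors(parents, t),
                  logical(1))])
}

# -- closed-form entropy / gain ---------------------------------------------
oracle_entropy <- function(p) {
  h <- 0
  if (p > 0) h <- h - p * log(p, base = 2)
  if (p < 1) h <- h - (1 - p) * log(1 - p, base = 2)
  h
}

oracle_gain <- function(y, v, mode = "weighted") {
  n <- length(y)
  h <- oracle_entropy(sum(y) / n)
  part <- function(sel) {
    if (sum(sel) == 0) return(c(h = 0, w = 0))
    c(h = oracle_entropy(sum(y[sel]) / sum(sel)), w = sum(sel) / n)
  }
  p0 <- part(!v); p1 <- part(v)
  if (mode == "weighted") h - p0["w"] * p0["h"] - p1["w"] * p1["h"]
  else h - p0["h"] - p1["h"]
}

# -- exhaustive-search reference tree learner -------------------------------
# At each node every attribute's gain is evaluated by direct formula; the
# best split (ties within 1e-12 -> smallest term id) is applied recursively
# under the same stopping rules the learner documents.
oracle_tree <- function(df, y, min_leaf = 2, mode = "weighted") {
  df <- df[sort(names(df))]
  build <- function(df, y) {
    np <- sum(y); nn <- sum(!y)
    leaf <- list(kind = "leaf", n_pos = np, n_neg = nn)
    if (np == 0 || nn == 0 || np + nn < 2 * min_leaf || ncol(df) == 0)
      return(leaf)
    gains <- rep(-Inf, ncol(df))
    for (k in seq_along(df)) {
      v <- df[[k]]
      if (sum(v) < min_leaf || sum(!v) < min_leaf) next
      gains[k] <- unname(oracle_gain(y, v, mode))
    }
    top <- max(gains)
    if (!is.finite(top) || top <= 0) return(leaf)
    k <- which(gains >= top - 1e-12)[1]
    v <- df[[k]]
    list(kind = "split", term = names(df)[k],
         yes = build(df[v, -k, drop = FALSE], y[v]),
         no  = build(df[!v, -k, drop = FALSE], y[!v]))
  }
  build(df, y)
}

# canonical shape of a fitted phenotree, comparable with oracle_tree output
tree_shape <- function(tree) {
  canon <- function(node) {
    if (node$leaf) list(kind = "leaf", n_pos = node$n_pos, n_neg = node$n_neg)
    else list(kind = "split", term = node$term,
              yes = canon(node$yes), no = canon(node$no))
  }
  canon(if (inherits(tree, "phenotree")) tree$root else tree)
}

# path-following traversal of an oracle/canonical tree
oracle_predict <- function(shape, flags) {
  node <- shape
  while (node$kind == "split") {
    present <- isTRUE(unname(flags[node$term]))
    node <- if (present) node$yes else node$no
  }
  node$n_pos / (node$n_pos + node$n_neg)
}

# -- Mann-Whitney identity for the AUC (midranks handle ties) ---------------
oracle_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n2 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# -- small random inputs ----------------------------------------------------
random_dag <- function(n_terms, max_parents = 2) {
  ids <- sprintf("T%02d", seq_len(n_terms))
  parents <- list()
  parents[[ids[1]]] <- character(0)
  for (i in seq_len(n_terms)[-1]) {
    k <- sample.int(min(max_parents, i - 1), 1)
    parents[[ids[i]]] <- ids[sample.int(i - 1, k)]
  }
  parents
}

random_training_set <- function(n = 20, p = 4) {
  df <- as.data.frame(matrix(runif(n * p) < 0.5, nrow = n))
  names(df) <- sprintf("A%02d", seq_len(p))
  signal <- df[[sample.int(p, 1)]]
  y <- runif(n) < ifelse(signal, 0.8, 0.25)
  if (all(y) || !any(y)) y[sample.int(n, 2)] <- c(TRUE, FALSE)
  list(df = df, y = y)
}

# tiny ontology chain A <- B <- C (C is_a B is_a A)
chain_ontology <- function() {
  phenotype_ontology(list(A = character(0), B = "A", C = "B"))
}

# gene ids in the synthetic generator's naming scheme
syn_gene_ids_for_test <- function(idx) sprintf("G%05d", idx)
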