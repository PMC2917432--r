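#' Undirected gene interaction network
#'
#' Edges are stored as unordered gene pairs; self-loops are dropped and
#' duplicate edges (in either orientation) collapsed.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @param nodes optional extra node ids (e.g. isolated genes); the node set is
#'   their union with all edge endpoints.
#' @return An object of class `interaction_network` with components `nodes`,
#'   `edges` (data.frame `from`/`to` with `from < to`) and `degree` (named
#'   integer vector).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have two columns")
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  keep <- a != b                                   # no self-loops
  a <- a[keep]; b <- b[keep]
  from <- pmin(a, b); to <- pmax(a, b)
  dup <- duplicated(paste(from, to, sep = "\r"))
  from <- from[!dup]; to <- to[!dup]
  nodes <- sort(unique(c(from, to, as.character(nodes))), method = "radix")
  deg <- integer(length(nodes)); names(deg) <- nodes
  tab <- table(c(from, to))
  deg[names(tab)] <- as.integer(tab)
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to,
                                    stringsAsFactors = FALSE),
                 degree = deg),
            class = "interaction_network")
}

#' Read an undirected edge list from TSV
#'
#' Two tab-separated columns `geneA`/`geneB` (no header required; a header
#' line is detected and skipped if present), comment lines starting `#`.
#'
#' @param path path to the edge-list file.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", quote = "",
                          colClasses = "character")
  if (nrow(df) > 0L && identical(tolower(df[1L, 1L]), "genea"))
    df <- df[-1L, , drop = FALSE]
  interaction_network(df[, 1:2])
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of interactions between two gene sets
#'
#' Counts the distinct network edges with one endpoint in `setA` and the
#' other in `setB` (in either orientation); each edge counts once even when
#' both endpoints lie in the overlap of the sets. Genes absent from the
#' network contribute nothing.
#'
#' @param setA,setB character vectors of gene ids (may overlap).
#' @param net an [interaction_network()].
#' @return Integer edge count.
#' @export
links_between <- function(setA, setB, net) {
  fA <- net$edges$from %in% setA; tA <- net$edges$to %in% setA
  fB <- net$edges$from %in% setB; tB <- net$edges$to %in% setB
  sum((fA & tB) | (fB & tA))
}

#' Monte-Carlo significance of the interaction count between two gene sets
#'
#' The empirical P value is the frequency with which randomly selected gene
#' sets of the same sizes have at least as many interactions as observed.
#' Per iteration, set A and/or set B (per `mode`) are replaced by uniform
#' samples from the network's nodes (or from degree-matched strata with
#' `null = "degree"`).
#'
#' @param setA,setB character vectors of gene ids.
#' @param net an [interaction_network()].
#' @param iterations number of Monte-Carlo iterations (default 1000).
#' @param mode which set(s) to randomize: `"both"`, `"A_only"` or `"B_only"`.
#' @param seed RNG seed.
#' @param null `"uniform"` (default) or `"degree"` (replacements sampled
#'   within degree-quintile strata of the original set, for sensitivity
#'   analysis).
#' @return An object of class `permutation_result`: `observed`, `null_counts`,
#'   `empirical_p` (= #\{null >= observed\} / iterations), `p_label` (the
#'   bound `"< 1/iterations"` when no null draw reaches the observed count),
#'   `mode`, `iterations`, `seed`.
#' @export
empirical_p_links <- function(setA, setB, net, iterations = 1000L,
                              mode = c("both", "A_only", "B_only"),
                              seed = 1L, null = c("uniform", "degree")) {
  mode <- match.arg(mode)
  null <- match.arg(null)
  nA <- length(unique(setA)); nB <- length(unique(setB))
  if (nA > length(net$nodes) || nB > length(net$nodes))
    stop("gene set larger than the network's node universe")
  observed <- links_between(setA, setB, net)

  draw <- if (null == "uniform") {
    function(orig, n) sample(net$nodes, n, replace = FALSE)
  } else {
    strata <- cut(rank(net$degree, ties.method = "first"),
                  breaks = 5L, labels = FALSE)
    names(strata) <- net$nodes
    function(orig, n) {
      present <- intersect(orig, net$nodes)
      want <- table(factor(strata[present], levels = 1:5))
      want[1L] <- want[1L] + (n - sum(want))    # genes outside the network
      unlist(lapply(1:5, function(s) {
        pool <- net$nodes[strata == s]
        sample(pool, min(want[s], length(pool)), replace = FALSE)
      }), use.names = FALSE)
    }
  }

  set.seed(seed)
  null_counts <- integer(iterations)
  for (i in seq_len(iterations)) {
    rA <- if (mode %in% c("both", "A_only")) draw(setA, nA) else setA
    rB <- if (mode %in% c("both", "B_only")) draw(setB, nB) else setB
    null_counts[i] <- links_between(rA, rB, net)
  }
  k <- sum(null_counts >= observed)
  structure(list(observed = observed, null_counts = null_counts,
                 empirical_p = k / iterations,
                 p_label = if (k == 0L) paste0("< ", 1, "/", iterations)
                           else sprintf("%.4g", k / iterations),
                 mode = mode, iterations = iterations, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Interaction-count permutation test (", x$mode, ", ",
      x$iterations, " iterations)\n", sep = "")
  cat("  observed links:", x$observed,
      "| null mean:", signif(mean(x$null_counts), 4),
      "| empirical P", x$p_label, "\n")
  invisible(x)
}

#' Degree statistics of a gene set against the network background
#'
#' Mean interaction degree of the set's members present in the network, and a
#' one-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) of whether their degrees exceed those of all network nodes.
#'
#' @param gene_set character vector of gene ids.
#' @param net an [interaction_network()].
#' @return List: `mean_degree`, `p_value` (one-sided, greater), `n_set`
#'   (set members found in the network), `background_mean`.
#' @export
degree_stats <- function(gene_set, net) {
  members <- intersect(unique(gene_set), net$nodes)
  if (length(members) == 0L)
    stop("no member of the gene set is present in the network")
  d_set <- net$degree[members]
  d_all <- net$degree
  wt <- suppressWarnings(
    stats::wilcox.test(d_set, d_all, alternative = "greater",
                       exact = FALSE, correct = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 0.5     # zero rank variance (e.g. regular graph)
  list(mean_degree = mean(d_set), p_value = p,
       n_set = length(members), background_mean = mean(d_all))
}
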