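#' Binary entropy in bits
#'
#' Entropy of a node holding a fraction `p_pos` of positive genes:
#' `-p*log2(p) - (1-p)*log2(1-p)` with the convention `0*log(0) = 0`.
#'
#' @param p_pos proportion(s) of positives, in \[0, 1\].
#' @return Entropy in bits, same length as `p_pos`.
#' @export
entropy_bits <- function(p_pos) {
  if (any(!is.finite(p_pos)) || any(p_pos < 0 | p_pos > 1))
    stop("p_pos must lie in [0, 1]")
  xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  -xlog2(p_pos) - xlog2(1 - p_pos)
}

#' Information gain of a binary split
#'
#' @param parent integer counts `c(n_pos, n_neg)` at the node.
#' @param split list of two count vectors `c(n_pos, n_neg)` for the
#'   attribute-absent and attribute-present children; they must partition the
#'   parent counts.
#' @param mode `"weighted"` (default): `H(N) - |N0|/|N| H(N0) - |N1|/|N| H(N1)`,
#'   the standard C4.5 size-weighted gain; `"literal"`: the unweighted
#'   difference `H(N) - H(N0) - H(N1)`.
#' @return Gain in bits.
#' @export
information_gain <- function(parent, split, mode = c("weighted", "literal")) {
  mode <- match.arg(mode)
  n <- sum(parent)
  if (n <= 0) stop("empty node")
  stopifnot(length(split) == 2L)
  c0 <- split[[1L]]; c1 <- split[[2L]]
  if (!isTRUE(all.equal(c0 + c1, parent)))
    stop("split counts must partition the node counts")
  h  <- entropy_bits(parent[1L] / n)
  n0 <- sum(c0); n1 <- sum(c1)
  h0 <- if (n0 > 0) entropy_bits(c0[1L] / n0) else 0
  h1 <- if (n1 > 0) entropy_bits(c1[1L] / n1) else 0
  if (mode == "weighted") h - (n0 / n) * h0 - (n1 / n) * h1
  else h - h0 - h1
}

#' Decision-tree configuration
#'
#' @param gain_mode split criterion variant, `"weighted"` or `"literal"`
#'   (see [information_gain()]).
#' @param min_leaf minimum number of training genes per leaf (default 2;
#'   prevents singleton leaves with degenerate probabilities).
#' @return A list of class `tree_config`.
#' @export
tree_config <- function(gain_mode = c("weighted", "literal"), min_leaf = 2L) {
  gain_mode <- match.arg(gain_mode)
  min_leaf <- as.integer(min_leaf)
  if (min_leaf < 1L) stop("min_leaf must be >= 1")
  structure(list(gain_mode = gain_mode, min_leaf = min_leaf),
            class = "tree_config")
}

#' Fit a C4.5-style decision tree on binary phenotype attributes
#'
#' Grows a binary tree by greedy recursive partitioning: at each node the
#' attribute (phenotype term) with maximal information gain is chosen, testing
#' presence vs absence of the term among the genes at the node. Recursion
#' stops when the node is pure, no split has positive gain, the node holds
#' fewer than `2 * min_leaf` genes, or a child would fall below `min_leaf`.
#' Leaves store the positive/negative training counts; the leaf probability
#' `n_pos / (n_pos + n_neg)` is the estimated probability that a gene reaching
#' the leaf shows the target phenotype.
#'
#' Ties in gain (within 1e-12 bits) are broken toward the lexicographically
#' smallest term id, so fits are reproducible across platforms.
#'
#' @param x logical matrix of training genes (rows, rownames = gene ids) by
#'   attributes (columns, colnames = term ids).
#' @param y logical vector: `TRUE` for gold-standard-positive genes.
#' @param config a [tree_config()].
#' @return An object of class `phenotree` with components `root` (nested node
#'   list), `config`, `n_pos`, `n_neg` and `attributes`.
#' @export
phenotree <- function(x, y, config = tree_config()) {
  if (!is.matrix(x)) stop("x must be a matrix")
  if (is.null(colnames(x))) stop("x must have attribute term ids as colnames")
  if (nrow(x) != length(y)) stop("length(y) must equal nrow(x)")
  if (nrow(x) == 0L) stop("at least one training instance is required")
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    stop("duplicate gene ids in training instances")
  storage.mode(x) <- "logical"
  y <- as.logical(y)
  x <- x[, sort(colnames(x), method = "radix"), drop = FALSE]
  root <- grow_node(x, y, config)
  structure(list(root = root, config = config,
                 n_pos = sum(y), n_neg = sum(!y),
                 attributes = colnames(x)),
            class = "phenotree")
}

GAIN_TIE_TOL <- 1e-12

grow_node <- function(x, y, config) {
  n <- length(y)
  np <- sum(y)
  nn <- n - np
  leaf <- list(leaf = TRUE, n_pos = np, n_neg = nn)
  if (np == 0L || nn == 0L) return(leaf)                 # pure
  if (n < 2L * config$min_leaf) return(leaf)             # too small to split
  if (ncol(x) == 0L) return(leaf)                        # attributes exhausted

  n1  <- colSums(x)
  n1p <- colSums(x & y)
  n0  <- n - n1
  n0p <- np - n1p
  gains <- gain_vector(np, nn, n0p, n0 - n0p, n1p, n1 - n1p, config$gain_mode)
  gains[n0 < config$min_leaf | n1 < config$min_leaf] <- -Inf

  best_gain <- max(gains)
  if (!is.finite(best_gain) || best_gain <= 0) return(leaf)
  j <- which(gains >= best_gain - GAIN_TIE_TOL)[1L]      # lexicographic tie-break
  sel <- x[, j]
  list(leaf = FALSE, term = colnames(x)[j], gain = gains[j],
       n_pos = np, n_neg = nn,
       yes = grow_node(x[sel, -j, drop = FALSE], y[sel], config),
       no  = grow_node(x[!sel, -j, drop = FALSE], y[!sel], config))
}

# vectorized gain over all candidate attributes, in bits
gain_vector <- function(np, nn, n0p, n0n, n1p, n1n, mode) {
  n <- np + nn
  h <- entropy_bits(np / n)
  n0 <- n0p + n0n
  n1 <- n1p + n1n
  h0 <- ifelse(n0 > 0, entropy_bits(ifelse(n0 > 0, n0p / pmax(n0, 1L), 0)), 0)
  h1 <- ifelse(n1 > 0, entropy_bits(ifelse(n1 > 0, n1p / pmax(n1, 1L), 0)), 0)
  if (mode == "weighted") h - (n0 / n) * h0 - (n1 / n) * h1
  else h - h0 - h1
}

#' Predict phenotype probabilities from a fitted tree
#'
#' Each gene is routed from the root by the presence/absence of the split
#' terms among its attributes; the probability at the reached leaf is
#' returned, with no smoothing. Attributes absent from `newdata`'s columns are
#' treated as phenotype-absent (absence of annotation is the implicit
#' negative).
#'
#' @param object a [phenotree()].
#' @param newdata logical matrix (genes x terms) or a single named logical
#'   vector of term presence flags.
#' @param ... unused.
#' @return Numeric vector of leaf probabilities in \[0, 1\].
#' @export
predict.phenotree <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) {
    nm <- names(newdata)
    newdata <- matrix(as.logical(newdata), nrow = 1L,
                      dimnames = list(NULL, nm))
  }
  storage.mode(newdata) <- "logical"
  out <- numeric(nrow(newdata))
  cols <- colnames(newdata)
  descend <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$leaf) {
      out[idx] <<- node$n_pos / (node$n_pos + node$n_neg)
      return(invisible())
    }
    present <- if (node$term %in% cols) newdata[idx, node$term]
               else rep(FALSE, length(idx))
    present[is.na(present)] <- FALSE
    descend(node$yes, idx[present])
    descend(node$no,  idx[!present])
  }
  descend(object$root, seq_len(nrow(newdata)))
  out
}

#' @export
print.phenotree <- function(x, ...) {
  cat("Phenotype decision tree (", x$config$gain_mode, " gain, min_leaf = ",
      x$config$min_leaf, ")\n", sep = "")
  cat("Training genes:", x$n_pos, "positive /", x$n_neg, "negative\n")
  show <- function(node, indent, branch) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, branch, "leaf (+", node$n_pos, "/-", node$n_neg, ") p=",
          signif(node$n_pos / (node$n_pos + node$n_neg), 3), "\n", sep = "")
    } else {
      cat(pad, branch, node$term, " (gain ", signif(node$gain, 3), ")\n",
          sep = "")
      show(node$yes, indent + 1L, "Y: ")
      show(node$no,  indent + 1L, "N: ")
    }
  }
  show(x$root, 0L, "")
  invisible(x)
}

# leaf (n_pos, n_neg) totals, used by invariant checks and summaries
tree_leaf_counts <- function(tree) {
  acc <- c(n_pos = 0L, n_neg = 0L)
  walk <- function(node) {
    if (node$leaf) acc <<- acc + c(node$n_pos, node$n_neg)
    else { walk(node$yes); walk(node$no) }
  }
  walk(if (inherits(tree, "phenotree")) tree$root else tree)
  acc
}
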