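#' Read a GWAS SNP table
#'
#' Tab-separated columns `snp_id`, `chrom`, `pos` (1-based), `assoc_p`,
#' `odds_ratio`; header required, `#` comments allowed.
#'
#' @param path path to the SNP TSV.
#' @return data.frame with the five columns, types coerced.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "assoc_p", "odds_ratio")
  if (!all(need %in% names(df)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$assoc_p <- as.numeric(df$assoc_p)
  df$odds_ratio <- as.numeric(df$odds_ratio)
  if (any(df$pos < 1L)) stop("SNP positions must be >= 1 (1-based)")
  if (any(df$odds_ratio <= 0)) stop("odds ratios must be positive")
  df[need]
}

#' Read gene loci from a BED-like TSV
#'
#' Tab-separated columns `chrom`, `start`, `end`, `gene` (header required).
#' Coordinates are converted to 1-based inclusive spans; set
#' `zero_based = TRUE` for BED-convention input (0-based, half-open start).
#'
#' @param path path to the loci TSV.
#' @param zero_based whether the input start coordinates are 0-based.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_loci <- function(path, zero_based = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(df)))
    stop("loci table must have columns: ", paste(need, collapse = ", "))
  df$start <- as.integer(df$start) + if (zero_based) 1L else 0L
  df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("locus start must not exceed end")
  df[c("gene", "chrom", "start", "end")]
}

#' Distance between a gene locus and a SNP
#'
#' Zero if the SNP lies within the gene span (1-based inclusive), otherwise
#' the distance in base pairs to the nearest gene boundary; `Inf` when gene
#' and SNP are on different chromosomes.
#'
#' @param locus list or one-row data.frame with `chrom`, `start`, `end`.
#' @param snp list or one-row data.frame with `chrom`, `pos`.
#' @return Distance in base pairs.
#' @export
gene_snp_distance <- function(locus, snp) {
  if (as.character(locus$chrom) != as.character(snp$chrom)) return(Inf)
  pos <- as.numeric(snp$pos)
  start <- as.numeric(locus$start); end <- as.numeric(locus$end)
  if (pos >= start && pos <= end) 0
  else min(abs(pos - start), abs(pos - end))
}

# per-gene minimum distance over a SNP table (vectorized over genes)
min_snp_distances <- function(loci, snps) {
  d <- rep(Inf, nrow(loci))
  for (ch in unique(snps$chrom)) {
    pos <- snps$pos[snps$chrom == ch]
    gi <- which(loci$chrom == ch)
    if (length(gi) == 0L || length(pos) == 0L) next
    for (i in gi) {
      inside <- any(pos >= loci$start[i] & pos <= loci$end[i])
      d[i] <- if (inside) 0
              else min(pmin(abs(pos - loci$start[i]), abs(pos - loci$end[i])))
    }
  }
  names(d) <- loci$gene
  d
}

#' Score and enrichment profile by distance to disease SNPs
#'
#' Assigns each scored gene its minimum distance over all SNPs, bins the
#' genes by `bin_edges`, and reports per bin the mean normalized score and
#' the fold enrichment of high-scoring genes (score at or above
#' `high_cutoff`) relative to the genome-wide background proportion. Genes on
#' chromosomes without SNPs have infinite distance and fall outside all bins.
#'
#' @param scores named numeric vector of gene scores (or a [phenoscore()]
#'   fit, whose `scores` are used).
#' @param loci gene loci data.frame (see [read_gene_loci()]).
#' @param snps SNP data.frame (see [read_snp_table()]).
#' @param bin_edges increasing numeric vector of distance bin edges in bp;
#'   bins are `[e1, e2), [e2, e3), ...`.
#' @param high_cutoff score threshold defining high-scoring genes (typically
#'   a [specificity_cutoff()]).
#' @return data.frame with one row per bin: `bin`, `lower`, `upper`, `n`,
#'   `mean_score`, `n_high`, `fold_enrichment`. Empty bins carry `NA` (missing,
#'   not zero).
#' @export
distance_profile <- function(scores, loci, snps, bin_edges, high_cutoff) {
  if (inherits(scores, "phenoscore")) scores <- scores$scores
  loci <- loci[loci$gene %in% names(scores), , drop = FALSE]
  if (nrow(loci) == 0L) stop("no scored gene has a locus")
  d <- min_snp_distances(loci, snps)
  s <- scores[loci$gene]
  high <- s >= high_cutoff
  M <- sum(scores >= high_cutoff)
  N <- length(scores)
  k <- length(bin_edges) - 1L
  out <- data.frame(bin = seq_len(k),
                    lower = bin_edges[-length(bin_edges)],
                    upper = bin_edges[-1L],
                    n = NA_integer_, mean_score = NA_real_,
                    n_high = NA_integer_, fold_enrichment = NA_real_)
  idx <- findInterval(d, bin_edges, rightmost.closed = FALSE)
  idx[d >= bin_edges[length(bin_edges)]] <- NA        # beyond last edge
  idx[idx == 0L] <- NA                                 # below first edge
  for (b in seq_len(k)) {
    sel <- which(!is.na(idx) & idx == b)
    if (length(sel) == 0L) next
    out$n[b] <- length(sel)
    out$mean_score[b] <- mean(s[sel])
    out$n_high[b] <- sum(high[sel])
    out$fold_enrichment[b] <-
      if (M > 0L) fold_enrichment(sum(high[sel]), length(sel), M, N)
      else NA_real_
  }
  out
}

# per-SNP maximum score among genes within window bp on the same chromosome
snp_max_scores <- function(scores, loci, snps, window) {
  vapply(seq_len(nrow(snps)), function(i) {
    gi <- which(loci$chrom == snps$chrom[i])
    if (length(gi) == 0L) return(NA_real_)
    pos <- snps$pos[i]
    d <- ifelse(pos >= loci$start[gi] & pos <= loci$end[gi], 0,
                pmin(abs(pos - loci$start[gi]), abs(pos - loci$end[gi])))
    near <- gi[d <= window]
    if (length(near) == 0L) NA_real_ else max(scores[loci$gene[near]])
  }, numeric(1))
}

#' Correlation between SNP odds ratios and nearby maximal gene scores
#'
#' For each SNP, takes the maximal disease score among genes within
#' `window_mbp` megabases (distance to the nearest gene boundary; genes
#' overlapping the SNP count as distance 0), then correlates these maxima
#' with the SNPs' association odds ratios. SNPs with no scored gene in the
#' window are excluded.
#'
#' @inheritParams distance_profile
#' @param window_mbp window half-width in Mbp (default 1).
#' @return List: `r` (Pearson correlation), `slope_p` (t-test P value of the
#'   regression slope of OR on max score), `n` (SNPs used), `data`
#'   (data.frame of `snp_id`, `max_score`, `odds_ratio`). `r` and `slope_p`
#'   are `NA` when either variable has zero variance.
#' @export
max_score_vs_or <- function(scores, loci, snps, window_mbp = 1) {
  if (inherits(scores, "phenoscore")) scores <- scores$scores
  loci <- loci[loci$gene %in% names(scores), , drop = FALSE]
  ms <- snp_max_scores(scores, loci, snps, window_mbp * 1e6)
  keep <- !is.na(ms)
  ms <- ms[keep]
  or <- snps$odds_ratio[keep]
  if (length(ms) < 3L)
    stop("need at least 3 SNPs with a scored gene in the window; have ",
         length(ms))
  dat <- data.frame(snp_id = snps$snp_id[keep], max_score = ms,
                    odds_ratio = or)
  if (stats::sd(ms) == 0 || stats::sd(or) == 0)
    return(list(r = NA_real_, slope_p = NA_real_, n = length(ms), data = dat))
  fit <- stats::lm(or ~ ms)
  list(r = stats::cor(ms, or),
       slope_p = summary(fit)$coefficients["ms", "Pr(>|t|)"],
       n = length(ms), data = dat)
}
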