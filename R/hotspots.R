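#' Bin gene loci into fixed-size genomic windows
#'
#' Divides each chromosome into contiguous windows of `bin_size` base pairs
#' (default 1 Mb) and accumulates, per window, the number of genes whose
#' start coordinate falls in it and their total literature mention counts.
#' Coordinates are 1-based inclusive on input; bins are 0-based. A gene
#' spanning a bin boundary is counted once, in the bin of its start. Empty
#' bins up to the last occupied bin of each chromosome are emitted with
#' zeros.
#'
#' @param loci Data frame with columns `gene`, `chromosome`, `start`, `end`
#'   (1-based, `start <= end`).
#' @param mentions Named integer vector of per-gene mention counts (see
#'   [count_mentions()]); genes not listed count 0.
#' @param bin_size Window width in base pairs (default 1e6).
#' @return Data frame `chromosome`, `bin_index`, `n_genes`, `n_mentions`.
#' @export
bin_genome <- function(loci, mentions = integer(0), bin_size = 1000000) {
  stopifnot(all(c("gene", "chromosome", "start", "end") %in% names(loci)),
    bin_size >= 1)
  if (any(loci$start < 1) || any(loci$end < 1))
    stop("coordinates must be positive (1-based)")
  if (any(loci$start > loci$end)) stop("locus with start > end")
  m <- rep(0L, nrow(loci))
  hit <- loci$gene %in% names(mentions)
  m[hit] <- as.integer(mentions[loci$gene[hit]])
  bin <- (loci$start - 1) %/% bin_size
  out <- list()
  for (chrom in unique(loci$chromosome)) {
    sel <- loci$chromosome == chrom
    bins <- seq(0, max(bin[sel]))
    n_genes <- tabulate(bin[sel] + 1L, nbins = length(bins))
    n_mentions <- vapply(bins, function(b) sum(m[sel][bin[sel] == b]),
      numeric(1))
    out[[chrom]] <- data.frame(chromosome = chrom, bin_index = bins,
      n_genes = as.integer(n_genes), n_mentions = as.integer(n_mentions),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count gene mentions in a tokenized corpus
#'
#' Total token occurrences of each gene across the corpus (a gene appearing
#' twice in one abstract counts twice). Gene tokens must be given in their
#' preprocessed, underscore-merged lowercase form; tokens outside the gene
#' set are ignored.
#'
#' @param tokens Named list of token vectors (see [tokenize_corpus()]).
#' @param gene_tokens Character vector of gene tokens.
#' @return Named integer vector over `gene_tokens` (zeros included).
#' @export
count_mentions <- function(tokens, gene_tokens) {
  counts <- rep(0L, length(gene_tokens))
  names(counts) <- gene_tokens
  all_tokens <- unlist(tokens, use.names = FALSE)
  tab <- table(all_tokens[all_tokens %in% gene_tokens])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Spearman rank correlation
#'
#' Tie-aware Spearman correlation (Pearson correlation of average-ranked
#' values), used to relate per-bin gene density to per-bin literature mention
#' density.
#'
#' @param x,y Numeric vectors of equal length (>= 2), neither constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("spearman undefined for a constant vector")
  cor(x, y, method = "spearman")
}
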