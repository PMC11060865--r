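#' Patho-score between two terms
#'
#' The Patho-score of a term pair is the cosine similarity of their embedding
#' vectors: it measures the extent to which the two terms co-occur in
#' pathology-related literature. Larger scores indicate stronger association.
#'
#' @param emb Embedding matrix.
#' @param a,b Tokens; both must be in the vocabulary.
#' @return Cosine similarity in \[-1, 1\]; symmetric in `a` and `b`.
#' @export
patho_score <- function(emb, a, b) {
  for (tok in c(a, b)) {
    if (!(tok %in% rownames(emb)))
      stop("token not in vocabulary: '", tok, "'")
  }
  cosine(emb[a, ], emb[b, ])
}

#' Add-one empirical p-value against a null score sample
#'
#' Given an observed score `ps` and null scores `r`, returns
#' \eqn{p = (\#\{r_i \ge ps\} + 1)/(|r| + 1)}. Ties count against
#' significance, and the smallest attainable p is \eqn{1/(|r|+1)}.
#'
#' @param ps Observed score.
#' @param r Numeric vector of null scores.
#' @return p-value in \eqn{(0, 1]}.
#' @export
empirical_pvalue_from_null <- function(ps, r) {
  stopifnot(length(r) >= 1)
  (sum(r >= ps) + 1) / (length(r) + 1)
}

#' Monte-Carlo empirical p-value for a Patho-score
#'
#' Draws `n_random` random term pairs (one token from each null pool,
#' excluding the observed pair itself), scores them, and computes the add-one
#' empirical p-value of the observed pair's Patho-score against that null
#' sample. Null pools are chosen by context: gene and disease tokens for
#' disease--gene scores, gene and organ tokens for organ profiles.
#'
#' @param emb Embedding matrix.
#' @param a,b The observed term pair (both in vocabulary).
#' @param null_pool_a,null_pool_b Token pools the null pairs are drawn from
#'   (with replacement); out-of-vocabulary pool tokens are dropped.
#' @param n_random Number of null pairs (default 999).
#' @param seed Integer seed.
#' @return A `pathoscore` list: `term_a`, `term_b`, `score`, `p_value`,
#'   `n_random`.
#' @export
empirical_pvalue <- function(emb, a, b, null_pool_a, null_pool_b,
                             n_random = 999, seed = 1) {
  stopifnot(n_random >= 1)
  vocab <- rownames(emb)
  null_pool_a <- intersect(null_pool_a, vocab)
  null_pool_b <- intersect(null_pool_b, vocab)
  if (length(null_pool_a) == 0L || length(null_pool_b) == 0L)
    stop("empty null pool after vocabulary filtering")
  if (length(null_pool_a) * length(null_pool_b) < 2L)
    stop("null pools admit no pair other than the observed one")
  ps <- patho_score(emb, a, b)
  r <- withr::with_seed(seed, {
    out <- numeric(n_random)
    filled <- 0L
    while (filled < n_random) {
      need <- n_random - filled
      ra <- sample(null_pool_a, need, replace = TRUE)
      rb <- sample(null_pool_b, need, replace = TRUE)
      keep <- !(ra == a & rb == b)
      ra <- ra[keep]; rb <- rb[keep]
      if (length(ra)) {
        out[filled + seq_along(ra)] <- vapply(seq_along(ra), function(i)
          patho_score(emb, ra[i], rb[i]), numeric(1))
        filled <- filled + length(ra)
      }
    }
    out
  })
  structure(list(term_a = a, term_b = b, score = ps,
    p_value = empirical_pvalue_from_null(ps, r), n_random = n_random),
    class = "pathoscore")
}

#' @export
print.pathoscore <- function(x, ...) {
  cat(sprintf("Patho-score %s ~ %s: %.4f (empirical p = %.4g, %d null pairs)\n",
    x$term_a, x$term_b, x$score, x$p_value, x$n_random))
  invisible(x)
}

#' ROC-AUC benchmark of Patho-scores against curated pairs
#'
#' Poses detection of disease--gene association as a binary classification
#' problem with the Patho-score as the single explanatory variable. Pairs
#' with out-of-vocabulary tokens are dropped and counted (mirroring curated
#' pairs whose tokens are absent from an embedding vocabulary). The AUC uses
#' the rank (Mann--Whitney) formulation with average ranks, so ties
#' contribute one half.
#'
#' @param emb Embedding matrix.
#' @param pairs Data frame with columns `gene`, `disease` and `class`
#'   (`"positive"` / `"negative"`).
#' @return List with `auc`, `roc_points` (data frame `threshold`, `tpr`,
#'   `fpr`) and `n_dropped` (OOV pairs).
#' @export
benchmark_auc <- function(emb, pairs) {
  stopifnot(all(c("gene", "disease", "class") %in% names(pairs)))
  vocab <- rownames(emb)
  ok <- pairs$gene %in% vocab & pairs$disease %in% vocab
  n_dropped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  pos <- pairs$class == "positive"
  if (sum(pos) == 0L || sum(!pos) == 0L)
    stop("one class is empty after out-of-vocabulary drops")
  scores <- vapply(seq_len(nrow(pairs)), function(i)
    patho_score(emb, pairs$gene[i], pairs$disease[i]), numeric(1))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  rk <- rank(scores)  # average ranks: tie-corrected Mann-Whitney
  auc <- (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  roc_points <- data.frame(
    threshold = c(Inf, thresholds),
    tpr = c(0, vapply(thresholds, function(th)
      sum(scores[pos] >= th) / n_pos, numeric(1))),
    fpr = c(0, vapply(thresholds, function(th)
      sum(scores[!pos] >= th) / n_neg, numeric(1))))
  list(auc = auc, roc_points = roc_points, n_dropped = n_dropped)
}

#' Offset consistency of relation triplets
#'
#' For triplets (disease, linked term, gene) -- e.g. a disease, one of its
#' symptoms or an impacted cell type, and a causative gene -- computes the
#' difference vectors disease->linked_term and disease->gene and reports, for
#' each relation, the cosine between the corresponding difference vectors of
#' every triplet pair. Parallel offsets across triplets (cosines near 1)
#' indicate that the embedding encodes the relation ("symptom of",
#' "causative gene for") as a consistent vector operation. PCA coordinates of
#' the (centered) token vectors are returned for plotting.
#'
#' @param emb Embedding matrix.
#' @param triplets Data frame with columns `disease`, `linked_term`, `gene`;
#'   at least two rows, all tokens in vocabulary.
#' @return List with `offset_cosines` (data frame `relation`, `triplet_i`,
#'   `triplet_j`, `cosine`) and `pca_coords` (data frame `token`, `role`,
#'   `PC1`, `PC2`).
#' @export
triplet_consistency <- function(emb, triplets) {
  stopifnot(all(c("disease", "linked_term", "gene") %in% names(triplets)))
  if (nrow(triplets) < 2L)
    stop("need at least two triplets to compare offsets")
  toks <- unlist(triplets[c("disease", "linked_term", "gene")],
    use.names = FALSE)
  missing <- setdiff(unique(toks), rownames(emb))
  if (length(missing))
    stop("token(s) not in vocabulary: ", paste(missing, collapse = ", "))
  n <- nrow(triplets)
  offsets <- list(
    linked_term = t(vapply(seq_len(n), function(i)
      emb[triplets$linked_term[i], ] - emb[triplets$disease[i], ],
      numeric(ncol(emb)))),
    gene = t(vapply(seq_len(n), function(i)
      emb[triplets$gene[i], ] - emb[triplets$disease[i], ],
      numeric(ncol(emb)))))
  rows <- list()
  for (rel in names(offsets)) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      rows[[length(rows) + 1L]] <- data.frame(relation = rel,
        triplet_i = i, triplet_j = j,
        cosine = cosine(offsets[[rel]][i, ], offsets[[rel]][j, ]))
    }
  }
  tok_mat <- emb[unique(toks), , drop = FALSE]
  pca <- prcomp(tok_mat, center = TRUE, scale. = FALSE, rank. = 2)
  role <- character(nrow(tok_mat))
  for (r in c("disease", "linked_term", "gene"))
    role[rownames(tok_mat) %in% triplets[[r]]] <- r
  list(offset_cosines = do.call(rbind, rows),
    pca_coords = data.frame(token = rownames(tok_mat), role = role,
      PC1 = pca$x[, 1], PC2 = pca$x[, 2], row.names = NULL))
}

#' Organ-wise Patho-score profile of a gene
#'
#' Scores a gene against a set of organ/tissue tokens and attaches an
#' empirical p-value per organ, using the gene x organ tokens as the null
#' pools. Out-of-vocabulary organs are reported in the `"oov"` attribute
#' rather than scored. The resulting table (organ, score, p_value) is the
#' contract consumed by body-map visualisation tools.
#'
#' @param emb Embedding matrix.
#' @param gene Gene token (must be in vocabulary).
#' @param organs Character vector of organ/tissue tokens.
#' @param n_random Null pairs per organ (default 999).
#' @param seed Integer seed.
#' @param adjust Add a Benjamini-Hochberg adjusted column `p_adj`
#'   (default `FALSE`; raw empirical p-values are the primary output).
#' @return Data frame `organ`, `score`, `p_value` (one row per in-vocabulary
#'   organ, sorted by decreasing score) with attribute `"oov"`.
#' @export
organ_profile <- function(emb, gene, organs, n_random = 999, seed = 1,
                          adjust = FALSE) {
  if (!(gene %in% rownames(emb)))
    stop("gene not in vocabulary: '", gene, "'")
  in_vocab <- organs[organs %in% rownames(emb)]
  oov <- setdiff(organs, in_vocab)
  if (length(in_vocab) == 0L) {
    out <- data.frame(organ = character(0), score = numeric(0),
      p_value = numeric(0))
    attr(out, "oov") <- oov
    return(out)
  }
  rows <- lapply(seq_along(in_vocab), function(i) {
    ps <- empirical_pvalue(emb, gene, in_vocab[i], null_pool_a = gene,
      null_pool_b = in_vocab, n_random = n_random, seed = seed + i)
    data.frame(organ = in_vocab[i], score = ps$score, p_value = ps$p_value)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$organ), , drop = FALSE]
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  attr(out, "oov") <- oov
  out
}

#' Median-normalize and log-transform an expression matrix
#'
#' Scales each sample (column) so that its median over expressed (positive)
#' genes equals the global median of sample medians, then applies
#' \eqn{\log_2(x + 1)}.
#'
#' @param mat Non-negative numeric matrix, genes x samples.
#' @return Normalized matrix of the same shape.
#' @export
normalize_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("expression values must be non-negative")
  sample_names <- colnames(mat)
  if (is.null(sample_names)) sample_names <- paste0("sample", seq_len(ncol(mat)))
  med <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    v <- v[v > 0]
    if (length(v) == 0L)
      stop("sample '", sample_names[j], "' has no expressed genes")
    median(v)
  }, numeric(1))
  target <- median(med)
  scaled <- sweep(mat, 2, target / med, "*")
  log2(scaled + 1)
}
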