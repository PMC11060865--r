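#' Train skip-gram word embeddings
#'
#' Trains word2vec-style skip-gram embeddings with negative sampling, from
#' scratch, on a tokenized corpus. The optimiser is single-threaded stochastic
#' gradient descent with a linearly decaying learning rate and a reduced
#' context window (effective radius uniform on `1..window` per center token),
#' so training is exactly reproducible from the seed.
#'
#' Defaults are corpus-scaled for interactive work (`epochs = 5`, `dim` as
#' given); the reference configuration for large pathology corpora -- 700
#' dimensions, window 5, long training -- is available by passing those values
#' explicitly.
#'
#' @param corpus Named list of token vectors (see [tokenize_corpus()]).
#' @param dim Embedding dimensionality. The large-corpus reference value is
#'   700; smaller corpora warrant smaller `dim`.
#' @param window Symmetric context window radius (default 5).
#' @param epochs Passes over the corpus.
#' @param negative Negative samples per positive pair.
#' @param min_count Tokens occurring fewer times are dropped from the
#'   vocabulary.
#' @param learning_rate Initial SGD learning rate (decays linearly to 1e-4 of
#'   its starting value).
#' @param seed Integer seed; identical seed and corpus give identical
#'   matrices.
#' @return An embedding matrix: numeric matrix with one row per vocabulary
#'   token (rownames are the tokens) and `dim` columns.
#' @export
train_skipgram <- function(corpus, dim = 700, window = 5, epochs = 5,
                           negative = 5, min_count = 2, learning_rate = 0.025,
                           seed = 1) {
  stopifnot(length(corpus) > 0, dim >= 1, window >= 1, epochs >= 1,
    negative >= 1, min_count >= 0)
  counts <- table(unlist(corpus, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L)
    stop("empty vocabulary after min_count filtering (min_count = ",
      min_count, ")")
  vocab <- names(counts)
  lookup <- seq_along(vocab) - 1L
  names(lookup) <- vocab
  docs <- lapply(corpus, function(toks) {
    ids <- lookup[toks]
    as.integer(ids[!is.na(ids)])
  })
  docs <- docs[lengths(docs) > 0L]
  mat <- .sg_train_cpp(docs, as.numeric(counts), as.integer(dim),
    as.integer(window), as.integer(epochs), as.integer(negative),
    learning_rate, as.integer(seed))
  rownames(mat) <- vocab
  mat
}

#' Mean-pooled document vector
#'
#' Represents an abstract as the arithmetic mean of the embedding vectors of
#' its in-vocabulary tokens; out-of-vocabulary tokens are skipped.
#'
#' @param tokens Character vector of tokens.
#' @param emb Embedding matrix from [train_skipgram()] or [load_vectors()].
#' @return Numeric vector of length `ncol(emb)`.
#' @export
abstract_vector <- function(tokens, emb) {
  hit <- tokens[tokens %in% rownames(emb)]
  if (length(hit) == 0L)
    stop("document has no in-vocabulary tokens; it cannot be represented")
  colMeans(emb[hit, , drop = FALSE])
}

#' Document-vector matrix for a tokenized corpus
#'
#' Applies [abstract_vector()] to every document. Documents with no
#' in-vocabulary tokens are dropped (their ids are recorded in the
#' `"dropped"` attribute) rather than erroring, since rare all-OOV documents
#' are expected when `min_count` filtering is on.
#'
#' @param tokens Named list of token vectors.
#' @param emb Embedding matrix.
#' @return Numeric matrix, one row per representable document, rownames the
#'   document ids.
#' @export
corpus_vectors <- function(tokens, emb) {
  vocab <- rownames(emb)
  ok <- vapply(tokens, function(t) any(t %in% vocab), logical(1))
  mat <- t(vapply(tokens[ok], abstract_vector, numeric(ncol(emb)), emb = emb))
  attr(mat, "dropped") <- names(tokens)[!ok]
  mat
}

#' Cosine similarity
#'
#' @param a,b Numeric vectors of equal length, both non-zero.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine undefined for zero-norm vectors")
  sum(a * b) / (na * nb)
}

#' Save embeddings in word2vec text format
#'
#' Writes the standard text format: a header line `"<vocab size> <dim>"`
#' followed by one line per token with its vector.
#'
#' @param emb Embedding matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_vectors <- function(emb, path) {
  stopifnot(is.matrix(emb), !is.null(rownames(emb)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  body <- vapply(seq_len(nrow(emb)), function(i) {
    paste(rownames(emb)[i], paste(formatC(emb[i, ], format = "g", digits = 8),
      collapse = " "))
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Load embeddings from word2vec text format
#'
#' Accepts vectors written by [save_vectors()] or by external tools using the
#' same format (e.g. transformer-derived vectors exported as text).
#'
#' @param path Path to a word2vec text file.
#' @return Embedding matrix with token rownames.
#' @export
load_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty vector file")
  header <- suppressWarnings(
    as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]))
  if (length(header) != 2L || any(is.na(header)))
    stop("malformed word2vec header: ", lines[1])
  n <- header[1]
  d <- header[2]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop("header declares ", n, " words but file has ", length(body))
  parts <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(parts) != d + 1L))
    stop("vector line length inconsistent with declared dimension ", d)
  mat <- suppressWarnings(
    t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d))))
  if (anyNA(mat)) stop("non-numeric vector entries in file")
  rownames(mat) <- vapply(parts, `[[`, "", 1L)
  mat
}
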