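# Shared fixtures. The embedding-bearing ones are expensive (a few seconds of
# skip-gram training each), so they are built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Corpus with 10 planted pairs at the given strength, plus its trained
# embedding (desk-scale configuration: dim 50, window 5, 5 epochs).
planted_fixture <- function(strength = 0.9, seed = 7) {
  memoise_fixture(sprintf("planted_%s_%d", strength, seed), function() {
    spec <- corpus_spec(n_patho = 1000, n_nonpatho = 1000,
      planted_pairs = planted_pairs(1:10, 1:10, strength = strength),
      seed = seed)
    gen <- generate_corpus(spec)
    toks <- tokenize_corpus(gen$corpus)
    emb <- train_skipgram(toks, dim = 50, window = 5, epochs = 5, seed = seed)
    list(gen = gen, toks = toks, emb = emb)
  })
}

# Topically separable two-class corpus with document vectors and labels,
# for classifier behavior checks.
separable_fixture <- function(seed = 7) {
  memoise_fixture(sprintf("separable_%d", seed), function() {
    spec <- corpus_spec(n_patho = 1000, n_nonpatho = 1000,
      class_separation = 0.9,
      planted_pairs = planted_pairs(1:10, 1:10, strength = 0.9), seed = seed)
    gen <- generate_corpus(spec)
    toks <- tokenize_corpus(gen$corpus)
    emb <- train_skipgram(toks, dim = 50, window = 5, epochs = 5, seed = seed)
    X <- corpus_vectors(toks, emb)
    y <- gen$corpus$label[match(rownames(X), gen$corpus$id)]
    list(gen = gen, X = X, y = y)
  })
}

# Null corpus: entities appear only as isolated mentions, no planted pairs.
null_fixture <- function(seed = 5) {
  memoise_fixture(sprintf("null_%d", seed), function() {
    spec <- corpus_spec(n_patho = 0, n_nonpatho = 2000, n_genes = 20,
      n_diseases = 20, isolated_entity_prob = 0.8, seed = seed)
    gen <- generate_corpus(spec)
    toks <- tokenize_corpus(gen$corpus)
    emb <- train_skipgram(toks, dim = 50, window = 5, epochs = 5, seed = seed)
    list(gen = gen, emb = emb)
  })
}

# Small deterministic embedding built by hand from a vector list.
toy_emb <- function(vectors) {
  mat <- do.call(rbind, vectors)
  rownames(mat) <- names(vectors)
  mat
}

# Random toy embedding over the given tokens.
random_emb <- function(tokens, dim = 10, seed = 1) {
  withr::with_seed(seed, {
    mat <- matrix(rnorm(length(tokens) * dim), nrow = length(tokens))
    rownames(mat) <- tokens
    mat
  })
}

# A single-layer (disease-disease) network from an edge data frame, as the
# simplest typed multiplex wrapper for graph-algorithm tests.
dd_network <- function(edges) {
  empty <- data.frame(u = character(0), v = character(0), weight = numeric(0))
  multiplex_network(edges, empty, empty)
}

# Random connected undirected graph on n nodes: a cycle backbone plus random
# chords, so no node is isolated.
random_graph_edges <- function(n, extra = n, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("d%02d", seq_len(n))
    backbone <- data.frame(u = ids, v = ids[c(2:n, 1)])
    chords <- data.frame(u = ids[sample.int(n, extra, replace = TRUE)],
      v = ids[sample.int(n, extra, replace = TRUE)])
    chords <- chords[chords$u != chords$v, , drop = FALSE]
    edges <- rbind(backbone, chords)
    edges$weight <- withr::with_seed(seed + 1,
      round(runif(nrow(edges), 0.5, 2), 3))
    edges
  })
}
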