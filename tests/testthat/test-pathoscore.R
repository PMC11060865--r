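test_that("patho_score is cosine similarity with vocabulary checks", {
  emb <- toy_emb(list(a = c(1, 0), b = c(0, 2), c = c(3, 3), d = c(2, 0)))
  expect_equal(patho_score(emb, "a", "a"), 1)
  expect_equal(patho_score(emb, "a", "b"), 0)
  expect_equal(patho_score(emb, "a", "c"), 1 / sqrt(2))
  expect_equal(patho_score(emb, "a", "d"), 1)
  expect_equal(patho_score(emb, "b", "c"), patho_score(emb, "c", "b"))
  expect_error(patho_score(emb, "a", "nope"), "'nope'")
})

test_that("empirical p-value matches brute-force counting on fixed nulls", {
  r <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(empirical_pvalue_from_null(0.25, r), 0.6)  # (2 + 1) / 5
  expect_equal(empirical_pvalue_from_null(0.99, r), 1 / 5)  # extreme high
  expect_equal(empirical_pvalue_from_null(0.05, r), 1)      # extreme low
  expect_equal(empirical_pvalue_from_null(0.3, r), 0.6)     # tie counts >=
  # brute-force agreement on random draws
  withr::with_seed(3, for (i in 1:50) {
    rr <- runif(sample(1:30, 1))
    ps <- runif(1)
    expect_equal(empirical_pvalue_from_null(ps, rr),
      (sum(rr >= ps) + 1) / (length(rr) + 1))
  })
})

test_that("p-value is monotone non-increasing in the observed score", {
  r <- withr::with_seed(1, runif(99))
  scores <- seq(-0.5, 1.2, length.out = 40)
  p <- vapply(scores, empirical_pvalue_from_null, numeric(1), r = r)
  expect_true(all(diff(p) <= 0))
  expect_equal(min(p), 1 / 100)
})

test_that("Monte-Carlo p-values are reproducible and floored at 1/(r+1)", {
  emb <- random_emb(c(paste0("g", 1:8), paste0("d", 1:8)), dim = 12, seed = 5)
  ps1 <- empirical_pvalue(emb, "g1", "d1", paste0("g", 1:8), paste0("d", 1:8),
    n_random = 99, seed = 2)
  ps2 <- empirical_pvalue(emb, "g1", "d1", paste0("g", 1:8), paste0("d", 1:8),
    n_random = 99, seed = 2)
  expect_identical(ps1, ps2)
  expect_gte(ps1$p_value, 1 / 100)
  expect_lte(ps1$p_value, 1)
  # self-pair has score 1: nothing can beat it, so p hits the floor
  top <- empirical_pvalue(emb, "g1", "g1", paste0("g", 1:8), paste0("d", 1:8),
    n_random = 99, seed = 2)
  expect_equal(top$p_value, 1 / 100)
  expect_error(empirical_pvalue(emb, "g1", "d1", "zz", "d1", n_random = 9),
    "null pool")
})

test_that("benchmark AUC matches the pairwise-concordance oracle", {
  # DERIVED example: pos (0.9, 0.7), neg (0.8, 0.1) -> 3 of 4 wins
  emb <- toy_emb(list(gA = c(1, 0), gB = c(1, 0.755), dA = c(0.9, 0.436),
    dB = c(1, 0.02), dC = c(0.1, 1)))
  # engineer scores directly instead: use brute force on synthetic scores
  auc_brute <- function(pos, neg) {
    wins <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
    mean(wins)
  }
  expect_equal(auc_brute(c(0.9, 0.7), c(0.8, 0.1)), 0.75)

  # oracle equivalence on random instances with <= 20 pairs, ties included
  withr::with_seed(7, for (i in 1:25) {
    n_tok <- sample(4:8, 1)
    emb <- random_emb(c(paste0("g", 1:n_tok), paste0("d", 1:n_tok)),
      dim = 4, seed = i)
    # duplicated vectors manufacture exact score ties
    emb[paste0("g", n_tok), ] <- emb["g1", ]
    n_pairs <- sample(4:20, 1)
    pairs <- data.frame(
      gene = paste0("g", sample(n_tok, n_pairs, TRUE)),
      disease = paste0("d", sample(n_tok, n_pairs, TRUE)),
      class = sample(c("positive", "negative"), n_pairs, TRUE))
    if (length(unique(pairs$class)) < 2) pairs$class[1:2] <- c("positive",
      "negative")
    res <- benchmark_auc(emb, pairs)
    scores <- vapply(seq_len(nrow(pairs)), function(k)
      patho_score(emb, pairs$gene[k], pairs$disease[k]), numeric(1))
    expect_equal(res$auc, auc_brute(scores[pairs$class == "positive"],
      scores[pairs$class == "negative"]))
  })
})

test_that("benchmark AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  emb <- random_emb(c(paste0("g", 1:10), paste0("d", 1:10)), dim = 6,
    seed = 11)
  pairs <- withr::with_seed(12, data.frame(
    gene = paste0("g", sample(10, 40, TRUE)),
    disease = paste0("d", sample(10, 40, TRUE)),
    class = sample(c("positive", "negative"), 40, TRUE)))
  res <- benchmark_auc(emb, pairs)
  scores <- vapply(seq_len(nrow(pairs)), function(k)
    patho_score(emb, pairs$gene[k], pairs$disease[k]), numeric(1))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = pairs$class, predictor = scores,
    levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
  expect_equal(res$auc, ref)
})

test_that("benchmark AUC has its boundary values and drops OOV pairs", {
  emb <- toy_emb(list(g1 = c(1, 0), g2 = c(0.9, 0.1), d1 = c(1, 0.05),
    d2 = c(-1, 0)))
  perfect <- data.frame(gene = c("g1", "g2"), disease = c("d1", "d2"),
    class = c("positive", "negative"))
  expect_equal(benchmark_auc(emb, perfect)$auc, 1)

  tied <- data.frame(gene = c("g1", "g1"), disease = c("d1", "d1"),
    class = c("positive", "negative"))
  expect_equal(benchmark_auc(emb, tied)$auc, 0.5)

  with_oov <- rbind(perfect, data.frame(gene = "gX", disease = "d1",
    class = "positive"))
  res <- benchmark_auc(emb, with_oov)
  expect_equal(res$n_dropped, 1L)
  expect_error(benchmark_auc(emb, data.frame(gene = c("gX", "g1"),
    disease = c("d1", "d1"), class = c("positive", "negative"))),
    "empty")
})

test_that("roc points trace a valid monotone curve", {
  emb <- random_emb(c(paste0("g", 1:6), paste0("d", 1:6)), dim = 5, seed = 3)
  pairs <- withr::with_seed(4, data.frame(
    gene = paste0("g", sample(6, 30, TRUE)),
    disease = paste0("d", sample(6, 30, TRUE)),
    class = sample(c("positive", "negative"), 30, TRUE)))
  rp <- benchmark_auc(emb, pairs)$roc_points
  expect_true(all(diff(rp$tpr) >= 0))
  expect_true(all(diff(rp$fpr) >= 0))
  expect_equal(rp$tpr[1], 0)
  expect_equal(rp$tpr[nrow(rp)], 1)
  expect_equal(rp$fpr[nrow(rp)], 1)
})

test_that("parallel relation offsets give unit cosines", {
  u <- c(1, 2, 0, -1)   # disease -> symptom offset
  w <- c(0, -1, 3, 2)   # disease -> gene offset
  d1 <- c(0.5, 0, 0, 0); d2 <- c(-2, 1, 4, 1); d3 <- c(3, 3, -2, 0)
  emb <- toy_emb(list(
    dis1 = d1, sym1 = d1 + u, gen1 = d1 + w,
    dis2 = d2, sym2 = d2 + u, gen2 = d2 + w,
    dis3 = d3, sym3 = d3 + u, gen3 = d3 + w))
  triplets <- data.frame(disease = paste0("dis", 1:3),
    linked_term = paste0("sym", 1:3), gene = paste0("gen", 1:3))
  res <- triplet_consistency(emb, triplets)
  expect_equal(res$offset_cosines$cosine, rep(1, 6))
  expect_equal(nrow(res$pca_coords), 9L)
  expect_true(all(c("PC1", "PC2") %in% names(res$pca_coords)))
})

test_that("random high-dimensional offsets are near-orthogonal", {
  toks <- as.vector(outer(c("dis", "sym", "gen"), 1:12, paste0))
  emb <- random_emb(toks, dim = 200, seed = 6)
  triplets <- data.frame(disease = paste0("dis", 1:12),
    linked_term = paste0("sym", 1:12), gene = paste0("gen", 1:12))
  res <- triplet_consistency(emb, triplets)
  expect_lt(mean(abs(res$offset_cosines$cosine)), 0.2)
})

test_that("triplet consistency validates its inputs", {
  emb <- random_emb(c("d1", "s1", "g1"), dim = 5)
  one <- data.frame(disease = "d1", linked_term = "s1", gene = "g1")
  expect_error(triplet_consistency(emb, one), "at least two")
  two <- rbind(one, data.frame(disease = "d2", linked_term = "s1",
    gene = "g1"))
  expect_error(triplet_consistency(emb, two), "d2")
})

test_that("organ profiles rank constructed associations first", {
  gene_vec <- c(1, 0.2, 0, 0)
  emb <- toy_emb(list(apoe = gene_vec, brain = gene_vec,
    liver = c(0, 1, 0.5, 0), heart = c(0, 0, 1, 1), skin = c(-1, 0, 0, 1)))
  prof <- organ_profile(emb, "apoe", c("brain", "liver", "heart", "skin"),
    n_random = 99, seed = 1)
  expect_equal(prof$organ[1], "brain")
  expect_equal(prof$score[1], 1)
  expect_equal(prof$p_value[1], min(prof$p_value))
  expect_length(attr(prof, "oov"), 0L)

  # all organs OOV: empty table plus report
  empty <- organ_profile(emb, "apoe", c("spleen", "lung"))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "oov"), c("spleen", "lung"))
  expect_error(organ_profile(emb, "nope", "brain"), "nope")
})

test_that("expression normalization scales sample medians to the global one", {
  # single cell: scale factor 1, only the log transform applies
  expect_equal(normalize_expression(matrix(1)), matrix(1))
  # sample medians 2 and 8 -> target median 5 -> factors 2.5 and 0.625,
  # making the two samples identical after scaling
  mat <- cbind(s1 = c(1, 2, 4), s2 = c(4, 8, 16))
  norm <- normalize_expression(mat)
  expect_equal(norm[, "s1"], log2(c(2.5, 5, 10) + 1), ignore_attr = TRUE)
  expect_equal(norm[, "s1"], norm[, "s2"], ignore_attr = TRUE)
  # already at a common median: fixed point of the scaling step
  flat <- cbind(a = c(1, 2, 3), b = c(2, 2, 2))
  expect_equal(normalize_expression(flat), log2(flat + 1))
  # all-zero sample is rejected by name
  bad <- cbind(good = c(1, 2), empty = c(0, 0))
  expect_error(normalize_expression(bad), "empty")
  expect_error(normalize_expression(matrix(-1)), "non-negative")
})
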