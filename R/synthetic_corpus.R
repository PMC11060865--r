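#' Specify a synthetic two-class corpus
#'
#' Defines the study conditions for a generated corpus of "patho" (pathology,
#' i.e. disease--gene related) and "nonpatho" abstracts with planted
#' gene--disease co-occurrence structure. Vocabulary tokens are synthetic
#' strings (`gene3`, `disease7`, `word42`), so every downstream stage --
#' preprocessing, embedding training, classification, scoring -- can be
#' exercised without external data.
#'
#' Background words carry topical structure: the background vocabulary is
#' partitioned into `n_topics` topics, each abstract draws one topic, and a
#' fraction `topic_purity` of its background tokens come from that topic's
#' block (the rest from the whole background vocabulary). Abstracts without
#' topical co-occurrence structure would make every word distributionally
#' identical, which degenerates word embeddings (see the package vignette);
#' real abstracts are strongly topical.
#'
#' When `class_separation > 0` the two classes prefer disjoint topic halves
#' (the first half of the topics is "pathology-flavored"): an abstract draws
#' its topic from its own class's half with probability `class_separation`
#' and uniformly otherwise. This emulates the topical distinctness of curated
#' relevant vs non-relevant abstract sets, which is what document
#' classification exploits; with the default 0 the topic mixture is identical
#' across classes and the classes differ only in entity mention structure.
#'
#' Each patho abstract picks one planted pair uniformly and, with probability
#' equal to that pair's `strength`, mentions the gene and the disease at two
#' independent random positions. Nonpatho abstracts contain background words
#' and, with probability `isolated_entity_prob`, a single isolated gene OR
#' disease mention -- never a gene--disease pair, which is the hard guarantee
#' the two classes are built on.
#'
#' @param n_patho,n_nonpatho Number of abstracts per class.
#' @param n_genes,n_diseases Entity vocabulary sizes.
#' @param n_background_words Background vocabulary size.
#' @param n_topics Number of background topics (default 20).
#' @param topic_purity Fraction of background tokens drawn from the
#'   abstract's own topic block (default 0.8).
#' @param class_separation Probability that an abstract's topic comes from its
#'   own class's topic half (default 0: classes share one topic mixture).
#' @param planted_pairs Data frame with columns `gene`, `disease` (integer
#'   indices into the entity vocabularies) and `strength` (co-mention
#'   probability in \[0, 1\]). May have zero rows for a null corpus.
#' @param abstract_length Mean token count per abstract (Poisson-distributed,
#'   floored at 3 so a co-mention always fits).
#' @param isolated_entity_prob Probability that a nonpatho abstract carries one
#'   isolated entity mention.
#' @param seed Integer seed making generation fully reproducible.
#' @return A `corpus_spec` list.
#' @examples
#' spec <- corpus_spec(n_patho = 10, n_nonpatho = 10,
#'   planted_pairs = planted_pairs(1:2, 1:2, strength = 0.9), seed = 1)
#' @export
corpus_spec <- function(n_patho = 1000, n_nonpatho = 1000, n_genes = 50,
                        n_diseases = 50, n_background_words = 500,
                        n_topics = 20, topic_purity = 0.8,
                        class_separation = 0,
                        planted_pairs = data.frame(gene = integer(0),
                          disease = integer(0), strength = numeric(0)),
                        abstract_length = 120, isolated_entity_prob = 0.5,
                        seed = 1) {
  stopifnot(n_patho >= 0, n_nonpatho >= 0, n_genes >= 1, n_diseases >= 1,
    n_background_words >= 1, n_topics >= 1,
    topic_purity >= 0, topic_purity <= 1,
    class_separation >= 0, class_separation <= 1, abstract_length > 0,
    isolated_entity_prob >= 0, isolated_entity_prob <= 1)
  planted_pairs <- as.data.frame(planted_pairs)
  if (nrow(planted_pairs)) {
    stopifnot(all(c("gene", "disease", "strength") %in% names(planted_pairs)))
    if (any(planted_pairs$gene < 1 | planted_pairs$gene > n_genes) ||
        any(planted_pairs$disease < 1 | planted_pairs$disease > n_diseases))
      stop("planted pair references an entity outside 1..n_genes / 1..n_diseases")
    if (any(planted_pairs$strength < 0 | planted_pairs$strength > 1))
      stop("planted strengths must lie in [0, 1]")
  }
  if (abstract_length < 3)
    stop("abstract_length too small to hold a planted co-mention plus background")
  structure(list(n_patho = as.integer(n_patho),
    n_nonpatho = as.integer(n_nonpatho), n_genes = as.integer(n_genes),
    n_diseases = as.integer(n_diseases),
    n_background_words = as.integer(n_background_words),
    n_topics = as.integer(n_topics), topic_purity = topic_purity,
    class_separation = class_separation,
    planted_pairs = planted_pairs, abstract_length = abstract_length,
    isolated_entity_prob = isolated_entity_prob, seed = as.integer(seed)),
    class = "corpus_spec")
}

#' Build a planted-pair table
#'
#' @param gene,disease Integer entity indices (recycled to equal length).
#' @param strength Co-mention probability, recycled.
#' @return Data frame suitable for the `planted_pairs` field of [corpus_spec()].
#' @export
planted_pairs <- function(gene, disease, strength = 0.9) {
  data.frame(gene = as.integer(gene), disease = as.integer(disease),
    strength = rep_len(strength, max(length(gene), length(disease))))
}

#' Generate a synthetic labeled corpus with planted associations
#'
#' Draws a corpus according to a [corpus_spec()]. Generation is deterministic
#' given the seed carried by the [corpus_spec()]: two calls with the same
#' specification produce byte-identical corpora.
#'
#' @param spec A [corpus_spec()].
#' @return A list with elements `corpus` (abstract data frame, as from
#'   [read_abstracts()]) and `truth` (data frame `gene`, `disease`,
#'   `is_planted`, carrying the full entity universe in attributes `genes` and
#'   `diseases`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  genes <- paste0("gene", seq_len(spec$n_genes))
  diseases <- paste0("disease", seq_len(spec$n_diseases))
  background <- paste0("word", seq_len(spec$n_background_words))
  topic_blocks <- split(background,
    rep(seq_len(spec$n_topics), length.out = length(background)))
  pp <- spec$planted_pairs

  n_topics <- length(topic_blocks)
  patho_topics <- seq_len(ceiling(n_topics / 2))
  draw_background <- function(len, class) {
    topic <- if (runif(1) < spec$class_separation) {
      own <- if (class == "patho") patho_topics
        else setdiff(seq_len(n_topics), patho_topics)
      if (length(own) == 1L) own else sample(own, 1L)
    } else {
      sample.int(n_topics, 1L)
    }
    block <- topic_blocks[[topic]]
    topical <- runif(len) < spec$topic_purity
    out <- character(len)
    out[topical] <- sample(block, sum(topical), replace = TRUE)
    out[!topical] <- sample(background, sum(!topical), replace = TRUE)
    out
  }

  withr::with_seed(spec$seed, {
    texts <- character(spec$n_patho + spec$n_nonpatho)
    ids <- character(length(texts))
    labels <- character(length(texts))
    for (i in seq_len(spec$n_patho)) {
      len <- max(3L, rpois(1, spec$abstract_length))
      toks <- draw_background(len, "patho")
      if (nrow(pp)) {
        j <- if (nrow(pp) == 1L) 1L else sample.int(nrow(pp), 1L)
        if (runif(1) < pp$strength[j]) {
          at <- sample.int(len, 2L)
          toks[at[1L]] <- genes[pp$gene[j]]
          toks[at[2L]] <- diseases[pp$disease[j]]
        }
      }
      ids[i] <- sprintf("patho%05d", i)
      labels[i] <- "patho"
      texts[i] <- paste(toks, collapse = " ")
    }
    for (i in seq_len(spec$n_nonpatho)) {
      len <- max(3L, rpois(1, spec$abstract_length))
      toks <- draw_background(len, "nonpatho")
      if (runif(1) < spec$isolated_entity_prob) {
        ent <- if (runif(1) < 0.5) sample(genes, 1L) else sample(diseases, 1L)
        toks[sample.int(len, 1L)] <- ent
      }
      k <- spec$n_patho + i
      ids[k] <- sprintf("nonpatho%05d", i)
      labels[k] <- "nonpatho"
      texts[k] <- paste(toks, collapse = " ")
    }
  })

  corpus <- data.frame(id = ids, text = texts, label = labels,
    stringsAsFactors = FALSE)
  corpus$species <- I(rep(list(character(0)), nrow(corpus)))

  truth <- data.frame(
    gene = genes[pp$gene], disease = diseases[pp$disease],
    is_planted = rep(TRUE, nrow(pp)), stringsAsFactors = FALSE)
  attr(truth, "genes") <- genes
  attr(truth, "diseases") <- diseases
  list(corpus = corpus, truth = truth)
}

#' Build a benchmark pair table from a truth table
#'
#' Positives are the planted pairs; negatives are sampled uniformly without
#' replacement from the non-planted cells of the gene x disease grid,
#' mirroring benchmark construction by randomly pairing genes with diseases.
#'
#' @param truth Truth table from [generate_corpus()].
#' @param n_negative Number of random negative pairs.
#' @param seed Integer seed.
#' @param genes,diseases Entity universes; default to the attributes carried
#'   by `truth`.
#' @return Data frame with columns `gene`, `disease`, `class`
#'   (`"positive"` / `"negative"`).
#' @export
generate_benchmark_pairs <- function(truth, n_negative, seed = 1,
                                     genes = attr(truth, "genes"),
                                     diseases = attr(truth, "diseases")) {
  if (is.null(genes) || is.null(diseases))
    stop("entity universe unknown: supply 'genes' and 'diseases'")
  grid <- expand.grid(gene = genes, disease = diseases,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  planted_key <- paste(truth$gene, truth$disease, sep = "\r")
  grid_key <- paste(grid$gene, grid$disease, sep = "\r")
  avail <- grid[!(grid_key %in% planted_key), , drop = FALSE]
  if (n_negative > nrow(avail))
    stop("n_negative (", n_negative, ") exceeds the ", nrow(avail),
      " available non-planted combinations")
  neg <- withr::with_seed(seed,
    avail[sample.int(nrow(avail), n_negative), , drop = FALSE])
  out <- rbind(
    data.frame(gene = truth$gene, disease = truth$disease,
      class = rep("positive", nrow(truth)), stringsAsFactors = FALSE),
    data.frame(gene = neg$gene, disease = neg$disease,
      class = rep("negative", nrow(neg)), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
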