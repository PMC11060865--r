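---
title: "Mining disease-gene associations from abstracts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease-gene associations from abstracts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most of what is known about which genes drive which diseases sits in free
text: millions of biomedical abstracts, far beyond what curation teams can
read. `pathomine` implements a literature-mining pipeline that turns a corpus
of entity-tagged abstracts into quantitative disease-gene association scores
and candidate rankings:

1. **Corpus preparation** -- tokenization, stop-word removal, merging of
   multi-word named entities into single tokens (`adipose tissue` becomes
   `adipose_tissue`), optional filtering to human-relatable abstracts.
2. **Stratification** -- a binary classifier on mean-pooled document vectors
   separates abstracts that describe a gene's role in disease pathogenesis
   ("patho-abstracts") from the rest; the pathology corpus is selected at a
   stringent probability threshold (0.8).
3. **Embeddings** -- skip-gram word vectors with negative sampling are
   trained from scratch on the stratified corpus.
4. **Patho-scores** -- the cosine similarity between two term vectors
   measures how strongly the terms associate in pathology literature, with a
   Monte-Carlo empirical p-value against random term pairs.
5. **Benchmarking** -- ROC-AUC of Patho-scores against curated positive
   pairs and random negative pairs, with the score as the single explanatory
   variable.
6. **Network diffusion** -- random walk with restart (RWR) over a multiplex
   disease-gene-protein network ranks latent candidates near seed nodes.
7. **Genomic hotspots** -- 1-Mb binning of gene density against literature
   mention density, compared by Spearman rank correlation.

A synthetic-corpus generator with planted gene-disease co-occurrence
structure makes the whole pipeline testable end to end without downloads.

## Models and statistics

### Skip-gram with negative sampling

For a center token $w$ and a context token $c$ within a symmetric window of
radius 5, the model maximises
$\log \sigma(v_w \cdot u_c) + \sum_{j=1}^{k} \log \sigma(-v_w \cdot u_{n_j})$
with $k = 5$ negatives $n_j$ drawn from the unigram distribution raised to
the 0.75 power. Optimisation is single-threaded SGD with a linearly decaying
learning rate (initial 0.025, floor $10^{-4}$ of the initial value) and a
*reduced window*: the effective radius per center is uniform on
`1..window`, as in the reference word2vec implementation. All randomness
(initialisation, window reduction, negative draws) comes from an internal
xorshift generator seeded by the `seed` argument, so a given corpus and seed
reproduce the embedding matrix bit for bit. Tokens occurring fewer than
`min_count = 2` times are dropped. A one-word vocabulary admits no
informative training triples, so the initialised vectors are returned
untouched.

The large-corpus reference configuration is 700 dimensions and long
training; the package defaults are corpus-scaled (dimension as given by the
caller, 5 epochs) because the synthetic study corpora hold $10^5$--$10^6$
tokens, not billions. Negative sampling was chosen over hierarchical softmax
as the conventional default where the architecture is otherwise unspecified.

### Patho-score and its empirical p-value

The Patho-score of a term pair is the cosine similarity of their vectors.
It is a *similarity* (larger = more associated): the pipeline treats larger
scores as stronger associations throughout, so an observed score $PS$ is
tested against null scores $r_1, \dots, r_m$ of random term pairs with the
add-one empirical p-value

$$p = \frac{\#\{i : r_i \ge PS\} + 1}{m + 1}.$$

Ties count against significance, the smallest attainable value is
$1/(m+1)$, and the default is $m = 999$ null pairs sampled with replacement
(excluding the observed pair itself). Null pools follow the context:
gene x disease tokens for disease-gene scores, gene x organ tokens for organ
profiles. Organ profiles report raw empirical p-values; a
Benjamini-Hochberg column is optional.

### ROC-AUC benchmark

Association detection is posed as binary classification with the Patho-score
as the only explanatory variable. The AUC uses the rank (Mann-Whitney)
formulation with average ranks, so exact score ties contribute one half;
pairs whose tokens fell out of the vocabulary are dropped and counted,
mirroring curated pairs absent from an embedding vocabulary.

### Classifier stage

Document vectors are arithmetic means of in-vocabulary token vectors.
Labeled abstracts are split 75:25 with stratification; gradient boosting
(100 rounds, learning rate 0.3) is the default backend, with SVM (degree-3
polynomial kernel, balanced class weights), logistic regression, random
forest (depth 2) and a small MLP behind the same interface. Cohen's kappa
$(p_o - p_e)/(1 - p_e)$ is the guiding metric because the abstract classes
are imbalanced in practice. Two separate cutoffs exist deliberately: the
0.5 probability cut for evaluation metrics and the 0.8 corpus-selection
threshold of `stratify_corpus()`; probabilities are not recalibrated before
thresholding. Manual annotations are aggregated by majority vote (ties
resolve to `unlabeled` and are reported) and their reliability measured by
Krippendorff's alpha with the nominal metric, computed from the coincidence
matrix of pairable values.

### Random walk with restart

With a column-stochastic transition matrix $M = A D^{-1}$ over the
aggregated network, the walk iterates
$p_{t+1} = (1 - r)\,M p_t + r\,p_0$ with restart probability $r = 0.7$ and
$p_0$ uniform over the seed nodes, until the L1 change falls below
$10^{-10}$ (at most 1000 iterations). The aggregation sums the three layer
adjacencies -- disease-disease, disease-gene, protein-protein -- with unit
layer weights (configurable): the iteration above is the monoplex equation
on the layer-summed graph, which is exactly the recurrence stated; a
supra-adjacency multiplex walk with inter-layer jump parameters is out of
scope. Isolated nodes get zero columns and the vector is renormalised after
each update so total mass stays 1. `rwr_exact()` solves
$p = r (I - (1-r) M)^{-1} p_0$ directly and serves as the oracle the power
iteration is tested against. Candidate lists take the top `k = 15` nodes of
a type by probability, ties broken lexicographically, seeds excluded.

### Hotspots

Each chromosome is divided into contiguous 1-Mb windows; a gene belongs to
the window containing its *start* coordinate (the spanning rule had to be
fixed somewhere; start-assignment keeps every gene in exactly one bin).
Mentions are counted at token-occurrence granularity -- a gene named twice
in one abstract counts twice -- and only exact merged tokens are counted,
not synonyms. Coordinates are 1-based inclusive on input, bins 0-based.
Per-bin gene counts and mention counts are compared with tie-aware Spearman
correlation.

## The synthetic corpus: what it emulates, and what not

`corpus_spec()` / `generate_corpus()` produce a two-class corpus:

* **Topical background.** The background vocabulary (500 words by default)
  is partitioned into 20 topics; each abstract draws one topic and takes 80%
  of its background tokens from that topic's block (`topic_purity`).
  This is essential, not cosmetic: in a corpus whose background is a single
  uniform distribution, every token has the same context distribution, all
  pointwise mutual information is constant, and the skip-gram objective is
  optimised by a rank-one embedding in which *every* cosine approaches 1 --
  we observed exactly this collapse, and it makes cosine uninformative.
  Topic structure is also what real abstracts have.
* **Planted associations.** Each patho abstract picks one planted
  (gene, disease) pair and, with probability `strength`, mentions both
  members at independent random positions. Co-occurrence within the
  training window is therefore probabilistic (more likely the longer the
  window and the shorter the abstract), and association strength is
  controlled by how many abstracts co-mention the pair.
* **The hard class guarantee.** Non-patho abstracts contain at most one
  isolated entity mention and never a planted pair. This is enforced by
  construction, not probabilistically.
* **Class-topic separation.** With `class_separation > 0` the classes
  prefer disjoint topic halves, emulating the topical distinctness of
  curated relevant/non-relevant abstract sets; it is what makes the
  document-classification stage learnable. The default is 0 so that
  embedding-benchmark corpora carry no class signal beyond the mentions.
* **Abstract length** defaults to a Poisson mean of 120 tokens,
  a realistic content-token count for a biomedical abstract after stop-word
  removal.

What the generator does *not* emulate: Zipfian word frequencies (word
frequencies are uniform within a topic block), grammar and word order
beyond co-occurrence, polysemy, entity synonymy, and the long-tailed
document-length distribution of real corpora. Passing tests on this
generator demonstrate that the pipeline's statistical machinery behaves as
specified -- recovery of planted signal, calibrated null p-values, oracle
agreement -- not that any particular real-world AUC would be attained;
headline numbers from full-scale corpora (millions of abstracts, curated
databases, transformer embeddings) are outside desk scale by design.

## Numerical and design choices

* **Preprocessing order.** Entity n-grams are merged *before* stop-word
  removal (so `loss of heterozygosity` survives as one token) using greedy
  longest-match, left to right -- the conventional gazetteer rule; ties in
  match length cannot occur at one position, and the leftmost match wins
  across positions. Only leading and trailing punctuation is stripped, after
  merging, so hyphenated entity names match and merged underscore tokens
  survive re-processing; `preprocess()` is idempotent on its own output.
* **Stop-word list.** A fixed English list ships with the package
  (reproducibility over configurability); callers may substitute their own.
* **Species filter.** The human-relatable keyword set (human, boy, girl,
  children, man, woman, men, women, patients, patient) matches species tags
  when present and falls back to token matching otherwise, with any-match
  semantics.
* **p-value orientation.** The empirical p-value counts null scores
  *greater than or equal to* the observed score: large similarity gives
  small p, and ties are conservative. The minimum is $1/(m+1)$, never 0.
* **Expression normalisation** scales each sample so its median over
  expressed (positive) genes equals the median of sample medians, then
  applies $\log_2(x + 1)$; base 2 with pseudo-count 1 is the field's usual
  choice where unstated.
* **Dangling RWR nodes.** Zero columns lose mass under $M$; the restart
  term plus per-iteration renormalisation restores a probability vector.
* **Convergence.** L1 norm, tolerance $10^{-10}$, cap 1000 iterations; the
  power iteration agrees with the closed-form solve to well under $10^{-8}$
  on all tested graphs.
* **Problem sizes.** The validation corpora use 1000 abstracts per class,
  50 genes x 50 diseases with 10 planted pairs, 50-dimensional vectors, 5
  epochs; null-calibration uses 500 pairs with 199 null draws each. These
  sizes give stable statistics while keeping a full pipeline run in minutes
  on one core.

## Known limitations

* The skip-gram trainer is deliberately single-threaded for exact
  reproducibility; it is not a replacement for large-scale tooling on
  billion-token corpora.
* "Cosine distance" in parts of the literature on this method actually
  behaves as a similarity; this package consistently uses cosine
  *similarity* and never the 1-minus form.
* The multiplex walk aggregates layers by summation; layer-specific restart
  weighting and supra-adjacency coupling are not implemented.
* Gene mention counting requires exact preprocessed tokens; aliases and
  synonyms must be resolved upstream (e.g. in the entity lexicon).
* Out-of-vocabulary terms cannot be scored -- unlike subword or
  transformer models, a word2vec-style vocabulary is closed.
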