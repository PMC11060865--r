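#' Stratified train/test split
#'
#' Splits labeled items into disjoint train and test index sets, preserving
#' class proportions (within one item per class) when `stratified = TRUE`.
#' The reference protocol uses a 75:25 split.
#'
#' @param labels Character or factor vector of class labels.
#' @param ratio Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed; the same seed gives identical partitions.
#' @param stratified Preserve per-class proportions (default `TRUE`).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, ratio = 0.75, seed = 1,
                             stratified = TRUE) {
  labels <- as.character(labels)
  if (any(table(labels) < 1L) || length(unique(labels)) < 2L)
    stop("need at least one item in each of two classes")
  if (ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly between 0 and 1 (got ", ratio, ")")
  idx <- withr::with_seed(seed, {
    if (stratified) {
      train <- integer(0)
      for (cl in unique(labels)) {
        members <- which(labels == cl)
        n_train <- round(length(members) * ratio)
        train <- c(train, sample(members, n_train))
      }
      sort(train)
    } else {
      sort(sample(seq_along(labels), round(length(labels) * ratio)))
    }
  })
  test <- setdiff(seq_along(labels), idx)
  if (length(idx) == 0L || length(test) == 0L)
    stop("split leaves an empty partition; adjust ratio")
  list(train = idx, test = test)
}

backend_defaults <- list(
  gradient_boosting = list(nrounds = 100, eta = 0.3, max_depth = 6),
  logistic_regression = list(),
  svm = list(degree = 3, cost = 1),
  random_forest = list(num_trees = 500, max_depth = 2),
  mlp = list(size = 16, decay = 1e-3, maxit = 300)
)

#' Train an abstract classifier
#'
#' Fits a binary classifier mapping document vectors to patho / nonpatho
#' labels. Gradient boosting is the default backend (it gave the best
#' agreement-corrected performance in the reference comparison, with 100
#' boosting rounds at learning rate 0.3); SVM (degree-3 polynomial kernel
#' with balanced class weights), logistic regression, random forest (depth 2)
#' and a small MLP are available behind the same surface.
#'
#' @param X Numeric matrix of document vectors, one row per abstract.
#' @param y Labels aligned with rows of `X`; values `"patho"` / `"nonpatho"`
#'   (both classes must be present).
#' @param backend One of `"gradient_boosting"`, `"logistic_regression"`,
#'   `"svm"`, `"random_forest"`, `"mlp"`.
#' @param hyperparameters Named list overriding the backend defaults.
#' @param seed Integer seed for stochastic backends.
#' @return A fitted `stratifier_model`.
#' @export
train_classifier <- function(X, y, backend = c("gradient_boosting",
                             "logistic_regression", "svm", "random_forest",
                             "mlp"), hyperparameters = list(), seed = 1) {
  backend <- match.arg(backend)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (!all(y %in% c("patho", "nonpatho")))
    stop("labels must be 'patho' or 'nonpatho'")
  if (length(unique(y)) < 2L)
    stop("both classes must be present to train a classifier")
  hp <- utils::modifyList(backend_defaults[[backend]], hyperparameters)
  y01 <- as.integer(y == "patho")
  colnames(X) <- paste0("V", seq_len(ncol(X)))

  fit <- withr::with_seed(seed, switch(backend,
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
        max_depth = hp$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y01, nthread = 1),
      nrounds = hp$nrounds, verbose = 0),
    logistic_regression = {
      df <- data.frame(X)
      df$.y <- y01
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    svm = {
      w <- length(y) / (2 * table(factor(y, levels = c("nonpatho", "patho"))))
      e1071::svm(X, factor(y, levels = c("nonpatho", "patho")),
        kernel = "polynomial", degree = hp$degree, cost = hp$cost,
        class.weights = c(nonpatho = unname(w["nonpatho"]),
          patho = unname(w["patho"])),
        probability = TRUE)
    },
    random_forest = ranger::ranger(x = X,
      y = factor(y, levels = c("nonpatho", "patho")),
      num.trees = hp$num_trees, max.depth = hp$max_depth,
      probability = TRUE, num.threads = 1, seed = seed),
    mlp = nnet::nnet(X, y01, size = hp$size, decay = hp$decay,
      maxit = hp$maxit, entropy = TRUE, trace = FALSE)
  ))

  structure(list(backend = backend, hyperparameters = hp, fit = fit,
    dim = ncol(X)), class = "stratifier_model")
}

#' Patho-class probabilities
#'
#' @param model A fitted [train_classifier()] model.
#' @param X Document-vector matrix.
#' @return Numeric vector of P(patho) in \[0, 1\], one per row of `X`.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "stratifier_model"))
  X <- as.matrix(X)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  p <- switch(model$backend,
    gradient_boosting = predict(model$fit,
      xgboost::xgb.DMatrix(X, nthread = 1)),
    logistic_regression = as.numeric(predict(model$fit,
      newdata = data.frame(X), type = "response")),
    svm = {
      pr <- predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "patho"]
    },
    random_forest = predict(model$fit, data = X,
      num.threads = 1)$predictions[, "patho"],
    mlp = as.numeric(predict(model$fit, X))
  )
  unname(pmin(pmax(p, 0), 1))
}

#' Classification metrics from a 2x2 confusion table
#'
#' Metrics are recomputable from the table alone: accuracy, precision,
#' recall and F1 for the patho class, and Cohen's kappa
#' \eqn{(p_o - p_e)/(1 - p_e)} with expected agreement from the marginal
#' products. The table is oriented `confusion[truth, prediction]` with rows
#' and columns ordered (patho, nonpatho).
#'
#' @param confusion 2x2 numeric matrix of counts.
#' @return List with fields `accuracy`, `precision`, `recall`, `f1`, `kappa`
#'   and the `confusion` table itself.
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(2L, 2L)), all(confusion >= 0))
  n <- sum(confusion)
  tp <- confusion[1, 1]; fn <- confusion[1, 2]
  fp <- confusion[2, 1]; tn <- confusion[2, 2]
  po <- (tp + tn) / n
  pe <- (sum(confusion[1, ]) * sum(confusion[, 1]) +
    sum(confusion[2, ]) * sum(confusion[, 2])) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = po, precision = precision, recall = recall, f1 = f1,
    kappa = kappa, confusion = confusion)
}

#' Evaluate a classifier on labeled data
#'
#' Thresholds P(patho) at `cutoff` (default 0.5; this evaluation cut is a
#' separate parameter from the corpus-selection threshold of
#' [stratify_corpus()]) and reports the metrics of [confusion_metrics()].
#' Kappa is the guiding metric under class imbalance.
#'
#' @param model Fitted model.
#' @param X Document-vector matrix.
#' @param y True labels (`"patho"` / `"nonpatho"`).
#' @param cutoff Probability cut for the confusion table.
#' @return An evaluation report (see [confusion_metrics()]).
#' @export
evaluate_classifier <- function(model, X, y, cutoff = 0.5) {
  y <- as.character(y)
  p <- predict_proba(model, X)
  pred <- ifelse(p >= cutoff, "patho", "nonpatho")
  lv <- c("patho", "nonpatho")
  confusion <- table(factor(y, levels = lv), factor(pred, levels = lv))
  confusion_metrics(unclass(as.matrix(confusion)))
}

#' Select pathology-relevant abstracts at a probability threshold
#'
#' Applies a fitted classifier to document vectors and keeps the abstracts
#' whose patho-class probability is at least `threshold` (default 0.8, the
#' stringent corpus-selection criterion), preserving input order. The
#' selected count is monotone non-increasing in the threshold.
#'
#' @param model Fitted model.
#' @param corpus Corpus data frame.
#' @param vectors Document-vector matrix with rownames equal to abstract ids
#'   (rows for a subset of the corpus are allowed; abstracts without a vector
#'   are never selected).
#' @param threshold Selection threshold in \[0, 1\].
#' @return The selected subset of `corpus`, with a `proba` column appended.
#' @export
stratify_corpus <- function(model, corpus, vectors, threshold = 0.8) {
  p <- predict_proba(model, vectors)
  names(p) <- rownames(vectors)
  select_at_threshold(corpus, p, threshold)
}

# threshold selection on precomputed probabilities; order preserved,
# abstracts without a probability never selected
select_at_threshold <- function(corpus, proba, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  proba <- proba[corpus$id]
  keep <- !is.na(proba) & proba >= threshold
  out <- corpus[keep, , drop = FALSE]
  out$proba <- unname(proba[keep])
  rownames(out) <- NULL
  out
}

#' Krippendorff's alpha for nominal annotations
#'
#' Chance-corrected inter-annotator agreement \eqn{\alpha = 1 - D_o/D_e}
#' computed from the coincidence matrix of pairable values, with the nominal
#' difference metric. Items coded by fewer than two annotators are skipped;
#' missing codes are `NA`.
#'
#' @param annotations Matrix with one row per annotator and one column per
#'   item; entries are nominal codes (character, factor or numeric), `NA` for
#'   missing.
#' @return Alpha in \[-1, 1\]. Perfect agreement gives 1 (also when expected
#'   disagreement is zero because only one code occurs).
#' @export
krippendorff_alpha <- function(annotations) {
  annotations <- as.matrix(annotations)
  if (nrow(annotations) < 2L) stop("need at least two annotators")
  codes <- sort(unique(as.character(annotations[!is.na(annotations)])))
  if (length(codes) == 0L) stop("no coded values")
  k <- length(codes)
  coincidence <- matrix(0, k, k, dimnames = list(codes, codes))
  for (item in seq_len(ncol(annotations))) {
    vals <- as.character(annotations[, item])
    vals <- vals[!is.na(vals)]
    m <- length(vals)
    if (m < 2L) next
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      coincidence[vals[i], vals[j]] <-
        coincidence[vals[i], vals[j]] + 1 / (m - 1)
    }
  }
  n <- sum(coincidence)
  if (n == 0) stop("no pairable values: every item has fewer than two codes")
  d_o <- sum(coincidence) - sum(diag(coincidence))
  marg <- rowSums(coincidence)
  d_e <- (sum(marg)^2 - sum(marg^2)) / (n - 1)
  d_o <- d_o / n
  d_e <- d_e / n
  if (d_e == 0) return(if (d_o == 0) 1 else NA_real_)
  1 - d_o / d_e
}

#' Majority-vote consensus labels
#'
#' Reduces multi-annotator codes to one label per item by modal vote; exact
#' ties resolve to `"unlabeled"` and the tied items are reported in the
#' `"ties"` attribute.
#'
#' @param annotations Matrix annotator x item of nominal codes (`NA` missing).
#' @return Character vector of consensus labels (one per item) with attribute
#'   `"ties"` giving the indices of tied items.
#' @export
majority_vote <- function(annotations) {
  annotations <- as.matrix(annotations)
  out <- character(ncol(annotations))
  ties <- integer(0)
  for (item in seq_len(ncol(annotations))) {
    vals <- as.character(annotations[, item])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      out[item] <- "unlabeled"
      next
    }
    tab <- sort(table(vals), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) {
      out[item] <- "unlabeled"
      ties <- c(ties, item)
    } else {
      out[item] <- names(tab)[1]
    }
  }
  attr(out, "ties") <- ties
  out
}
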